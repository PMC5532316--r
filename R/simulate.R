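# Seeded synthetic fixtures with known ground truth for every stage:
# transcriptome, probes, drug-perturbed instance intensities, and disease
# profiles with a planted best-matching drug. All randomness flows from one
# seed; each artifact derives its own stream seed (see .deriveSeed) so the
# stages are independently reproducible.

#' Fixture specification
#'
#' Study conditions of the synthetic generator. Defaults describe a
#' desk-scale lncRNA panel: 60 lncRNA genes (a scaled-down measurable
#' universe) plus 20 protein-coding genes, 1-3 isoforms of 200-400 nt each,
#' 5 probes per lncRNA gene with 10\% made cross-biotype and 5 decoys, 10
#' drugs x 3 instances each perturbing 10 genes by +/-1.5 log2 units over
#' probe noise sd 0.3, and a two-class disease profile (6 samples per
#' class) shifting 8 members of one target drug's set by 1.5.
#'
#' @param seed master seed.
#' @param n_lnc_genes,n_coding_genes gene counts per biotype.
#' @param transcripts_per_gene integer range (length 2) of isoforms.
#' @param transcript_length integer range (length 2) of lengths in nt.
#' @param probes_per_gene probes sampled per lncRNA gene.
#' @param n_decoy_probes random probes verified absent from all transcripts.
#' @param cross_biotype_fraction fraction of lncRNA probes additionally
#'   copied into a protein-coding transcript.
#' @param n_drugs,instances_per_drug perturbation design.
#' @param effect_genes_per_drug genes shifted per drug.
#' @param effect_log2fc log2 shift magnitude in treatment samples.
#' @param noise_sd probe-level Gaussian noise sd (log2 scale).
#' @param n_disease_samples_per_class samples per phenotype class.
#' @param target_drug_overlap number of target-set members shifted in the
#'   disease profile.
#' @return A named list.
#' @export
fixtureSpec <- function(seed = 1L,
                        n_lnc_genes = 60L, n_coding_genes = 20L,
                        transcripts_per_gene = c(1L, 3L),
                        transcript_length = c(200L, 400L),
                        probes_per_gene = 5L, n_decoy_probes = 5L,
                        cross_biotype_fraction = 0.1,
                        n_drugs = 10L, instances_per_drug = 3L,
                        effect_genes_per_drug = 10L,
                        effect_log2fc = 1.5, noise_sd = 0.3,
                        n_disease_samples_per_class = 6L,
                        target_drug_overlap = 8L) {
  spec <- list(seed = as.integer(seed),
               n_lnc_genes = as.integer(n_lnc_genes),
               n_coding_genes = as.integer(n_coding_genes),
               transcripts_per_gene = as.integer(transcripts_per_gene),
               transcript_length = as.integer(transcript_length),
               probes_per_gene = as.integer(probes_per_gene),
               n_decoy_probes = as.integer(n_decoy_probes),
               cross_biotype_fraction = cross_biotype_fraction,
               n_drugs = as.integer(n_drugs),
               instances_per_drug = as.integer(instances_per_drug),
               effect_genes_per_drug = as.integer(effect_genes_per_drug),
               effect_log2fc = effect_log2fc, noise_sd = noise_sd,
               n_disease_samples_per_class =
                 as.integer(n_disease_samples_per_class),
               target_drug_overlap = as.integer(target_drug_overlap))
  counts <- spec[c("n_lnc_genes", "n_coding_genes", "probes_per_gene",
                   "n_decoy_probes", "n_drugs", "instances_per_drug",
                   "effect_genes_per_drug", "n_disease_samples_per_class",
                   "target_drug_overlap")]
  if (any(unlist(counts) < 0L)) stop("counts must be >= 0")
  if (cross_biotype_fraction < 0 || cross_biotype_fraction > 1)
    stop("cross_biotype_fraction must be in [0, 1]")
  if (effect_log2fc < 0 || noise_sd < 0)
    stop("effect_log2fc and noise_sd must be >= 0")
  spec
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

#' Simulate an annotated transcriptome
#'
#' Random i.i.d.-uniform nucleotide sequences grouped into genes with the
#' configured isoform counts and biotypes; deterministic per seed.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list with \code{transcripts} (a \code{\link{transcriptSet}}) and
#'   \code{annotation} (data.frame: transcript_id, gene_id, gene_name,
#'   biotype).
#' @export
simulateTranscriptome <- function(spec = fixtureSpec()) {
  if (spec$n_lnc_genes + spec$n_coding_genes == 0L)
    stop("at least one gene required")
  set.seed(.deriveSeed(spec$seed, "transcriptome"))
  genes <- c(sprintf("LNCG%04d", seq_len(spec$n_lnc_genes)),
             sprintf("CODG%04d", seq_len(spec$n_coding_genes)))
  biotypes <- rep(c("lncRNA", "protein_coding"),
                  c(spec$n_lnc_genes, spec$n_coding_genes))
  ann <- list()
  seqs <- character(0)
  for (i in seq_along(genes)) {
    k <- sample(spec$transcripts_per_gene[1]:spec$transcripts_per_gene[2], 1L)
    for (j in seq_len(k)) {
      tid <- sprintf("%s.T%d", genes[i], j)
      len <- sample(spec$transcript_length[1]:spec$transcript_length[2], 1L)
      seqs[tid] <- .randSeq(len)
      ann[[tid]] <- data.frame(transcript_id = tid, gene_id = genes[i],
                               gene_name = paste0("name-", genes[i]),
                               biotype = biotypes[i],
                               stringsAsFactors = FALSE)
    }
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  tx <- transcriptSet(seqs, names(seqs), annotation$gene_id,
                      annotation$biotype, annotation$gene_name)
  list(transcripts = tx, annotation = annotation)
}

# all length-L substrings of a set of sequences, as a deduplicated lookup
# table; used for the independent fixed-string scan that certifies truth
.subsSet <- function(tx_chr, L) {
  out <- lapply(tx_chr, function(s) {
    n <- nchar(s)
    if (n < L) return(character(0))
    substring(s, 1:(n - L + 1L), L:n)
  })
  unique(unlist(out, use.names = FALSE))
}

#' Simulate probes with known filter fates
#'
#' Samples \code{probes_per_gene} exact substrings from each lncRNA gene's
#' transcripts; a configured fraction of them is additionally copied into a
#' protein-coding transcript (making them cross-biotype by construction);
#' decoy probes are random sequences verified absent from all transcripts
#' (resampled on collision). The returned truth records each probe's
#' expected filter fate and the gene->probe map expected to survive
#' reannotation, certified at generation by an independent fixed-string
#' scan of the emitted transcripts.
#'
#' @param transcriptome output of \code{\link{simulateTranscriptome}}.
#' @param spec a \code{\link{fixtureSpec}}.
#' @param probe_length probe length in nt.
#' @param min_probes_per_gene support threshold used when computing the
#'   expected surviving gene map.
#' @return list with \code{probes} (a \code{\link{probeSet}}),
#'   \code{transcripts} (possibly modified by cross-biotype insertion),
#'   and \code{truth} (list: \code{probe_table} with per-probe fates,
#'   \code{expected_map} gene -> surviving probe ids).
#' @export
simulateProbes <- function(transcriptome, spec = fixtureSpec(),
                           probe_length = 25L, min_probes_per_gene = 3L) {
  set.seed(.deriveSeed(spec$seed, "probes"))
  tx <- transcriptome$transcripts
  ann <- transcriptome$annotation
  tx_chr <- setNames(as.character(tx), names(tx))
  if (any(nchar(tx_chr) < probe_length))
    stop("all transcripts must be at least probe_length long")
  lnc_genes <- unique(ann$gene_id[ann$biotype == "lncRNA"])
  coding_tids <- ann$transcript_id[ann$biotype == "protein_coding"]

  rows <- list()
  pnum <- 0L
  for (g in lnc_genes) {
    tids <- ann$transcript_id[ann$gene_id == g]
    for (j in seq_len(spec$probes_per_gene)) {
      tid <- if (length(tids) == 1L) tids else sample(tids, 1L)
      L <- nchar(tx_chr[[tid]])
      off <- sample.int(L - probe_length + 1L, 1L) - 1L
      pnum <- pnum + 1L
      rows[[pnum]] <- data.frame(
        probe_id = sprintf("P%06d", pnum),
        sequence = substr(tx_chr[[tid]], off + 1L, off + probe_length),
        gene_id = g, source_transcript = tid, is_decoy = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  ptab <- do.call(rbind, rows)

  # cross-biotype: copy a random subset of probe sequences into coding
  # transcripts at non-overlapping positions
  n_cross <- round(spec$cross_biotype_fraction * nrow(ptab))
  cross_idx <- if (n_cross > 0L) sample.int(nrow(ptab), n_cross) else
    integer(0)
  used <- lapply(setNames(nm = coding_tids), function(x) integer(0))
  for (i in cross_idx) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      tid <- if (length(coding_tids) == 1L) coding_tids else
        sample(coding_tids, 1L)
      L <- nchar(tx_chr[[tid]])
      pos <- sample.int(L - probe_length + 1L, 1L)
      window <- pos:(pos + probe_length - 1L)
      if (length(intersect(window, used[[tid]])) > 0L) next
      substr(tx_chr[[tid]], pos, pos + probe_length - 1L) <-
        ptab$sequence[i]
      used[[tid]] <- c(used[[tid]], window)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place cross-biotype probe; ",
                      "coding transcripts too short or too few")
  }

  # decoys: random sequences verified absent on both strands
  all_subs <- .subsSet(tx_chr, probe_length)
  if (spec$n_decoy_probes > 0L) {
    for (d in seq_len(spec$n_decoy_probes)) {
      repeat {
        s <- .randSeq(probe_length)
        if (!(s %in% all_subs) && !(.revcompChar(s) %in% all_subs)) break
      }
      pnum <- pnum + 1L
      ptab <- rbind(ptab, data.frame(
        probe_id = sprintf("P%06d", pnum), sequence = s,
        gene_id = NA_character_, source_transcript = NA_character_,
        is_decoy = TRUE, stringsAsFactors = FALSE))
    }
  }

  # certify fates by an independent fixed-string scan of the (modified)
  # coding transcripts, both strands
  cod_subs <- .subsSet(tx_chr[coding_tids], probe_length)
  rc <- .revcompChar(ptab$sequence)
  is_cross <- !ptab$is_decoy &
    (ptab$sequence %in% cod_subs | rc %in% cod_subs)
  ptab$is_cross_biotype <- is_cross
  ptab$expected_fate <- ifelse(ptab$is_decoy, "no_hit",
                        ifelse(ptab$is_cross_biotype,
                               "cross_biotype_removed", "retained"))

  # identical sequences sampled for two distinct genes would be multi-gene
  # probes; at 25 nt over random sequence this is effectively impossible,
  # but record the fate correctly if it ever happens
  for (s in unique(ptab$sequence[duplicated(ptab$sequence)])) {
    idx <- which(ptab$sequence == s & !ptab$is_decoy)
    if (length(unique(ptab$gene_id[idx])) > 1L)
      ptab$expected_fate[idx][ptab$expected_fate[idx] == "retained"] <-
        "multi_gene_removed"
  }

  keep <- ptab$expected_fate == "retained"
  em <- split(ptab$probe_id[keep], ptab$gene_id[keep])
  em <- lapply(em, sort)
  small <- lengths(em) < min_probes_per_gene
  lost_genes <- names(em)[small]
  ptab$expected_fate[ptab$gene_id %in% lost_genes &
                       ptab$expected_fate == "retained"] <-
    "gene_below_min_probes"
  expected_map <- em[!small]
  expected_map <- expected_map[.stableOrder(names(expected_map))]

  tx_new <- transcriptSet(tx_chr, names(tx_chr), ann$gene_id, ann$biotype,
                          ann$gene_name)
  probes <- probeSet(ptab$sequence, ptab$probe_id,
                     probe_length = probe_length)
  list(probes = probes, transcripts = tx_new,
       truth = list(probe_table = ptab, expected_map = expected_map))
}

#' Simulate drug-perturbed instance intensities
#'
#' Probe-level log2 intensities: a Normal(7, 1) baseline per gene shared by
#' the gene's probes across all samples, plus probe-level Normal(0,
#' noise_sd) noise per sample; each drug shifts its effect genes by
#' +/- \code{effect_log2fc} in treatment samples. Effect genes are drawn
#' from the genes expected to survive reannotation so the intended DEL set
#' is measurable. Each instance has one treatment and two control samples.
#'
#' @param probe_truth \code{truth} from \code{\link{simulateProbes}}.
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list with \code{matrix} (probes x samples), \code{instances}
#'   (instance metadata table) and \code{truth} (list: \code{del_sets}
#'   drug -> intended DEL gene ids, \code{del_signs} drug -> named signs).
#' @export
simulateInstances <- function(probe_truth, spec = fixtureSpec()) {
  set.seed(.deriveSeed(spec$seed, "instances"))
  ptab <- probe_truth$probe_table
  genes <- names(probe_truth$expected_map)
  if (spec$effect_genes_per_drug > length(genes))
    stop("effect_genes_per_drug exceeds the ", length(genes),
         " measurable genes")
  drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
  inst <- list()
  sample_ids <- character(0)
  for (d in seq_along(drugs)) for (k in seq_len(spec$instances_per_drug)) {
    iid <- sprintf("INST_%02d_%02d", d, k)
    trt <- sprintf("T_%02d_%02d", d, k)
    ctl <- sprintf("C_%02d_%02d_%d", d, k, 1:2)
    inst[[iid]] <- data.frame(instance_id = iid, drug_name = drugs[d],
                              treatment_samples = trt,
                              control_samples = .joinIds(ctl),
                              stringsAsFactors = FALSE)
    sample_ids <- c(sample_ids, trt, ctl)
  }
  instances <- do.call(rbind, inst)
  rownames(instances) <- NULL

  # per-gene baseline shared across samples; decoys get their own baseline
  all_genes <- unique(ptab$gene_id[!ptab$is_decoy])
  base_gene <- setNames(rnorm(length(all_genes), 7, 1), all_genes)
  base_probe <- ifelse(ptab$is_decoy, rnorm(nrow(ptab), 7, 1),
                       base_gene[ptab$gene_id])

  del_sets <- list(); del_signs <- list()
  effect <- matrix(0, nrow(ptab), length(sample_ids),
                   dimnames = list(ptab$probe_id, sample_ids))
  for (d in seq_along(drugs)) {
    eg <- if (length(genes) == 1L) genes else
      sample(genes, spec$effect_genes_per_drug)
    sg <- setNames(sample(c(-1, 1), length(eg), TRUE), eg)
    del_signs[[drugs[d]]] <- sg
    del_sets[[drugs[d]]] <- sort(eg)
    probe_rows <- which(ptab$gene_id %in% eg & !ptab$is_decoy)
    shift <- sg[ptab$gene_id[probe_rows]] * spec$effect_log2fc
    for (k in seq_len(spec$instances_per_drug)) {
      trt <- sprintf("T_%02d_%02d", d, k)
      effect[probe_rows, trt] <- shift
    }
  }
  noise <- matrix(rnorm(nrow(ptab) * length(sample_ids), 0, spec$noise_sd),
                  nrow(ptab), length(sample_ids))
  mat <- matrix(rep(base_probe, length(sample_ids)), nrow(ptab),
                length(sample_ids),
                dimnames = list(ptab$probe_id, sample_ids)) +
    effect + noise
  if (spec$effect_log2fc == 0)
    del_sets <- lapply(del_sets, function(x) character(0))
  list(matrix = mat, instances = instances,
       truth = list(del_sets = del_sets, del_signs = del_signs))
}

#' Simulate a disease expression profile with a planted drug match
#'
#' Two-class gene-level profile over the measurable universe: class-1
#' samples shift \code{target_drug_overlap} members of the target drug's
#' set upward by \code{effect_log2fc} over Normal(0, noise_sd) noise on a
#' shared Normal(7, 1) per-gene baseline. Emits both the profile (LSEA
#' input) and the shifted-gene list (ORA input).
#'
#' @param drug_sets a \linkS4class{DrugSetCollection} or named list.
#' @param spec a \code{\link{fixtureSpec}}.
#' @param target_drug drug whose set carries the planted signal; default
#'   the first drug name in sorted order.
#' @param universe gene universe of the profile; defaults to the union of
#'   all set members, padded with null genes up to \code{n_lnc_genes}.
#' @return list with \code{expr} (genes x samples), \code{labels} (named
#'   0/1), \code{query} (shifted gene ids), \code{target_drug}.
#' @export
simulateDiseaseProfile <- function(drug_sets, spec = fixtureSpec(),
                                   target_drug = NULL, universe = NULL) {
  if (is(drug_sets, "DrugSetCollection")) drug_sets <- setMembers(drug_sets)
  if (is.null(target_drug)) target_drug <- sort(names(drug_sets))[1]
  if (!target_drug %in% names(drug_sets))
    stop("target drug absent from drug_sets: ", target_drug)
  if (spec$n_disease_samples_per_class < 1L)
    stop("need at least one sample per class")
  set.seed(.deriveSeed(spec$seed, "disease"))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(drug_sets, use.names = FALSE)))
    pad <- spec$n_lnc_genes - length(universe)
    if (pad > 0L) universe <- c(universe, sprintf("NULLG%04d", seq_len(pad)))
  }
  members <- intersect(drug_sets[[target_drug]], universe)
  k <- min(spec$target_drug_overlap, length(members))
  shifted <- sort(if (length(members) == 1L) members else
    sample(members, k))

  npc <- spec$n_disease_samples_per_class
  samples <- sprintf("S%02d", seq_len(2L * npc))
  labels <- setNames(rep(c(0L, 1L), each = npc), samples)
  base <- rnorm(length(universe), 7, 1)
  expr <- matrix(rep(base, length(samples)), length(universe),
                 length(samples), dimnames = list(universe, samples)) +
    matrix(rnorm(length(universe) * length(samples), 0, spec$noise_sd),
           length(universe), length(samples))
  expr[shifted, labels == 1L] <- expr[shifted, labels == 1L] +
    spec$effect_log2fc
  list(expr = expr, labels = labels, query = shifted,
       target_drug = target_drug)
}
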
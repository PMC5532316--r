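#' @importFrom Biostrings DNAStringSet PDict matchPDict reverseComplement
#'   readBStringSet writeXStringSet width alphabetFrequency startIndex
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Construct a validated probe set
#'
#' Probes are short oligo sequences of one fixed length (default 25 nt).
#'
#' @param sequences character vector or \code{DNAStringSet} of probe
#'   sequences (A/C/G/T only, all of length \code{probe_length}).
#' @param probe_id unique probe identifiers.
#' @param probeset_id optional probe-set (transcript-group) identifiers.
#' @param probe_length expected probe length.
#' @return A named \code{DNAStringSet} with a \code{probeset_id} metadata
#'   column when given.
#' @export
probeSet <- function(sequences, probe_id = names(sequences),
                     probeset_id = NULL, probe_length = 25L) {
  if (is.null(probe_id)) stop("probe_id required")
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  seqs <- toupper(as.character(sequences))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("probe sequence with non-ACGT characters: ",
         paste(probe_id[bad], collapse = ", "))
  wrong <- nchar(seqs) != probe_length
  if (any(wrong))
    stop(sprintf("probe sequence not of length %d: %s", probe_length,
                 paste(probe_id[wrong], collapse = ", ")))
  x <- DNAStringSet(seqs)
  names(x) <- probe_id
  if (!is.null(probeset_id))
    mcols(x)$probeset_id <- as.character(probeset_id)
  x
}

#' Construct a validated transcript set
#'
#' Transcripts carry a gene assignment and a biotype; records with biotypes
#' other than \code{lncRNA} / \code{protein_coding} are dropped with a
#' logged count.
#'
#' @param sequences character vector or \code{DNAStringSet}.
#' @param transcript_id unique transcript identifiers.
#' @param gene_id gene identifier per transcript.
#' @param biotype \code{"lncRNA"} or \code{"protein_coding"} per transcript.
#' @param gene_name optional display name per transcript.
#' @return A named \code{DNAStringSet} with \code{gene_id}, \code{biotype}
#'   (and optionally \code{gene_name}) metadata columns.
#' @export
transcriptSet <- function(sequences, transcript_id = names(sequences),
                          gene_id, biotype, gene_name = NULL) {
  if (is.null(transcript_id)) stop("transcript_id required")
  if (anyDuplicated(transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(transcript_id[duplicated(transcript_id)]),
               collapse = ", "))
  seqs <- toupper(as.character(sequences))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) stop("empty transcript sequence")
  keep <- biotype %in% c("lncRNA", "protein_coding")
  if (!all(keep))
    .msg(sum(!keep), " transcript(s) with unsupported biotype dropped")
  x <- DNAStringSet(seqs[keep])
  names(x) <- transcript_id[keep]
  mcols(x)$gene_id <- as.character(gene_id[keep])
  mcols(x)$biotype <- as.character(biotype[keep])
  if (!is.null(gene_name)) mcols(x)$gene_name <- as.character(gene_name[keep])
  x
}

#' Find exact full-length probe matches in a transcriptome
#'
#' Every mismatch-free, full-length occurrence of each probe (and/or its
#' reverse complement, per \code{strand_mode}) in every transcript is
#' reported; multiple offsets within one transcript yield one hit per
#' offset. Matching uses a precompiled dictionary
#' (\code{Biostrings::matchPDict}), equivalent to an exhaustive
#' sliding-window scan.
#'
#' @param probes probe \code{DNAStringSet} (see \code{\link{probeSet}}).
#' @param transcripts transcript \code{DNAStringSet} (see
#'   \code{\link{transcriptSet}}).
#' @param params \code{\link{reannotationParams}}.
#' @return data.frame with columns \code{probe_id}, \code{transcript_id},
#'   \code{gene_id}, \code{biotype}, \code{strand} (\code{forward} /
#'   \code{revcomp}) and \code{offset} (0-based match start within the
#'   transcript), ordered by (probe_id, transcript_id, offset, strand).
#' @export
findExactHits <- function(probes, transcripts,
                          params = reannotationParams()) {
  if (length(probes) == 0L) stop("empty probe list")
  if (length(transcripts) == 0L) stop("empty transcript list")
  if (any(width(probes) != params$probe_length))
    stop("probe width differs from params$probe_length")
  tx_meta <- mcols(transcripts)
  if (is.null(tx_meta$gene_id) || is.null(tx_meta$biotype))
    stop("transcripts must carry gene_id and biotype metadata")

  dicts <- list()
  if (params$strand_mode %in% c("forward", "both"))
    dicts$forward <- PDict(probes)
  if (params$strand_mode %in% c("revcomp", "both"))
    dicts$revcomp <- PDict(reverseComplement(probes))

  pid <- names(probes)
  out <- vector("list", length(transcripts) * length(dicts))
  k <- 0L
  for (ti in seq_along(transcripts)) {
    if (width(transcripts)[ti] < params$probe_length) next
    subj <- transcripts[[ti]]
    for (strand in names(dicts)) {
      starts <- startIndex(matchPDict(dicts[[strand]], subj))
      n_hits <- lengths(starts)
      if (sum(n_hits) == 0L) next
      idx <- rep.int(seq_along(starts), n_hits)
      k <- k + 1L
      out[[k]] <- data.frame(
        probe_id = pid[idx],
        transcript_id = names(transcripts)[ti],
        gene_id = tx_meta$gene_id[ti],
        biotype = tx_meta$biotype[ti],
        strand = strand,
        offset = unlist(starts, use.names = FALSE) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (k == 0L) {
    data.frame(probe_id = character(0), transcript_id = character(0),
               gene_id = character(0), biotype = character(0),
               strand = character(0), offset = integer(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out[seq_len(k)])
  hits <- hits[.stableOrder(hits$probe_id, hits$transcript_id, hits$offset,
                            hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Remove cross-biotype probes
#'
#' A probe with at least one hit to a protein-coding transcript is removed
#' entirely (all of its hits, including lncRNA hits); probes hitting only
#' coding transcripts contribute nothing downstream and are removed too.
#'
#' @param hits hit table from \code{\link{findExactHits}}.
#' @return The hit table restricted to probes whose hits are all lncRNA.
#' @export
filterCrossBiotype <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  coding_probes <- unique(hits$probe_id[hits$biotype == "protein_coding"])
  keep <- hits$biotype == "lncRNA" & !(hits$probe_id %in% coding_probes)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse hits to the gene level
#'
#' Probes hitting multiple transcripts (isoforms) of one gene count once for
#' that gene. Under the \code{drop_multi_gene} policy, probes hitting
#' transcripts of more than one distinct lncRNA gene are discarded (logged).
#'
#' @param hits lncRNA-only hit table (after \code{\link{filterCrossBiotype}}).
#' @param policy ambiguity policy; only \code{"drop_multi_gene"}.
#' @return Named list: gene_id -> sorted character vector of probe ids.
#' @export
collapseToGenes <- function(hits, policy = "drop_multi_gene") {
  policy <- match.arg(policy, "drop_multi_gene")
  if (nrow(hits) > 0L && any(hits$biotype != "lncRNA"))
    stop("collapseToGenes expects lncRNA-only hits")
  if (nrow(hits) == 0L) return(structure(list(), names = character(0)))
  pairs <- unique(hits[, c("gene_id", "probe_id")])
  genes_per_probe <- table(pairs$probe_id)
  multi <- names(genes_per_probe)[genes_per_probe > 1L]
  if (length(multi))
    .msg(length(multi), " probe(s) spanning multiple lncRNA genes dropped")
  pairs <- pairs[!(pairs$probe_id %in% multi), , drop = FALSE]
  g2p <- split(pairs$probe_id, pairs$gene_id)
  g2p <- lapply(g2p, function(p) sort(unique(p)))
  g2p[.stableOrder(names(g2p))]
}

#' Apply the minimum-probe-support filter
#'
#' lncRNA genes matched by fewer than \code{min_probes} surviving probes are
#' discarded.
#'
#' @param gene_map named list from \code{\link{collapseToGenes}}.
#' @param min_probes minimum probe count per gene.
#' @param params reannotation parameters stored in the result.
#' @param provenance optional counter list accumulated by the caller.
#' @param gene_names optional named character of display names.
#' @return A \linkS4class{ReannotationMap}.
#' @export
applyMinProbeFilter <- function(gene_map, min_probes = 3L,
                                params = reannotationParams(
                                  min_probes_per_gene = min_probes),
                                provenance = list(), gene_names = character(0)) {
  min_probes <- as.integer(min_probes)
  if (min_probes < 1L) stop("min_probes must be >= 1")
  keep <- lengths(gene_map) >= min_probes
  provenance$genes_before_min_filter <- length(gene_map)
  provenance$genes_removed_min_probes <- sum(!keep)
  provenance$genes_retained <- sum(keep)
  g2p <- gene_map[keep]
  gene_names <- gene_names[names(gene_names) %in% names(g2p)]
  new("ReannotationMap", geneToProbes = g2p, geneNames = gene_names,
      params = params, provenance = provenance)
}

#' Reannotate probes to lncRNA genes
#'
#' Runs the full four-stage filter chain: (i) exact full-length matching of
#' probes to transcripts; (ii) removal of probes targeting both lncRNA and
#' protein-coding transcripts; (iii) gene-level collapse of transcript hits
#' (dropping probes spanning two lncRNA genes); (iv) removal of lncRNA genes
#' supported by fewer than \code{min_probes_per_gene} probes. Per-stage
#' probe and gene counters are recorded in the result's provenance; at every
#' stage input = retained + removed.
#'
#' @inheritParams findExactHits
#' @return A \linkS4class{ReannotationMap}.
#' @examples
#' tx <- transcriptSet(c(T1 = paste(rep("ACGT", 15), collapse = "")),
#'                     gene_id = "G1", biotype = "lncRNA")
#' pr <- probeSet(rep(substr(as.character(tx[[1]]), 1, 25), 3),
#'                probe_id = c("p1", "p2", "p3"))
#' # three identical probes collapse to one unique sequence per id; all hit G1
#' buildReannotation(pr, tx)
#' @export
buildReannotation <- function(probes, transcripts,
                              params = reannotationParams()) {
  hits <- findExactHits(probes, transcripts, params)
  n_input <- length(probes)
  matched <- unique(hits$probe_id)
  prov <- list(probes_input = n_input,
               probes_unmatched = n_input - length(matched),
               probes_matched = length(matched))

  lnc_hits <- filterCrossBiotype(hits)
  surv1 <- unique(lnc_hits$probe_id)
  prov$probes_cross_biotype_removed <- length(matched) - length(surv1)
  prov$probes_after_cross_filter <- length(surv1)

  gene_map <- collapseToGenes(lnc_hits, params$ambiguity_policy)
  surv2 <- unlist(gene_map, use.names = FALSE)
  prov$probes_multi_gene_removed <- length(surv1) - length(surv2)
  prov$probes_after_gene_collapse <- length(surv2)

  gene_names <- character(0)
  meta <- mcols(transcripts)
  if (!is.null(meta$gene_name)) {
    gn <- meta$gene_name[!duplicated(meta$gene_id)]
    names(gn) <- meta$gene_id[!duplicated(meta$gene_id)]
    gene_names <- gn
  }
  map <- applyMinProbeFilter(gene_map, params$min_probes_per_gene, params,
                             prov, gene_names)
  map@provenance$probes_retained <-
    length(unlist(map@geneToProbes, use.names = FALSE))
  map@provenance$probes_in_dropped_genes <-
    map@provenance$probes_after_gene_collapse -
    map@provenance$probes_retained
  validObject(map)
  map
}
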
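#' Reannotation parameters
#'
#' Parameters of the probe-to-gene reannotation filter chain. Probes are
#' retained only on a full-length perfect match (no mismatch), so the
#' classical alignment e-value pre-filter is subsumed by exact matching;
#' \code{evalue_cutoff} is kept as a documented, inert parameter for
#' provenance.
#'
#' @param probe_length expected probe length in nt (default 25, the
#'   Affymetrix 3' array probe length); validated at load.
#' @param min_probes_per_gene minimum number of surviving probes a lncRNA
#'   gene needs to be kept (default 3).
#' @param strand_mode \code{"both"} (default): a probe matches a transcript
#'   if either the probe or its reverse complement occurs verbatim;
#'   \code{"forward"} / \code{"revcomp"} restrict to one orientation.
#' @param ambiguity_policy what to do with probes matching transcripts of
#'   more than one distinct lncRNA gene; only \code{"drop_multi_gene"}
#'   (discard, logged) is implemented.
#' @param evalue_cutoff documentary only; exact full-length matching makes
#'   any e-value filter at or below this value a no-op.
#' @return A named list of validated parameters.
#' @export
reannotationParams <- function(probe_length = 25L,
                               min_probes_per_gene = 3L,
                               strand_mode = c("both", "forward", "revcomp"),
                               ambiguity_policy = "drop_multi_gene",
                               evalue_cutoff = 1e-6) {
  strand_mode <- match.arg(strand_mode)
  ambiguity_policy <- match.arg(ambiguity_policy, "drop_multi_gene")
  probe_length <- as.integer(probe_length)
  min_probes_per_gene <- as.integer(min_probes_per_gene)
  if (probe_length <= 0L) stop("probe_length must be > 0")
  if (min_probes_per_gene < 1L) stop("min_probes_per_gene must be >= 1")
  list(probe_length = probe_length,
       min_probes_per_gene = min_probes_per_gene,
       strand_mode = strand_mode,
       ambiguity_policy = ambiguity_policy,
       evalue_cutoff = evalue_cutoff)
}

#' Signature parameters
#'
#' @param fc_threshold fold-change cutoff for calling a differentially
#'   expressed lncRNA (DEL); a gene is a DEL when
#'   \code{|log2fc| >= log2(fc_threshold)}. Typical values 1.5 and 2.
#'   The exact \code{log2(fc_threshold)} is used, not its rounded two-decimal
#'   display value (0.58 at threshold 1.5).
#' @param summarization probe-to-gene summarization, \code{"median"}
#'   (default) or \code{"mean"}.
#' @param del_direction restrict DEL calls to one direction
#'   (\code{"up"}/\code{"down"}) or keep \code{"both"} (default).
#' @return A named list of validated parameters.
#' @export
signatureParams <- function(fc_threshold = 1.5,
                            summarization = c("median", "mean"),
                            del_direction = c("both", "up", "down")) {
  summarization <- match.arg(summarization)
  del_direction <- match.arg(del_direction)
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L ||
      fc_threshold <= 1)
    stop("fc_threshold must be a single number > 1")
  list(fc_threshold = fc_threshold,
       summarization = summarization,
       del_direction = del_direction)
}

#' LSEA parameters
#'
#' @param metric per-gene ranking statistic between the two phenotype
#'   classes: \code{"signal2noise"} (default; difference of class means over
#'   the sum of floored class standard deviations), \code{"t_stat"} (Welch),
#'   or \code{"diff_of_means"}. With fewer than two samples in either class
#'   the first two fall back to \code{diff_of_means} (logged).
#' @param weight_exponent 0 or 1. 0 is the unweighted running sum (equal
#'   hit increments); 1 weights each hit by its absolute ranking score.
#' @param n_permutations permutation count for the null (default 1000).
#' @param permutation_mode \code{"phenotype"} (default; relabel samples and
#'   re-rank) or \code{"gene_set"} (random member sets of equal size).
#' @param seed integer seed controlling the permutation stream.
#' @param min_set_size smallest overlap with the ranked list a set needs to
#'   be tested (default 3).
#' @param fdr_method \code{"gsea"} (default; sign-stratified pooled-NES
#'   ratio) or \code{"BH"} (Benjamini-Hochberg on nominal p).
#' @return A named list of validated parameters.
#' @export
lseaParams <- function(metric = c("signal2noise", "t_stat", "diff_of_means"),
                       weight_exponent = 1,
                       n_permutations = 1000L,
                       permutation_mode = c("phenotype", "gene_set"),
                       seed = 1L,
                       min_set_size = 3L,
                       fdr_method = c("gsea", "BH")) {
  metric <- match.arg(metric)
  permutation_mode <- match.arg(permutation_mode)
  fdr_method <- match.arg(fdr_method)
  n_permutations <- as.integer(n_permutations)
  min_set_size <- as.integer(min_set_size)
  if (!weight_exponent %in% c(0, 1))
    stop("weight_exponent must be 0 or 1")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (min_set_size < 1L) stop("min_set_size must be >= 1")
  list(metric = metric, weight_exponent = weight_exponent,
       n_permutations = n_permutations, permutation_mode = permutation_mode,
       seed = as.integer(seed), min_set_size = min_set_size,
       fdr_method = fdr_method)
}
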
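#' @import methods
NULL

#' ReannotationMap: gene-level lncRNA probe assignments
#'
#' Result of the four-stage probe reannotation filter chain. Each surviving
#' lncRNA gene carries the set of probes that interrogate it exclusively
#' (no cross-biotype probe, no probe shared between two lncRNA genes, and at
#' least \code{min_probes_per_gene} probes per gene).
#'
#' @slot geneToProbes named list; lncRNA gene id -> character vector of
#'   probe ids (sorted, unique).
#' @slot geneNames named character; optional display names per gene id.
#' @slot params list of reannotation parameters (see
#'   \code{\link{reannotationParams}}).
#' @slot provenance list of per-stage probe/gene counters; at every filter
#'   stage input = retained + removed.
#'
#' @seealso \code{\link{buildReannotation}}
#' @exportClass ReannotationMap
setClass("ReannotationMap",
  representation(geneToProbes = "list", geneNames = "character",
                 params = "list", provenance = "list"))

setValidity("ReannotationMap", function(object) {
  g2p <- object@geneToProbes
  if (length(g2p) > 0 && is.null(names(g2p)))
    return("geneToProbes must be a named list")
  if (anyDuplicated(names(g2p)))
    return("duplicate gene ids in geneToProbes")
  if (!all(vapply(g2p, is.character, logical(1))))
    return("geneToProbes elements must be character vectors")
  minp <- object@params$min_probes_per_gene
  if (!is.null(minp) && length(g2p) > 0 &&
      any(lengths(g2p) < minp))
    return(sprintf("gene with fewer than %d probes present", minp))
  probes <- unlist(g2p, use.names = FALSE)
  if (anyDuplicated(probes))
    return("a probe is assigned to more than one gene")
  TRUE
})

#' SignatureSet: per-instance lncRNA fold-change signatures
#'
#' Holds gene-level log2 fold changes (treatment minus control) for a
#' collection of drug-perturbation instances, together with the
#' differentially expressed lncRNA (DEL) calls made from them.
#'
#' @slot log2fc numeric matrix, genes x instances.
#' @slot dels integer matrix of the same dimension with values in
#'   \{-1, 0, 1\}: sign of the call, 0 = not a DEL.
#' @slot instances data.frame with columns \code{instance_id},
#'   \code{drug_name}, \code{treatment_samples}, \code{control_samples}
#'   (sample ids comma-joined), one row per column of \code{log2fc}.
#' @slot params list of signature parameters (see
#'   \code{\link{signatureParams}}).
#'
#' @seealso \code{\link{buildSignatureSet}}, \code{\link{buildDrugSets}}
#' @exportClass SignatureSet
setClass("SignatureSet",
  representation(log2fc = "matrix", dels = "matrix",
                 instances = "data.frame", params = "list"))

setValidity("SignatureSet", function(object) {
  if (!identical(dim(object@log2fc), dim(object@dels)))
    return("log2fc and dels must have identical dimensions")
  if (!identical(colnames(object@log2fc), object@instances$instance_id))
    return("log2fc columns must match instances$instance_id in order")
  if (anyDuplicated(object@instances$instance_id))
    return("duplicate instance_id")
  if (length(object@dels) > 0 && !all(object@dels %in% c(-1L, 0L, 1L)))
    return("dels values must be -1, 0 or 1")
  thr <- object@params$fc_threshold
  if (!is.null(thr) && length(object@dels) > 0) {
    called <- object@dels != 0L
    if (any(abs(object@log2fc[called]) < log2(thr) - 1e-12))
      return("a DEL call violates |log2fc| >= log2(fc_threshold)")
  }
  TRUE
})

#' DrugSetCollection: drug-induced lncRNA sets
#'
#' One member set per drug: the union of the drug's per-instance DELs.
#' This is the unit against which disease queries are enriched.
#'
#' @slot sets named list; drug name -> character vector of gene ids.
#' @slot nInstances named integer; supporting instance count per drug.
#'
#' @seealso \code{\link{buildDrugSets}}, \code{\link{readGmt}}
#' @exportClass DrugSetCollection
setClass("DrugSetCollection",
  representation(sets = "list", nInstances = "integer"))

setValidity("DrugSetCollection", function(object) {
  if (length(object@sets) > 0 && is.null(names(object@sets)))
    return("sets must be named by drug")
  if (anyDuplicated(names(object@sets)))
    return("duplicate drug names")
  if (any(lengths(object@sets) == 0L))
    return("empty member set")
  if (!identical(names(object@sets), names(object@nInstances)))
    return("nInstances names must match set names")
  TRUE
})

#' Construct a DrugSetCollection
#'
#' @param sets named list of character vectors (drug -> member gene ids).
#' @param nInstances integer vector of supporting instance counts, recycled
#'   to 1 if scalar; defaults to 1 per set.
#' @return A \linkS4class{DrugSetCollection}.
#' @export
DrugSetCollection <- function(sets, nInstances = rep(1L, length(sets))) {
  sets <- lapply(sets, function(m) sort(unique(as.character(m))))
  if (length(nInstances) == 1L) nInstances <- rep(nInstances, length(sets))
  nInstances <- as.integer(nInstances)
  names(nInstances) <- names(sets)
  new("DrugSetCollection", sets = sets, nInstances = nInstances)
}
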
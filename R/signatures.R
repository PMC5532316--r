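# Per-instance log2 fold-change signatures, DEL calls, drug-induced sets.

.checkExprMatrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs row (feature) and column (sample) names")
  if (anyDuplicated(rownames(expr))) stop("duplicate row ids in matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in matrix")
  if (any(!is.finite(expr))) stop("non-finite values in expression matrix")
  invisible(expr)
}

.parseInstanceTable <- function(instances) {
  need <- c("instance_id", "drug_name", "treatment_samples", "control_samples")
  miss <- setdiff(need, names(instances))
  if (length(miss))
    stop("instance table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(instances$instance_id))
    stop("duplicate instance_id: ",
         paste(unique(instances$instance_id[duplicated(instances$instance_id)]),
               collapse = ", "))
  instances
}

#' Summarize probe-level expression to the gene level
#'
#' Gene value per sample is the median (default) or mean of the log2 values
#' of the gene's assigned probes. Probes absent from the matrix are logged
#' and skipped; a gene whose surviving probe count falls below the map's
#' \code{min_probes_per_gene} is dropped with a warning.
#'
#' @param probe_matrix numeric matrix, probes x samples, log2 scale.
#' @param map a \linkS4class{ReannotationMap}.
#' @param method \code{"median"} or \code{"mean"}.
#' @return Numeric matrix, genes x samples.
#' @export
summarizeGeneExpression <- function(probe_matrix, map,
                                    method = c("median", "mean")) {
  method <- match.arg(method)
  .checkExprMatrix(probe_matrix)
  stopifnot(is(map, "ReannotationMap"))
  fun <- if (method == "median") stats::median else mean
  minp <- map@params$min_probes_per_gene
  g2p <- map@geneToProbes
  rows <- vector("list", length(g2p))
  kept <- logical(length(g2p))
  n_missing <- 0L
  for (i in seq_along(g2p)) {
    pids <- intersect(g2p[[i]], rownames(probe_matrix))
    n_missing <- n_missing + (length(g2p[[i]]) - length(pids))
    if (length(pids) < minp) next
    sub <- probe_matrix[pids, , drop = FALSE]
    rows[[i]] <- apply(sub, 2L, fun)
    kept[i] <- TRUE
  }
  if (n_missing > 0L)
    .msg(n_missing, " mapped probe(s) absent from the matrix, skipped")
  if (any(!kept))
    warning(sum(!kept), " gene(s) dropped: fewer than ", minp,
            " probes present in the matrix")
  if (!any(kept))
    return(matrix(numeric(0), nrow = 0, ncol = ncol(probe_matrix),
                  dimnames = list(character(0), colnames(probe_matrix))))
  out <- do.call(rbind, rows[kept])
  rownames(out) <- names(g2p)[kept]
  out
}

#' Per-instance log2 fold changes
#'
#' For each instance, log2fc(gene) = mean over its treatment samples minus
#' mean over its control samples, on an already log2-scale gene matrix.
#'
#' @param expr gene-level numeric matrix (genes x samples, log2 scale).
#' @param instances data.frame with columns \code{instance_id},
#'   \code{drug_name}, \code{treatment_samples}, \code{control_samples};
#'   the sample columns are comma- or semicolon-joined sample ids.
#' @return Numeric matrix, genes x instances.
#' @export
instanceLog2fc <- function(expr, instances) {
  .checkExprMatrix(expr)
  instances <- .parseInstanceTable(instances)
  out <- matrix(NA_real_, nrow(expr), nrow(instances),
                dimnames = list(rownames(expr), instances$instance_id))
  for (i in seq_len(nrow(instances))) {
    trt <- .splitIds(instances$treatment_samples[i])
    ctl <- .splitIds(instances$control_samples[i])
    if (length(trt) == 0L || length(ctl) == 0L)
      stop("instance ", instances$instance_id[i],
           " needs >= 1 treatment and >= 1 control sample")
    absent <- setdiff(c(trt, ctl), colnames(expr))
    if (length(absent))
      stop("instance ", instances$instance_id[i],
           " references absent sample id(s): ",
           paste(absent, collapse = ", "))
    out[, i] <- rowMeans(expr[, trt, drop = FALSE]) -
      rowMeans(expr[, ctl, drop = FALSE])
  }
  out
}

#' Call differentially expressed lncRNAs (DELs)
#'
#' A gene is a DEL in an instance when \code{|log2fc| >= log2(fc_threshold)}
#' (the exact value, not a rounded display figure), optionally restricted to
#' one direction.
#'
#' @param log2fc numeric matrix (genes x instances) of log2 fold changes.
#' @param params \code{\link{signatureParams}}.
#' @return Integer matrix of the same shape with values -1/0/1 (sign of the
#'   call; 0 = not a DEL).
#' @export
callDels <- function(log2fc, params = signatureParams()) {
  cut <- log2(params$fc_threshold)
  dels <- matrix(0L, nrow(log2fc), ncol(log2fc), dimnames = dimnames(log2fc))
  dels[log2fc >= cut] <- 1L
  dels[log2fc <= -cut] <- -1L
  if (params$del_direction == "up") dels[dels < 0L] <- 0L
  if (params$del_direction == "down") dels[dels > 0L] <- 0L
  dels
}

#' Build per-instance signatures with DEL calls
#'
#' @param expr gene-level log2 expression matrix.
#' @param instances instance metadata table (see
#'   \code{\link{instanceLog2fc}}).
#' @param params \code{\link{signatureParams}}.
#' @return A \linkS4class{SignatureSet}.
#' @export
buildSignatureSet <- function(expr, instances, params = signatureParams()) {
  lfc <- instanceLog2fc(expr, instances)
  dels <- callDels(lfc, params)
  instances <- as.data.frame(instances)[, c("instance_id", "drug_name",
                                            "treatment_samples",
                                            "control_samples")]
  rownames(instances) <- NULL
  new("SignatureSet", log2fc = lfc, dels = dels, instances = instances,
      params = params)
}

#' Merge instance DELs into drug-induced lncRNA sets
#'
#' Per drug, members are the union of DEL gene ids over the drug's
#' instances (unsigned by default, matching the sets used for enrichment);
#' drugs whose instances produced no DELs are omitted.
#'
#' @param signatures a \linkS4class{SignatureSet}.
#' @param direction \code{"both"} (default, unsigned union), \code{"up"} or
#'   \code{"down"} to build direction-restricted sets.
#' @return A \linkS4class{DrugSetCollection}.
#' @export
buildDrugSets <- function(signatures, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is(signatures, "SignatureSet"))
  dels <- delMatrix(signatures)
  inst <- instanceInfo(signatures)
  drugs <- sort(unique(inst$drug_name))
  sets <- list()
  n_inst <- integer(0)
  for (d in drugs) {
    cols <- inst$instance_id[inst$drug_name == d]
    sub <- dels[, cols, drop = FALSE]
    hit <- switch(direction,
                  both = rowSums(sub != 0L) > 0L,
                  up = rowSums(sub > 0L) > 0L,
                  down = rowSums(sub < 0L) > 0L)
    members <- rownames(sub)[hit]
    if (length(members) == 0L) next
    sets[[d]] <- sort(members)
    n_inst[d] <- length(cols)
  }
  DrugSetCollection(sets, n_inst)
}
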
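# lncRNA Set Enrichment Analysis: GSEA-style running-sum statistic over a
# two-class ranked list, with a permutation null yielding NES, nominal p,
# FDR q and FWER p per drug-induced lncRNA set.

.checkLabels <- function(expr, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != ncol(expr))
      stop("unnamed labels must have one entry per matrix column")
    names(labels) <- colnames(expr)
  }
  if (!all(labels %in% c(0, 1)))
    stop("class labels must be 0 or 1")
  absent <- setdiff(names(labels), colnames(expr))
  if (length(absent))
    stop("labeled sample(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L)
    stop("both classes must be non-empty")
  labels
}

# vectorized per-gene two-class scores; c1/c0 are column index vectors
.rankScores <- function(expr, c1, c0, metric) {
  n1 <- length(c1); n0 <- length(c0)
  x1 <- expr[, c1, drop = FALSE]; x0 <- expr[, c0, drop = FALSE]
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  if (metric == "diff_of_means") return(mu1 - mu0)
  v1 <- rowSums((x1 - mu1)^2) / (n1 - 1L)
  v0 <- rowSums((x0 - mu0)^2) / (n0 - 1L)
  if (metric == "t_stat") {
    se <- sqrt(v1 / n1 + v0 / n0)
    s <- (mu1 - mu0) / se
    s[se == 0] <- 0
    return(s)
  }
  # signal2noise with the customary floor on each class sd
  s1 <- pmax(sqrt(v1), pmax(0.2 * abs(mu1), 0.2))
  s0 <- pmax(sqrt(v0), pmax(0.2 * abs(mu0), 0.2))
  (mu1 - mu0) / (s1 + s0)
}

#' Rank genes by a two-class differential-expression metric
#'
#' Scores every gene between class 1 and class 0 and returns the ranked
#' list L (descending score; ties broken lexicographically by gene id for
#' determinism). \code{signal2noise} = (mu1 - mu0) / (s1 + s0) with each
#' class sd floored at \code{max(0.2 |mu|, 0.2)}; \code{t_stat} is the
#' Welch statistic; \code{diff_of_means} = mu1 - mu0. With fewer than two
#' samples in either class, the first two fall back to
#' \code{diff_of_means} (logged).
#'
#' @param expr gene-level numeric matrix, genes x samples.
#' @param labels named vector of 0/1 class labels (or unnamed, aligned with
#'   the matrix columns).
#' @param metric see above.
#' @return data.frame with columns \code{gene_id}, \code{score}, rows in
#'   rank order.
#' @export
rankGenes <- function(expr, labels,
                      metric = c("signal2noise", "t_stat", "diff_of_means")) {
  metric <- match.arg(metric)
  .checkExprMatrix(expr)
  labels <- .checkLabels(expr, labels)
  c1 <- match(names(labels)[labels == 1], colnames(expr))
  c0 <- match(names(labels)[labels == 0], colnames(expr))
  if (metric != "diff_of_means" && (length(c1) < 2L || length(c0) < 2L)) {
    .msg("fewer than 2 samples in a class; falling back to diff_of_means")
    metric <- "diff_of_means"
  }
  score <- .rankScores(expr, c1, c0, metric)
  ord <- .stableOrder(-score, rownames(expr))
  data.frame(gene_id = rownames(expr)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

# ES of one walk; hit is a logical vector in rank order, w_abs = |score|
.esOnly <- function(hit, w_abs, w) {
  N <- length(hit); Nh <- sum(hit)
  inc <- rep.int(-1 / (N - Nh), N)
  if (w == 0) {
    inc[hit] <- 1 / Nh
  } else {
    hw <- w_abs[hit]^w
    s <- sum(hw)
    inc[hit] <- if (s > 0) hw / s else 1 / Nh
  }
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Running-sum enrichment score
#'
#' Walks down the ranked list, increasing the running sum at each set
#' member (hit) and decreasing it at each non-member; the enrichment score
#' ES is the signed running-sum value of maximal absolute deviation from
#' zero. With \code{weight_exponent = 0} hits add \code{1/Nh} and misses
#' subtract \code{1/(N - Nh)} (the walk ends exactly at zero); with
#' \code{weight_exponent = 1} each hit adds its absolute ranking score over
#' the summed absolute hit scores.
#'
#' @param ranked data.frame from \code{\link{rankGenes}} (columns
#'   \code{gene_id}, \code{score}).
#' @param members character vector of set member gene ids.
#' @param weight_exponent 0 or 1.
#' @return list with \code{es}, \code{running_sum} (numeric vector along
#'   the list) and \code{leading_edge} (hits at or before the extremum for
#'   positive ES, after it for negative ES).
#' @export
enrichmentScore <- function(ranked, members, weight_exponent = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene_id", "score") %in%
                                         colnames(ranked)))
  if (anyDuplicated(ranked$gene_id)) stop("duplicate ids in ranked list")
  hit <- ranked$gene_id %in% members
  N <- length(hit); Nh <- sum(hit)
  if (Nh == 0L) stop("no set member present in the ranked list")
  if (Nh == N) stop("set covers the entire ranked list; ES undefined")
  inc <- rep.int(-1 / (N - Nh), N)
  if (weight_exponent == 0) {
    inc[hit] <- 1 / Nh
  } else {
    hw <- abs(ranked$score[hit])^weight_exponent
    s <- sum(hw)
    inc[hit] <- if (s > 0) hw / s else 1 / Nh
  }
  run <- cumsum(inc)
  i <- which.max(abs(run))
  es <- run[i]
  le <- if (es > 0) ranked$gene_id[hit & seq_len(N) <= i]
        else if (es < 0) ranked$gene_id[hit & seq_len(N) > i]
        else character(0)
  list(es = es, running_sum = run, leading_edge = le)
}

#' Permutation null distribution of enrichment scores
#'
#' \code{phenotype} mode relabels the samples by a uniformly random
#' permutation of the 0/1 labels, re-ranks the genes, and recomputes the ES
#' of every set; \code{gene_set} mode keeps the observed ranking and draws
#' random member sets of equal size from the ranked universe. Reproducible
#' given \code{params$seed}.
#'
#' @param expr gene-level numeric matrix.
#' @param labels 0/1 class labels (see \code{\link{rankGenes}}).
#' @param drug_sets \linkS4class{DrugSetCollection} or named list; sets are
#'   intersected with the matrix rows and filtered at
#'   \code{params$min_set_size}.
#' @param params \code{\link{lseaParams}}.
#' @return Numeric matrix, \code{n_permutations} x tested sets, of null ES
#'   values (columns named by drug).
#' @export
permutationNull <- function(expr, labels, drug_sets, params = lseaParams()) {
  .checkExprMatrix(expr)
  labels <- .checkLabels(expr, labels)
  if (is(drug_sets, "DrugSetCollection")) drug_sets <- setMembers(drug_sets)
  sets <- lapply(drug_sets, function(m) intersect(m, rownames(expr)))
  sets <- sets[lengths(sets) >= params$min_set_size &
                 lengths(sets) < nrow(expr)]
  if (length(sets) == 0L) stop("no set passes min_set_size after overlap")
  if (params$permutation_mode == "phenotype" &&
      (sum(labels == 1) < 2L || sum(labels == 0) < 2L))
    stop("phenotype permutation needs >= 2 samples per class; ",
         "use permutation_mode = \"gene_set\"")

  set.seed(.deriveSeed(params$seed, "lsea-permutation"))
  nperm <- params$n_permutations
  w <- params$weight_exponent
  null <- matrix(NA_real_, nperm, length(sets),
                 dimnames = list(NULL, names(sets)))
  hitM <- vapply(sets, function(m) rownames(expr) %in% m,
                 logical(nrow(expr)))

  if (params$permutation_mode == "phenotype") {
    metric <- params$metric
    if (metric != "diff_of_means" &&
        (sum(labels == 1) < 2L || sum(labels == 0) < 2L))
      metric <- "diff_of_means"
    for (k in seq_len(nperm)) {
      perm <- labels[sample.int(length(labels))]
      names(perm) <- names(labels)
      c1 <- match(names(perm)[perm == 1], colnames(expr))
      c0 <- match(names(perm)[perm == 0], colnames(expr))
      score <- .rankScores(expr, c1, c0, metric)
      ord <- .stableOrder(-score, rownames(expr))
      w_abs <- abs(score[ord])
      for (j in seq_along(sets))
        null[k, j] <- .esOnly(hitM[ord, j], w_abs, w)
    }
  } else {
    ranked <- rankGenes(expr, labels, params$metric)
    w_abs <- abs(ranked$score)
    N <- nrow(ranked)
    for (k in seq_len(nperm)) {
      for (j in seq_along(sets)) {
        hit <- logical(N)
        hit[sample.int(N, length(sets[[j]]))] <- TRUE
        null[k, j] <- .esOnly(hit, w_abs, w)
      }
    }
  }
  null
}

#' Normalize enrichment scores and assess significance
#'
#' Per set: NES = ES divided by the mean absolute null ES of matching sign;
#' nominal p = add-one tail fraction among matching-sign null ES; FWER p =
#' add-one fraction of permutations whose maximum absolute null NES reaches
#' |NES|; FDR q (default) is the GSEA-style sign-stratified ratio of pooled
#' null-NES to observed-NES tail fractions, clipped to [0, 1] and made
#' monotone (BH on nominal p available via \code{fdr_method}).
#' A set with no matching-sign null samples gets an undefined NES
#' (\code{nes_defined = FALSE}) and ranks last.
#'
#' @param observed named numeric vector of observed ES per set.
#' @param null null ES matrix from \code{\link{permutationNull}} (columns
#'   matching \code{names(observed)}).
#' @param fdr_method \code{"gsea"} or \code{"BH"}.
#' @return data.frame with columns \code{drug}, \code{es}, \code{nes},
#'   \code{p_nominal}, \code{q_fdr}, \code{p_fwer}, \code{nes_defined},
#'   sorted by nominal p then decreasing |NES|.
#' @export
normalizeAndTest <- function(observed, null, fdr_method = c("gsea", "BH")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(is.matrix(null), identical(colnames(null), names(observed)),
            nrow(null) >= 1L)
  nperm <- nrow(null)
  nset <- length(observed)
  nes <- rep(NA_real_, nset)
  p_nom <- rep(NA_real_, nset)
  defined <- rep(TRUE, nset)
  pos_mean <- neg_mean <- rep(NA_real_, nset)
  for (j in seq_len(nset)) {
    pos <- null[, j][null[, j] > 0]
    neg <- null[, j][null[, j] < 0]
    if (length(pos)) pos_mean[j] <- mean(pos)
    if (length(neg)) neg_mean[j] <- mean(abs(neg))
    es <- observed[j]
    if (es > 0) {
      if (length(pos) == 0L) { defined[j] <- FALSE; next }
      nes[j] <- es / pos_mean[j]
      p_nom[j] <- (1 + sum(pos >= es)) / (1 + length(pos))
    } else if (es < 0) {
      if (length(neg) == 0L) { defined[j] <- FALSE; next }
      nes[j] <- es / neg_mean[j]
      p_nom[j] <- (1 + sum(neg <= es)) / (1 + length(neg))
    } else {
      nes[j] <- 0
      p_nom[j] <- 1
    }
  }

  # null NES: normalize each null ES by its own column's matching-sign mean
  nullNES <- null
  for (j in seq_len(nset)) {
    cj <- null[, j]
    out <- numeric(nperm)
    out[cj > 0] <- if (is.na(pos_mean[j])) NA_real_ else
      cj[cj > 0] / pos_mean[j]
    out[cj < 0] <- if (is.na(neg_mean[j])) NA_real_ else
      cj[cj < 0] / neg_mean[j]
    nullNES[, j] <- out
  }

  # FWER: permutation distribution of the maximum |null NES| across sets
  perm_max <- apply(abs(nullNES), 1L, max, na.rm = TRUE)
  p_fwer <- rep(NA_real_, nset)
  ok <- defined & !is.na(nes)
  p_fwer[ok] <- vapply(nes[ok], function(z)
    (1 + sum(perm_max >= abs(z))) / (1 + nperm), numeric(1))
  # a family-wise estimate can never be less significant-looking than its
  # own set's nominal p; floor it so estimator discreteness cannot invert
  p_fwer[ok] <- pmax(p_fwer[ok], p_nom[ok])

  if (fdr_method == "BH") {
    q <- rep(NA_real_, nset)
    q[ok] <- stats::p.adjust(p_nom[ok], method = "BH")
  } else {
    q <- .gseaFdr(nes, nullNES, ok)
  }

  res <- data.frame(drug = names(observed), es = unname(observed),
                    nes = nes, p_nominal = p_nom, q_fdr = q,
                    p_fwer = p_fwer, nes_defined = defined,
                    stringsAsFactors = FALSE)
  ord <- .stableOrder(!res$nes_defined, res$p_nominal, -abs(res$nes),
                      res$drug)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# GSEA-style sign-stratified FDR over pooled null NES
.gseaFdr <- function(nes, nullNES, ok) {
  q <- rep(NA_real_, length(nes))
  pool <- as.vector(nullNES)
  pool <- pool[!is.na(pool)]
  pool_pos <- pool[pool > 0]; pool_neg <- pool[pool < 0]
  obs <- nes[ok]
  obs_pos <- obs[obs > 0]; obs_neg <- obs[obs < 0]
  raw <- rep(NA_real_, length(nes))
  for (j in which(ok)) {
    z <- nes[j]
    if (z > 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= z) else 0
      den <- mean(obs_pos >= z)
      raw[j] <- min(1, num / den)
    } else if (z < 0) {
      num <- if (length(pool_neg)) mean(pool_neg <= z) else 0
      den <- mean(obs_neg <= z)
      raw[j] <- min(1, num / den)
    } else raw[j] <- 1
  }
  # monotone: a more extreme NES never gets a larger q
  for (j in which(ok)) {
    z <- nes[j]
    if (z > 0) q[j] <- min(raw[ok & !is.na(nes) & nes >= z])
    else if (z < 0) q[j] <- min(raw[ok & !is.na(nes) & nes <= z])
    else q[j] <- 1
  }
  q
}

#' lncRNA Set Enrichment Analysis
#'
#' Full pipeline: rank the genes between the two phenotype classes, compute
#' the running-sum enrichment score of every drug-induced lncRNA set,
#' build the permutation null, and report ES, NES, nominal p, FDR q and
#' FWER p per drug. Deterministic under a fixed \code{params$seed}.
#'
#' @inheritParams permutationNull
#' @return data.frame with columns \code{drug}, \code{size} (set overlap
#'   with the matrix rows), \code{es}, \code{nes}, \code{p_nominal},
#'   \code{q_fdr}, \code{p_fwer}, \code{leading_edge} (comma-joined),
#'   \code{nes_defined}; sorted by nominal p then decreasing |NES|.
#' @export
lsea <- function(expr, labels, drug_sets, params = lseaParams()) {
  .checkExprMatrix(expr)
  labels <- .checkLabels(expr, labels)
  if (is(drug_sets, "DrugSetCollection")) drug_sets <- setMembers(drug_sets)
  overlap <- vapply(drug_sets, function(m)
    length(intersect(m, rownames(expr))), integer(1))
  keep <- overlap >= params$min_set_size & overlap < nrow(expr)
  if (!any(keep))
    stop("no drug set passes min_set_size; overlap counts: ",
         paste(names(overlap), overlap, sep = "=", collapse = ", "))
  sets <- lapply(drug_sets[keep], function(m) intersect(m, rownames(expr)))

  ranked <- rankGenes(expr, labels, params$metric)
  obs <- vapply(sets, function(m)
    enrichmentScore(ranked, m, params$weight_exponent)$es, numeric(1))
  le <- vapply(sets, function(m)
    .joinIds(sort(enrichmentScore(ranked, m,
                                  params$weight_exponent)$leading_edge)),
    character(1))
  null <- permutationNull(expr, labels, sets, params)
  res <- normalizeAndTest(obs, null, params$fdr_method)
  idx <- match(res$drug, names(sets))
  res$size <- lengths(sets)[idx]
  res$leading_edge <- unname(le[idx])
  res[, c("drug", "size", "es", "nes", "p_nominal", "q_fdr", "p_fwer",
          "leading_edge", "nes_defined")]
}
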
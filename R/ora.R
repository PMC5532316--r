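# Hypergeometric over-representation analysis of a query lncRNA list
# against drug-induced lncRNA sets.

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing an overlap of at least \code{r} between a query
#' of size \code{n} and a set of size \code{t} drawn without replacement
#' from a universe of \code{m} genes:
#' \deqn{p = 1 - \sum_{x=0}^{r-1} \frac{\binom{t}{x}\binom{m-t}{n-x}}
#'   {\binom{m}{n}} = P(X \ge r).}
#' Computed in log space (via \code{lchoose} and log-sum-exp) by summing the
#' upper tail directly, which is numerically stable for small tail masses.
#'
#' @param m universe size.
#' @param t set size within the universe.
#' @param n query size within the universe.
#' @param r observed overlap.
#' @return The p-value, a number in [0, 1].
#' @examples
#' hypergeomPvalue(20, 5, 6, 3)  # 5090/38760
#' @export
hypergeomPvalue <- function(m, t, n, r) {
  for (v in list(m = m, t = t, n = n, r = r))
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop("m, t, n, r must be single non-negative integers")
  if (t > m) stop("violated: t <= m")
  if (n > m) stop("violated: n <= m")
  if (r > min(t, n)) stop("violated: r <= min(t, n)")
  if (r == 0) return(1)
  x <- r:min(t, n)
  logterms <- lchoose(t, x) + lchoose(m - t, n - x) - lchoose(m, n)
  min(1, exp(.logSumExp(logterms)))
}

#' FDR q-values
#'
#' Benjamini-Hochberg step-up q-values (default), or the
#' Benjamini-Yekutieli variant for arbitrary dependence.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} (default) or \code{"BY"}.
#' @return q-values in the input order.
#' @export
bhFdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}

#' Over-representation analysis against drug-induced lncRNA sets
#'
#' Scores a query lncRNA list against every drug set with the upper-tail
#' hypergeometric test inside a fixed gene universe. Query and sets are
#' intersected with the universe before counting (out-of-universe ids
#' logged); q-values are computed across all tested sets.
#'
#' @param query character vector of query gene ids.
#' @param drug_sets a \linkS4class{DrugSetCollection} (or named list of
#'   character vectors).
#' @param universe character vector of gene ids defining the measurable
#'   universe (typically \code{geneIds} of the reannotation map).
#' @param min_set_size,max_set_size sets outside these bounds (after
#'   universe intersection) are excluded, logged. Defaults are permissive.
#' @param fdr_method passed to \code{\link{bhFdr}}.
#' @return data.frame with one row per tested set, columns \code{drug},
#'   \code{m}, \code{t}, \code{n}, \code{r}, \code{overlap_members}
#'   (comma-joined), \code{p_value}, \code{q_value}; sorted by ascending
#'   p-value, ties broken by drug name.
#' @export
oraEnrich <- function(query, drug_sets, universe,
                      min_set_size = 1L, max_set_size = Inf,
                      fdr_method = c("BH", "BY")) {
  fdr_method <- match.arg(fdr_method)
  if (is(drug_sets, "DrugSetCollection")) drug_sets <- setMembers(drug_sets)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(as.character(query))
  out_q <- setdiff(query, universe)
  if (length(out_q))
    .msg(length(out_q), " query id(s) outside the universe ignored")
  query <- intersect(query, universe)
  if (length(query) == 0L)
    stop("query is empty after intersection with the universe")

  m <- length(universe)
  n <- length(query)
  drugs <- names(drug_sets)
  rows <- vector("list", length(drug_sets))
  for (i in seq_along(drug_sets)) {
    members <- intersect(unique(drug_sets[[i]]), universe)
    t <- length(members)
    if (t < min_set_size || t > max_set_size) {
      .msg("set ", drugs[i], " excluded (size ", t, " outside bounds)")
      next
    }
    ov <- sort(intersect(query, members))
    rows[[i]] <- data.frame(
      drug = drugs[i], m = m, t = t, n = n, r = length(ov),
      overlap_members = .joinIds(ov),
      p_value = hypergeomPvalue(m, t, n, length(ov)),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no drug set passed the size bounds")
  res <- do.call(rbind, rows)
  res$q_value <- bhFdr(res$p_value, fdr_method)
  res <- res[.stableOrder(res$p_value, res$drug), , drop = FALSE]
  rownames(res) <- NULL
  res
}
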
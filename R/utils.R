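# Internal helpers shared across modules.

#' @importFrom stats median rnorm runif sd setNames p.adjust
#' @importFrom utils read.delim write.table packageVersion combn head
NULL

.msg <- function(...) {
  if (isTRUE(getOption("lncSigMatch.verbose", TRUE))) message(...)
  invisible(NULL)
}

# log(sum(exp(x))) without overflow; empty input -> -Inf
.logSumExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# locale-independent ordering (radix = C collation), used everywhere a
# deterministic tie-break on identifiers is required
.stableOrder <- function(...) order(..., method = "radix")

# 31-bit polynomial string hash (stays within exact double arithmetic),
# reported as 8 hex digits. Used to stamp output files with a config
# fingerprint and to derive per-stage seeds.
.hash32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 216613
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# All randomness flows from one user seed; each artifact derives its own
# stream seed so stages are independently reproducible.
.deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- strtoi(.hash32(stream), 16L)
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

# fixed 6-significant-digit float formatting for deterministic writers
.fmtNum <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

# split a comma/semicolon-joined id string into a character vector
.splitIds <- function(x) {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "[,;]")[[1]])
}

.joinIds <- function(x) paste(x, collapse = ",")

# reverse complement for plain character vectors (ACGT only)
.revcompChar <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
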
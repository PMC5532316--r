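# Independent brute-force oracles, deliberately written with different
# machinery than the implementation (base-R substring tables and explicit
# loops instead of Biostrings dictionaries and cumsum).

options(lncSigMatch.verbose = FALSE)

base_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# sliding-window exact-match oracle over named character vectors
oracle_hits <- function(probe_seqs, tx_seqs, gene_id, biotype,
                        strand_mode = "both") {
  L <- nchar(probe_seqs[[1]])
  rows <- list()
  k <- 0L
  for (ti in seq_along(tx_seqs)) {
    s <- tx_seqs[[ti]]
    n <- nchar(s)
    if (n < L) next
    subs <- substring(s, 1:(n - L + 1L), L:n)
    for (pi in seq_along(probe_seqs)) {
      variants <- character(0)
      if (strand_mode %in% c("forward", "both"))
        variants["forward"] <- probe_seqs[[pi]]
      if (strand_mode %in% c("revcomp", "both"))
        variants["revcomp"] <- base_revcomp(probe_seqs[[pi]])
      for (st in names(variants)) {
        for (o in which(subs == variants[[st]])) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            probe_id = names(probe_seqs)[pi],
            transcript_id = names(tx_seqs)[ti],
            gene_id = gene_id[ti], biotype = biotype[ti],
            strand = st, offset = o - 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(probe_id = character(0), transcript_id = character(0),
                      gene_id = character(0), biotype = character(0),
                      strand = character(0), offset = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$probe_id, out$transcript_id, out$offset, out$strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# explicit-loop running-sum oracle; scores/hit in rank order
oracle_es <- function(scores, hit, w) {
  N <- length(hit)
  Nh <- sum(hit)
  denom <- sum(abs(scores[hit])^w)
  run <- 0
  walk <- numeric(N)
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (w == 0) 1 / Nh else abs(scores[i])^w / denom
    } else {
      run <- run - 1 / (N - Nh)
    }
    walk[i] <- run
  }
  best <- 1L
  for (i in seq_len(N)) if (abs(walk[i]) > abs(walk[best])) best <- i
  list(es = walk[best], walk = walk)
}

# exhaustive-enumeration hypergeometric upper tail: overlap of a size-n
# draw from 1..m with the set 1..t
oracle_hyper_enum <- function(m, t, n, r) {
  if (r == 0) return(1)
  if (n == 0) return(0)
  draws <- combn(m, n)
  mean(colSums(draws <= t) >= r)
}

# hand-rolled BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# small fixture spec used across reannotation tests (<=100 probes, <=50
# transcripts)
small_spec <- function(seed, ...) {
  fixtureSpec(seed = seed, n_lnc_genes = 6L, n_coding_genes = 3L,
              transcripts_per_gene = c(1L, 2L),
              transcript_length = c(60L, 120L),
              probes_per_gene = 4L, n_decoy_probes = 3L,
              cross_biotype_fraction = 0.2, ...)
}

tx_as_char <- function(tx) setNames(as.character(tx), names(tx))
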
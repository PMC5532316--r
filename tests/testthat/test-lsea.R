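two_class_expr <- function(seed, n_genes = 30, n_per_class = 5) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(2 * n_per_class))
  expr <- matrix(rnorm(n_genes * length(samples), 7, 1), n_genes,
                 length(samples),
                 dimnames = list(sprintf("G%02d", seq_len(n_genes)), samples))
  labels <- setNames(rep(c(0L, 1L), each = n_per_class), samples)
  list(expr = expr, labels = labels)
}

test_that("ranking metrics match their per-gene formulas", {
  d <- two_class_expr(4, n_genes = 50)
  c1 <- names(d$labels)[d$labels == 1]
  c0 <- names(d$labels)[d$labels == 0]
  for (metric in c("signal2noise", "t_stat", "diff_of_means")) {
    rk <- rankGenes(d$expr, d$labels, metric)
    # direct per-gene recomputation oracle
    for (g in sample(rownames(d$expr), 12)) {
      x1 <- d$expr[g, c1]; x0 <- d$expr[g, c0]
      want <- switch(metric,
        diff_of_means = mean(x1) - mean(x0),
        t_stat = (mean(x1) - mean(x0)) /
          sqrt(var(x1) / length(x1) + var(x0) / length(x0)),
        signal2noise = (mean(x1) - mean(x0)) /
          (max(sd(x1), 0.2 * abs(mean(x1)), 0.2) +
           max(sd(x0), 0.2 * abs(mean(x0)), 0.2)))
      expect_equal(rk$score[rk$gene_id == g], want)
    }
    expect_true(!is.unsorted(rev(rk$score)))
  }
  # identical values in both classes -> score 0 under all metrics
  flat <- d$expr; flat["G01", ] <- 5
  for (metric in c("signal2noise", "t_stat", "diff_of_means")) {
    rk <- rankGenes(flat, d$labels, metric)
    expect_equal(rk$score[rk$gene_id == "G01"], 0)
  }
  # diff_of_means arithmetic
  e <- matrix(c(4, 6, 1, 3), 1, 4,
              dimnames = list("G1", c("a", "b", "c", "d")))
  lab <- setNames(c(1L, 1L, 0L, 0L), colnames(e))
  expect_equal(rankGenes(e, lab, "diff_of_means")$score, 3)
  # single sample per class falls back to diff_of_means
  e1 <- e[, c("a", "c"), drop = FALSE]
  lab1 <- setNames(c(1L, 0L), colnames(e1))
  expect_equal(rankGenes(e1, lab1, "signal2noise")$score, 3)
  expect_error(rankGenes(e, setNames(rep(1L, 4), colnames(e))),
               "non-empty")
})

test_that("the running sum reproduces the worked walk and its bounds", {
  ranked <- data.frame(gene_id = sprintf("g%02d", 1:10),
                       score = seq(10, 1), stringsAsFactors = FALSE)
  members <- c("g01", "g05", "g09")   # hits at ranks 1, 5, 9
  out <- enrichmentScore(ranked, members, weight_exponent = 0)
  walk <- c(1/3, 1/3 - 1/7, 1/3 - 2/7, 1/3 - 3/7, 2/3 - 3/7, 2/3 - 4/7,
            2/3 - 5/7, 2/3 - 6/7, 1 - 6/7, 0)
  expect_equal(out$running_sum, walk, tolerance = 1e-9)
  expect_equal(round(out$running_sum, 4),
               c(0.3333, 0.1905, 0.0476, -0.0952, 0.2381, 0.0952,
                 -0.0476, -0.1905, 0.1429, 0.0000))
  expect_equal(out$es, 1/3, tolerance = 1e-9)
  expect_identical(out$leading_edge, "g01")

  # contiguous top hits attain the maximum ES of 1
  top <- enrichmentScore(ranked, c("g01", "g02", "g03"), 0)
  expect_equal(top$es, 1)
  expect_identical(top$leading_edge, c("g01", "g02", "g03"))

  # equal ranking scores collapse weight 1 onto weight 0
  flat <- transform(ranked, score = 2)
  flat <- flat[order(flat$gene_id), ]
  expect_equal(enrichmentScore(flat, members, 1)$es,
               enrichmentScore(flat, members, 0)$es)

  expect_error(enrichmentScore(ranked, "absent"), "no set member")
  expect_error(enrichmentScore(ranked, ranked$gene_id), "entire")
})

test_that("ES equals the brute-force oracle; weight-0 walks conserve to zero", {
  set.seed(55)
  for (i in 1:60) {
    N <- sample(20:200, 1)
    Nh <- sample(2:min(20, N - 1), 1)
    scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("g%03d", 1:N), score = scores,
                         stringsAsFactors = FALSE)
    members <- ranked$gene_id[sample.int(N, Nh)]
    hit <- ranked$gene_id %in% members
    for (w in c(0, 1)) {
      got <- enrichmentScore(ranked, members, w)
      want <- oracle_es(scores, hit, w)
      expect_equal(got$es, want$es, tolerance = 1e-9)
      expect_equal(got$running_sum, want$walk, tolerance = 1e-9)
      expect_true(abs(got$es) <= 1 + 1e-12)
      expect_lt(abs(got$running_sum[N]), 1e-9)
    }
    # reversing the list negates the extremum of the walk (the sign is
    # only determined when the extremum is unique: with the lattice-valued
    # unweighted walk, +x and -x can tie)
    rev_ranked <- data.frame(gene_id = rev(ranked$gene_id),
                             score = rev(scores))
    es_fwd <- enrichmentScore(ranked, members, 0)$es
    es_rev <- enrichmentScore(rev_ranked, members, 0)$es
    expect_equal(abs(es_rev), abs(es_fwd), tolerance = 1e-9)
    walk <- oracle_es(scores, hit, 0)$walk
    tied <- any(walk >= abs(es_fwd) - 1e-9) &&
      any(walk <= -abs(es_fwd) + 1e-9)
    if (!tied) expect_equal(es_rev, -es_fwd, tolerance = 1e-9)
  }
})

test_that("weighted ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  for (i in 1:25) {
    N <- sample(30:150, 1)
    scores <- sort(rnorm(N, 0, 1.5), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("g%03d", 1:N), score = scores,
                         stringsAsFactors = FALSE)
    idx <- sort(sample.int(N, sample(3:15, 1)))
    stats <- setNames(scores, ranked$gene_id)
    for (w in c(0, 1)) {
      got <- enrichmentScore(ranked, ranked$gene_id[idx], w)$es
      want <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = w)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("permutation null is seeded, centered, and shaped as requested", {
  d <- two_class_expr(8, n_genes = 25, n_per_class = 6)
  sets <- list(A = rownames(d$expr)[1:5], B = rownames(d$expr)[6:12])
  p <- lseaParams(n_permutations = 50, seed = 3)
  n1 <- permutationNull(d$expr, d$labels, sets, p)
  n2 <- permutationNull(d$expr, d$labels, sets, p)
  expect_identical(n1, n2)
  expect_identical(dim(n1), c(50L, 2L))
  expect_false(identical(n1,
    permutationNull(d$expr, d$labels, sets,
                    lseaParams(n_permutations = 50, seed = 4))))
  p1 <- lseaParams(n_permutations = 1, seed = 1)
  expect_identical(nrow(permutationNull(d$expr, d$labels, sets, p1)), 1L)

  # label-exchangeable data: null ES mean near zero
  big <- permutationNull(d$expr, d$labels, sets,
                         lseaParams(n_permutations = 2000, seed = 5))
  for (j in 1:2) {
    se <- sd(big[, j]) / sqrt(nrow(big))
    expect_lt(abs(mean(big[, j])), 3 * se + 1e-3)
  }

  # too few samples for phenotype permutation: advice to switch modes
  small <- d$expr[, c(1, 2, 7)]
  lab <- setNames(c(0L, 0L, 1L), colnames(small))
  expect_error(permutationNull(small, lab, sets,
                               lseaParams(n_permutations = 10)),
               "gene_set")
  gs <- permutationNull(small, lab, sets,
                        lseaParams(n_permutations = 10,
                                   permutation_mode = "gene_set"))
  expect_identical(dim(gs), c(10L, 2L))
})

test_that("normalization and testing follow the permutation conventions", {
  obs <- c(A = 0.8, B = -0.5, C = 0)
  set.seed(9)
  null <- cbind(A = c(runif(40, 0.05, 0.6), -runif(10, 0.05, 0.6)),
                B = c(runif(25, 0.05, 0.6), -runif(25, 0.05, 0.6)),
                C = c(runif(25, 0.05, 0.6), -runif(25, 0.05, 0.6)))
  res <- normalizeAndTest(obs, null)
  a <- res[res$drug == "A", ]
  pos <- null[, "A"][null[, "A"] > 0]
  expect_equal(a$nes, 0.8 / mean(pos))
  # es above every same-sign null: add-one lower bound
  expect_equal(a$p_nominal, 1 / (1 + length(pos)))
  b <- res[res$drug == "B", ]
  neg <- null[, "B"][null[, "B"] < 0]
  expect_equal(b$nes, -0.5 / mean(abs(neg)))
  expect_equal(b$p_nominal,
               (1 + sum(neg <= -0.5)) / (1 + length(neg)))
  cc <- res[res$drug == "C", ]
  expect_equal(cc$nes, 0)
  expect_equal(cc$p_nominal, 1)
  expect_true(all(res$p_fwer >= res$p_nominal))
  expect_true(all(res$q_fdr >= 0 & res$q_fdr <= 1))
  expect_identical(res$drug[1], "A")
})

test_that("lsea is deterministic and antisymmetric under label swap", {
  d <- two_class_expr(12, n_genes = 40, n_per_class = 6)
  set.seed(31)
  sets <- lapply(1:6, function(i) sample(rownames(d$expr), 8))
  names(sets) <- sprintf("drug%02d", 1:6)
  p <- lseaParams(n_permutations = 100, seed = 2)
  r1 <- lsea(d$expr, d$labels, sets, p)
  r2 <- lsea(d$expr, d$labels, sets, p)
  expect_identical(r1, r2)

  # swapping the labels negates the observed scores exactly; the
  # null-derived quantities match up to occasional extremum ties in
  # permuted walks, so they are compared with a small tolerance
  swapped <- setNames(1L - d$labels, names(d$labels))
  r3 <- lsea(d$expr, swapped, sets, p)
  m <- match(r1$drug, r3$drug)
  expect_equal(r3$es[m], -r1$es, tolerance = 1e-9)
  expect_equal(r3$nes[m], -r1$nes, tolerance = 0.05)
  expect_equal(r3$p_nominal[m], r1$p_nominal, tolerance = 0.05)

  tiny <- list(X = c("nope1", "nope2"))
  expect_error(lsea(d$expr, d$labels, tiny, p), "overlap")
})

test_that("a planted top-ranked set attains rank 1 by nominal p", {
  spec <- fixtureSpec(seed = 101)
  txo <- simulateTranscriptome(spec)
  pro <- simulateProbes(txo, spec)
  ins <- simulateInstances(pro$truth, spec)
  dis <- simulateDiseaseProfile(ins$truth$del_sets, spec)
  res <- lsea(dis$expr, dis$labels, ins$truth$del_sets,
              lseaParams(n_permutations = 500, seed = 101,
                         permutation_mode = "gene_set"))
  expect_identical(res$drug[1], dis$target_drug)
  expect_lt(res$p_nominal[1], 0.05)
})
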
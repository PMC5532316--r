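test_that("exact matching finds planted probes with correct offset and strand", {
  set.seed(42)
  tx_seq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  tx <- transcriptSet(c(T1 = tx_seq), gene_id = "G1", biotype = "lncRNA")
  planted <- substr(tx_seq, 11, 35)   # offset 10, 0-based
  probes <- probeSet(c(p_fwd = planted, p_rc = base_revcomp(planted),
                       p_absent = paste0(strrep("AC", 12), "A")))
  hits <- findExactHits(probes, tx)
  expect_setequal(unique(hits$probe_id), c("p_fwd", "p_rc"))
  fwd <- hits[hits$probe_id == "p_fwd", ]
  expect_true(any(fwd$offset == 10L & fwd$strand == "forward"))
  rc <- hits[hits$probe_id == "p_rc", ]
  expect_true(any(rc$offset == 10L & rc$strand == "revcomp"))

  fwd_only <- findExactHits(probes, tx,
                            reannotationParams(strand_mode = "forward"))
  expect_true(all(fwd_only$strand == "forward"))
  # restricting the strand mode never adds a hit
  expect_true(nrow(fwd_only) <= nrow(hits))

  expect_error(findExactHits(probes[0], tx), "empty probe")
  expect_error(findExactHits(probes, tx[0]), "empty transcript")
  # probe longer than every transcript: zero hits, not an error
  short_tx <- transcriptSet(c(S1 = "ACGTACGT"), gene_id = "G9",
                            biotype = "lncRNA")
  expect_identical(nrow(findExactHits(probes, short_tx)), 0L)
})

test_that("hit lists equal the naive sliding-window oracle on random fixtures", {
  for (seed in 1:6) {
    spec <- small_spec(seed)
    txo <- simulateTranscriptome(spec)
    pro <- simulateProbes(txo, spec, min_probes_per_gene = 2L)
    tx <- pro$transcripts
    meta <- S4Vectors::mcols(tx)
    probe_chr <- setNames(as.character(pro$probes), names(pro$probes))
    for (mode in c("both", "forward")) {
      got <- findExactHits(pro$probes, tx,
                           reannotationParams(strand_mode = mode))
      want <- oracle_hits(probe_chr, tx_as_char(tx), meta$gene_id,
                          meta$biotype, strand_mode = mode)
      expect_equal(got, want)
    }
  }
})

test_that("cross-biotype probes are removed entirely, by set algebra", {
  hits <- data.frame(
    probe_id = c("p1", "p1", "p2", "p3", "p3"),
    transcript_id = c("L1", "C1", "L1", "C1", "C2"),
    gene_id = c("A", "X", "A", "X", "Y"),
    biotype = c("lncRNA", "protein_coding", "lncRNA",
                "protein_coding", "protein_coding"),
    strand = "forward", offset = 0L, stringsAsFactors = FALSE)
  out <- filterCrossBiotype(hits)
  # p1 hits lncRNA and coding -> all hits gone; p3 coding-only -> gone
  expect_identical(unique(out$probe_id), "p2")
  # idempotent
  expect_identical(filterCrossBiotype(out), out)
  expect_identical(nrow(filterCrossBiotype(hits[0, ])), 0L)

  # random fixture: survivor set equals the set-difference oracle
  spec <- small_spec(11)
  pro <- simulateProbes(simulateTranscriptome(spec), spec)
  all_hits <- findExactHits(pro$probes, pro$transcripts)
  kept <- filterCrossBiotype(all_hits)
  bad <- unique(all_hits$probe_id[all_hits$biotype == "protein_coding"])
  expect_setequal(unique(kept$probe_id),
                  setdiff(unique(all_hits$probe_id), bad))
})

test_that("gene-level collapse deduplicates isoforms and drops multi-gene probes", {
  hits <- data.frame(
    probe_id = c("p1", "p1", "p2", "p2", "p3"),
    transcript_id = c("A.T1", "A.T2", "A.T1", "B.T1", "B.T1"),
    gene_id = c("A", "A", "A", "B", "B"),
    biotype = "lncRNA", strand = "forward", offset = 0L,
    stringsAsFactors = FALSE)
  g2p <- collapseToGenes(hits)
  expect_identical(g2p, list(A = "p1", B = "p3"))
  expect_error(collapseToGenes(transform(hits, biotype = "protein_coding")),
               "lncRNA-only")

  # random fixture: per-gene probe sets equal a group-by oracle
  spec <- small_spec(5)
  pro <- simulateProbes(simulateTranscriptome(spec), spec)
  lnc <- filterCrossBiotype(findExactHits(pro$probes, pro$transcripts))
  got <- collapseToGenes(lnc)
  pairs <- unique(lnc[, c("gene_id", "probe_id")])
  multi <- names(which(tapply(pairs$gene_id, pairs$probe_id,
                              function(g) length(unique(g))) > 1))
  pairs <- pairs[!pairs$probe_id %in% multi, ]
  want <- lapply(split(pairs$probe_id, pairs$gene_id), sort)
  expect_identical(got, want[order(names(want), method = "radix")])
})

test_that("minimum-probe filter keeps exactly the supported genes", {
  gm <- list(A = paste0("a", 1:5), B = paste0("b", 1:2), C = paste0("c", 1:3))
  map <- applyMinProbeFilter(gm, 3L)
  expect_identical(geneIds(map), c("A", "C"))
  expect_identical(map@provenance$genes_removed_min_probes, 1L)
  expect_error(applyMinProbeFilter(gm, 0L), ">= 1")
})

test_that("full filter chain reproduces fixture truth with balanced provenance", {
  for (seed in c(3, 17)) {
    spec <- small_spec(seed)
    pro <- simulateProbes(simulateTranscriptome(spec), spec,
                          min_probes_per_gene = 2L)
    params <- reannotationParams(min_probes_per_gene = 2L)
    map <- buildReannotation(pro$probes, pro$transcripts, params)
    expect_identical(map@geneToProbes, pro$truth$expected_map)

    pv <- map@provenance
    expect_identical(pv$probes_input,
                     pv$probes_unmatched + pv$probes_matched)
    expect_identical(pv$probes_matched,
                     pv$probes_cross_biotype_removed +
                       pv$probes_after_cross_filter)
    expect_identical(pv$probes_after_cross_filter,
                     pv$probes_multi_gene_removed +
                       pv$probes_after_gene_collapse)
    expect_identical(pv$probes_after_gene_collapse,
                     pv$probes_in_dropped_genes + pv$probes_retained)

    # raising min_probes_per_gene never adds a gene
    stricter <- buildReannotation(pro$probes, pro$transcripts,
                                  reannotationParams(min_probes_per_gene = 3L))
    expect_true(all(geneIds(stricter) %in% geneIds(map)))

    # identical call twice -> byte-identical serialized map
    f1 <- tempfile(); f2 <- tempfile()
    writeReannotationMap(map, f1)
    writeReannotationMap(buildReannotation(pro$probes, pro$transcripts,
                                           params), f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("an all-coding transcriptome yields an empty map, not an error", {
  tx <- transcriptSet(c(C1 = strrep("ACGT", 20)), gene_id = "X",
                      biotype = "protein_coding")
  probes <- probeSet(c(p1 = substr(strrep("ACGT", 20), 1, 25)))
  map <- buildReannotation(probes, tx)
  expect_length(geneIds(map), 0L)
})
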
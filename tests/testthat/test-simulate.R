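## Synthetic truth generator, count simulator, mini-SAM writer, metrics.

test_that("perturbation classes follow the half/double and swap rules", {
  tr <- simulateTruth(n_genes = 200, seed = 10)
  g <- tr$genes
  expect_equal(sort(unique(g$class)), sort(c("NONE", "DE", "DS", "DE-DS")))
  expect_equal(unname(table(g$class)[c("NONE", "DE", "DS", "DE-DS")]),
               rep(50L, 4), ignore_attr = TRUE)
  for (i in seq_len(nrow(g))) {
    P <- tr$props[[i]]
    mu <- tr$total_mean[i, ]
    if (g$class[i] == "NONE") {
      expect_equal(P[1, ], P[2, ])
      expect_equal(mu[1], mu[2])
    } else if (g$class[i] == "DE") {
      expect_true(mu[2] %in% c(mu[1] / 2, mu[1] * 2))
      expect_equal(P[1, ], P[2, ])
    } else if (g$class[i] == "DS") {
      expect_equal(mu[1], mu[2])
      expect_equal(P[2, 1:2], P[1, 2:1])   # top two proportions swapped
      if (g$k[i] > 2) expect_equal(P[2, 3], P[1, 3])
    } else {
      expect_true(mu[2] %in% c(mu[1] / 2, mu[1] * 2))
      expect_equal(P[2, 1:2], P[1, 2:1])
    }
    expect_equal(rowSums(P), c(1, 1))
    ## baseline proportions sorted decreasing (the "top two" are 1 and 2)
    expect_true(all(diff(P[1, ]) <= 0))
  }
})

test_that("simulation is reproducible and respects the planted structure", {
  tr <- simulateTruth(n_genes = 25, seed = 3)
  jx1 <- simulateJunctionExperiment(tr, n_per_condition = 8, seed = 4)
  jx2 <- simulateJunctionExperiment(tr, n_per_condition = 8, seed = 4)
  expect_identical(counts(jx1), counts(jx2))
  jx3 <- simulateJunctionExperiment(tr, n_per_condition = 8, seed = 5)
  expect_false(identical(counts(jx1), counts(jx3)))
  ## builder-grouped bunches coincide with the planted genes
  rd <- SummarizedExperiment::rowData(jx1)
  expect_equal(length(unique(rd$bunch_id)), 25)
  expect_true(all(tapply(rd$gene_ids, rd$bunch_id,
                         function(g) length(unique(g))) == 1))
})

test_that("empirical per-condition means converge to the truth", {
  tr <- simulateTruth(n_genes = 12, seed = 21, mean_sdlog = 0.3)
  jx <- simulateJunctionExperiment(tr, n_per_condition = 1000,
                                   libsize_sdlog = 0, seed = 22)
  cond <- sampleConditions(jx)
  rd <- SummarizedExperiment::rowData(jx)
  k <- tr$genes$k
  row_gene <- rep(seq_len(nrow(tr$genes)), k)
  member <- unlist(lapply(k, seq_len))
  truth_mean <- vapply(seq_len(nrow(jx)), function(r) {
    g <- row_gene[r]
    tr$total_mean[g, ] * tr$props[[g]][, member[r]]
  }, numeric(2))
  for (i in 1:2) {
    emp <- rowMeans(counts(jx)[, cond == paste0("cond", i)])
    rel <- abs(emp - truth_mean[i, ]) / pmax(truth_mean[i, ], 1)
    expect_lt(median(rel), 0.05)
  }
})

test_that("mini-SAM output realizes the truth table exactly", {
  gr <- random_junctions(40, seed = 6)
  cm <- matrix(rpois(length(gr) * 3, 6), ncol = 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  d <- tempfile()
  paths <- writeMiniSam(gr, cm, d, seed = 7)
  expect_length(paths, 3)
  for (j in seq_along(paths)) {
    jx <- extractJunctions(paths[[j]])
    truth_key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr),
                       GenomicRanges::end(gr), GenomicRanges::strand(gr))
    got_key <- paste(GenomicRanges::seqnames(jx), GenomicRanges::start(jx),
                     GenomicRanges::end(jx), GenomicRanges::strand(jx))
    nonzero <- cm[, j] > 0
    expect_setequal(got_key, truth_key[nonzero])
    expect_equal(jx$count[match(truth_key[nonzero], got_key)],
                 unname(cm[nonzero, j]))
  }
  ## zero-count junctions emit no records; decoys never create junctions
  expect_true(file.exists(file.path(d, "truth.tsv")))
})

test_that("mini-SAM generation is byte-stable given truth and seed", {
  gr <- random_junctions(10, seed = 8)
  cm <- matrix(3L, length(gr), 1, dimnames = list(NULL, "s1"))
  p1 <- writeMiniSam(gr, cm, tempfile(), seed = 9)
  p2 <- writeMiniSam(gr, cm, tempfile(), seed = 9)
  expect_identical(readLines(p1[[1]]), readLines(p2[[1]]))
})

test_that("benchmark metrics implement Sn, Pr and F1 with the gold sets", {
  tr <- simulateTruth(n_genes = 40, seed = 12)
  gold_dsr <- tr$genes$gene_id[tr$genes$class %in% c("DS", "DE-DS")]
  perfect <- evaluateCalls(gold_dsr, tr, "DSR")
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  none <- evaluateCalls(character(0), tr, "DSR")
  expect_equal(none$sensitivity, 0)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)
  ## TP=3, FP=1, FN=rest; DE genes count as DSA gold but DSR false calls
  some <- evaluateCalls(c(gold_dsr[1:3], "not_a_gene"), tr, "DSR")
  expect_equal(some$tp, 3)
  expect_equal(some$fp, 1)
  expect_equal(some$precision, 0.75)
  expect_equal(some$sensitivity, 3 / length(gold_dsr))
  de_gene <- tr$genes$gene_id[tr$genes$class == "DE"][1]
  expect_equal(evaluateCalls(de_gene, tr, "DSR")$fp, 1)
  expect_equal(evaluateCalls(de_gene, tr, "DSA")$tp, 1)
})
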
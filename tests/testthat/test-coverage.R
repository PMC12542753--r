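test_that("bedGraph sets round-trip through manifest reader", {
  set.seed(7)
  L <- 400
  fwd <- matrix(rpois(L * 6, 5), L, 6)
  rev <- matrix(rpois(L * 6, 2), L, 6)
  exp <- toy_experiment(fwd, rev, n_replicates = 2)
  dir <- withr::local_tempdir()
  mp <- write_bedgraph_set(exp, dir)
  back <- read_bedgraph_set(mp, genome_length = L)
  expect_equal(back$tracks, exp$tracks)
  expect_equal(back$library_size, exp$library_size)
  expect_equal(back$timepoints, exp$timepoints)
})

test_that("manifest gaps and overlapping intervals are rejected", {
  exp <- toy_experiment_const(c(rep(0, 10), rep(5, 10)), n_replicates = 2)
  dir <- withr::local_tempdir()
  mp <- write_bedgraph_set(exp, dir)
  manifest <- read.delim(mp)
  # drop the reverse strand of one sample
  drop <- manifest$strand == "-" & manifest$timepoint_min == 60 &
    manifest$replicate == 2
  expect_error(read_bedgraph_set(manifest[!drop, ], dir = dir),
               "60 2 -")
  # overlapping intervals within one file
  bad <- file.path(dir, "bad.bedGraph")
  writeLines(c("toy\t0\t10\t5", "toy\t5\t15\t3"), bad)
  m2 <- manifest
  m2$path[1] <- "bad.bedGraph"
  expect_error(read_bedgraph_set(m2, dir = dir), "overlapping")
  # an empty bedGraph yields an all-zero track
  writeLines(character(0), file.path(dir, "empty.bedGraph"))
  m3 <- manifest
  m3$path[1] <- "empty.bedGraph"
  back <- read_bedgraph_set(m3, dir = dir, genome_length = 20)
  expect_true(all(back$tracks[, 1, 1, m3$strand[1]] == 0))
})

test_that("bedGraph intervals are 0-based half-open on disk", {
  dir <- withr::local_tempdir()
  bg <- file.path(dir, "one.bedGraph")
  writeLines("toy\t0\t10\t5", bg)   # covers 1-based positions 1..10
  manifest <- data.frame(path = "one.bedGraph", timepoint_min = 5,
                         replicate = 1, strand = "+", library_size = 1e6)
  manifest <- rbind(manifest,
                    within(manifest, strand <- "-"))
  writeLines(character(0), file.path(dir, "zero.bedGraph"))
  manifest$path[2] <- "zero.bedGraph"
  exp <- read_bedgraph_set(manifest, dir = dir, genome_length = 20)
  expect_equal(exp$tracks[, 1, 1, "+"], c(rep(5, 10), rep(0, 10)))
})

test_that("gene_rpkm matches its definition and scale laws", {
  # 1000-nt feature, depth such that count_equiv = 100 reads, library 1e6
  L <- 1200
  depth <- 100 * 75 / 1000   # sum(depth)/75 = 100 over 1000 bases
  v <- c(rep(0, 100), rep(depth, 1000), rep(0, 100))
  exp <- toy_experiment_const(v, library_size = 1e6)
  feat <- toy_feature(101, 1100)
  expect_equal(gene_rpkm(exp, feat, 5, 1), 100)
  # all-zero track
  feat0 <- toy_feature(1, 50)
  exp0 <- toy_experiment_const(rep(0, 100))
  expect_equal(gene_rpkm(exp0, feat0, 5, 1), 0)
  # doubling library size halves RPKM
  exp2 <- toy_experiment_const(v, library_size = 2e6)
  expect_equal(gene_rpkm(exp2, feat, 5, 1), 50)
  # additive over disjoint sub-intervals weighted by length
  left <- toy_feature(101, 600); right <- toy_feature(601, 1100)
  lw <- 500 / 1000
  expect_equal(gene_rpkm(exp, feat, 5, 1),
               lw * gene_rpkm(exp, left, 5, 1) +
                 (1 - lw) * gene_rpkm(exp, right, 5, 1))
})

test_that("gene_rpkm equals a per-position brute-force oracle", {
  set.seed(11)
  for (i in 1:10) {
    L <- 200
    v <- rpois(L, 20)
    lib <- sample(5e5:2e6, 1)
    exp <- toy_experiment_const(v, library_size = lib)
    s <- sample(1:150, 1); e <- s + sample(10:49, 1)
    feat <- toy_feature(s, e)
    oracle <- {
      tot <- 0
      for (p in s:e) tot <- tot + v[p]
      (tot / 75) * 1e9 / ((e - s + 1) * lib)
    }
    expect_equal(gene_rpkm(exp, feat, 5, 1), oracle, tolerance = 1e-12)
  }
})

test_that("temporal profiles are percent-of-max and scale invariant", {
  L <- 120
  base <- c(2, 10, 5, 4, 3, 1)
  fwd <- matrix(rep(base, each = L), L, 6)
  exp <- toy_experiment(fwd)
  feat <- toy_feature(11, 110)
  pr <- temporal_profile(exp, feat)
  expect_equal(pr$pct_of_max, c(20, 100, 50, 40, 30, 10))
  expect_true(pr$expressed)
  expect_equal(max(pr$pct_of_max), 100)
  # uniform track rescaling leaves pct_of_max unchanged
  pr2 <- temporal_profile(toy_experiment(fwd * 7.3), feat)
  expect_equal(pr2$pct_of_max, pr$pct_of_max)
  # uniform library rescaling leaves pct_of_max unchanged
  pr3 <- temporal_profile(toy_experiment(fwd, library_size = 3.1e6), feat)
  expect_equal(pr3$pct_of_max, pr$pct_of_max)
  # all-zero gene: unexpressed, NA percent vector, no crash
  pr0 <- temporal_profile(exp, toy_feature(1, 5, "-"))
  expect_false(pr0$expressed)
  expect_true(all(is.na(pr0$pct_of_max)))
})

test_that("temporal_profiles matrix agrees with the single-feature path", {
  set.seed(3)
  L <- 300
  fwd <- matrix(rpois(L * 6, 30), L, 6)
  rev <- matrix(rpois(L * 6, 10), L, 6)
  exp <- toy_experiment(fwd, rev, n_replicates = 3)
  ann <- toy_annotation(toy_feature(21, 120, "+", "a"),
                        toy_feature(151, 260, "-", "b"),
                        genome_length = L)
  prs <- temporal_profiles(exp, ann)
  for (i in 1:2) {
    single <- temporal_profile(exp, ann$features[i, ])
    expect_equal(unname(prs$rpkm[i, ]), single$rpkm)
    expect_equal(unname(prs$pct_of_max[i, ]), single$pct_of_max)
  }
})
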
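step_track <- function(L, at, depth) c(rep(0, at - 1), rep(depth, L - at + 1))

test_that("an ideal replicated coverage step yields a single exact TSS", {
  L <- 400
  exp <- toy_experiment_const(step_track(L, 100, 50), n_replicates = 3)
  tss <- detect_tss(exp, "+")
  expect_equal(nrow(tss), 1L)
  expect_equal(tss$position, 100L)
  expect_equal(tss$strand, "+")
  expect_true(tss$step_ratio >= 5)
  # nothing on the empty strand
  expect_equal(nrow(detect_tss(exp, "-")), 0L)
})

test_that("a linear ramp produces no TSS", {
  L <- 700
  ramp <- c(rep(0, 100), seq(0, 50, length.out = 500), rep(50, 100))
  exp <- toy_experiment_const(ramp, n_replicates = 3)
  expect_equal(nrow(detect_tss(exp, "+")), 0L)
})

test_that("the replicate quorum suppresses irreproducible steps", {
  L <- 400
  nt <- length(default_tp)
  tracks <- array(0, dim = c(L, nt, 3, 2),
                  dimnames = list(NULL, NULL, NULL, c("+", "-")))
  stepv <- step_track(L, 100, 50)
  for (ti in seq_len(nt)) {
    tracks[, ti, 1, "+"] <- stepv
    tracks[, ti, 2, "+"] <- stepv
    # replicate 3 never shows the step
  }
  exp <- coverage_experiment(tracks, default_tp, matrix(1e6, nt, 3))
  expect_equal(nrow(detect_tss(exp, "+", replicate_quorum = 3)), 0L)
  expect_equal(detect_tss(exp, "+", replicate_quorum = 2)$position, 100L)
})

test_that("reverse-strand TSSs mirror forward ones", {
  set.seed(5)
  L <- 1000
  fwd <- step_track(L, 301, 60)   # forward TSS at 301
  exp <- toy_experiment_const(fwd, n_replicates = 2)
  f <- detect_tss(exp, "+")
  # mirrored genome: reverse strand carries the mirrored track
  exp_m <- toy_experiment_const(rep(0, L), rev_vec = rev(fwd),
                                n_replicates = 2)
  r <- detect_tss(exp_m, "-")
  expect_equal(nrow(r), nrow(f))
  expect_equal(r$position, L - f$position + 1L)
})

test_that("TSS orientation follows the precedence rules", {
  ann <- toy_annotation(
    toy_feature(500, 900, "+", "fwdA"),
    toy_feature(1200, 1500, "-", "revB"),
    genome_length = 2000)
  t0 <- data.frame(position = c(350, 700, 1300, 1550, 60),
                   strand = c("+", "+", "+", "-", "+"),
                   stringsAsFactors = FALSE)
  out <- orient_tss(t0, ann)
  # 150 nt upstream of fwdA, outside all features -> sense
  expect_equal(out$orientation[1], "sense")
  expect_equal(out$target_feature[1], "fwdA")
  # inside a same-strand ORF -> internal promoter
  expect_equal(out$orientation[2], "internal_sense")
  expect_equal(out$target_feature[2], "fwdA")
  # forward TSS inside a reverse ORF -> antisense
  expect_equal(out$orientation[3], "antisense")
  expect_equal(out$target_feature[3], "revB")
  # reverse TSS 50 nt upstream (to the right) of revB 5' end -> sense
  expect_equal(out$orientation[4], "sense")
  # far from everything -> orphan
  expect_equal(out$orientation[5], "orphan")
})

test_that("antisense-dominated genes are called at >= 3 timepoints", {
  L <- 300
  feat <- toy_feature(51, 250, "+", "g1")
  ann <- toy_annotation(feat, genome_length = L)
  sense <- matrix(rep(c(10, 10, 10, 5, 5, 5), each = L), L, 6)
  anti <- matrix(rep(c(0, 0, 0, 50, 50, 50), each = L), L, 6)
  exp <- toy_experiment(sense, anti, n_replicates = 2)
  out <- call_antisense_genes(exp, ann)
  expect_equal(out$n_antisense_dominant, 3L)
  expect_true(out$called)
  # two dominant timepoints are not enough
  anti2 <- matrix(rep(c(0, 0, 0, 0, 50, 50), each = L), L, 6)
  out2 <- call_antisense_genes(toy_experiment(sense, anti2), ann)
  expect_equal(out2$n_antisense_dominant, 2L)
  expect_false(out2$called)
  # sense identically zero, antisense positive at all timepoints
  zero <- matrix(0, L, 6)
  anti3 <- matrix(5, L, 6)
  out3 <- call_antisense_genes(toy_experiment(zero, anti3), ann)
  expect_equal(out3$n_antisense_dominant, 6L)
  expect_true(out3$called)
  # swapping replicate order changes nothing
  exp_sw <- exp
  exp_sw$tracks <- exp$tracks[, , 2:1, ]
  expect_equal(call_antisense_genes(exp_sw, ann), out)
})

test_that("TSS profiles are percent-of-max with late shapes preserved", {
  L <- 200
  shape <- c(0, 0, 10, 40, 100, 60)
  fwd <- matrix(0, L, 6)
  fwd[101:L, ] <- rep(shape, each = 100)
  exp <- toy_experiment(fwd, n_replicates = 3)
  pr <- tss_profile(exp, 101, "+")
  expect_equal(pr$pct_of_max, 100 * shape / max(shape))
  expect_equal(which.max(pr$pct_of_max), 5L)  # peaks at 180 min
  # constant coverage -> flat 100%
  flat <- tss_profile(toy_experiment_const(rep(7, L)), 50, "+")
  expect_equal(flat$pct_of_max, rep(100, 6))
  # group of one TSS has sd 0 everywhere
  grp <- tss_profile_group(exp, data.frame(position = 101, strand = "+"))
  expect_equal(grp$sd, rep(0, 6))
  expect_equal(grp$n, 1L)
  # window beyond the genome end warns and truncates
  expect_warning(tss_profile(exp, L - 3, "+"), "truncated")
})

test_that("planted-step genomes are recovered exactly and exclusively", {
  set.seed(9)
  for (rep in 1:5) {
    L <- 4000
    starts <- sort(sample(seq(100, L - 300, by = 400), 4))
    v <- rep(0, L)
    for (s in starts) v[s:min(L, s + 250)] <- v[s:min(L, s + 250)] + 40
    exp <- toy_experiment_const(v, n_replicates = 3)
    tss <- detect_tss(exp, "+")
    expect_equal(tss$position, starts)
  }
})
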
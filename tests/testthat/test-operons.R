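# assemble_operons expects: annotation, classes (feature_id + label),
# experiment, oriented TSS table

classes_df <- function(ids, labels)
  data.frame(feature_id = ids, label = labels, stringsAsFactors = FALSE)

tss_df <- function(position = integer(), strand = character(),
                   orientation = character())
  data.frame(position = position, strand = strand,
             orientation = orientation, stringsAsFactors = FALSE)

test_that("same-class contiguous covered genes form one operon", {
  # gaps {0, -4}: g1 ends 200, g2 starts 201; g2 ends 400, g3 starts 397
  ann <- toy_annotation(toy_feature(101, 200, "+", "g1"),
                        toy_feature(201, 400, "+", "g2"),
                        toy_feature(397, 520, "+", "g3"),
                        genome_length = 800)
  cov <- rep(0, 800); cov[60:540] <- 50
  exp <- toy_experiment_const(cov)
  tss <- tss_df(60, "+", "sense")
  ops <- assemble_operons(ann, classes_df(c("g1", "g2", "g3"), "middle"),
                          exp, tss)
  expect_length(ops, 1L)
  expect_equal(ops[[1]]$members, c("g1", "g2", "g3"))
  expect_equal(ops[[1]]$leading_tss, 60)
  expect_false(ops[[1]]$monocistronic)
  expect_false(ops[[1]]$orphan)
})

test_that("an internal promoter splits a gene run at the truncated gene", {
  # nine abutting genes: 1-4 middle_down, 5-9 middle, internal TSS in g5;
  # hand-traced expectation: units {g1..g4} and {g5..g9}
  n <- 9
  starts <- 101 + (0:(n - 1)) * 150
  feats <- do.call(rbind, lapply(seq_len(n), function(i)
    toy_feature(starts[i], starts[i] + 149, "+", sprintf("g%d", i))))
  ann <- genome_annotation(feats, "toy", 2200)
  labels <- c(rep("middle_down", 4), rep("middle", 5))
  ip <- starts[5] + 70
  # coverage: upstream transcript over g1-g4 peaking early-mid, downstream
  # transcript from the internal promoter to g9
  cov <- matrix(0, 2200, 6)
  cov[70:(starts[5] - 1), ] <- rep(c(5, 25, 50, 20, 8, 5) * 10, each =
                                     length(70:(starts[5] - 1)))
  cov[ip:(starts[9] + 149), ] <- rep(c(2, 10, 50, 45, 40, 35) * 10, each =
                                       length(ip:(starts[9] + 149)))
  exp <- toy_experiment(cov)
  tss <- tss_df(c(70, ip), c("+", "+"), c("sense", "internal_sense"))
  ops <- assemble_operons(ann, classes_df(feats$feature_id, labels), exp,
                          tss)
  expect_length(ops, 2L)
  expect_equal(ops[[1]]$members, sprintf("g%d", 1:4))
  expect_equal(ops[[2]]$members, sprintf("g%d", 5:9))
  expect_equal(ops[[2]]$leading_tss, ip)
  expect_true(ops[[2]]$internal_promoter)
  expect_true(ops[[2]]$first_member_truncated)
  expect_false(ops[[1]]$first_member_truncated)
})

test_that("an uncovered gap breaks continuity into two units", {
  ann <- toy_annotation(toy_feature(101, 300, "+", "g1"),
                        toy_feature(321, 520, "+", "g2"),
                        genome_length = 900)
  cov <- rep(0, 900)
  cov[80:300] <- 50        # only g1 covered; 20-nt gap and g2 uncovered
  cov[480:560] <- 50       # partial g2 coverage, span mostly uncovered
  exp <- toy_experiment_const(cov)
  tss <- tss_df(80, "+", "sense")
  ops <- assemble_operons(ann, classes_df(c("g1", "g2"), "late"), exp, tss)
  expect_length(ops, 2L)
  expect_true(all(vapply(ops, `[[`, logical(1), "monocistronic")))
})

test_that("reverse-strand operons chain in transcription order", {
  # two abutting reverse genes transcribed right-to-left, TSS to the right
  ann <- toy_annotation(toy_feature(201, 400, "-", "g1"),
                        toy_feature(401, 600, "-", "g2"),
                        genome_length = 900)
  rev_cov <- rep(0, 900); rev_cov[180:650] <- 40
  exp <- toy_experiment_const(rep(0, 900), rev_vec = rev_cov)
  tss <- tss_df(650, "-", "sense")
  ops <- assemble_operons(ann, classes_df(c("g1", "g2"), "late"), exp, tss)
  expect_length(ops, 1L)
  expect_equal(ops[[1]]$members, c("g2", "g1"))  # 5' gene first
  expect_equal(ops[[1]]$leading_tss, 650)
})

test_that("operon summaries do the stated arithmetic", {
  # 28 units, 12 monocistronic, 80 genes
  sizes <- c(rep(1, 12), rep(4, 12), rep(5, 4))
  fake <- structure(lapply(seq_along(sizes), function(i)
    list(members = sprintf("u%d_%d", i, seq_len(sizes[i])))),
    class = "operon_set")
  s <- summarize_operons(fake)
  expect_equal(s$n_units, 28)
  expect_equal(s$n_monocistronic, 12)
  expect_equal(s$pct_monocistronic, 42.9)
  expect_equal(s$mean_genes_per_operon, 80 / 28, tolerance = 1e-12)
  # degenerate cases
  one <- structure(list(list(members = "a")), class = "operon_set")
  s1 <- summarize_operons(one)
  expect_equal(s1$pct_monocistronic, 100)
  expect_equal(s1$mean_genes_per_operon, 1)
  two <- structure(list(list(members = "a"),
                        list(members = c("b", "c", "d"))),
                   class = "operon_set")
  s2 <- summarize_operons(two)
  expect_equal(s2$pct_monocistronic, 50)
  expect_equal(s2$mean_genes_per_operon, 2)
})

test_that("assembly partitions classified features exactly once", {
  set.seed(21)
  sim <- simulate_experiment(simulation_spec(seed = 77))
  profiles <- temporal_profiles(sim$experiment, sim$annotation)
  classes <- classify_all(profiles)
  tss <- detect_tss_both(sim$experiment, sim$annotation)
  ops <- assemble_operons(sim$annotation, classes, sim$experiment, tss)
  members <- unlist(operon_partition(ops))
  classified <- classes$feature_id[classes$label != "unclassified"]
  expect_setequal(members, classified)
  expect_equal(anyDuplicated(members), 0L)
  # determinism: a second run gives the identical structure
  ops2 <- assemble_operons(sim$annotation, classes, sim$experiment, tss)
  expect_identical(operon_partition(ops), operon_partition(ops2))
  # missing class map entries are an error
  expect_error(assemble_operons(sim$annotation, classes[-1, ],
                                sim$experiment, tss), "missing")
})

test_that("tightening gap_max only ever splits units", {
  set.seed(22)
  sim <- simulate_experiment(simulation_spec(seed = 78))
  profiles <- temporal_profiles(sim$experiment, sim$annotation)
  classes <- classify_all(profiles)
  tss <- detect_tss_both(sim$experiment, sim$annotation)
  wide <- operon_partition(assemble_operons(sim$annotation, classes,
                                            sim$experiment, tss,
                                            gap_max = 30))
  tight <- operon_partition(assemble_operons(sim$annotation, classes,
                                             sim$experiment, tss,
                                             gap_max = 2))
  # every tight unit must be a contiguous sub-block of some wide unit
  for (u in tight) {
    host <- Filter(function(wu) all(u %in% wu), wide)
    expect_length(host, 1L)
  }
})

test_that("greedy assembly matches exhaustive partition enumeration", {
  set.seed(23)
  n_cases <- 200
  for (case in seq_len(n_cases)) {
    n <- sample(2:10, 1)
    inst <- random_assembly_instance(n)
    ann <- genome_annotation(inst$feats, "toy", inst$L)
    exp <- toy_experiment(inst$cov, timepoints = c(5, 60),
                          n_replicates = 1)
    got <- operon_partition(
      assemble_operons(ann, classes_df(inst$feats$feature_id, inst$labels),
                       exp, inst$tss))
    got_idx <- lapply(got, function(m) match(m, inst$feats$feature_id))
    valid <- Filter(function(p)
      oracle_partition_valid(p, inst$feats, inst$labels, inst$cov,
                             inst$tss),
      oracle_partitions(n))
    expect_length(valid, 1L)
    expect_identical(got_idx, valid[[1]])
  }
})
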
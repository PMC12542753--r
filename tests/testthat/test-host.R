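test_that("identical count matrices yield no DEGs", {
  set.seed(1)
  m <- matrix(rpois(300, 50), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  out <- call_degs(m, m)
  expect_true(all(out$direction == "ns"))
  expect_true(all(out$log2_fold_change == 0))
})

test_that("a 4x count increase is called up with log2FC near 2", {
  set.seed(2)
  genes <- sprintf("g%03d", 1:200)
  ctl <- matrix(rpois(600, 100), 200, 3, dimnames = list(genes, NULL))
  inf <- matrix(rpois(600, 100), 200, 3, dimnames = list(genes, NULL))
  inf[1, ] <- rpois(3, 400)
  out <- call_degs(inf, ctl, lib_infected = rep(1e6, 3),
                   lib_control = rep(1e6, 3))
  expect_equal(out$direction[1], "up")
  expect_equal(out$log2_fold_change[1], 2, tolerance = 0.2)
  expect_error(call_degs(inf[1:10, ], ctl), "universe")
})

test_that("planted DEGs are recovered with controlled FPR under Poisson", {
  set.seed(31)
  n <- 2000
  genes <- sprintf("g%04d", seq_len(n))
  mu <- rlnorm(n, log(80), 1)
  planted <- sample(genes, 100)
  fold <- ifelse(genes %in% planted, 4, 1)
  ctl <- vapply(1:3, function(r) rpois(n, mu), numeric(n))
  inf <- vapply(1:3, function(r) rpois(n, mu * fold), numeric(n))
  rownames(ctl) <- rownames(inf) <- genes
  out <- call_degs(inf, ctl)
  up <- deg_set(out, "up")
  expect_gte(sum(planted %in% up), 90)
  # the exact test is valid (if anything conservative) under Poisson noise
  fpr <- mean(out$direction[!genes %in% planted] != "ns")
  expect_lte(fpr, 0.05 * 1.5)
})

test_that("planted 4-fold DEGs are found under NB overdispersion", {
  set.seed(32)
  n <- 2000
  genes <- sprintf("g%04d", seq_len(n))
  mu <- rlnorm(n, log(80), 1)
  planted <- sample(genes, 100)
  fold <- ifelse(genes %in% planted, 4, 1)
  ctl <- vapply(1:3, function(r) rnbinom(n, mu = mu, size = 20),
                numeric(n))
  inf <- vapply(1:3, function(r) rnbinom(n, mu = mu * fold, size = 20),
                numeric(n))
  rownames(ctl) <- rownames(inf) <- genes
  out <- call_degs(inf, ctl)
  expect_gte(sum(planted %in% deg_set(out, "up")), 90)
  # note: the exact test is anticonservative under overdispersion; the
  # BH-adjusted variant trims the excess
  out_bh <- call_degs(inf, ctl, p_adjust = "BH", alpha = 0.01)
  expect_lt(sum(out_bh$direction != "ns"), sum(out$direction != "ns"))
})

test_that("category enrichment reproduces the worked motility example", {
  # genome of 4,053 genes, category N holds 37; 118 downregulated genes of
  # which 5 in N
  genes <- sprintf("g%04d", 1:4053)
  map <- setNames(rep("X", 4053), genes)
  map[1:37] <- "N"
  degs <- c(genes[1:5], genes[101:213])
  out <- enrich_categories(degs, map)
  n_row <- out[out$category == "N", ]
  expect_equal(round(n_row$pct_expected, 2), 0.91)
  expect_equal(round(n_row$pct_observed, 2), 4.24)
  expect_equal(round(n_row$fold, 2), 4.64)
  expect_equal(n_row$signed_representation, n_row$fold)
  # hypergeometric option: that configuration is significant at 0.05
  out_h <- enrich_categories(degs, map, hypergeometric = TRUE)
  expect_lte(out_h$p_hyper[out_h$category == "N"], 0.05)
})

test_that("enrichment conserves counts and is exact at the null", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:500)
  map <- setNames(sample(LETTERS[1:8], 500, replace = TRUE), genes)
  degs <- sample(genes, 60)
  out <- enrich_categories(degs, map)
  expect_equal(sum(out$deg_count_in_category), length(degs))
  expect_equal(sum(out$category_size), 500)
  # DEG set == genome -> fold exactly 1 everywhere
  out_all <- enrich_categories(genes, map)
  expect_equal(out_all$fold, rep(1, nrow(out_all)))
  expect_equal(out_all$signed_representation, rep(1, nrow(out_all)))
  # simple arithmetic case: 10/100 in category, 4/20 DEGs -> fold 2
  map2 <- setNames(rep(c("A", "B"), c(10, 90)), sprintf("h%03d", 1:100))
  degs2 <- c(sprintf("h%03d", 1:4), sprintf("h%03d", 11:26))
  out2 <- enrich_categories(degs2, map2)
  expect_equal(out2$fold[out2$category == "A"], 2)
  expect_equal(out2$signed_representation[out2$category == "A"], 2)
  # unmapped genes fall into category S but stay in the universe
  out3 <- enrich_categories(c(degs2, "notmapped"), map2,
                            genome_size = 101)
  s_row <- out3[out3$category == "S", ]
  expect_equal(s_row$category_size, 1L)
  expect_equal(s_row$deg_count_in_category, 1L)
  expect_equal(sum(out3$deg_count_in_category), 21L)
  expect_equal(sum(out3$category_size), 101L)
  # empty DEG set warns and returns nothing
  expect_warning(e0 <- enrich_categories(character(0), map), "empty")
  expect_equal(nrow(e0), 0L)
})

test_that("signed representation is monotone in fold and avoids (-1, 1)", {
  folds <- c(0.1, 0.25, 0.5, 0.99, 1, 1.01, 2, 4.64, 10)
  signed <- ifelse(folds >= 1, folds, -1 / folds)
  expect_true(all(signed >= 1 | signed <= -1))
  expect_true(all(diff(signed) > 0))
  # and the package computes the same convention
  map <- setNames(rep(c("A", "B"), c(50, 50)), sprintf("g%03d", 1:100))
  degs <- c(sprintf("g%03d", 1:5), sprintf("g%03d", 51:65))  # A under, B over
  out <- enrich_categories(degs, map)
  a <- out[out$category == "A", ]
  expect_equal(a$signed_representation, -1 / a$fold)
  expect_lte(a$signed_representation, -1)
})

test_that("core DEG sets follow set algebra", {
  sets <- list(t60 = c("A", "B", "C"), t120 = c("B", "C"),
               t180 = c("B", "C", "D"))
  out <- core_deg_sets(sets)
  expect_setequal(out$core, c("B", "C"))
  expect_setequal(out$exclusive$t60, "A")
  expect_setequal(out$exclusive$t180, "D")
  # disjoint sets have an empty core
  expect_length(core_deg_sets(list(a = "X", b = "Y"))$core, 0L)
  # a single-set window is its own core
  expect_setequal(core_deg_sets(list(a = c("P", "Q")))$core, c("P", "Q"))
})
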
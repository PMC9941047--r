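test_that("loss calls require zero mutant reads at assessable depth", {
  base <- data.frame(chrom = "1", pos = c(10, 20, 30, 40), ref = "A",
                     alt = "T", alt_count = 12L, depth = 90L,
                     category = "LOSS_PRONE", clonal = TRUE,
                     qc_flags = "", stringsAsFactors = FALSE)
  prog <- data.frame(chrom = "1", pos = c(10, 20, 30), ref = "A",
                     alt = "T", alt_count = c(0L, 3L, 0L),
                     depth = c(80L, 80L, 0L), stringsAsFactors = FALSE)
  paired <- pair_mutations(base, prog, min_progression_depth = 1)
  expect_true(paired$lost[1])
  expect_false(paired$lost[2])
  expect_false(paired$assessable[3])     # depth 0
  expect_false(paired$assessable[4])     # absent from progression
  expect_match(paired$qc_flags[4], "unassessable")

  strict <- pair_mutations(base, prog, min_progression_depth = 100)
  expect_true(all(!strict$assessable))
})

fig4_counts <- data.frame(
  category = c("LOSS_PRONE", "MULTI_COPY", "ONLY_COPY"),
  clonal = TRUE,
  n_total = c(1688L, 1031L, 117L),
  n_lost = c(358L, 4L, 1L))

test_that("per-stratum loss frequencies reproduce the serial-NSCLC counts", {
  sc <- make_serial_counts(fig4_counts)
  paired <- pair_mutations(sc$baseline, sc$progression)
  ls <- loss_summary(paired)
  cl <- ls[ls$clonality == "clonal", ]
  get <- function(cat, col) cl[cl$category == cat, col]
  expect_equal(get("LOSS_PRONE", "n_total"), 1688)
  expect_equal(get("LOSS_PRONE", "n_lost"), 358)
  expect_equal(get("MULTI_COPY", "loss_frequency"), 4 / 1031)
  expect_equal(get("ONLY_COPY", "loss_frequency"), 1 / 117)
  expect_equal(get("PERSISTENT", "n_total"), 1148)
  expect_equal(get("PERSISTENT", "n_lost"), 5)
  # totals: 2836 clonal mutations, 363 lost, 98.6% of them loss-prone
  expect_equal(sum(cl$n_total[cl$category != "PERSISTENT"]), 2836)
  total_lost <- sum(cl$n_lost[cl$category != "PERSISTENT"])
  expect_equal(total_lost, 363)
  expect_equal(get("LOSS_PRONE", "n_lost") / total_lost, 0.986,
               tolerance = 1e-3)
  # empty strata report NA frequency, zero counts
  sub <- ls[ls$clonality == "subclonal", ]
  expect_true(all(sub$n_total == 0))
  expect_true(all(is.na(sub$loss_frequency)))
})

test_that("loss association reports both odds-ratio estimators", {
  sc <- make_serial_counts(fig4_counts)
  paired <- pair_mutations(sc$baseline, sc$progression)
  assoc <- loss_association(loss_summary(paired), "clonal")
  expect_equal(unname(assoc$table["LOSS_PRONE", ]), c(358, 1330))
  expect_equal(unname(assoc$table["PERSISTENT", ]), c(5, 1143))
  expect_equal(assoc$or_sample, (358 * 1143) / (1330 * 5))
  expect_equal(assoc$or_cmle, cmle_oracle(358, 1330, 5, 1143),
               tolerance = 1e-6)
  expect_lt(assoc$p, 1e-16)
  expect_false(assoc$haldane)
})

test_that("degenerate and zero-cell tables are handled explicitly", {
  tab11 <- data.frame(
    clonality = "clonal",
    category = c("LOSS_PRONE", "PERSISTENT"),
    n_total = c(2L, 2L), n_lost = c(1L, 1L),
    loss_frequency = 0.5)
  r <- loss_association(tab11, "clonal")
  expect_equal(r$or_sample, 1)
  expect_equal(r$p, 1)

  zero <- data.frame(
    clonality = "clonal",
    category = c("LOSS_PRONE", "PERSISTENT"),
    n_total = c(10L, 10L), n_lost = c(4L, 0L),
    loss_frequency = c(0.4, 0))
  rz <- loss_association(zero, "clonal")
  expect_true(rz$haldane)
  expect_equal(rz$or_sample, (4.5 * 10.5) / (6.5 * 0.5))
  expect_true(is.finite(rz$p))
})

test_that("conditional-MLE odds ratio matches the likelihood oracle", {
  set.seed(21)
  for (i in 1:40) {
    a <- sample(1:24, 1); b <- sample(1:24, 1)
    c_ <- sample(1:24, 1); d <- sample(1:24, 1)
    expect_equal(odds_ratio_cmle(a, b, c_, d),
                 cmle_oracle(a, b, c_, d), tolerance = 1e-6)
    # and stays consistent with the estimator fisher.test reports
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expect_equal(odds_ratio_cmle(a, b, c_, d),
                 unname(fisher.test(tab)$estimate), tolerance = 1e-3)
  }
  # boundary tables sit on the edge of the support
  expect_equal(odds_ratio_cmle(0, 5, 3, 7), 0)
  expect_equal(odds_ratio_cmle(5, 0, 3, 7), Inf)
})

test_that("simulated serial pairs recover the category odds of loss", {
  arms <- toy_arms(c("1", "2", "3"))
  params <- sim_params(arms = arms, purity_range = c(0.7, 0.7),
                       mutation_rate = 5, p_clonal = 1)
  sim <- simulate_profile(params, seed = 301)
  base <- simulate_mutations(sim, params, seed = 302)
  expect_gt(nrow(base), 1500)
  # loss strata are defined by the generator's truth labels so the check
  # isolates the pairing + association estimators
  baseline <- base
  baseline$category <- base$true_category
  baseline$clonal <- base$true_clonal
  baseline$qc_flags <- ""
  true_or <- (0.21 / 0.79) / (0.004 / 0.996)
  ors <- numeric(200)
  for (r in 1:200) {
    pair <- simulate_serial_pair(base, params, purity = 0.7,
                                 seed = 5000 + r)
    paired <- pair_mutations(baseline, pair$progression)
    ls <- loss_summary(paired)
    ors[r] <- loss_association(ls, "clonal")$or_cmle
  }
  expect_equal(median(ors), true_or, tolerance = 0.25)
})

test_that("equal loss probabilities center the odds ratio at one", {
  arms <- toy_arms(c("1", "2"))
  params <- sim_params(arms = arms, mutation_rate = 5, p_clonal = 1,
                       purity_range = c(0.7, 0.7),
                       loss_probs = c(clonal_loss_prone = 0.1,
                                      clonal_persistent = 0.1,
                                      subclonal_loss_prone = 0.1,
                                      subclonal_persistent = 0.1))
  sim <- simulate_profile(params, seed = 311)
  base <- simulate_mutations(sim, params, seed = 312)
  ann <- annotate_mutations(base, sim$profile)
  ors <- numeric(60)
  for (r in 1:60) {
    pair <- simulate_serial_pair(base, params, purity = 0.7,
                                 seed = 7000 + r)
    ls <- loss_summary(pair_mutations(ann, pair$progression))
    ors[r] <- loss_association(ls, "clonal")$or_cmle
  }
  expect_equal(median(log(ors)), 0, tolerance = 0.35)

  # no losses at all when probabilities are zero
  params0 <- sim_params(arms = arms, mutation_rate = 2,
                        loss_probs = c(clonal_loss_prone = 0,
                                       clonal_persistent = 0,
                                       subclonal_loss_prone = 0,
                                       subclonal_persistent = 0))
  sim0 <- simulate_profile(params0, seed = 321)
  base0 <- simulate_mutations(sim0, params0, seed = 322)
  pair0 <- simulate_serial_pair(base0, params0, purity = 0.7, seed = 323)
  expect_true(all(!pair0$lost_truth))
})
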
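test_that("expected VAF follows the purity/copy-number dosage model", {
  expect_equal(expected_vaf(1, 1, 1, 2, 2), 0.5)
  expect_equal(expected_vaf(2, 1, 0.5, 4, 2), 1 / 3)
  expect_equal(expected_vaf(1, 0.5, 0.8, 1, 2), 1 / 3)
  expect_warning(v <- expected_vaf(3, 1, 0.5, 2, 2),
                 "exceeds tumor copy number")
  expect_equal(v, 3 * 0.5 / (0.5 * 2 + 0.5 * 2))
})

test_that("mC interval matches frozen oracle values", {
  # oracle: cp_oracle(45, 100) scaled by D = (0.6*3 + 0.4*2)/0.6
  ci <- mc_confidence_interval(45, 100, purity = 0.6, n_T = 3)
  expect_equal(ci$mc_point, 1.95)
  expect_equal(ci$mc_low, 1.5180538, tolerance = 1e-6)
  expect_equal(ci$mc_high, 2.3951189, tolerance = 1e-6)

  z <- mc_confidence_interval(0, 100, purity = 0.7, n_T = 2)
  expect_equal(z$mc_point, 0)
  expect_equal(z$mc_low, 0)

  b <- mc_confidence_interval(100, 100, purity = 1, n_T = 1)
  expect_equal(b$mc_point, 1)
  expect_equal(b$mc_high, 1)  # D = 1 at purity 1, n_T 1
})

test_that("Clopper-Pearson endpoints equal the binomial tail-sum oracle", {
  for (level in c(0.90, 0.95, 0.99)) {
    for (n in 1:30) {
      for (x in 0:n) {
        got <- clopper_pearson(x, n, level)
        want <- cp_oracle(x, n, level)
        expect_equal(got$low, unname(want["low"]), tolerance = 1e-9)
        expect_equal(got$high, unname(want["high"]), tolerance = 1e-9)
      }
    }
  }
})

test_that("widening the confidence level never shrinks the interval", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:500, 1)
    x <- sample(0:n, 1)
    narrow <- clopper_pearson(x, n, 0.90)
    wide <- clopper_pearson(x, n, 0.99)
    expect_lte(wide$low, narrow$low)
    expect_gte(wide$high, narrow$high)
  }
})

test_that("rule system resolves the three interval positions", {
  # R1: interval contains an integer -> clonal at that multiplicity
  r1 <- assign_multiplicity(1.95, 1.5180538, 2.3951189, n_T = 3,
                            major_cn = 2)
  expect_equal(r1$rule, "R1")
  expect_equal(r1$multiplicity, 2L)
  expect_true(r1$clonal)
  expect_equal(r1$ccf, 0.975)

  # R2: interval below 1 -> m = 1, subclonal unless C > 0.75
  # oracle: alt 200 / depth 1000, D = 4
  ci <- mc_confidence_interval(200, 1000, purity = 1, n_T = 4)
  expect_equal(ci$mc_low, 0.7024823, tolerance = 1e-6)
  expect_equal(ci$mc_high, 0.9046375, tolerance = 1e-6)
  r2 <- assign_multiplicity(ci$mc_point, ci$mc_low, ci$mc_high,
                            n_T = 4, major_cn = 2)
  expect_equal(r2$rule, "R2")
  expect_equal(r2$multiplicity, 1L)
  expect_equal(r2$ccf, 0.8)
  expect_true(r2$clonal)  # 0.8 > 0.75 tolerance

  # R3: interval above 1 with no integer -> m = ceiling(upper bound)
  ci3 <- mc_confidence_interval(330, 1000, purity = 1, n_T = 4)
  expect_equal(ci3$mc_low, 1.2035722, tolerance = 1e-6)
  expect_equal(ci3$mc_high, 1.4404466, tolerance = 1e-6)
  r3 <- assign_multiplicity(ci3$mc_point, ci3$mc_low, ci3$mc_high,
                            n_T = 4, major_cn = 2)
  expect_equal(r3$rule, "R3")
  expect_equal(r3$multiplicity, 2L)
  expect_equal(r3$ccf, 0.66)
  expect_false(r3$clonal)
})

test_that("every supported mutation gets exactly one rule", {
  set.seed(23)
  for (i in 1:300) {
    depth <- sample(20:400, 1)
    alt <- sample(1:depth, 1)
    purity <- runif(1, 0.2, 1)
    n_T <- sample(1:6, 1)
    ci <- mc_confidence_interval(alt, depth, purity, n_T)
    call <- assign_multiplicity(ci$mc_point, ci$mc_low, ci$mc_high,
                                n_T = n_T, major_cn = max(1, n_T - 1))
    expect_true(call$rule %in% c("R1", "R2", "R3"))
    expect_true(call$ccf >= 0 && call$ccf <= 1)
    expect_false(is.na(call$clonal))
    if (call$rule == "R2") expect_lt(ci$mc_high, 1)
    if (call$rule == "R3") expect_gt(ci$mc_low, 1)
  }
})

test_that("R1 tie between two integers resolves to the smaller", {
  r <- assign_multiplicity(1.5, 0.9, 2.1, n_T = 4, major_cn = 4)
  expect_equal(r$multiplicity, 1L)
  r2 <- assign_multiplicity(1.6, 0.9, 2.1, n_T = 4, major_cn = 4)
  expect_equal(r2$multiplicity, 2L)
})

test_that("multiplicity is capped at the major copy number", {
  r <- assign_multiplicity(2.9, 2.55, 3.3, n_T = 3, major_cn = 2)
  expect_equal(r$multiplicity_raw, 3L)
  expect_equal(r$multiplicity, 2L)
  expect_match(r$qc_flags, "m_gt_major")
  # ccf recomputed on the capped m and capped at 1
  expect_equal(r$ccf, 1)
  expect_match(r$qc_flags, "ccf_capped")
})

test_that("zero-support mutations get no call", {
  r <- assign_multiplicity(0, 0, 0.15, n_T = 2, major_cn = 1)
  expect_true(is.na(r$rule))
  expect_equal(r$qc_flags, "zero_support")
})

test_that("annotation excludes sex chromosomes, gaps and unassigned segments", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmajor_cn\tminor_cn",
               "1\t1\t10000\t2\t1",
               "1\t20001\t30000\tNA\tNA",
               "X\t1\t10000\t1\t0"), f)
  seg <- read_segments(f)
  unlink(f)
  prof <- segment_profile("S1", seg, purity = 0.8)
  muts <- make_mutations(c("1", "1", "1", "X"),
                         c(500, 15000, 25000, 500),
                         c(40, 40, 40, 40), rep(100L, 4))
  ann <- annotate_mutations(muts, prof)
  expect_false(ann$category[1] == "EXCLUDED")
  expect_equal(ann$category[2], "EXCLUDED")
  expect_match(ann$qc_flags[2], "no_cn")
  expect_equal(ann$category[3], "EXCLUDED")
  expect_match(ann$qc_flags[3], "cn_unassigned")
  expect_equal(ann$category[4], "EXCLUDED")
  expect_match(ann$qc_flags[4], "sex_chrom")
  expect_true(is.na(ann$multiplicity[4]))
})

test_that("clonal multiplicity is recovered on deep synthetic data", {
  arms <- toy_arms(c("1", "2", "3"))
  params <- sim_params(arms = arms, purity_range = c(0.8, 0.95),
                       mean_depth = 250, mutation_rate = 0.5)
  hits <- 0; total <- 0
  for (s in 1:8) {
    sim <- simulate_profile(params, seed = 400 + s)
    muts <- simulate_mutations(sim, params, seed = 500 + s)
    ann <- annotate_mutations(muts, sim$profile)
    sel <- muts$true_clonal & muts$true_m %in% 1:3 &
      !is.na(ann$multiplicity)
    hits <- hits + sum(ann$multiplicity[sel] == muts$true_m[sel])
    total <- total + sum(sel)
  }
  expect_gt(total, 500)
  expect_gte(hits / total, 0.85)
})
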
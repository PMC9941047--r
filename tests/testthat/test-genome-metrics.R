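profile_from_states <- function(states, arm_len = 100e6, chrom = "1",
                                purity = 0.7, sample_id = "S") {
  # states: data.frame(frac, major, minor) tiling one arm
  stopifnot(abs(sum(states$frac) - 1) < 1e-9)
  ends <- round(cumsum(states$frac) * arm_len)
  starts <- c(1, head(ends, -1) + 1)
  seg <- make_segments(rep(chrom, nrow(states)), starts, ends,
                       states$major, states$minor)
  segment_profile(sample_id, seg, purity = purity)
}

test_that("arm state calls follow the 75% covered-length rule", {
  arms <- toy_arms("1")[1, , drop = FALSE]  # 1p, [0, 100Mb)

  dip <- profile_from_states(data.frame(frac = 1, major = 1, minor = 1))
  expect_equal(classify_arm_state(dip, arms)$state, "DIPLOID")

  hap <- profile_from_states(data.frame(frac = c(0.8, 0.2),
                                        major = c(1, 2), minor = c(0, 1)))
  expect_equal(classify_arm_state(hap, arms)$state, "HAPLOID")

  # 70% copy-neutral without LOH + 30% LOH: neither rule reaches 75%
  mixed <- profile_from_states(data.frame(frac = c(0.7, 0.3),
                                          major = c(1, 2),
                                          minor = c(1, 0)))
  expect_equal(classify_arm_state(mixed, arms)$state, "OTHER")

  # copy-neutral LOH (2-0) is not diploid even at 100%
  loh <- profile_from_states(data.frame(frac = 1, major = 2, minor = 0))
  expect_equal(classify_arm_state(loh, arms)$state, "OTHER")

  # exactly 75% meets the threshold
  edge <- profile_from_states(data.frame(frac = c(0.75, 0.25),
                                         major = c(1, 3),
                                         minor = c(1, 1)))
  expect_equal(classify_arm_state(edge, arms)$state, "DIPLOID")

  # an uncovered arm is OTHER
  expect_equal(classify_arm_state(dip, toy_arms("2"))$state,
               c("OTHER", "OTHER"))
})

test_that("loss rates reproduce the length-ratio equations", {
  arms <- toy_arms(c("1", "2"))
  # chr1: two diploid arms 100 Mb each, with 10 Mb hemizygous loss on 1p
  # chr2: 2p haploid (100 Mb total cn 1), 1 Mb of it homozygous-deleted
  seg <- make_segments(
    c("1", "1", "1", "2", "2", "2"),
    c(1, 10e6 + 1, 100e6 + 1, 1, 99e6 + 1, 100e6 + 1),
    c(10e6, 100e6, 200e6, 99e6, 100e6, 200e6),
    c(1, 1, 1, 1, 0, 3),
    c(0, 1, 1, 0, 0, 2))
  prof <- segment_profile("S", seg, purity = 0.6)
  lr <- compute_loss_rates(prof, arms)
  expect_equal(lr$n_diploid_arms, 2)
  expect_equal(lr$n_haploid_arms, 1)
  # R_D = (2*0 + 10 Mb) / (2 * 200 Mb) = 0.025
  expect_equal(lr$r_diploid, 10e6 / (2 * 200e6))
  # R_H = 1 Mb / 100 Mb
  expect_equal(lr$r_haploid, 0.01)

  # no diploid arms -> rate undefined, not zero
  hap_only <- profile_from_states(data.frame(frac = 1, major = 1,
                                             minor = 0))
  lr2 <- compute_loss_rates(hap_only, toy_arms("1"))
  expect_true(is.na(lr2$r_diploid))
  expect_equal(lr2$r_haploid, 0)
})

test_that("aneuploidy fractions and WGD follow the length accounting", {
  all11 <- profile_from_states(data.frame(frac = 1, major = 1, minor = 1))
  a <- compute_aneuploidy(all11)
  expect_equal(a$frac_allelic_imbalance, 0)
  expect_equal(a$frac_multi_copy, 0)
  expect_false(a$wgd)

  all22 <- profile_from_states(data.frame(frac = 1, major = 2, minor = 2))
  b <- compute_aneuploidy(all22)
  expect_equal(b$frac_allelic_imbalance, 0)
  expect_equal(b$frac_multi_copy, 1)
  expect_true(b$wgd)

  half <- profile_from_states(data.frame(frac = c(0.5, 0.5),
                                         major = c(2, 1),
                                         minor = c(1, 1)))
  expect_equal(compute_aneuploidy(half)$frac_allelic_imbalance, 0.5)

  # sex chromosomes never enter
  seg <- rbind(make_segments("1", 1, 10e6, 1, 1),
               make_segments("X", 1, 50e6, 4, 2))
  p <- segment_profile("S", seg, purity = 0.5)
  expect_equal(compute_aneuploidy(p)$frac_multi_copy, 0)
})

test_that("WGD threshold is strict at the boundary", {
  at60 <- profile_from_states(data.frame(frac = c(0.6, 0.4),
                                         major = c(2, 1),
                                         minor = c(1, 1)))
  expect_true(call_wgd(at60))
  at50 <- profile_from_states(data.frame(frac = c(0.5, 0.5),
                                         major = c(2, 1),
                                         minor = c(1, 1)))
  expect_false(call_wgd(at50))

  # doubling a non-WGD genome always yields WGD
  seg <- at50$segments
  seg$major_cn <- seg$major_cn * 2L
  seg$minor_cn <- seg$minor_cn * 2L
  seg$total_cn <- seg$major_cn + seg$minor_cn
  doubled <- segment_profile("S", seg, purity = 0.7)
  expect_true(call_wgd(doubled))
})

test_that("metrics are invariant under segment splitting", {
  params <- sim_params(arms = toy_arms())
  sim <- simulate_profile(params, seed = 31)
  prof <- sim$profile
  seg <- prof$segments
  # split every segment at its midpoint
  mid <- floor((seg$start + seg$end) / 2)
  ok <- mid > seg$start & mid < seg$end
  left <- seg; left$end[ok] <- mid[ok]
  right <- seg[ok, ]; right$start <- mid[ok]
  split_prof <- segment_profile(prof$sample_id, rbind(left, right),
                                purity = prof$purity)
  expect_equal(compute_aneuploidy(split_prof), compute_aneuploidy(prof))
  arms <- toy_arms()
  expect_equal(compute_loss_rates(split_prof, arms),
               compute_loss_rates(prof, arms))
  expect_equal(call_wgd(split_prof), call_wgd(prof))
})

test_that("estimated loss rates recover simulated per-copy loss rates", {
  # toy loss process on a 2000-tile genome: in diploid arms each of the
  # two copies is independently lost per tile; in haploid arms the single
  # copy is lost at the homozygous-event rate only.
  arms <- toy_arms(c("1", "2"))
  simulate_loss_profile <- function(p_hemi, p_homo, seed) {
    set.seed(seed)
    tiles <- 500
    rows <- list()
    for (i in seq_len(nrow(arms))) {
      a <- arms[i, ]
      bounds <- round(seq(a$start, a$end, length.out = tiles + 1))
      haploid <- a$chrom == "2"
      if (haploid) {
        lost <- runif(tiles) < p_homo
        major <- ifelse(lost, 0L, 1L)
        minor <- 0L
      } else {
        l1 <- runif(tiles) < p_hemi / 2
        l2 <- runif(tiles) < p_hemi / 2
        major <- 1L - (l1 & l2)
        minor <- 1L - (l1 | l2)
        major <- pmax(major, minor)
      }
      rows[[i]] <- data.frame(chrom = a$chrom,
                              start = bounds[-length(bounds)],
                              end = bounds[-1],
                              major_cn = major, minor_cn = minor,
                              total_cn = major + minor,
                              cn_unassigned = FALSE)
    }
    segment_profile("L", do.call(rbind, rows), purity = 0.7)
  }
  p_hemi <- 0.10   # per-copy hemizygous-scale rate in diploid arms
  p_homo <- 0.02   # homozygous event rate (rarer)
  r_d <- r_h <- numeric(20)
  for (s in 1:20) {
    prof <- simulate_loss_profile(p_hemi, p_homo, seed = 900 + s)
    lr <- compute_loss_rates(prof, arms)
    r_d[s] <- lr$r_diploid
    r_h[s] <- lr$r_haploid
  }
  # R_D estimates the per-copy loss fraction (each copy lost w.p.
  # p_hemi / 2); R_H the homozygous event rate
  expect_equal(mean(r_d), p_hemi / 2, tolerance = 0.15)
  expect_equal(mean(r_h), p_homo, tolerance = 0.25)
  # with homozygous loss rarer than hemizygous, diploid arms lose faster
  expect_gt(mean(r_d), mean(r_h))
})
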
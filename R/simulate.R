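# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulation parameters
#'
#' Ground-truth generator settings for FACETS-like synthetic tumor
#' genomes. Defaults describe a generic solid-tumor exome cohort: purity
#' uniform on 0.4-0.9, a diploid-dominant allele-state mix with arm-scale
#' gains and losses, 30% whole-genome-doubled samples, one mutation per
#' covered Mb, 80% clonal mutations, mean distinct depth 100, and serial
#' loss probabilities matching the longitudinal loss frequencies observed
#' in serial NSCLC (clonal loss-prone 0.21, clonal persistent 0.004,
#' subclonal loss-prone 0.148, subclonal persistent 0.093).
#'
#' @param arms Arm template table ([read_arms()]); NULL loads the shipped
#'   hg19 table. Sex chromosomes are dropped.
#' @param purity_range Uniform purity range in (0, 1].
#' @param cn_state_distribution Named probability vector over allele
#'   states \code{"major,minor"}.
#' @param p_wgd Probability a sample is whole-genome doubled (all drawn
#'   states doubled).
#' @param segments_per_arm Integer range (min, max) of segments per arm.
#' @param mutation_rate Mutations per covered Mb.
#' @param p_clonal Probability a mutation is clonal (C = 1).
#' @param subclonal_ccf_shape Beta shape parameters; subclonal C is
#'   Beta(a, b) rescaled to (0, clonal_tolerance) so truth clonality is
#'   unambiguous.
#' @param p_early Probability a clonal mutation on a gained segment
#'   predates the gain (multiplicity = major copy number).
#' @param mean_depth Mean distinct depth (Poisson; >= 30).
#' @param depth_size Optional negative-binomial size for overdispersed
#'   depth (NULL = Poisson).
#' @param loss_probs Named per-stratum loss probabilities for serial
#'   pairs.
#' @param clonal_tolerance Clonality tolerance shared with the analysis.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(arms = NULL,
                       purity_range = c(0.4, 0.9),
                       cn_state_distribution = c(
                         "1,0" = 0.10, "1,1" = 0.45, "2,0" = 0.05,
                         "2,1" = 0.15, "2,2" = 0.10, "3,1" = 0.07,
                         "3,2" = 0.05, "4,2" = 0.03),
                       p_wgd = 0.3,
                       segments_per_arm = c(1L, 5L),
                       mutation_rate = 1,
                       p_clonal = 0.8,
                       subclonal_ccf_shape = c(2, 2),
                       p_early = 0.5,
                       mean_depth = 100,
                       depth_size = NULL,
                       loss_probs = c(clonal_loss_prone = 0.21,
                                      clonal_persistent = 0.004,
                                      subclonal_loss_prone = 0.148,
                                      subclonal_persistent = 0.093),
                       clonal_tolerance = 0.75) {
  stopifnot(purity_range[1] > 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2],
            abs(sum(cn_state_distribution) - 1) < 1e-8,
            p_wgd >= 0, p_wgd <= 1, p_clonal >= 0, p_clonal <= 1,
            p_early >= 0, p_early <= 1, mean_depth >= 30,
            all(loss_probs >= 0), all(loss_probs <= 1))
  if (is.null(arms)) arms <- read_arms("hg19")
  arms <- arms[!is_sex_chrom(arms$chrom), , drop = FALSE]
  structure(list(
    arms = arms, purity_range = purity_range,
    cn_state_distribution = cn_state_distribution,
    p_wgd = p_wgd, segments_per_arm = as.integer(segments_per_arm),
    mutation_rate = mutation_rate, p_clonal = p_clonal,
    subclonal_ccf_shape = subclonal_ccf_shape, p_early = p_early,
    mean_depth = mean_depth, depth_size = depth_size,
    loss_probs = loss_probs, clonal_tolerance = clonal_tolerance
  ), class = "sim_params")
}

#' Simulate an allele-specific copy number profile
#'
#' Partitions each template arm into segments at uniform breakpoints,
#' draws an allele state per segment from the state distribution, and
#' with probability \code{p_wgd} doubles every state (whole-genome
#' doubling). Deterministic given (params, seed).
#'
#' @param params [sim_params()].
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return list with \code{profile} (a [segment_profile()]) and
#'   \code{truth} (list with \code{wgd}, \code{purity}).
#' @export
simulate_profile <- function(params, seed = NULL, sample_id = "sim") {
  with_rng_seed(seed, {
    arms <- params$arms
    wgd <- stats::runif(1) < params$p_wgd
    purity <- stats::runif(1, params$purity_range[1],
                           params$purity_range[2])
    states <- names(params$cn_state_distribution)
    segs <- lapply(seq_len(nrow(arms)), function(i) {
      a <- arms[i, ]
      k <- sample(seq(params$segments_per_arm[1],
                      params$segments_per_arm[2]), 1)
      cuts <- sort(c(a$start, a$end,
                     if (k > 1) round(stats::runif(k - 1, a$start, a$end))))
      cuts <- unique(cuts)
      st <- sample(states, length(cuts) - 1, replace = TRUE,
                   prob = params$cn_state_distribution)
      mm <- do.call(rbind, strsplit(st, ","))
      major <- as.integer(mm[, 1])
      minor <- as.integer(mm[, 2])
      if (wgd) {
        major <- 2L * major
        minor <- 2L * minor
      }
      data.frame(chrom = a$chrom, start = cuts[-length(cuts)],
                 end = cuts[-1], major_cn = major, minor_cn = minor,
                 total_cn = major + minor, cn_unassigned = FALSE,
                 stringsAsFactors = FALSE)
    })
    segments <- do.call(rbind, segs)
    profile <- segment_profile(sample_id, segments, purity = purity)
    list(profile = profile, truth = list(wgd = wgd, purity = purity))
  })
}

#' Simulate somatic mutation calls with ground truth
#'
#' Draws mutation counts per segment as Poisson in the segment length,
#' assigns clonality, cellular fraction and multiplicity (an early clonal
#' mutation on a gained segment carries multiplicity equal to the major
#' copy number with probability \code{p_early}; multiplicity is 1 on
#' single-copy segments), then samples read counts by inverting the
#' expected-VAF model: depth is Poisson (or negative binomial) and the
#' mutant count binomial at \eqn{V = mC\alpha/(\alpha n_T + 2(1-\alpha))}.
#' Segments at total copy number 0 receive no mutations.
#'
#' @param sim Output of [simulate_profile()].
#' @param params [sim_params()].
#' @param seed Integer seed.
#' @param rate_multiplier Multiplier on the mutation rate for
#'   persistent-eligible segments (total copy 1 or major > 1); used to
#'   inject cohort effects.
#' @return Mutation data.frame in [read_mutations()] layout plus truth
#'   columns \code{true_m, true_ccf, true_clonal, true_category} and the
#'   local segment state.
#' @export
simulate_mutations <- function(sim, params, seed = NULL,
                               rate_multiplier = 1) {
  with_rng_seed(seed, {
    seg <- sim$profile$segments
    purity <- sim$profile$purity
    seg <- seg[seg$total_cn > 0, , drop = FALSE]
    eligible <- seg$total_cn == 1 | seg$major_cn > 1
    rate <- params$mutation_rate * ifelse(eligible, rate_multiplier, 1)
    n_per_seg <- stats::rpois(nrow(seg),
                              rate * (seg$end - seg$start) / 1e6)
    idx <- rep(seq_len(nrow(seg)), n_per_seg)
    n <- length(idx)
    if (n == 0) {
      empty <- mutations_from_table(data.frame(
        chrom = character(), pos = numeric(), ref = character(),
        alt = character(), alt_count = numeric(), depth = numeric(),
        variant_classification = character(), gene = character(),
        stringsAsFactors = FALSE))
      empty$true_m <- integer(); empty$true_ccf <- numeric()
      empty$true_clonal <- logical(); empty$true_category <- character()
      empty$major_cn_true <- integer(); empty$minor_cn_true <- integer()
      return(empty)
    }
    pos <- floor(stats::runif(n, seg$start[idx], seg$end[idx])) + 1
    # unique loci per chromosome keep (chrom,pos,ref,alt) keys unambiguous
    for (iter in 1:10) {
      dup <- duplicated(paste(seg$chrom[idx], pos))
      if (!any(dup)) break
      pos[dup] <- floor(stats::runif(sum(dup), seg$start[idx][dup],
                                     seg$end[idx][dup])) + 1
    }
    clonal <- stats::runif(n) < params$p_clonal
    ccf <- ifelse(clonal, 1,
                  stats::rbeta(n, params$subclonal_ccf_shape[1],
                               params$subclonal_ccf_shape[2]) *
                    params$clonal_tolerance)
    major <- seg$major_cn[idx]
    total <- seg$total_cn[idx]
    m <- rep(1L, n)
    early <- clonal & major > 1 & total > 1 &
      stats::runif(n) < params$p_early
    m[early] <- major[early]
    depth <- if (is.null(params$depth_size)) {
      stats::rpois(n, params$mean_depth)
    } else {
      stats::rnbinom(n, size = params$depth_size,
                     mu = params$mean_depth)
    }
    depth <- pmax(depth, 1L)
    v <- expected_vaf(m, ccf, purity, total, 2)
    alt <- stats::rbinom(n, depth, v)
    truth_cat <- categorize(total, m)$category
    out <- mutations_from_table(data.frame(
      chrom = seg$chrom[idx], pos = pos,
      ref = "A", alt = "T",
      alt_count = alt, depth = depth,
      variant_classification = "Missense_Mutation",
      gene = NA_character_, stringsAsFactors = FALSE))
    out$true_m <- m
    out$true_ccf <- ccf
    out$true_clonal <- clonal
    out$true_category <- truth_cat
    out$major_cn_true <- major
    out$minor_cn_true <- seg$minor_cn[idx]
    out
  })
}

#' Simulate a progression sample for a serial pair
#'
#' Each baseline mutation is independently lost with its stratum's
#' probability (clonality x persistent/loss-prone, from the truth
#' labels). Lost mutations get a progression mutant count of zero;
#' retained mutations get re-sampled depth and binomial mutant counts at
#' the same expected VAF.
#'
#' @param baseline Mutation data.frame with truth columns, from
#'   [simulate_mutations()].
#' @param purity Progression sample purity (defaults to the baseline's
#'   sampling model via \code{params}).
#' @param params [sim_params()] supplying \code{loss_probs} and the read
#'   count model.
#' @param seed Integer seed.
#' @return list with \code{progression} (data.frame \code{chrom, pos,
#'   ref, alt, alt_count, depth}) and \code{lost_truth} (logical).
#' @export
simulate_serial_pair <- function(baseline, params, purity, seed = NULL) {
  with_rng_seed(seed, {
    n <- nrow(baseline)
    persistent <- baseline$true_category %in% c("MULTI_COPY", "ONLY_COPY")
    stratum <- paste0(ifelse(baseline$true_clonal, "clonal_",
                             "subclonal_"),
                      ifelse(persistent, "persistent", "loss_prone"))
    p_loss <- params$loss_probs[stratum]
    lost <- stats::runif(n) < p_loss
    depth <- pmax(stats::rpois(n, params$mean_depth), 1L)
    total <- baseline$major_cn_true + baseline$minor_cn_true
    v <- expected_vaf(baseline$true_m, baseline$true_ccf, purity,
                      pmax(total, 1), 2)
    alt <- stats::rbinom(n, depth, v)
    # a retained mutation can still drop to zero reads by sampling;
    # losses force zero
    alt[lost] <- 0L
    progression <- data.frame(
      chrom = baseline$chrom, pos = baseline$pos,
      ref = baseline$ref, alt = baseline$alt,
      alt_count = alt, depth = depth, stringsAsFactors = FALSE)
    list(progression = progression, lost_truth = lost)
  })
}

#' Simulate a labeled cohort and run the estimation pipeline
#'
#' Generates \code{n_samples} synthetic tumors, labels half responders,
#' multiplies the responders' mutation rate on persistent-eligible
#' segments by \code{effect}, runs the full annotation pipeline
#' (multiplicity, category, burden), and returns per-sample estimated and
#' true burdens with aneuploidy metrics.
#'
#' @param params [sim_params()].
#' @param n_samples Number of samples (>= 4).
#' @param effect Multiplicative pTMB-rate shift for responders (1 =
#'   null).
#' @param seed Integer seed; per-sample seeds are derived from it.
#' @param config [ptmb_config()] used by the estimation pipeline.
#' @return data.frame: one row per sample with burden summary columns,
#'   \code{response}, truth columns \code{true_ptmb, true_tmb, true_wgd}
#'   and aneuploidy metrics.
#' @export
simulate_cohort <- function(params, n_samples, effect = 1, seed = NULL,
                            config = ptmb_config()) {
  stopifnot(n_samples >= 4)
  with_rng_seed(seed, {
    response <- rep(c("R", "NR"), length.out = n_samples)
    seeds <- sample.int(2^31 - 1, n_samples)
    rows <- lapply(seq_len(n_samples), function(i) {
      sim <- simulate_profile(params, seed = seeds[i],
                              sample_id = sprintf("S%03d", i))
      mult <- if (response[i] == "R") effect else 1
      muts <- simulate_mutations(sim, params, seed = seeds[i] %% 2^30 + 1,
                                 rate_multiplier = mult)
      ann <- annotate_mutations(muts, sim$profile, config)
      summ <- summarize_burden(ann, config, sim$profile$sample_id)
      an <- compute_aneuploidy(sim$profile, config$wgd_fraction)
      truth_p <- sum(muts$true_category %in% c("MULTI_COPY", "ONLY_COPY"))
      cbind(summ,
            data.frame(response = response[i],
                       true_ptmb = truth_p,
                       true_tmb = nrow(muts),
                       true_wgd = sim$truth$wgd,
                       purity = sim$truth$purity),
            an)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
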
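#' Expected variant allele fraction
#'
#' For a mutation carried at multiplicity \code{m} (mutant copies per
#' cancer cell) by a fraction \code{C} of cancer cells, in a tumor of
#' purity \code{alpha} with local tumor copy number \code{n_T} and normal
#' copy number \code{n_N}, the expected VAF is
#' \deqn{V = m C \alpha / (\alpha n_T + (1 - \alpha) n_N).}
#'
#' @param m Multiplicity (integer >= 1); vectorized.
#' @param C Cellular fraction in \[0, 1\].
#' @param purity Tumor purity alpha in (0, 1\].
#' @param n_T Local tumor total copy number (integer >= 1).
#' @param n_N Normal copy number (2 for autosomes).
#' @return Expected VAF in \[0, 1\]. A warning is raised (value still
#'   returned) when \code{m > n_T}, which is physically inconsistent.
#' @export
expected_vaf <- function(m, C, purity, n_T, n_N = 2) {
  stopifnot(all(m >= 1), all(C >= 0 & C <= 1),
            all(purity > 0 & purity <= 1), all(n_T >= 1), all(n_N >= 0))
  if (any(m > n_T)) {
    warning("multiplicity exceeds tumor copy number for some mutations")
  }
  m * C * purity / (purity * n_T + (1 - purity) * n_N)
}

# Dosage factor D: VAF * D is on the mC scale.
mc_dosage <- function(purity, n_T, n_N = 2) {
  (purity * n_T + (1 - purity) * n_N) / purity
}

#' Confidence interval for multiplicity times cellular fraction
#'
#' The mutant read count is modeled as binomial in the distinct depth. A
#' Clopper-Pearson (exact) interval is built for the underlying VAF and
#' rescaled by the dosage factor \eqn{D = (\alpha n_T + (1-\alpha) n_N) /
#' \alpha}, giving an interval for the product \eqn{mC}. Vectorized over
#' mutations.
#'
#' @param alt_count Distinct mutant read count(s).
#' @param depth Distinct total depth(s), >= 1.
#' @param purity Tumor purity.
#' @param n_T Local tumor copy number per mutation.
#' @param n_N Normal copy number (2).
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns \code{mc_point, mc_low, mc_high}.
#' @export
mc_confidence_interval <- function(alt_count, depth, purity, n_T, n_N = 2,
                                   level = 0.95) {
  stopifnot(all(depth >= 1), all(alt_count >= 0), all(alt_count <= depth),
            level > 0, level < 1)
  k <- length(alt_count)
  n_T <- rep_len(n_T, k)
  ci <- clopper_pearson(alt_count, depth, level)
  D <- mc_dosage(purity, n_T, n_N)
  data.frame(mc_point = (alt_count / depth) * D,
             mc_low = ci$low * D,
             mc_high = ci$high * D)
}

#' Clopper-Pearson binomial interval
#'
#' Exact two-sided interval for a binomial proportion, via the beta
#' quantile representation of the binomial tail. Vectorized.
#'
#' @param x Successes.
#' @param n Trials.
#' @param level Confidence level.
#' @return data.frame with \code{low, high}.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  low <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  high <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  data.frame(low = low, high = high)
}

#' Resolve multiplicity and cellular fraction from an mC interval
#'
#' Applies the three-rule system to the confidence interval for the
#' product \eqn{mC}:
#' \itemize{
#'   \item R1: the interval contains an integer k >= 1 -- the mutation is
#'     clonal and the contained integer nearest to the point estimate is
#'     the multiplicity (ties go to the smaller integer);
#'     \code{ccf = min(mc_point / m, 1)}.
#'   \item R2: the interval lies entirely below 1 -- multiplicity 1,
#'     \code{ccf = mc_point}, clonal only when ccf exceeds the tolerance
#'     (default 0.75).
#'   \item R3: the interval lies entirely above 1 with no integer inside
#'     -- multiplicity is the smallest integer that rescales the interval
#'     into \[0, 1\] (the ceiling of the upper bound); clonality as in R2.
#' }
#' Multiplicity is additionally capped at the major allele copy number (a
#' point mutation can occupy at most all copies of one parental
#' haplotype); the uncapped value is kept in \code{multiplicity_raw} and
#' the cap is flagged. Vectorized.
#'
#' @param mc_point,mc_low,mc_high Point estimate and interval for mC.
#' @param tolerance Clonality tolerance on the cellular fraction.
#' @param n_T Tumor total copy number per mutation.
#' @param major_cn Major allele copy number per mutation (cap).
#' @return data.frame with \code{multiplicity_raw, multiplicity, ccf,
#'   clonal, rule, qc_flags}. Mutations with \code{mc_point == 0} get no
#'   call (rule \code{NA}, flag \code{zero_support}); \code{n_T == 0} with
#'   support gets flag \code{cn_inconsistent}.
#' @export
assign_multiplicity <- function(mc_point, mc_low, mc_high,
                                tolerance = 0.75, n_T = 2L,
                                major_cn = 1L) {
  k <- length(mc_point)
  n_T <- rep_len(n_T, k)
  major_cn <- rep_len(major_cn, k)
  m_raw <- rep(NA_integer_, k)
  ccf <- rep(NA_real_, k)
  clonal <- rep(NA, k)
  rule <- rep(NA_character_, k)
  flags <- character(k)

  no_call <- mc_point == 0
  flags[no_call] <- "zero_support"
  bad_cn <- !no_call & n_T == 0
  flags[bad_cn] <- "cn_inconsistent"
  live <- !no_call & !bad_cn

  # R1: an integer k >= 1 inside the closed interval
  lo_int <- pmax(1, ceiling(mc_low))
  hi_int <- floor(mc_high)
  r1 <- live & hi_int >= lo_int & mc_high >= 1
  # nearest contained integer to the point, half-ties toward the smaller
  near <- floor(mc_point)
  near <- ifelse(mc_point - near > 0.5, near + 1, near)
  m1 <- pmin(pmax(near, lo_int), hi_int)
  m_raw[r1] <- as.integer(m1[r1])
  clonal[r1] <- TRUE
  rule[r1] <- "R1"

  # R2: entirely below 1
  r2 <- live & !r1 & mc_high < 1
  m_raw[r2] <- 1L
  rule[r2] <- "R2"

  # R3: entirely above 1, no integer inside
  r3 <- live & !r1 & !r2
  m_raw[r3] <- as.integer(ceiling(mc_high[r3]))
  rule[r3] <- "R3"

  capped <- live & !is.na(m_raw) & major_cn >= 1 & m_raw > major_cn
  m <- m_raw
  m[capped] <- as.integer(major_cn[capped])
  flags[capped] <- vapply(which(capped), function(i)
    join_flags(flags[i], "m_gt_major"), character(1))

  ccf[live] <- mc_point[live] / m[live]
  over <- live & ccf > 1
  flags[over] <- vapply(which(over), function(i)
    join_flags(flags[i], "ccf_capped"), character(1))
  ccf[over] <- 1

  sub <- live & rule %in% c("R2", "R3")
  clonal[sub] <- ccf[sub] > tolerance

  data.frame(multiplicity_raw = m_raw, multiplicity = m, ccf = ccf,
             clonal = clonal, rule = rule, qc_flags = flags,
             stringsAsFactors = FALSE)
}

#' Annotate mutations with copy number, multiplicity and category
#'
#' Intersects mutation calls with the sample's segmental allele-specific
#' copy number profile, estimates multiplicity and cellular fraction via
#' the binomial-interval rule system, and assigns the persistence
#' category. Mutations on sex chromosomes, in gaps between segments, or on
#' segments lacking allele-specific assignment are categorized
#' \code{EXCLUDED} (flags \code{sex_chrom}, \code{no_cn},
#' \code{cn_unassigned}) and carry no multiplicity call.
#'
#' @param muts Mutation data.frame from [read_mutations()].
#' @param profile A [segment_profile()].
#' @param config A [ptmb_config()].
#' @return The mutation data.frame extended with \code{major_cn, minor_cn,
#'   total_cn, mc_point, mc_low, mc_high, multiplicity_raw, multiplicity,
#'   ccf, clonal, rule, category, qc_flags}.
#' @export
annotate_mutations <- function(muts, profile, config = ptmb_config()) {
  stopifnot(inherits(profile, "segment_profile"))
  n <- nrow(muts)
  seg <- profile$segments
  idx <- rep(NA_integer_, n)
  for (chr in unique(muts$chrom)) {
    sel <- which(muts$chrom == chr)
    s_idx <- which(seg$chrom == chr)
    if (length(s_idx) == 0) next
    s <- seg[s_idx, , drop = FALSE]
    p0 <- muts$pos[sel] - 1
    j <- findInterval(p0, s$start)
    ok <- j >= 1 & j <= nrow(s)
    ok[ok] <- p0[ok] < s$end[j[ok]]
    idx[sel[ok]] <- s_idx[j[ok]]
  }

  out <- muts
  out$major_cn <- seg$major_cn[idx]
  out$minor_cn <- seg$minor_cn[idx]
  out$total_cn <- seg$total_cn[idx]
  out$mc_point <- NA_real_
  out$mc_low <- NA_real_
  out$mc_high <- NA_real_
  out$multiplicity_raw <- NA_integer_
  out$multiplicity <- NA_integer_
  out$ccf <- NA_real_
  out$clonal <- NA
  out$rule <- NA_character_
  out$category <- NA_character_
  out$qc_flags <- character(n)

  sex <- is_sex_chrom(muts$chrom)
  no_cn <- !sex & is.na(idx)
  unassigned <- !sex & !no_cn & seg$cn_unassigned[idx]
  excluded <- sex | no_cn | unassigned
  out$qc_flags[sex] <- "sex_chrom"
  out$qc_flags[no_cn] <- "no_cn"
  out$qc_flags[unassigned] <- "cn_unassigned"
  out$category[excluded] <- "EXCLUDED"

  live <- which(!excluded)
  if (length(live) > 0) {
    n_T <- out$total_cn[live]
    # total copy 0 cannot host a mutation: flagged, no call, excluded
    zero_cn <- n_T == 0 & out$alt_count[live] > 0
    callable <- live[!zero_cn]
    if (any(zero_cn)) {
      bad <- live[zero_cn]
      out$qc_flags[bad] <- "cn_inconsistent"
      out$category[bad] <- "EXCLUDED"
    }
    if (length(callable) > 0) {
      ci <- mc_confidence_interval(out$alt_count[callable],
                                   out$depth[callable],
                                   profile$purity,
                                   out$total_cn[callable],
                                   n_N = 2,
                                   level = config$ci_level)
      out$mc_point[callable] <- ci$mc_point
      out$mc_low[callable] <- ci$mc_low
      out$mc_high[callable] <- ci$mc_high
      mult <- assign_multiplicity(ci$mc_point, ci$mc_low, ci$mc_high,
                                  tolerance = config$clonal_tolerance,
                                  n_T = out$total_cn[callable],
                                  major_cn = out$major_cn[callable])
      out$multiplicity_raw[callable] <- mult$multiplicity_raw
      out$multiplicity[callable] <- mult$multiplicity
      out$ccf[callable] <- mult$ccf
      out$clonal[callable] <- mult$clonal
      out$rule[callable] <- mult$rule
      out$qc_flags[callable] <- mapply(join_flags,
                                       out$qc_flags[callable],
                                       mult$qc_flags,
                                       USE.NAMES = FALSE)
      cat_call <- categorize(
        total_cn = out$total_cn[callable],
        multiplicity = out$multiplicity[callable],
        multiplicity_raw = out$multiplicity_raw[callable]
      )
      out$category[callable] <- cat_call$category
      if (any(cat_call$m_cn_conflict, na.rm = TRUE)) {
        ii <- callable[which(cat_call$m_cn_conflict)]
        out$qc_flags[ii] <- vapply(ii, function(i)
          join_flags(out$qc_flags[i], "m_cn_conflict"), character(1))
      }
      # mutations whose support was zero get no category call either:
      # they are unassessable rather than a burden class
      zs <- callable[is.na(mult$rule)]
      out$category[zs] <- "EXCLUDED"
    }
  }
  out
}
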
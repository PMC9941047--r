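# Overlap lengths of segments clipped to an arm (0-based half-open).
clip_to_arm <- function(seg, arm) {
  s <- seg[norm_chrom(seg$chrom) == norm_chrom(arm$chrom), , drop = FALSE]
  if (nrow(s) == 0) return(s[0, , drop = FALSE])
  ov_start <- pmax(s$start, arm$start)
  ov_end <- pmin(s$end, arm$end)
  keep <- ov_end > ov_start
  s <- s[keep, , drop = FALSE]
  s$len <- (ov_end - ov_start)[keep]
  s
}

#' Classify a chromosome arm's copy-number state
#'
#' An arm is \code{DIPLOID} when at least \code{arm_state_fraction}
#' (default 75%) of the covered length is copy neutral without LOH
#' (allele state 1-1), \code{HAPLOID} when at least that fraction has
#' total copy number 1, and \code{OTHER} otherwise. Fractions are over
#' the summed length of segments overlapping the arm (clipped to the
#' arm), not the arm's nominal length; arms with zero covered length are
#' \code{OTHER}.
#'
#' @param profile A [segment_profile()].
#' @param arms Arm table from [read_arms()] (one or more rows).
#' @param arm_state_fraction Length-fraction threshold (ties count).
#' @return data.frame with \code{arm_id, chrom, arm, covered, state}.
#' @export
classify_arm_state <- function(profile, arms, arm_state_fraction = 0.75) {
  seg <- profile$segments
  seg <- seg[!seg$cn_unassigned, , drop = FALSE]
  res <- lapply(seq_len(nrow(arms)), function(i) {
    arm <- arms[i, ]
    s <- clip_to_arm(seg, arm)
    covered <- sum(s$len)
    if (covered == 0) {
      state <- "OTHER"
    } else {
      frac_dip <- sum(s$len[s$major_cn == 1 & s$minor_cn == 1]) / covered
      frac_hap <- sum(s$len[s$total_cn == 1]) / covered
      state <- if (frac_dip >= arm_state_fraction) "DIPLOID"
      else if (frac_hap >= arm_state_fraction) "HAPLOID"
      else "OTHER"
    }
    data.frame(arm_id = arm$arm_id, chrom = arm$chrom, arm = arm$arm,
               covered = covered, state = state,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Background rates of genomic loss in diploid and haploid arms
#'
#' Over arms called \code{DIPLOID}, the per-copy loss rate is
#' \deqn{R_D = (2 l_D^{HD} + l_D^{HM}) / (2 l_D)}
#' where \eqn{l_D} is the summed segment length in those arms,
#' \eqn{l_D^{HD}} the length at total copy number 0 (homozygous
#' deletion, two copies lost) and \eqn{l_D^{HM}} the length at total copy
#' number 1 (hemizygous loss). Over \code{HAPLOID} arms,
#' \deqn{R_H = l_H^{HD} / l_H} counts the remaining copy's deletions.
#' Sex chromosomes never enter. Rates are \code{NA} when the respective
#' arm set is empty (undefined, not zero).
#'
#' @param profile A [segment_profile()].
#' @param arms Arm table from [read_arms()].
#' @param arm_state_fraction Threshold for [classify_arm_state()].
#' @return One-row data.frame with \code{r_diploid, r_haploid, l_D,
#'   l_D_HD, l_D_HM, l_H, l_H_HD, n_diploid_arms, n_haploid_arms}.
#' @export
compute_loss_rates <- function(profile, arms, arm_state_fraction = 0.75) {
  arms <- arms[!is_sex_chrom(arms$chrom), , drop = FALSE]
  states <- classify_arm_state(profile, arms, arm_state_fraction)
  seg <- profile$segments
  seg <- seg[!seg$cn_unassigned & !is_sex_chrom(seg$chrom), , drop = FALSE]
  sum_lens <- function(arm_ids) {
    tot <- hd <- hm <- 0
    for (i in which(arms$arm_id %in% arm_ids)) {
      s <- clip_to_arm(seg, arms[i, ])
      tot <- tot + sum(s$len)
      hd <- hd + sum(s$len[s$total_cn == 0])
      hm <- hm + sum(s$len[s$total_cn == 1])
    }
    c(tot = tot, hd = hd, hm = hm)
  }
  dip <- sum_lens(states$arm_id[states$state == "DIPLOID"])
  hap <- sum_lens(states$arm_id[states$state == "HAPLOID"])
  r_d <- if (dip["tot"] > 0) {
    (2 * dip["hd"] + dip["hm"]) / (2 * dip["tot"])
  } else NA_real_
  r_h <- if (hap["tot"] > 0) hap["hd"] / hap["tot"] else NA_real_
  data.frame(
    r_diploid = unname(r_d), r_haploid = unname(r_h),
    l_D = unname(dip["tot"]), l_D_HD = unname(dip["hd"]),
    l_D_HM = unname(dip["hm"]),
    l_H = unname(hap["tot"]), l_H_HD = unname(hap["hd"]),
    n_diploid_arms = sum(states$state == "DIPLOID"),
    n_haploid_arms = sum(states$state == "HAPLOID")
  )
}

#' Aneuploidy metrics and whole-genome doubling
#'
#' Computes, over the autosomal covered length with assigned
#' allele-specific values: the fraction with allelic imbalance (major !=
#' minor), the fraction at a single copy (total 1), the fraction with
#' multiple copies of a parental haplotype (major > 1), and the WGD call.
#'
#' @param profile A [segment_profile()].
#' @param wgd_fraction Strict threshold for [call_wgd()].
#' @return One-row data.frame with \code{frac_allelic_imbalance,
#'   frac_single_copy, frac_multi_copy, wgd, covered_length}.
#' @export
compute_aneuploidy <- function(profile, wgd_fraction = 0.50) {
  seg <- profile$segments
  seg <- seg[!seg$cn_unassigned & !is_sex_chrom(seg$chrom), , drop = FALSE]
  len <- seg$end - seg$start
  total <- sum(len)
  if (total == 0) stop("no covered autosomal length with assigned copy number")
  data.frame(
    frac_allelic_imbalance = sum(len[seg$major_cn != seg$minor_cn]) / total,
    frac_single_copy = sum(len[seg$total_cn == 1]) / total,
    frac_multi_copy = sum(len[seg$major_cn > 1]) / total,
    wgd = call_wgd(profile, wgd_fraction),
    covered_length = total
  )
}

#' Whole-genome doubling call
#'
#' TRUE when strictly more than \code{wgd_fraction} (default 50%) of the
#' autosomal covered length has major allele-specific copy number 2 or
#' above.
#'
#' @param profile A [segment_profile()].
#' @param wgd_fraction Strict threshold.
#' @return Logical flag.
#' @export
call_wgd <- function(profile, wgd_fraction = 0.50) {
  seg <- profile$segments
  seg <- seg[!seg$cn_unassigned & !is_sex_chrom(seg$chrom), , drop = FALSE]
  len <- seg$end - seg$start
  total <- sum(len)
  if (total == 0) return(NA)
  sum(len[seg$major_cn >= 2]) / total > wgd_fraction
}
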
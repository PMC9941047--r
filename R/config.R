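#' Analysis configuration
#'
#' Bundles the tunable thresholds used across the pipeline. Defaults follow
#' the decision rules of the underlying method: a 95% confidence level for
#' the read-count binomial interval, a cellular-fraction tolerance of 0.75
#' for calling a mutation clonal, a 75% length threshold for arm-state
#' calls, and a strict 50% major-copy-number fraction for whole-genome
#' doubling.
#'
#' @param ci_level Confidence level for the binomial interval on the
#'   mutant-read proportion (fraction in (0,1)).
#' @param clonal_tolerance Cellular-fraction threshold above which a
#'   mutation with multiplicity resolved by the subclonal rule is still
#'   called clonal (the "tolerance threshold of 1").
#' @param arm_state_fraction Minimum fraction of covered arm length in the
#'   defining copy-number state for a DIPLOID/HAPLOID arm call (ties count
#'   as meeting the threshold).
#' @param wgd_fraction Autosomal length fraction with major copy number
#'   >= 2 that must be strictly exceeded to call whole-genome doubling.
#' @param vaf_filter Optional minimum variant allele fraction; mutations
#'   below it are dropped (\code{NULL} disables; 0.10 reproduces the
#'   preprocessing used for some NSCLC/HNSCC cohorts).
#' @param drop_indels Drop indel calls before burden counting (used for
#'   cohorts where indels are artifact-prone).
#' @param persistent_mode Either \code{"full"} (persistent = multi-copy +
#'   only-copy) or \code{"single_copy_only"} (persistent = only-copy, the
#'   mesothelioma convention).
#' @param quantile_grid Quantiles at which TMB/pTMB high-low
#'   reclassification is evaluated.
#' @param min_progression_depth Minimum distinct depth at a baseline locus
#'   in the progression sample for a loss call to be assessable.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class \code{ptmb_config}.
#' @export
ptmb_config <- function(ci_level = 0.95,
                        clonal_tolerance = 0.75,
                        arm_state_fraction = 0.75,
                        wgd_fraction = 0.50,
                        vaf_filter = NULL,
                        drop_indels = FALSE,
                        persistent_mode = c("full", "single_copy_only"),
                        quantile_grid = seq(0.05, 0.95, by = 0.05),
                        min_progression_depth = 1L,
                        seed = NULL) {
  persistent_mode <- match.arg(persistent_mode)
  stopifnot(
    is.numeric(ci_level), length(ci_level) == 1, ci_level > 0, ci_level < 1,
    is.numeric(clonal_tolerance), clonal_tolerance > 0, clonal_tolerance < 1,
    is.numeric(arm_state_fraction), arm_state_fraction > 0,
    arm_state_fraction < 1,
    is.numeric(wgd_fraction), wgd_fraction > 0, wgd_fraction < 1,
    is.null(vaf_filter) ||
      (is.numeric(vaf_filter) && vaf_filter > 0 && vaf_filter < 1),
    is.logical(drop_indels), length(drop_indels) == 1,
    is.numeric(quantile_grid), all(quantile_grid > 0), all(quantile_grid < 1),
    is.numeric(min_progression_depth), min_progression_depth >= 0
  )
  structure(
    list(
      ci_level = ci_level,
      clonal_tolerance = clonal_tolerance,
      arm_state_fraction = arm_state_fraction,
      wgd_fraction = wgd_fraction,
      vaf_filter = vaf_filter,
      drop_indels = drop_indels,
      persistent_mode = persistent_mode,
      quantile_grid = quantile_grid,
      min_progression_depth = as.integer(min_progression_depth),
      seed = seed
    ),
    class = "ptmb_config"
  )
}

#' @export
print.ptmb_config <- function(x, ...) {
  cat("ptmb configuration\n")
  cat("  ci_level:             ", x$ci_level, "\n")
  cat("  clonal_tolerance:     ", x$clonal_tolerance, "\n")
  cat("  arm_state_fraction:   ", x$arm_state_fraction, "\n")
  cat("  wgd_fraction:         ", x$wgd_fraction, "\n")
  cat("  vaf_filter:           ",
      if (is.null(x$vaf_filter)) "none" else x$vaf_filter, "\n")
  cat("  drop_indels:          ", x$drop_indels, "\n")
  cat("  persistent_mode:      ", x$persistent_mode, "\n")
  cat("  min_progression_depth:", x$min_progression_depth, "\n")
  invisible(x)
}

# Sex chromosome labels excluded from all burden and genome metrics.
SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "x", "y", "chrx", "chry")

is_sex_chrom <- function(chrom) chrom %in% SEX_CHROMS

# Strip an optional "chr" prefix so arm tables and profiles can mix styles.
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

join_flags <- function(...) {
  parts <- c(...)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) "" else paste(parts, collapse = ";")
}
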
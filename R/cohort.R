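#' High/low labels at an empirical quantile
#'
#' Thresholds a burden (or any numeric) vector at the empirical quantile
#' \code{q} (linear interpolation between order statistics) and labels a
#' sample HIGH only when its value strictly exceeds the threshold, so a
#' constant vector yields no HIGH samples.
#'
#' @param values Numeric vector (n >= 2).
#' @param q Quantile in (0, 1).
#' @return Logical vector, TRUE = HIGH.
#' @export
high_low_labels <- function(values, q) {
  stopifnot(length(values) >= 2, q > 0, q < 1, !anyNA(values))
  values > stats::quantile(values, probs = q, type = 7, names = FALSE)
}

#' TMB versus pTMB reclassification curve
#'
#' For each quantile on a grid (default 5% to 95% in 5% steps), labels
#' samples high/low by each burden measure and records the fraction whose
#' labels disagree (pTMB-low/TMB-high plus pTMB-high/TMB-low). The rate
#' is symmetric in the two inputs.
#'
#' @param tmb,ptmb Paired per-sample burden vectors.
#' @param quantile_grid Quantiles at which to evaluate.
#' @return list with \code{curve} (data.frame \code{quantile, rate}),
#'   \code{median_rate} and \code{max_rate}.
#' @export
reclassification_curve <- function(tmb, ptmb,
                                   quantile_grid = seq(0.05, 0.95,
                                                       by = 0.05)) {
  if (length(tmb) != length(ptmb)) {
    stop("tmb and ptmb must be paired vectors of equal length")
  }
  rates <- vapply(quantile_grid, function(q) {
    mean(high_low_labels(tmb, q) != high_low_labels(ptmb, q))
  }, numeric(1))
  list(curve = data.frame(quantile = quantile_grid, rate = rates),
       median_rate = stats::median(rates),
       max_rate = max(rates))
}

#' Two-group comparison by Mann-Whitney U
#'
#' Two-sided Mann-Whitney U test between responder groups. The exact null
#' distribution is used when both groups have at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param values Numeric vector.
#' @param group Two-level factor/character (e.g. "R"/"NR").
#' @return list with \code{U} (statistic for the first group level),
#'   \code{p}, \code{n1}, \code{n2}, \code{exact}.
#' @export
group_comparison <- function(values, group) {
  group <- as.factor(group)
  lev <- levels(group)
  if (length(lev) != 2) stop("group must have exactly two levels")
  x <- values[group == lev[1]]
  y <- values[group == lev[2]]
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y), exact = use_exact)
}

#' Cohen's d effect size between responder groups
#'
#' \eqn{d = (\bar x_{NR} - \bar x_R) / s_{pooled}} with the pooled
#' standard deviation weighted by n - 1. The fixed NR - R order makes a
#' responders-higher biomarker come out negative. NULL when the pooled SD
#' is zero.
#'
#' @param values Numeric vector.
#' @param response Character/factor with levels "R" and "NR".
#' @return Signed effect size, or NULL if undefined.
#' @export
effect_size <- function(values, response) {
  x_nr <- values[response == "NR"]
  x_r <- values[response == "R"]
  if (length(x_nr) < 2 || length(x_r) < 2) {
    stop("each group needs at least 2 observations")
  }
  n1 <- length(x_nr); n2 <- length(x_r)
  sp2 <- ((n1 - 1) * stats::var(x_nr) + (n2 - 1) * stats::var(x_r)) /
    (n1 + n2 - 2)
  if (sp2 == 0) return(NULL)
  (mean(x_nr) - mean(x_r)) / sqrt(sp2)
}

#' Spearman correlation with t-approximation p value
#'
#' Spearman's rho with average ranks for ties; the two-sided p value uses
#' the asymptotic t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}
#' on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return list with \code{rho}, \code{p}, \code{n}; \code{rho} NULL when
#'   either vector is constant.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NULL, p = NULL, n = length(x)))
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Response rates in discordantly classified tumors
#'
#' Labels samples high/low by TMB and by pTMB at the second tertile
#' (strictly above), cross-tabulates responders and nonresponders across
#' the two discordant groups (pTMB-high/TMB-low versus
#' pTMB-low/TMB-high), and runs a two-sided Fisher's exact test
#' (probability-mass method). The test is skipped when a discordant group
#' is empty.
#'
#' @param tmb,ptmb Paired burden vectors.
#' @param response Character vector of "R"/"NR".
#' @return list with \code{table} (2x2: rows = discordant group, cols =
#'   R/NR), \code{p} (NULL when skipped), and the per-sample group label.
#' @export
discordant_response_table <- function(tmb, ptmb, response) {
  stopifnot(length(tmb) == length(ptmb),
            length(response) == length(tmb))
  hi_t <- high_low_labels(tmb, 2 / 3)
  hi_p <- high_low_labels(ptmb, 2 / 3)
  grp <- rep(NA_character_, length(tmb))
  grp[hi_p & !hi_t] <- "pTMB_high_TMB_low"
  grp[!hi_p & hi_t] <- "pTMB_low_TMB_high"
  tab <- matrix(c(
    sum(grp == "pTMB_high_TMB_low" & response == "R", na.rm = TRUE),
    sum(grp == "pTMB_high_TMB_low" & response == "NR", na.rm = TRUE),
    sum(grp == "pTMB_low_TMB_high" & response == "R", na.rm = TRUE),
    sum(grp == "pTMB_low_TMB_high" & response == "NR", na.rm = TRUE)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("pTMB_high_TMB_low", "pTMB_low_TMB_high"),
                  c("R", "NR")))
  p <- if (any(rowSums(tab) == 0)) NULL else
    stats::fisher.test(tab)$p.value
  list(table = tab, p = p, group = grp)
}

#' Cohort association report
#'
#' Convenience wrapper running the response-association statistics for a
#' set of burden columns of a cohort table.
#'
#' @param cohort data.frame with burden columns and a \code{response}
#'   column of "R"/"NR".
#' @param features Column names to test.
#' @return data.frame with one row per feature: \code{feature, n_R, n_NR,
#'   U, p, d, rho_vs_tmb}.
#' @export
associate_response <- function(cohort,
                               features = c("tmb", "ptmb", "clonal_ptmb",
                                            "multi_copy", "only_copy",
                                            "loss_prone")) {
  features <- intersect(features, names(cohort))
  rows <- lapply(features, function(f) {
    v <- cohort[[f]]
    gc_ <- group_comparison(v, cohort$response)
    d <- effect_size(v, cohort$response)
    rc <- if (f == "tmb") list(rho = 1) else
      rank_correlation(v, cohort$tmb)
    data.frame(feature = f,
               n_R = sum(cohort$response == "R"),
               n_NR = sum(cohort$response == "NR"),
               U = gc_$U, p = gc_$p,
               d = if (is.null(d)) NA_real_ else d,
               rho_vs_tmb = if (is.null(rc$rho)) NA_real_ else rc$rho,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
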
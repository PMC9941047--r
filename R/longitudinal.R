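#' Call mutation loss between baseline and progression samples
#'
#' Matches each baseline mutation to the progression sample's read counts
#' at the same locus (keyed by chrom, pos, ref, alt). A mutation is lost
#' when its progression mutant allele fraction is zero (alt count 0) at a
#' locus with at least \code{min_progression_depth} distinct reads; loci
#' below that depth, or absent from the progression table, are
#' \code{unassessable} and drop out of every denominator.
#'
#' @param baseline Annotated baseline mutation data.frame (with
#'   \code{category} and \code{clonal}).
#' @param progression data.frame with \code{chrom, pos, ref, alt,
#'   alt_count, depth} measured in the progression sample at baseline
#'   loci.
#' @param min_progression_depth Minimum assessable depth (default 1).
#' @return \code{baseline} extended with \code{prog_alt_count,
#'   prog_depth, lost, assessable}.
#' @export
pair_mutations <- function(baseline, progression,
                           min_progression_depth = 1L) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  i <- match(key(baseline), key(progression))
  out <- baseline
  out$prog_alt_count <- progression$alt_count[i]
  out$prog_depth <- progression$depth[i]
  out$assessable <- !is.na(i) & out$prog_depth >= min_progression_depth
  out$lost <- ifelse(out$assessable, out$prog_alt_count == 0, NA)
  out$qc_flags <- ifelse(
    out$assessable, out$qc_flags,
    vapply(out$qc_flags, join_flags, character(1), "unassessable",
           USE.NAMES = FALSE))
  out
}

#' Per-stratum loss summary for a serial pair
#'
#' Counts losses per clonality stratum and persistence category, plus the
#' pooled persistent stratum (multi-copy plus only-copy). Frequencies are
#' \code{NA} where a stratum is empty.
#'
#' @param paired Output of [pair_mutations()] (assessable, categorized
#'   mutations; EXCLUDED and unassessable rows are ignored).
#' @return data.frame with one row per (clonality, category) including
#'   category \code{PERSISTENT}: \code{clonality, category, n_total,
#'   n_lost, loss_frequency}.
#' @export
loss_summary <- function(paired) {
  d <- paired[!is.na(paired$category) & paired$category != "EXCLUDED" &
                paired$assessable & !is.na(paired$clonal), , drop = FALSE]
  strata <- expand.grid(
    clonality = c("clonal", "subclonal"),
    category = c("LOSS_PRONE", "MULTI_COPY", "ONLY_COPY", "PERSISTENT"),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    cl <- strata$clonality[i] == "clonal"
    categ <- strata$category[i]
    in_cat <- if (categ == "PERSISTENT") {
      d$category %in% c("MULTI_COPY", "ONLY_COPY")
    } else d$category == categ
    sel <- d$clonal == cl & in_cat
    n_tot <- sum(sel)
    n_lost <- sum(d$lost[sel])
    data.frame(clonality = strata$clonality[i], category = categ,
               n_total = n_tot, n_lost = n_lost,
               loss_frequency = if (n_tot > 0) n_lost / n_tot else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional maximum-likelihood odds ratio of a 2x2 table
#'
#' The estimator attached to Fisher's exact test: conditioning on all
#' margins, the first cell follows a noncentral hypergeometric
#' distribution with odds parameter psi, and the conditional MLE solves
#' the score equation \eqn{E_\psi[X] = a}. Solved by bisection on
#' log(psi) to near machine precision. Returns 0 or Inf when the observed
#' cell sits on the boundary of its support.
#'
#' @param a,b,c_,d Cell counts (rows: exposure; columns: outcome).
#' @return The conditional MLE of the odds ratio.
#' @export
odds_ratio_cmle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  supp <- max(0, k - r2):min(k, r1)
  if (length(supp) == 1) return(NaN)
  if (a <= min(supp)) return(0)
  if (a >= max(supp)) return(Inf)
  lc <- lchoose(r1, supp) + lchoose(r2, k - supp)
  score <- function(lpsi) {
    lw <- lc + supp * lpsi
    w <- exp(lw - max(lw))
    sum(supp * w) / sum(w) - a
  }
  # E[X | psi] is strictly increasing in psi; bracket then bisect
  lo <- -1; hi <- 1
  while (score(lo) > 0) lo <- lo * 2
  while (score(hi) < 0) hi <- hi * 2
  exp(stats::uniroot(score, c(lo, hi), tol = 1e-12)$root)
}

#' Loss-frequency association between loss-prone and persistent mutations
#'
#' Builds the 2x2 table (loss-prone vs persistent) x (lost vs retained)
#' within a clonality stratum and reports the odds ratio two ways: the
#' sample odds ratio ad/bc (with Haldane 0.5 correction and a flag when a
#' cell is zero) and the conditional maximum-likelihood odds ratio
#' attached to Fisher's exact test, with the two-sided exact p value
#' (probability-mass method).
#'
#' @param summary Output of [loss_summary()].
#' @param clonality \code{"clonal"} or \code{"subclonal"}.
#' @return list with \code{table}, \code{or_sample}, \code{or_cmle},
#'   \code{p}, \code{haldane} flag.
#' @export
loss_association <- function(summary, clonality = "clonal") {
  s <- summary[summary$clonality == clonality, , drop = FALSE]
  lp <- s[s$category == "LOSS_PRONE", ]
  pe <- s[s$category == "PERSISTENT", ]
  a <- lp$n_lost
  b <- lp$n_total - lp$n_lost
  c_ <- pe$n_lost
  d <- pe$n_total - pe$n_lost
  if (min(a + b, c_ + d, a + c_, b + d) < 1) {
    stop("loss association needs all margins >= 1")
  }
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("LOSS_PRONE", "PERSISTENT"),
                                c("lost", "retained")))
  haldane <- any(tab == 0)
  or_sample <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else (a * d) / (b * c_)
  ft <- stats::fisher.test(tab)
  list(table = tab, or_sample = or_sample,
       or_cmle = odds_ratio_cmle(a, b, c_, d), p = ft$p.value,
       haldane = haldane)
}
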
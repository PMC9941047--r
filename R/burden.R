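#' Apply cohort-level mutation filters
#'
#' Optional preprocessing used by some cohorts: a minimum variant allele
#' fraction (e.g. 0.10), dropping indels, and restriction to
#' nonsynonymous calls for burden counting.
#'
#' @param muts Mutation data.frame.
#' @param config A [ptmb_config()] supplying \code{vaf_filter} and
#'   \code{drop_indels}.
#' @param nonsynonymous_only Keep nonsynonymous calls only (default TRUE,
#'   the burden convention).
#' @return Filtered mutation data.frame.
#' @export
filter_mutations <- function(muts, config = ptmb_config(),
                             nonsynonymous_only = TRUE) {
  keep <- rep(TRUE, nrow(muts))
  if (!is.null(config$vaf_filter)) {
    keep <- keep & muts$vaf >= config$vaf_filter
  }
  if (isTRUE(config$drop_indels)) {
    keep <- keep & muts$variant_class != "INDEL"
  }
  if (nonsynonymous_only) {
    keep <- keep & muts$is_nonsynonymous
  }
  muts[keep, , drop = FALSE]
}

#' Persistence category of a mutation
#'
#' A mutation in a region with a single copy per cell (total copy number
#' 1) is \code{ONLY_COPY}; a mutation present in more than one copy per
#' cancer cell (multiplicity > 1) is \code{MULTI_COPY}; every other
#' assessed mutation is \code{LOSS_PRONE}. A raw multiplicity above 1 on a
#' total-copy-1 segment is physically impossible, so the copy-number state
#' wins and the conflict is flagged.
#'
#' @param total_cn Total copy number per mutation.
#' @param multiplicity Capped multiplicity call.
#' @param multiplicity_raw Uncapped multiplicity (for conflict flagging).
#' @return data.frame with \code{category} and logical
#'   \code{m_cn_conflict}.
#' @export
categorize <- function(total_cn, multiplicity,
                       multiplicity_raw = multiplicity) {
  category <- ifelse(total_cn == 1, "ONLY_COPY",
                     ifelse(!is.na(multiplicity) & multiplicity > 1,
                            "MULTI_COPY", "LOSS_PRONE"))
  conflict <- total_cn == 1 & !is.na(multiplicity_raw) &
    multiplicity_raw > 1
  data.frame(category = category, m_cn_conflict = conflict,
             stringsAsFactors = FALSE)
}

#' Per-sample burden summary
#'
#' Counts TMB (all assessed nonsynonymous mutations), pTMB (persistent
#' mutations: multi-copy plus only-copy, or only-copy alone under the
#' single-copy-only convention used for mesothelioma), loss-prone
#' mutations (TMB minus persistent) and their clonal restrictions.
#' \code{EXCLUDED} mutations sit outside every denominator.
#'
#' @param muts Annotated mutation data.frame from [annotate_mutations()].
#' @param config A [ptmb_config()]; \code{persistent_mode} selects the
#'   persistent definition.
#' @param sample_id Optional sample label for the output row.
#' @return One-row data.frame with columns \code{sample_id, tmb, ptmb,
#'   clonal_ptmb, multi_copy, clonal_multi_copy, only_copy,
#'   clonal_only_copy, loss_prone, clonal_loss_prone, n_excluded,
#'   persistent_mode}.
#' @export
summarize_burden <- function(muts, config = ptmb_config(),
                             sample_id = NA_character_) {
  cat_ <- muts$category
  clonal <- !is.na(muts$clonal) & muts$clonal
  n_mc <- sum(cat_ == "MULTI_COPY", na.rm = TRUE)
  n_oc <- sum(cat_ == "ONLY_COPY", na.rm = TRUE)
  n_lp <- sum(cat_ == "LOSS_PRONE", na.rm = TRUE)
  c_mc <- sum(cat_ == "MULTI_COPY" & clonal, na.rm = TRUE)
  c_oc <- sum(cat_ == "ONLY_COPY" & clonal, na.rm = TRUE)
  c_lp <- sum(cat_ == "LOSS_PRONE" & clonal, na.rm = TRUE)
  n_ex <- sum(is.na(cat_) | cat_ == "EXCLUDED")
  if (config$persistent_mode == "full") {
    ptmb <- n_mc + n_oc
    c_ptmb <- c_mc + c_oc
    loss_prone <- n_lp
    c_loss <- c_lp
  } else {
    ptmb <- n_oc
    c_ptmb <- c_oc
    loss_prone <- n_lp + n_mc
    c_loss <- c_lp + c_mc
  }
  data.frame(
    sample_id = sample_id,
    tmb = n_mc + n_oc + n_lp,
    ptmb = ptmb,
    clonal_ptmb = c_ptmb,
    multi_copy = n_mc,
    clonal_multi_copy = c_mc,
    only_copy = n_oc,
    clonal_only_copy = c_oc,
    loss_prone = loss_prone,
    clonal_loss_prone = c_loss,
    n_excluded = n_ex,
    persistent_mode = config$persistent_mode,
    stringsAsFactors = FALSE
  )
}

#' Restrict mutations to a targeted panel
#'
#' Simulates panel-targeted sequencing from exome-wide calls: keeps
#' mutations whose position falls in the panel intervals and recomputes
#' the burden summary on the subset. Copy-number annotation is left
#' unchanged (allele-specific copy number is assumed derivable from the
#' panel itself).
#'
#' @param muts Annotated mutation data.frame.
#' @param intervals Panel intervals from [read_intervals()].
#' @param config A [ptmb_config()].
#' @param sample_id Optional sample label.
#' @param panel_mb Optional panel footprint in Mb; when given, per-Mb
#'   burden columns \code{tmb_per_mb} and \code{ptmb_per_mb} are added.
#' @return list with \code{muts} (subset) and \code{summary}.
#' @export
restrict_to_panel <- function(muts, intervals, config = ptmb_config(),
                              sample_id = NA_character_,
                              panel_mb = NULL) {
  inside <- positions_in_intervals(muts$chrom, muts$pos, intervals)
  sub <- muts[inside, , drop = FALSE]
  summ <- summarize_burden(sub, config, sample_id)
  if (!is.null(panel_mb) && panel_mb > 0) {
    summ$tmb_per_mb <- summ$tmb / panel_mb
    summ$ptmb_per_mb <- summ$ptmb / panel_mb
  }
  list(muts = sub, summary = summ)
}

#' Persistent mutation-associated neoantigen burden
#'
#' Joins precomputed MHC class I binding predictions to persistent
#' mutations. A persistent mutation with at least one peptide of
#' predicted IC50 strictly below 500 nM is pMANA-encoding; an expressed
#' pMANA additionally requires nonzero median expression of its gene in
#' the matching tumor type. Binding prediction itself is an input, not a
#' computation of this package.
#'
#' @param muts Annotated mutation data.frame (with \code{category} and
#'   \code{gene}).
#' @param predictions data.frame with \code{chrom, pos, ref, alt, ic50}
#'   (one row per predicted peptide; multiple rows per mutation allowed).
#' @param expression Optional data.frame with \code{gene,
#'   median_expression}.
#' @param ic50_threshold Binding threshold in nM (strict less-than).
#' @return list with counts \code{pmana}, \code{expressed_pmana},
#'   \code{n_persistent}, \code{n_unpredicted}, and the persistent subset
#'   with logical columns \code{pmana}, \code{expressed_pmana}.
#' @export
pmana_burden <- function(muts, predictions, expression = NULL,
                         ic50_threshold = 500) {
  persistent <- muts[muts$category %in% c("MULTI_COPY", "ONLY_COPY"), ,
                     drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  pk <- key(persistent)
  best <- tapply(predictions$ic50, key(predictions), min)
  has_pred <- pk %in% names(best)
  best_ic50 <- rep(NA_real_, nrow(persistent))
  best_ic50[has_pred] <- unname(best[pk[has_pred]])
  persistent$pmana <- !is.na(best_ic50) & best_ic50 < ic50_threshold
  persistent$qc_flags <- ifelse(
    has_pred, persistent$qc_flags,
    vapply(persistent$qc_flags, join_flags, character(1),
           "no_prediction", USE.NAMES = FALSE))
  expressed <- rep(TRUE, nrow(persistent))
  if (!is.null(expression)) {
    med <- expression$median_expression[
      match(persistent$gene, expression$gene)]
    expressed <- !is.na(med) & med > 0
  }
  persistent$expressed_pmana <- persistent$pmana & expressed
  list(pmana = sum(persistent$pmana),
       expressed_pmana = sum(persistent$expressed_pmana),
       n_persistent = nrow(persistent),
       n_unpredicted = sum(!has_pred),
       muts = persistent)
}
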
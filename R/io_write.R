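ANNOTATED_COLUMNS <- c("chrom", "pos", "ref", "alt", "alt_count",
                       "depth", "major_cn", "minor_cn", "multiplicity",
                       "ccf", "clonal", "category", "qc_flags")

#' Write per-sample annotation results
#'
#' Writes the annotated mutation table as TSV (fixed column order) and
#' the per-sample metrics (burden summary plus optional aneuploidy
#' metrics) as JSON. Output is deterministic: identical inputs produce
#' byte-identical files.
#'
#' @param annotated Annotated mutation data.frame.
#' @param summary One-row burden summary from [summarize_burden()].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix (default the summary's sample id).
#' @param metrics Optional extra one-row data.frame (e.g.
#'   [compute_aneuploidy()]) merged into the JSON.
#' @return Invisibly, the two file paths.
#' @export
write_annotated <- function(annotated, summary, dir,
                            prefix = summary$sample_id,
                            metrics = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir)
  }
  if (is.na(prefix) || !nzchar(prefix)) prefix <- "sample"
  tsv <- file.path(dir, paste0(prefix, ".annotated.tsv"))
  js <- file.path(dir, paste0(prefix, ".metrics.json"))
  cols <- intersect(ANNOTATED_COLUMNS, names(annotated))
  tab <- annotated[, cols, drop = FALSE]
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x)
    ifelse(is.na(x), NA, sprintf("%.6g", x)))
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  payload <- as.list(summary)
  if (!is.null(metrics)) payload <- c(payload, as.list(metrics))
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, json = js))
}
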
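#' Read a panel interval set (BED)
#'
#' Reads a BED file (0-based half-open, no header, first three columns
#' used), then sorts and merges overlapping or book-ended intervals so the
#' result is a canonical disjoint set. Re-reading a written set is a
#' fixed point.
#'
#' @param path BED file path.
#' @return data.frame with columns \code{chrom, start, end} (0-based
#'   half-open, disjoint, sorted).
#' @export
read_intervals <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  if (ncol(raw) < 3) stop("BED file ", path, " needs at least 3 columns")
  iv <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.numeric(raw[[2]]),
                   end = as.numeric(raw[[3]]),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(iv$start) | is.na(iv$end) | iv$end <= iv$start |
                 iv$start < 0)
  if (length(bad) > 0) {
    stop("invalid interval at line ", bad[1], " of ", path,
         " (need 0 <= start < end)")
  }
  merge_intervals(iv)
}

#' Merge an interval set
#'
#' Sorts intervals and merges overlapping or book-ended runs per
#' chromosome. Idempotent.
#'
#' @param iv data.frame with \code{chrom, start, end} (0-based half-open).
#' @return Canonical disjoint sorted interval data.frame.
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  out <- vector("list", length(unique(iv$chrom)))
  k <- 0
  for (chr in unique(iv$chrom)) {
    s <- iv[iv$chrom == chr, , drop = FALSE]
    # run starts where start exceeds the running max of previous ends
    run_end <- cummax(s$end)
    new_run <- c(TRUE, s$start[-1] > run_end[-nrow(s)])
    grp <- cumsum(new_run)
    k <- k + 1
    out[[k]] <- data.frame(
      chrom = chr,
      start = tapply(s$start, grp, min),
      end = tapply(s$end, grp, max),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an interval set as BED
#'
#' @param iv Interval data.frame (0-based half-open).
#' @param path Output path.
#' @export
write_intervals <- function(iv, path) {
  out <- data.frame(chrom = iv$chrom,
                    start = format(iv$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(iv$end, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Membership of 1-based positions in a disjoint sorted interval set.
positions_in_intervals <- function(chrom, pos, iv) {
  if (nrow(iv) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  hit <- rep(FALSE, length(pos))
  p0 <- pos - 1  # 0-based point
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    s <- iv[iv$chrom == chr, , drop = FALSE]
    if (nrow(s) == 0) next
    idx <- findInterval(p0[sel], s$start)
    ok <- idx >= 1 & idx <= nrow(s)
    ok[ok] <- p0[sel][ok] < s$end[idx[ok]]
    hit[sel] <- ok
  }
  hit
}

#' Chromosome arm boundary table
#'
#' Loads the arm boundary table shipped with the package (cytoband-derived
#' approximate boundaries for hg19 or hg38; p arm runs to the centromere
#' start, q arm from the centromere end) or a user-supplied TSV with
#' columns \code{chrom, arm, start, end} in 1-based inclusive coordinates.
#' Arm boundaries are an input: any table in the same format can stand in
#' for the shipped ones.
#'
#' @param build \code{"hg19"} or \code{"hg38"} for the shipped tables.
#' @param path Optional path to a custom arm TSV (overrides \code{build}).
#' @return data.frame with \code{chrom, arm, arm_id, start, end} (0-based
#'   half-open) sorted by chromosome and start.
#' @export
read_arms <- function(build = c("hg19", "hg38"), path = NULL) {
  if (is.null(path)) {
    build <- match.arg(build)
    path <- system.file("extdata", paste0("arms_", build, ".tsv"),
                        package = "ptmb", mustWork = TRUE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "arm", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("arm table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(raw$end < raw$start | raw$start < 1)
  if (length(bad) > 0) {
    stop("invalid arm boundary at line ", bad[1] + 1L)
  }
  arms <- data.frame(
    chrom = as.character(raw$chrom),
    arm = as.character(raw$arm),
    arm_id = paste0(norm_chrom(raw$chrom), raw$arm),
    start = as.numeric(raw$start) - 1,
    end = as.numeric(raw$end),
    stringsAsFactors = FALSE
  )
  arms <- arms[order(arms$chrom, arms$start), , drop = FALSE]
  for (chr in unique(arms$chrom)) {
    s <- arms[arms$chrom == chr, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping arms on chromosome ", chr)
    }
  }
  rownames(arms) <- NULL
  arms
}
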
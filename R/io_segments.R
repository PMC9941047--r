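#' Read an allele-specific segmental copy number profile
#'
#' Reads a FACETS-style tab-separated table of integer allele-specific copy
#' number segments. Input coordinates are 1-based inclusive; internally all
#' coordinates are 0-based half-open. Rows whose allele-specific values are
#' missing (\code{NA}) are retained and flagged \code{cn_unassigned} so that
#' downstream stages can exclude mutations on them explicitly rather than
#' silently losing genome.
#'
#' @param path Path to a TSV with header. The \code{major_minor} dialect
#'   expects columns \code{chrom, start, end, major_cn, minor_cn}; the
#'   \code{total_minor} dialect expects \code{chrom, start, end, total_cn,
#'   minor_cn} (major derived as total - minor).
#' @param dialect Column dialect, see above.
#' @return A data.frame of segments with columns \code{chrom, start, end,
#'   major_cn, minor_cn, total_cn, cn_unassigned}; coordinates 0-based
#'   half-open.
#' @seealso [segment_profile()] to attach purity/ploidy and validate.
#' @export
read_segments <- function(path, dialect = c("major_minor", "total_minor")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", "", "."))
  need <- if (dialect == "major_minor") {
    c("chrom", "start", "end", "major_cn", "minor_cn")
  } else {
    c("chrom", "start", "end", "total_cn", "minor_cn")
  }
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("segment file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  segments_from_table(raw, dialect = dialect, source = path)
}

# Shared normalization for file and in-memory tables. `source` only feeds
# error messages; line numbers are 1-based data rows (header excluded).
segments_from_table <- function(raw, dialect = "major_minor",
                                source = "segments") {
  n <- nrow(raw)
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), major_cn = integer(),
                      minor_cn = integer(), total_cn = integer(),
                      cn_unassigned = logical(),
                      stringsAsFactors = FALSE))
  }
  start1 <- suppressWarnings(as.numeric(raw$start))
  end1 <- suppressWarnings(as.numeric(raw$end))
  bad <- which(is.na(start1) | is.na(end1) | !is.finite(start1) |
                 !is.finite(end1) | start1 < 1 | end1 < start1)
  if (length(bad) > 0) {
    stop("malformed segment row at line ", bad[1] + 1L, " of ", source,
         " (need numeric 1-based start <= end)")
  }
  if (dialect == "major_minor") {
    major <- suppressWarnings(as.numeric(raw$major_cn))
    minor <- suppressWarnings(as.numeric(raw$minor_cn))
  } else {
    total <- suppressWarnings(as.numeric(raw$total_cn))
    minor <- suppressWarnings(as.numeric(raw$minor_cn))
    major <- total - minor
  }
  unassigned <- is.na(major) | is.na(minor)
  bad_cn <- which(!unassigned & (major < 0 | minor < 0 |
                                   major != round(major) |
                                   minor != round(minor)))
  if (length(bad_cn) > 0) {
    stop("malformed copy number at line ", bad_cn[1] + 1L, " of ", source,
         " (need non-negative integers)")
  }
  swapped <- which(!unassigned & major < minor)
  if (length(swapped) > 0) {
    stop("major_cn < minor_cn at line ", swapped[1] + 1L, " of ", source)
  }
  data.frame(
    chrom = as.character(raw$chrom),
    start = start1 - 1,
    end = end1,
    major_cn = ifelse(unassigned, NA_integer_, as.integer(major)),
    minor_cn = ifelse(unassigned, NA_integer_, as.integer(minor)),
    total_cn = ifelse(unassigned, NA_integer_,
                      as.integer(major) + as.integer(minor)),
    cn_unassigned = unassigned,
    stringsAsFactors = FALSE
  )
}

#' Construct a sample's segment profile
#'
#' Attaches purity/ploidy to a normalized segment table and validates the
#' partition assumption: segments on a chromosome must not overlap.
#'
#' @param sample_id Sample identifier.
#' @param segments Segment data.frame as returned by [read_segments()] (or
#'   an in-memory table with the same columns; 1-based tables can be passed
#'   through [segments_from_table()] first).
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Tumor ploidy (positive; informational).
#' @param tumor_type Optional tumor-type label.
#' @return An object of class \code{segment_profile}.
#' @export
segment_profile <- function(sample_id, segments, purity, ploidy = NA_real_,
                            tumor_type = NA_character_) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "major_cn", "minor_cn",
                  "total_cn", "cn_unassigned") %in% names(segments)))
  if (!is.numeric(purity) || length(purity) != 1 || is.na(purity) ||
      purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]")
  }
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  # partition check per chromosome: no overlap between consecutive segments
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on chromosome ", chr,
           " in sample ", sample_id)
    }
  }
  structure(
    list(sample_id = as.character(sample_id), segments = segments,
         purity = purity, ploidy = ploidy, tumor_type = tumor_type),
    class = "segment_profile"
  )
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile:", x$sample_id, "\n")
  cat("  segments:", nrow(x$segments), "on",
      length(unique(x$segments$chrom)), "chromosomes\n")
  cat("  purity:", x$purity, " ploidy:", x$ploidy, "\n")
  invisible(x)
}

#' Write a segment profile back to the 1-based TSV dialect
#'
#' Inverse of [read_segments()]; round-trips exactly.
#'
#' @param segments Internal 0-based segment data.frame.
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(
    chrom = segments$chrom,
    start = format(segments$start + 1, scientific = FALSE, trim = TRUE),
    end = format(segments$end, scientific = FALSE, trim = TRUE),
    major_cn = segments$major_cn,
    minor_cn = segments$minor_cn,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
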
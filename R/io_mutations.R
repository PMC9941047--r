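NONSYN_PATTERN <- paste0(
  "missense|nonsense|nonstop|frame_?shift|splice|in_?frame|",
  "translation_start"
)

#' Read somatic mutation calls
#'
#' Reads somatic mutation calls from a MAF-like tab-separated table or a
#' VCF. Positions are 1-based. The nonsynonymous flag is derived from the
#' variant classification (missense, nonsense, frameshift, splice-site and
#' in-frame indel classes count as nonsynonymous); burden counting uses
#' only nonsynonymous calls.
#'
#' @param path Input file.
#' @param format \code{"maf_tsv"} (columns \code{chrom, pos, ref, alt,
#'   t_alt_count, t_depth, variant_classification}, optional \code{gene})
#'   or \code{"vcf"} (per-sample \code{AD} and \code{DP} genotype fields;
#'   requires the VariantAnnotation package).
#' @param sample For VCF input, the tumor sample name or column index
#'   (default 1).
#' @return A data.frame with columns \code{chrom, pos, ref, alt, alt_count,
#'   depth, vaf, variant_class, variant_classification, is_nonsynonymous,
#'   gene}.
#' @export
read_mutations <- function(path, format = c("maf_tsv", "vcf"), sample = 1L) {
  format <- match.arg(format)
  if (format == "maf_tsv") read_mutations_maf(path) else
    read_mutations_vcf(path, sample)
}

read_mutations_maf <- function(path) {
  # read everything as character: allele columns like "T" must not be
  # parsed as logicals
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", "", "."))
  need <- c("chrom", "pos", "ref", "alt", "t_alt_count", "t_depth",
            "variant_classification")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("mutation file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  mutations_from_table(data.frame(
    chrom = as.character(raw$chrom),
    pos = as.numeric(raw$pos),
    ref = as.character(raw$ref),
    alt = as.character(raw$alt),
    alt_count = as.numeric(raw$t_alt_count),
    depth = as.numeric(raw$t_depth),
    variant_classification = as.character(raw$variant_classification),
    gene = if ("gene" %in% names(raw)) as.character(raw$gene)
           else NA_character_,
    stringsAsFactors = FALSE
  ), source = path)
}

read_mutations_vcf <- function(path, sample = 1L) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) == 0) {
    return(mutations_from_table(data.frame(
      chrom = character(), pos = numeric(), ref = character(),
      alt = character(), alt_count = numeric(), depth = numeric(),
      variant_classification = character(), gene = character(),
      stringsAsFactors = FALSE
    )))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  if (is.null(ad) || is.null(dp)) {
    stop("VCF ", path, " must carry AD and DP genotype fields")
  }
  alt_counts <- vapply(ad[, sample], function(x) as.numeric(x[2]),
                       numeric(1))
  alt_alleles <- vapply(as.list(rr$ALT), function(a)
    as.character(a)[1], character(1))
  mutations_from_table(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = alt_alleles,
    alt_count = alt_counts,
    depth = as.numeric(dp[, sample]),
    variant_classification = NA_character_,
    gene = NA_character_,
    stringsAsFactors = FALSE
  ), source = path)
}

# Validates counts, derives vaf, SNV/INDEL class and nonsynonymous flag.
mutations_from_table <- function(tab, source = "mutations") {
  n <- nrow(tab)
  if (n > 0) {
    bad <- which(is.na(tab$pos) | tab$pos < 1 |
                   is.na(tab$depth) | tab$depth < 1 |
                   is.na(tab$alt_count) | tab$alt_count < 0)
    if (length(bad) > 0) {
      stop("malformed mutation row at line ", bad[1] + 1L, " of ", source)
    }
    over <- which(tab$alt_count > tab$depth)
    if (length(over) > 0) {
      stop("alt_count > depth at line ", over[1] + 1L, " of ", source)
    }
  }
  is_snv <- nchar(tab$ref) == 1 & nchar(tab$alt) == 1 &
    tab$ref != "-" & tab$alt != "-"
  cls <- tolower(ifelse(is.na(tab$variant_classification), "",
                        tab$variant_classification))
  # classification labels indels even when alleles look substitution-like
  is_snv <- is_snv & !grepl("ins$|del$|frame", cls)
  nonsyn <- grepl(NONSYN_PATTERN, cls)
  # VCF input carries no classification; count substitutions as candidate
  # nonsynonymous so the caller can filter with annotation of their own.
  nonsyn[is.na(tab$variant_classification)] <- TRUE
  data.frame(
    chrom = tab$chrom,
    pos = tab$pos,
    ref = tab$ref,
    alt = tab$alt,
    alt_count = as.integer(tab$alt_count),
    depth = as.integer(tab$depth),
    vaf = ifelse(tab$depth > 0, tab$alt_count / tab$depth, NA_real_),
    variant_class = ifelse(is_snv, "SNV", "INDEL"),
    variant_classification = tab$variant_classification,
    is_nonsynonymous = nonsyn,
    gene = tab$gene,
    stringsAsFactors = FALSE
  )
}

#' Write mutation calls to the MAF-like TSV dialect
#'
#' Inverse of [read_mutations()] for the \code{maf_tsv} format.
#'
#' @param muts Mutation data.frame.
#' @param path Output path.
#' @export
write_mutations <- function(muts, path) {
  out <- data.frame(
    chrom = muts$chrom,
    pos = format(muts$pos, scientific = FALSE, trim = TRUE),
    ref = muts$ref,
    alt = muts$alt,
    t_alt_count = muts$alt_count,
    t_depth = muts$depth,
    variant_classification = muts$variant_classification,
    gene = muts$gene,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
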
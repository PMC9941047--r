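# Independent brute-force oracles. These deliberately avoid the code
# paths they check: binomial interval endpoints by root-finding on tail
# sums, Fisher p and the conditional-MLE odds ratio by direct
# hypergeometric enumeration, Mann-Whitney by permutation enumeration,
# and the type-7 quantile by its textbook formula.

# Clopper-Pearson endpoints via uniroot on the binomial tail.
cp_oracle <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  low <- if (x == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  high <- if (x == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(x, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(low = low, high = high)
}

# Two-sided Fisher p by the probability-mass method over the
# hypergeometric support of a 2x2 table (rows r1 = a+b, r2 = c+d,
# first column k = a+c).
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  supp <- max(0, k - r2):min(k, r1)
  probs <- stats::dhyper(supp, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Conditional MLE of the odds ratio: maximize the noncentral
# hypergeometric log-likelihood over log(psi) by golden-section search
# (stats::optimize).
cmle_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  supp <- max(0, k - r2):min(k, r1)
  if (a == min(supp)) return(0)
  if (a == max(supp)) return(Inf)
  lc <- lchoose(r1, supp) + lchoose(r2, k - supp)
  loglik <- function(lpsi) {
    terms <- lc + supp * lpsi
    (lc[supp == a] + a * lpsi) - matrixStats_logsumexp(terms)
  }
  opt <- stats::optimize(loglik, c(-25, 25), maximum = TRUE,
                         tol = 1e-10)
  exp(opt$maximum)
}

matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Two-sided exact Mann-Whitney p by full enumeration of group
# assignments (no ties assumed).
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Type-7 empirical quantile: h = (n-1)q + 1 between order statistics.
quantile7_oracle <- function(values, q) {
  s <- sort(values)
  h <- (length(s) - 1) * q + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Small reusable builders ------------------------------------------------

make_segments <- function(chrom, start1, end1, major, minor) {
  segments_from_table_public(data.frame(
    chrom = chrom, start = start1, end = end1,
    major_cn = major, minor_cn = minor, stringsAsFactors = FALSE))
}

# access the internal normalizer through the file reader contract
segments_from_table_public <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(f))
  read_segments(f, dialect = "major_minor")
}

make_mutations <- function(chrom, pos, alt_count, depth,
                           classification = "Missense_Mutation") {
  n <- length(pos)
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(
    chrom = chrom, pos = pos, ref = "A", alt = "T",
    t_alt_count = alt_count, t_depth = depth,
    variant_classification = rep_len(classification, n)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(f))
  read_mutations(f, format = "maf_tsv")
}

# Arm table for a toy genome: two arms per chromosome, 100 Mb each.
toy_arms <- function(chroms = c("1", "2")) {
  f <- tempfile(fileext = ".tsv")
  rows <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, arm = c("p", "q"),
               start = c(1, 100e6 + 1), end = c(100e6, 200e6))
  }))
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(f))
  read_arms(path = f)
}

# Annotated baseline + progression pair embodying given per-stratum
# counts; used for the longitudinal arithmetic checks.
make_serial_counts <- function(counts) {
  # counts: data.frame(category, clonal, n_total, n_lost)
  rows <- list()
  pos <- 1
  for (i in seq_len(nrow(counts))) {
    n <- counts$n_total[i]
    lost <- counts$n_lost[i]
    rows[[i]] <- data.frame(
      chrom = "1", pos = pos:(pos + n - 1), ref = "A", alt = "T",
      alt_count = 10L, depth = 100L,
      category = counts$category[i], clonal = counts$clonal[i],
      qc_flags = "",
      prog_alt = c(rep(0L, lost), rep(8L, n - lost)),
      stringsAsFactors = FALSE)
    pos <- pos + n
  }
  base <- do.call(rbind, rows)
  progression <- data.frame(
    chrom = base$chrom, pos = base$pos, ref = base$ref, alt = base$alt,
    alt_count = base$prog_alt, depth = 100L, stringsAsFactors = FALSE)
  base$prog_alt <- NULL
  list(baseline = base, progression = progression)
}
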
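#' Construct a statistical test result
#'
#' Lightweight container used by the statistics layer.
#'
#' @param name statistic name
#' @param value statistic value
#' @param p_value p-value in \[0, 1\]
#' @param ... extra metadata stored alongside
#' @return object of class `stat_result`
#' @export
stat_result <- function(name, value, p_value, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(list(name = name, value = value, p_value = p_value, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.3g\n", x$name, x$value, x$p_value))
  extra <- setdiff(names(x), c("name", "value", "p_value"))
  for (e in extra)
    if (is.numeric(x[[e]]) && length(x[[e]]) == 1)
      cat(sprintf("  %s = %.4g\n", e, x[[e]]))
  invisible(x)
}

#' Conversion-tract length records
#'
#' Tract lengths are measured two ways: the minimal length is the distance
#' between the first and last LOH SNP of the tract, the maximal length the
#' distance between the heterozygous SNPs flanking it; the point estimate is
#' their mean.  Hybrid tracts have their 3:1 and 4:0 segments — and short
#' internal heterozygous patches — merged into a single tract before
#' measurement (the classifier performs the merge; here it is validated).
#'
#' @param events a `recomb_events` data.frame (rows without a conversion
#'   tract, i.e. `pattern` "none", are rejected)
#' @return data.frame of class `tract_lengths` with columns `chrom`,
#'   `min_len`, `max_len`, `estimate` (bp) and `crossover_associated`
#' @export
tract_lengths <- function(events) {
  if (any(events$pattern == "none"))
    stop("event without a conversion tract (pattern \"none\")")
  ev <- events[!is.na(events$tract_min), , drop = FALSE]
  out <- data.frame(chrom = ev$chrom,
                    min_len = ev$tract_min,
                    max_len = ev$tract_max,
                    estimate = (ev$tract_min + ev$tract_max) / 2,
                    crossover_associated =
                      ev$kind %in% c("CO", "CO_with_conversion"))
  stopifnot(all(out$min_len <= out$estimate & out$estimate <= out$max_len))
  class(out) <- c("tract_lengths", "data.frame")
  out
}

#' Median with a rank-based 95% confidence interval
#'
#' The confidence interval comes from the binomial distribution of order
#' statistics around the median: writing z for `qnorm((1+conf)/2)`, the
#' interval is bounded by the sample values at ranks `n/2 - z*sqrt(n)/2`
#' (rounded down) and `1 + n/2 + z*sqrt(n)/2` (rounded up) — the standard
#' construction tabulated for small n in biostatistics references.
#'
#' @param x numeric vector with at least 8 observations
#' @param conf confidence level (default 0.95)
#' @return list with `median`, `lo`, `hi`, `n`
#' @export
median_with_ci <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 observations for a median CI")
  r <- stats::qnorm((1 + conf) / 2)
  lo_rank <- max(1L, floor(n / 2 - r * sqrt(n) / 2))
  hi_rank <- min(n, ceiling(1 + n / 2 + r * sqrt(n) / 2))
  s <- sort(x)
  list(median = stats::median(x), lo = s[lo_rank], hi = s[hi_rank], n = n)
}

#' Compare two length distributions by the Mann-Whitney test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) U test.  Exact p-values are
#' used for small, tie-free samples; otherwise the normal approximation with
#' tie correction.
#'
#' @param a,b numeric vectors (both nonempty)
#' @return `stat_result` with the U statistic, p-value and sample sizes
#' @export
compare_distributions <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = !ties && length(a) + length(b) <= 50,
                       correct = FALSE))
  stat_result("mann_whitney_U", unname(wt$statistic), wt$p.value,
              n1 = length(a), n2 = length(b), two_sided = TRUE)
}

#' Bin event midpoints over an interval and test their distribution
#'
#' Midpoints of the maximal tract spans are binned into equal intervals and
#' compared against a reference set of counts (chi-square on the contingency
#' table, or Fisher's exact test when any expected count is small) or, with
#' no reference, against the uniform expectation.
#'
#' @param midpoints numeric positions (bp); events outside `bounds` are
#'   dropped with a warning
#' @param bounds interval break points (length >= 2, increasing)
#' @param reference optional reference counts per bin (same number of bins)
#' @return `stat_result` with `counts` (and `reference`) attached
#' @export
bin_midpoint_distribution <- function(midpoints, bounds, reference = NULL) {
  outside <- midpoints < min(bounds) | midpoints > max(bounds)
  if (any(outside)) {
    warning(sum(outside), " event(s) outside the binning bounds, excluded")
    midpoints <- midpoints[!outside]
  }
  counts <- as.integer(table(cut(midpoints, bounds, include.lowest = TRUE)))
  if (is.null(reference)) {
    ht <- suppressWarnings(stats::chisq.test(counts))
    stat_result("chisq_uniform", unname(ht$statistic), ht$p.value,
                counts = counts, df = unname(ht$parameter))
  } else {
    stopifnot(length(reference) == length(counts))
    tab <- rbind(counts, reference)
    exp_small <- any(suppressWarnings(stats::chisq.test(tab))$expected < 5)
    if (exp_small) {
      ht <- stats::fisher.test(tab, workspace = 2e6)
      stat_result("fisher_exact", NA_real_, ht$p.value, counts = counts,
                  reference = reference)
    } else {
      ht <- stats::chisq.test(tab)
      stat_result("chisq_vs_reference", unname(ht$statistic), ht$p.value,
                  counts = counts, reference = reference)
    }
  }
}

#' Correct observed event counts for crossover detection
#'
#' Only half of the crossovers occurring in the first division after
#' irradiation co-segregate so as to produce LOH; conversions and BIR events
#' are always detectable.  The corrected crossover count is therefore twice
#' the observed one, and of the observed crossover-unassociated conversions,
#' a number equal to the observed crossover count actually derives from the
#' undetected crossovers' tracts.
#'
#' @param n_co observed crossovers
#' @param n_bir observed BIR events
#' @param n_conv observed conversions unassociated with crossovers
#'   (must be >= `n_co`)
#' @return list with `co_corrected` (2 x n_co), `bir`, `conv_unassociated`
#'   (n_conv - n_co), `conv_co_associated` (2 x n_co), `association_fraction`
#'   (2 n_co / (n_conv + n_co)) and `co_bir_ratio`
#' @examples
#' detection_corrected_counts(60, 21, 300)
#' @export
detection_corrected_counts <- function(n_co, n_bir, n_conv) {
  if (any(c(n_co, n_bir, n_conv) < 0)) stop("counts must be >= 0")
  if (n_conv < n_co)
    stop("inconsistent input: fewer conversions than crossovers")
  list(co_corrected = 2 * n_co, bir = n_bir,
       conv_unassociated = n_conv - n_co,
       conv_co_associated = 2 * n_co,
       association_fraction = if (n_conv + n_co > 0)
         2 * n_co / (n_conv + n_co) else NA_real_,
       co_bir_ratio = if (n_bir > 0) 2 * n_co / n_bir else NA_real_)
}

#' Normalize treated event counts against an untreated control
#'
#' The expected number of spontaneous events among the treated colonies is
#' the untreated count scaled by the ratio of colonies examined
#' (`n_treated / n_untreated`); it is subtracted from the treated count.
#' Per-kb frequencies divide the normalized count by the number of treated
#' colonies and the interval length, after multiplying by the detection
#' factor (2 for crossovers, of which only half are detected; 1 otherwise).
#'
#' @param observed_treated,observed_untreated event counts
#' @param n_treated,n_untreated colonies examined in each arm
#' @param length_kb interval length in kb (optional, for per-kb frequency)
#' @param detection_factor 2 for crossovers, 1 for conversions/BIR
#' @return one-row data.frame of class `assay_count` with `normalized`
#'   (clamped at 0 with a warning if negative) and `per_kb`
#' @examples
#' normalized_induced(49, 1, 3902, 5197)
#' @export
normalized_induced <- function(observed_treated, observed_untreated,
                               n_treated, n_untreated,
                               length_kb = NA_real_, detection_factor = 1) {
  if (any(c(observed_treated, observed_untreated) < 0))
    stop("counts must be >= 0")
  if (n_untreated <= 0) stop("n_untreated must be > 0")
  norm <- observed_treated - observed_untreated * (n_treated / n_untreated)
  if (norm < 0) {
    warning("normalized count negative; clamped to 0")
    norm <- 0
  }
  per_kb <- if (is.na(length_kb)) NA_real_
    else norm / n_treated * detection_factor / length_kb
  structure(data.frame(observed_treated = observed_treated,
                       observed_untreated = observed_untreated,
                       n_treated = n_treated, n_untreated = n_untreated,
                       normalized = norm, length_kb = length_kb,
                       detection_factor = detection_factor,
                       per_kb = per_kb),
            class = c("assay_count", "data.frame"))
}

#' Test an observed event count in a genomic region against expectation
#'
#' Under a uniform distribution of events, the expected count in a region is
#' the total event count times the fraction of the (assayable) genome the
#' region occupies.  Both an exact binomial p-value and a chi-square
#' p-value (1 df, optionally continuity-corrected) are reported.
#'
#' @param n_events total number of events
#' @param observed events observed inside the region
#' @param fraction fraction of the genome occupied by the region, in (0, 1)
#' @param correct apply Yates continuity correction to the chi-square
#'   (default FALSE)
#' @return `stat_result` whose value is the expected count, with
#'   `p_binomial` and `p_chisq` attached (`p_value` is the binomial one)
#' @examples
#' region_expectation_test(60, observed = 0, fraction = 0.10)
#' @export
region_expectation_test <- function(n_events, observed, fraction,
                                    correct = FALSE) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  expected <- n_events * fraction
  if (n_events == 0)
    return(stat_result("region_expected", 0, 1,
                       p_binomial = 1, p_chisq = 1, observed = 0))
  p_bin <- min(1, stats::binom.test(observed, n_events, fraction)$p.value)
  e <- c(expected, n_events - expected)
  o <- c(observed, n_events - observed)
  adj <- if (correct) pmin(abs(o - e) - 0.5, abs(o - e)) else abs(o - e)
  x2 <- sum(adj^2 / e)
  p_chi <- stats::pchisq(x2, 1, lower.tail = FALSE)
  stat_result("region_expected", expected, p_bin,
              p_binomial = p_bin, p_chisq = p_chi, chisq = x2,
              observed = observed, n_total = n_events)
}

#' Correlate per-chromosome event counts with chromosome length
#'
#' Ordinary least-squares regression of event count on chromosome length.
#'
#' @param counts events per chromosome
#' @param lengths chromosome lengths (same order)
#' @return `stat_result` whose value is r-squared, with the slope p-value
#' @export
chromosome_size_correlation <- function(counts, lengths) {
  if (length(counts) != length(lengths) || length(counts) < 3)
    stop("need counts and lengths for at least 3 chromosomes")
  if (stats::var(lengths) == 0) stop("chromosome lengths have zero variance")
  fit <- stats::lm(counts ~ lengths)
  s <- summary(fit)
  stat_result("r_squared", s$r.squared, s$coefficients["lengths", 4],
              slope = unname(stats::coef(fit)["lengths"]),
              n_chromosomes = length(counts))
}

#' Element enrichment within conversion tracts by permutation
#'
#' For each annotation class, counts the tracts overlapping at least one
#' element, then builds a null distribution by placing tracts of the same
#' lengths uniformly at random on the SNP-covered portion of the genome
#' (array-invisible SNP-free regions are excluded, since observed tracts can
#' only be seen where there are markers).  Two-sided empirical p-values use
#' the add-one correction; Benjamini-Hochberg adjustment is applied across
#' classes.
#'
#' @param tracts data.frame with `chrom`, `start`, `end` (1-based inclusive)
#' @param annotations an [annotation_set()]
#' @param map a [snp_map()] (defines the SNP-covered spans)
#' @param n_perm number of permutations (>= 1000)
#' @param classes annotation classes to test (default: all present)
#' @return data.frame with one row per class: `class`, `observed`,
#'   `null_mean`, `p`, `adjusted_p`, `direction`
#' @export
element_enrichment <- function(tracts, annotations, map, n_perm = 1000,
                               classes = NULL) {
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  ann <- annotations$intervals
  if (is.null(classes)) classes <- unique(ann$class)
  keep <- vapply(classes, function(cl) {
    ok <- any(ann$class == cl)
    if (!ok) warning("annotation class '", cl, "' is empty; skipped")
    ok
  }, TRUE)
  classes <- classes[keep]
  # fix the seqlevels to the full chromosome set so disjoint chromosome
  # usage between tracts and elements does not trip seqinfo merging
  lv <- map$chromosomes$name
  ann_gr <- lapply(classes, function(cl) {
    d <- ann[ann$class == cl, ]
    GenomicRanges::GRanges(factor(d$chrom, levels = lv),
                           IRanges::IRanges(d$start, d$end))
  })
  names(ann_gr) <- classes

  count_hits <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(factor(chrom, levels = lv),
                                 IRanges::IRanges(start, end))
    vapply(ann_gr, function(agr)
      sum(IRanges::overlapsAny(gr, agr)), 0L)
  }
  observed <- count_hits(tracts$chrom, tracts$start, tracts$end)

  # SNP-covered spans: first to last SNP per chromosome
  spans <- do.call(rbind, lapply(split(map$snps, map$snps$chrom), function(s)
    data.frame(chrom = s$chrom[1], lo = min(s$pos), hi = max(s$pos))))
  spans$len <- spans$hi - spans$lo
  lens <- tracts$end - tracts$start
  n_tr <- length(lens)
  null <- matrix(0L, n_perm, length(classes))
  for (p in seq_len(n_perm)) {
    ci <- sample.int(nrow(spans), n_tr, replace = TRUE,
                     prob = spans$len / sum(spans$len))
    st <- floor(stats::runif(n_tr, spans$lo[ci],
                             pmax(spans$lo[ci] + 1, spans$hi[ci] - lens)))
    null[p, ] <- count_hits(spans$chrom[ci], st, st + lens)
  }
  p_emp <- vapply(seq_along(classes), function(k) {
    lo <- (sum(null[, k] <= observed[k]) + 1) / (n_perm + 1)
    hi <- (sum(null[, k] >= observed[k]) + 1) / (n_perm + 1)
    min(1, 2 * min(lo, hi))
  }, 0)
  nm <- colMeans(null)
  data.frame(class = classes, observed = unname(observed),
             null_mean = unname(nm), p = p_emp,
             adjusted_p = stats::p.adjust(p_emp, "BH"),
             direction = ifelse(observed > nm, "over",
                                ifelse(observed < nm, "under", "none")),
             row.names = NULL)
}

#' AA/TT dinucleotide frequency of a sequence
#'
#' Counts overlapping dinucleotides; AA and TT are pooled because they are
#' the same motif on opposite strands (the predominant substrate of
#' UV-induced pyrimidine dimer formation).
#'
#' @param x character vector of sequences or a `Biostrings::DNAStringSet`
#' @param max_other maximum tolerated fraction of non-ACGT characters
#' @return frequency (AA + TT) / total dinucleotides
#' @examples
#' dinucleotide_freq("AAAA")  # 1
#' dinucleotide_freq("ACGT")  # 0
#' @export
dinucleotide_freq <- function(x, max_other = 0.01) {
  counts <- .dinuc_counts(x, max_other)
  unname((counts[["AA"]] + counts[["TT"]]) / sum(counts))
}

.dinuc_counts <- function(x, max_other = 0.01) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  freq <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  other <- sum(freq[, "other"]) / max(1, sum(freq))
  if (other > max_other)
    stop("sequence contains too many non-ACGT characters")
  counts <- Biostrings::dinucleotideFrequency(x, step = 1)
  if (is.matrix(counts)) counts <- colSums(counts)
  counts
}

#' Compare AA/TT dinucleotide content of two regions
#'
#' Fisher's exact test on the 2x2 table of AA/TT versus other dinucleotide
#' counts in the two sequence sets.
#'
#' @param x,y sequences (see [dinucleotide_freq()])
#' @return `stat_result` whose value is the frequency difference (x - y)
#' @export
dinucleotide_compare <- function(x, y) {
  cx <- .dinuc_counts(x); cy <- .dinuc_counts(y)
  aatt <- c(cx[["AA"]] + cx[["TT"]], cy[["AA"]] + cy[["TT"]])
  tot <- c(sum(cx), sum(cy))
  ht <- stats::fisher.test(rbind(aatt, tot - aatt))
  stat_result("aatt_freq_difference", aatt[1] / tot[1] - aatt[2] / tot[2],
              ht$p.value, freq_x = aatt[1] / tot[1],
              freq_y = aatt[2] / tot[2])
}

#' Fold stimulation of sectoring over the spontaneous rate
#'
#' @param sector_frequency observed sectored-colony frequency per division
#' @param spontaneous_rate spontaneous rate per division
#' @return fold stimulation
#' @examples
#' fold_stimulation(9.4e-3, 1.1e-6)
#' @export
fold_stimulation <- function(sector_frequency, spontaneous_rate) {
  if (spontaneous_rate <= 0) stop("spontaneous_rate must be > 0")
  sector_frequency / spontaneous_rate
}
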
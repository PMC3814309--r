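test_that("tract length records average the minimal and maximal spans", {
  ev <- data.frame(chrom = "chr1", kind = "NCO_conversion", pattern = "3:1",
                   tract_min = 6000, tract_max = 10000)
  tl <- tract_lengths(ev)
  expect_equal(tl$estimate, 8000)
  expect_true(tl$min_len <= tl$estimate && tl$estimate <= tl$max_len)
  expect_false(tl$crossover_associated)
  ev$kind <- "CO_with_conversion"
  expect_true(tract_lengths(ev)$crossover_associated)
  ev$pattern <- "none"
  expect_error(tract_lengths(ev), "without a conversion tract")
})

test_that("hybrid segments and internal het gaps merge into one tract", {
  # 2 kb hom-both + 0.5 kb het gap + 3 kb hom-one-sector, on a 0.5 kb grid
  pos <- seq(10000, by = 500, length.out = 60)
  st_a <- rep("HET", 60); st_b <- rep("HET", 60)
  st_a[20:24] <- "HOM_P1"   # 2 kb, shared (4:0)
  st_b[20:24] <- "HOM_P1"
  st_a[26:32] <- "HOM_P1"   # 3 kb after a 0.5 kb het gap (3:1)
  a <- sector_call_from_states(states_track("chr1", pos, st_a))
  b <- sector_call_from_states(states_track("chr1", pos, st_b))
  ev <- classify_events(a, b)
  expect_equal(nrow(ev), 1)       # single merged tract
  expect_equal(ev$pattern, "hybrid_3:1/4:0")
  tl <- tract_lengths(ev)
  # minimal span covers both segments and the gap
  expect_equal(tl$min_len, pos[32] - pos[20])
})

test_that("median confidence intervals follow the rank construction", {
  m <- median_with_ci(1:9 * 1000)
  expect_equal(m$median, 5000)
  expect_lte(m$lo, m$median); expect_gte(m$hi, m$median)
  expect_error(median_with_ci(1:7), "at least 8")
  set.seed(41)
  for (i in 1:20) {
    x <- rlnorm(sample(8:200, 1))
    ci <- median_with_ci(x)
    expect_lte(ci$lo, ci$median); expect_gte(ci$hi, ci$median)
  }
  # parameter recovery on the simulator's tract family
  set.seed(42)
  draws <- rgamma_med(2000, median = 5.6)
  ci <- median_with_ci(draws)
  expect_equal(ci$median, 5.6, tolerance = 0.3 / 5.6)
  expect_lt(ci$lo, 5.6); expect_gt(ci$hi, 5.6)
})

test_that("Mann-Whitney agrees with exact enumeration for small samples", {
  r <- compare_distributions(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$value, 0)                 # U = 0
  expect_equal(r$p_value, mw_enum_p(c(1, 2, 3), c(10, 20, 30)))
  set.seed(43)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:(12 - n1), 1)
    x <- sample(1000, n1); y <- sample(2000:3000, n2)
    y <- y[!y %in% x]
    r <- compare_distributions(x, y)
    expect_equal(r$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
  # identical samples: no evidence of a shift
  expect_equal(compare_distributions(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  expect_error(compare_distributions(numeric(), 1:3), "nonempty")
})

test_that("distinct tract-length distributions are separated decisively", {
  set.seed(44)
  a <- rgamma_med(1000, 4.9)
  b <- rgamma_med(1000, 7.6)
  expect_lt(compare_distributions(a, b)$p_value, 1e-5)
})

test_that("midpoint binning tests behave at both extremes", {
  bounds <- c(33, 63, 93, 123, 153) * 1000
  set.seed(45)
  p_unif <- replicate(20, {
    mids <- runif(40, 33000, 153000)
    bin_midpoint_distribution(mids, bounds)$p_value
  })
  expect_gte(mean(p_unif > 0.05), 0.8)   # type-I behaviour
  expect_lt(bin_midpoint_distribution(rep(50000, 40), bounds)$p_value, 0.001)
  expect_warning(bin_midpoint_distribution(c(50000, 999999), bounds),
                 "outside")
  # a reference set shifts the comparison to a contingency test
  r <- bin_midpoint_distribution(runif(40, 33000, 153000), bounds,
                                 reference = c(10, 10, 10, 10))
  expect_true(r$name %in% c("chisq_vs_reference", "fisher_exact"))
})

test_that("detection correction doubles crossovers and reassigns conversions", {
  d <- detection_corrected_counts(60, 21, 300)
  expect_equal(d$co_corrected, 120)
  expect_equal(d$conv_unassociated, 240)
  expect_equal(d$conv_co_associated, 120)
  expect_equal(d$association_fraction, 1 / 3)
  expect_equal(d$co_bir_ratio, 120 / 21)
  d0 <- detection_corrected_counts(0, 5, 10)
  expect_equal(d0$co_corrected, 0)
  expect_equal(d0$conv_unassociated, 10)
  expect_error(detection_corrected_counts(10, 5, 5), "inconsistent")
})

test_that("control normalization follows the colony-ratio rule", {
  a <- normalized_induced(49, 1, 3902, 5197)
  expect_equal(a$normalized, 49 - 3902 / 5197, tolerance = 1e-12)
  expect_equal(round(a$normalized), 48)
  # linear in the treated count; identity when the control is clean
  a2 <- normalized_induced(59, 1, 3902, 5197)
  expect_equal(a2$normalized - a$normalized, 10)
  expect_equal(normalized_induced(7, 0, 3902, 5197)$normalized, 7)
  expect_warning(n <- normalized_induced(0, 10, 3902, 5197)$normalized,
                 "clamped")
  expect_equal(n, 0)
})

test_that("regional expectation tests are calibrated and additive", {
  r <- region_expectation_test(60, observed = 0, fraction = 0.10)
  expect_equal(r$value, 6)
  expect_lt(r$p_chisq, 0.05)
  r0 <- region_expectation_test(0, observed = 0, fraction = 0.10)
  expect_equal(r0$value, 0); expect_equal(r0$p_value, 1)
  # expected counts sum to n over a partition of the genome
  fr <- c(0.2, 0.3, 0.5)
  ex <- vapply(fr, function(f)
    region_expectation_test(50, observed = 10, fraction = f)$value, 0)
  expect_equal(sum(ex), 50)
  expect_error(region_expectation_test(10, 1, fraction = 1.5), "fraction")
})

test_that("event counts track chromosome size when placement is uniform", {
  len <- c(230, 800, 320, 1100, 577, 270, 1090, 560,
           440, 745, 665, 2230, 920, 780, 1090, 950) * 1000
  r <- suppressWarnings(chromosome_size_correlation(len / 1000, len))
  expect_equal(r$value, 1)       # exactly proportional counts
  set.seed(46)
  r2_unif <- replicate(20, {
    counts <- table(factor(sample(seq_along(len), 381, TRUE,
                                  prob = len / sum(len)), levels = seq_along(len)))
    chromosome_size_correlation(as.numeric(counts), len)$value
  })
  expect_gte(mean(r2_unif > 0.7), 0.9)
  # permuted counts decorrelate
  counts <- as.numeric(table(factor(sample(seq_along(len), 381, TRUE,
                                           prob = len / sum(len)),
                                    levels = seq_along(len))))
  r2_perm <- replicate(50, chromosome_size_correlation(sample(counts), len)$value)
  expect_lt(mean(r2_perm), 0.2)
  expect_error(chromosome_size_correlation(1:3, c(5, 5, 5)), "variance")
})

test_that("permutation enrichment detects construction and respects BH", {
  g <- tiny_genome()
  # class covering the whole genome: every tract and every permutation hits
  all_ann <- annotation_set(data.frame(chrom = c("chr1", "chr2"),
                                       start = 1,
                                       end = c(200000, 150000),
                                       class = "everything"), g$map)
  tracts <- data.frame(chrom = "chr1", start = c(2, 5, 9) * 10000,
                       end = c(2, 5, 9) * 10000 + 4000)
  set.seed(47)
  r_all <- element_enrichment(tracts, all_ann, g$map, n_perm = 1000)
  expect_equal(r_all$observed, 3)
  expect_equal(r_all$p, 1)

  # tracts deliberately placed off a chr2-only class: under-representation
  sparse <- annotation_set(data.frame(chrom = "chr2",
                                      start = seq(10001, 130001, by = 10000),
                                      end = seq(14000, 134000, by = 10000),
                                      class = "sparse"), g$map)
  tr2 <- data.frame(chrom = "chr1", start = seq(20000, 180000, by = 10000),
                    end = seq(24000, 184000, by = 10000))
  set.seed(48)
  r_sp <- element_enrichment(tr2, sparse, g$map, n_perm = 2000)
  expect_equal(r_sp$observed, 0)
  expect_equal(r_sp$direction, "under")
  expect_lt(r_sp$p, 0.01)
  expect_gte(r_sp$adjusted_p, r_sp$p)

  expect_warning(element_enrichment(tr2, sparse, g$map, n_perm = 1000,
                                    classes = c("sparse", "absent")),
                 "empty")
  expect_error(element_enrichment(tr2, sparse, g$map, n_perm = 10), "n_perm")
})

test_that("dinucleotide frequencies follow closed forms", {
  expect_equal(dinucleotide_freq("AAAA"), 1)
  expect_equal(dinucleotide_freq("ACGT"), 0)
  expect_equal(dinucleotide_freq("AATT"), 2 / 3)
  set.seed(49)
  seqs <- paste(sample(c("A", "C", "G", "T"), 2e5, TRUE,
                       prob = c(0.31, 0.19, 0.19, 0.31)), collapse = "")
  # under independence: f(AA) + f(TT) = 2 p^2
  expect_equal(dinucleotide_freq(seqs), 2 * 0.31^2, tolerance = 0.02)
  expect_error(dinucleotide_freq("ANNNNA"), "non-ACGT")
  # an AT-depleted region is detected against the background
  set.seed(50)
  poor <- paste(sample(c("A", "C", "G", "T"), 2e5, TRUE,
                       prob = c(0.27, 0.23, 0.23, 0.27)), collapse = "")
  cmp <- dinucleotide_compare(seqs, poor)
  expect_gt(cmp$value, 0)
  expect_lt(cmp$p_value, 1e-4)
})

test_that("fold stimulation is a plain rate ratio", {
  expect_equal(fold_stimulation(9.4e-3, 1.1e-6), 9.4e-3 / 1.1e-6)
  expect_error(fold_stimulation(1e-3, 0), "spontaneous_rate")
})
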
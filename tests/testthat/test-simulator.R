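test_that("dimer placement is Poisson in dose and uniform over the genome", {
  g <- tiny_genome()
  expect_equal(nrow(place_dimers(sim_config(dose = 0), g$map)), 0)
  set.seed(1)
  n1 <- replicate(40, nrow(place_dimers(sim_config(dose = 1), g$map)))
  n15 <- replicate(40, nrow(place_dimers(sim_config(dose = 15), g$map)))
  # dimers_per_jm2 = 500 scaled by dose
  expect_equal(mean(n1), 500, tolerance = 0.05)
  expect_equal(mean(n1) / mean(n15), 1 / 15, tolerance = 0.1)
  les <- place_dimers(sim_config(dose = 15), g$map)
  expect_true(all(les$pos >= 1))
  len <- g$map$chromosomes$length[match(les$chrom, g$map$chromosomes$name)]
  expect_true(all(les$pos <= len))
  # both homologs and strands used
  expect_setequal(unique(les$homolog), 1:2)
  expect_setequal(unique(les$strand), 1:2)
})

test_that("closely-opposed pairs become DSCBs only within the separation cap", {
  cfg <- sim_config(dscb_from_opposed = 1, scb_rate_per_dimer = 0)
  close_pair <- structure(
    data.frame(chrom = "chr1", pos = c(1000, 1040), homolog = 1L,
               strand = c(1L, 2L)), class = c("lesion_set", "data.frame"))
  b <- derive_breaks(close_pair, cfg)
  expect_equal(nrow(b), 1)
  expect_equal(b$kind, "DSCB")
  expect_equal(b$pos, 1020)
  far_pair <- close_pair; far_pair$pos <- c(1000, 1200)
  expect_equal(nrow(derive_breaks(far_pair, cfg)), 0)
  # same strand never pairs
  same <- close_pair; same$strand <- c(1L, 1L)
  expect_equal(nrow(derive_breaks(same, cfg)), 0)
  # different homologs never pair
  other <- close_pair; other$homolog <- c(1L, 2L)
  expect_equal(nrow(derive_breaks(other, cfg)), 0)
})

test_that("SCB counts scale linearly and the DSCB share rises with dose", {
  g <- tiny_genome()
  set.seed(7)
  cfg1 <- sim_config(dose = 1); cfg15 <- sim_config(dose = 15)
  frac <- function(cfg, n_cells) {
    k <- do.call(rbind, lapply(seq_len(n_cells), function(i)
      derive_breaks(place_dimers(cfg, g$map), cfg)))
    c(dscb = sum(k$kind == "DSCB"), tot = nrow(k))
  }
  higher <- replicate(20, {
    f1 <- frac(cfg1, 60); f15 <- frac(cfg15, 8)
    (f15["dscb"] / f15["tot"]) > (f1["dscb"] / max(1, f1["tot"]))
  })
  expect_gte(sum(higher), 18)
})

test_that("closely-opposed expectation matches enumeration and Monte Carlo", {
  expect_equal(expected_closely_opposed(0, 1e5, 75), 0)
  expect_equal(expected_closely_opposed(1, 1e5, 75), 0)
  # two dimers on 100 bp, window 100 bp: any opposite-strand pair qualifies
  expect_equal(expected_closely_opposed(2, 100, 100), 0.5)
  expect_error(expected_closely_opposed(10, 0, 75), "genome_len")
  set.seed(3)
  exp_val <- expected_closely_opposed(300, 1e5, 500)
  mc <- mc_closely_opposed(300, 1e5, 500, reps = 150)
  expect_lt(abs(exp_val - mc$mean), 3 * mc$se)
})

test_that("repair outcomes reproduce the canonical sector patterns", {
  g <- tiny_genome()
  brk <- list(chrom = "chr2", pos = 100000, homolog = 1L, kind = "SCB")

  # SCB + SDSA: interstitial 3:1 in one daughter, the other fully het
  set.seed(5)
  st <- new_chromatid_set(g$map, g$marker)
  res <- repair_break(st, brk, det_config("sdsa"))
  expect_equal(res$event$kind, "NCO_conversion")
  expect_equal(res$event$mechanism, "SCB")
  col <- segregate(res$state, list(res$event))
  expect_equal(col$events$pattern, "3:1")
  tr_a <- col$daughters$a; tr_b <- col$daughters$b
  loh_a <- sum(tr_a$state != "HET"); loh_b <- sum(tr_b$state != "HET")
  expect_true(xor(loh_a > 0, loh_b > 0))
  loh <- if (loh_a > 0) tr_a else tr_b
  idx <- which(loh$state != "HET")
  expect_true(all(diff(idx) == 1))        # contiguous interstitial run
  expect_gt(min(loh$pos[idx]), 10000)     # does not reach either end
  expect_lt(max(loh$pos[idx]), 140000)

  # DSCB with equal tracts: identical interstitial LOH in both daughters
  set.seed(6)
  st <- new_chromatid_set(g$map, g$marker)
  res <- repair_break(st, modifyList(brk, list(kind = "DSCB")),
                      det_config("sdsa", dscb_equal = 1))
  expect_equal(res$event$mechanism, "DSCB")
  col <- segregate(res$state, list(res$event))
  expect_equal(col$events$pattern, "4:0")
  a_idx <- which(col$daughters$a$state != "HET")
  b_idx <- which(col$daughters$b$state != "HET")
  expect_identical(a_idx, b_idx)
  expect_identical(col$daughters$a$state[a_idx], col$daughters$b$state[b_idx])

  # BIR: terminal LOH in exactly one daughter, from the break to the telomere
  set.seed(8)
  st <- new_chromatid_set(g$map, g$marker)
  res <- repair_break(st, brk, det_config("bir"))
  expect_equal(res$event$kind, "BIR")
  col <- segregate(res$state, list(res$event))
  tr_a <- col$daughters$a; tr_b <- col$daughters$b
  loh <- if (any(tr_a$state != "HET")) tr_a else tr_b
  other <- if (any(tr_a$state != "HET")) tr_b else tr_a
  expect_true(all(other$state == "HET"))
  idx <- which(loh$state != "HET")
  # chr2 break at 100 kb is distal to the 60 kb centromere: runs to the end
  expect_equal(max(loh$pos[idx]), max(loh$pos[loh$chrom == "chr2"]))
  expect_gte(min(loh$pos[idx]), 100000)

  # break outside the chromosome errors
  expect_error(repair_break(st, list(chrom = "chr2", pos = 2e6,
                                     homolog = 1L, kind = "SCB"),
                            det_config("sdsa")),
               "outside")
})

test_that("allele copies are conserved and labels match literal counts", {
  g <- tiny_genome()
  set.seed(9)
  st <- new_chromatid_set(g$map, g$marker)
  res <- repair_break(st, list(chrom = "chr1", pos = 120000, homolog = 1L,
                               kind = "SCB"), det_config("sdsa"))
  al <- res$state$chrom$chr1$alleles
  expect_true(all(rowSums(al == 1) + rowSums(al == 2) == 4))
  conv <- res$state$chrom$chr1$pos %in% res$event$conv1
  expect_true(all(rowSums(al[conv, , drop = FALSE] == 2) == 3))  # 3:1
  expect_true(all(rowSums(al[!conv, , drop = FALSE] == 2) == 2)) # still het

  st <- new_chromatid_set(g$map, g$marker)
  res <- repair_break(st, list(chrom = "chr1", pos = 120000, homolog = 2L,
                               kind = "DSCB"), det_config("sdsa", dscb_equal = 1))
  al <- res$state$chrom$chr1$alleles
  conv <- res$state$chrom$chr1$pos %in% res$event$conv1
  expect_gt(sum(conv), 0)
  expect_true(all(rowSums(al[conv, , drop = FALSE] == 1) == 4))  # 4:0
})

test_that("without patchy repair or restoration, tracts are contiguous runs", {
  g <- tiny_genome()
  set.seed(11)
  for (i in 1:20) {
    st <- new_chromatid_set(g$map, g$marker)
    res <- repair_break(st, list(chrom = "chr2",
                                 pos = sample(30000:120000, 1),
                                 homolog = sample(1:2, 1), kind = "SCB"),
                        det_config("sdsa"))
    cv <- res$event$conv1
    if (length(cv) < 2) next
    span_snps <- g$map$snps$pos[g$map$snps$chrom == "chr2" &
                                  g$map$snps$pos >= min(cv) &
                                  g$map$snps$pos <= max(cv)]
    expect_identical(sort(cv), span_snps)
  }
})

test_that("the recipient is always the broken homolog", {
  g <- tiny_genome()
  set.seed(12)
  for (h in 1:2) {
    st <- new_chromatid_set(g$map, g$marker)
    res <- repair_break(st, list(chrom = "chr2", pos = 80000, homolog = h,
                                 kind = "SCB"), det_config("sdsa"))
    expect_equal(res$event$recipient, c("P1", "P2")[h])
    # the converted alleles are the donor's
    al <- res$state$chrom$chr2$alleles
    conv <- res$state$chrom$chr2$pos %in% res$event$conv1
    donor_allele <- if (h == 1) 2L else 1L
    cols <- if (h == 1) 1:2 else 3:4
    expect_true(any(al[conv, cols] == donor_allele))
  }
})

test_that("a single crossover sectors the colony in half of segregations", {
  g <- tiny_genome()
  set.seed(13)
  st <- new_chromatid_set(g$map, g$marker)
  res <- repair_break(st, list(chrom = "chr1", pos = 40000, homolog = 1L,
                               kind = "SCB"),
                      det_config("dsbr_co", tract_kb = 2))
  expect_true(res$event$crossover)
  sect <- replicate(2000, segregate(res$state, list(res$event))$selected_sectored)
  expect_equal(mean(sect), 0.5, tolerance = 0.04)
})

test_that("colony colour reports marker copy number", {
  g <- tiny_genome()
  set.seed(14)
  st <- new_chromatid_set(g$map, g$marker)
  col <- segregate(st)                       # no events
  expect_equal(unname(col$colors), c("pink", "pink"))
  expect_false(col$sectored)
  expect_equal(col$color_pattern, "pink/pink")
  # losing the marker-carrying homolog in one daughter: red/pink
  col <- segregate(st, lose = list(chrom = "chr1", daughter = 1, homolog = 1))
  expect_setequal(unname(col$colors), c("red", "pink"))
  expect_true(col$sectored)
  expect_false(col$selected_sectored)
})

test_that("array simulation encodes zygosity with truncated Gaussian noise", {
  track <- states_track("chr1", c(1000, 2000, 3000),
                        c("HET", "HOM_P1", "HOM_P2"))
  r0 <- simulate_array(track, noise_sd = 0)
  expect_equal(r0$ratio_P1, c(1.0, 1.8, 0.2))
  expect_equal(r0$ratio_P2, c(1.0, 0.2, 1.8))
  set.seed(15); r1 <- simulate_array(track, noise_sd = 0.1)
  set.seed(15); r2 <- simulate_array(track, noise_sd = 0.1)
  expect_identical(r1, r2)
  set.seed(16)
  big <- simulate_array(states_track("chr1", 1:500 * 100,
                                     rep("HOM_P1", 500)), noise_sd = 2)
  expect_true(all(big$ratio_P1 >= 0 & big$ratio_P2 >= 0))
  expect_error(simulate_array(track, noise_sd = -1), "noise_sd")
})

test_that("experiments are reproducible and dose 0 yields no events", {
  g <- tiny_genome()
  cfg <- sim_config(dose = 15)
  e1 <- simulate_experiment(cfg, g, n_cells = 10, seed = 99)
  e2 <- simulate_experiment(cfg, g, n_cells = 10, seed = 99)
  expect_identical(lapply(e1$colonies, `[[`, "events"),
                   lapply(e2$colonies, `[[`, "events"))
  expect_identical(e1$sector_frequency, e2$sector_frequency)
  e0 <- simulate_experiment(sim_config(dose = 0), g, n_cells = 20, seed = 1)
  expect_equal(sum(vapply(e0$colonies, function(c) nrow(c$events), 0L)), 0)
  expect_equal(e0$n_sectored, 0)
})

test_that("second-division persistence generates tri-sector colonies", {
  g <- tiny_genome()
  cfg <- det_config("sdsa", dose = 15, second_division_prob = 1)
  set.seed(17)
  col <- simulate_colony(cfg, g)
  expect_true(!is.null(col$daughters$a2))
  expect_true(isTRUE(col$tri_sector))
  # off by default
  expect_null(simulate_colony(det_config("sdsa", dose = 15), g, seed = 1)$daughters$a2)
})
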
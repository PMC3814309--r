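#' Simulation configuration
#'
#' Parameters of the forward simulator of UV-induced recombinogenic lesions
#' and their repair.  Defaults are calibrated to the study conditions of a
#' G1-synchronized diploid irradiated at 15 J/m2: about 500 pyrimidine dimers
#' per diploid genome per J/m2 (~7500 at 15 J/m2), closely-opposed dimers
#' (opposite strands, <= 75 bp apart) as the source of double-sister-chromatid
#' breaks (DSCBs), isolated lesions as the source of single-chromatid breaks
#' (SCBs), and a pathway mix of synthesis-dependent strand annealing (SDSA),
#' double-Holliday-junction repair with or without crossover, and
#' break-induced replication (BIR) that reproduces the observed
#' conversion : crossover : BIR event ratio after allowing for the fact that
#' only half of crossovers are detectable as loss of heterozygosity.
#'
#' @param dose UV dose in J/m2.
#' @param dimers_per_jm2 expected pyrimidine dimers per diploid genome per
#'   J/m2.
#' @param closely_opposed_max_sep maximum separation (bp) for two
#'   opposite-strand dimers to count as closely opposed.
#' @param clustered_dimer_excess fraction of dimers placed deliberately close
#'   to an existing dimer on the opposite strand (dose-independent clustering
#'   of near-opposed pairs); 0 disables clustering.
#' @param scb_rate_per_dimer probability that an isolated dimer gives rise to
#'   a single-chromatid break.
#' @param dscb_from_opposed probability that a closely-opposed pair gives rise
#'   to a G1 double-strand break (hence a DSCB after replication).
#' @param interhomolog_prob fraction of S/G2 single-chromatid breaks repaired
#'   off the homolog rather than (invisibly) off the sister chromatid; SCBs
#'   destined for sister repair are simply not emitted.  G1-origin DSCBs have
#'   no intact sister and always use the homolog.
#' @param pathway_probs named probabilities for `sdsa`, `dsbr_co`, `dsbr_nco`
#'   and `bir`; must sum to 1.
#' @param tract_median_kb median (kb) of the underlying tract-length
#'   distribution for conversions not associated with a crossover.  Observed
#'   tract-length medians measured from classified events run about 1 kb
#'   higher, because tracts covering fewer than two SNPs are undetectable at
#'   ~1 kb marker spacing; the defaults (3.9 / 7.15 kb) are calibrated so the
#'   observed medians land at about 4.9 / 7.6 kb.
#' @param tract_median_co_kb median (kb) of the underlying tract-length
#'   distribution for crossover-associated conversions.
#' @param tract_shape gamma shape parameter of the tract-length distribution
#'   (the scale is set so the median equals the requested median exactly).
#' @param patchy_repair_prob probability that heteroduplex repair in a tract
#'   is patchy (each SNP independently repaired toward donor or recipient).
#' @param restoration_prob probability that a (non-patchy) tract is repaired
#'   toward the recipient (restoration-type, producing no LOH).
#' @param dscb_equal_tract_prob probability that the two broken sisters of a
#'   DSCB are resected and repaired with identical tract bounds (a pure 4:0
#'   tract); otherwise each sister draws its own tract (3:1/4:0 hybrids).
#' @param noise_sd standard deviation of Gaussian noise added to simulated
#'   hybridization ratios.
#' @param r_hi,r_lo hybridization ratios of a homozygous SNP for the retained
#'   and the lost allele (a heterozygous SNP reads ~1 in both channels).
#' @param second_division_prob probability that residual damage persists into
#'   the second division, producing a tri-sector colony; 0 (default) confines
#'   all events to the first division.
#' @param seed optional default seed carried in the config.
#' @return object of class `sim_config`
#' @examples
#' cfg <- sim_config(dose = 15)
#' cfg
#' @export
sim_config <- function(dose = 15,
                       dimers_per_jm2 = 500,
                       closely_opposed_max_sep = 75,
                       clustered_dimer_excess = 0,
                       scb_rate_per_dimer = 0.00255,
                       dscb_from_opposed = 0.048,
                       interhomolog_prob = 0.21,
                       pathway_probs = c(sdsa = 0.37, dsbr_co = 0.315,
                                         dsbr_nco = 0.26, bir = 0.055),
                       tract_median_kb = 3.9,
                       tract_median_co_kb = 7.15,
                       tract_shape = 2,
                       patchy_repair_prob = 0.05,
                       restoration_prob = 0.02,
                       dscb_equal_tract_prob = 0.4,
                       noise_sd = 0.1,
                       r_hi = 1.8, r_lo = 0.2,
                       second_division_prob = 0,
                       seed = NULL) {
  cfg <- list(dose = dose, dimers_per_jm2 = dimers_per_jm2,
              closely_opposed_max_sep = closely_opposed_max_sep,
              clustered_dimer_excess = clustered_dimer_excess,
              scb_rate_per_dimer = scb_rate_per_dimer,
              dscb_from_opposed = dscb_from_opposed,
              interhomolog_prob = interhomolog_prob,
              pathway_probs = pathway_probs,
              tract_median_kb = tract_median_kb,
              tract_median_co_kb = tract_median_co_kb,
              tract_shape = tract_shape,
              patchy_repair_prob = patchy_repair_prob,
              restoration_prob = restoration_prob,
              dscb_equal_tract_prob = dscb_equal_tract_prob,
              noise_sd = noise_sd, r_hi = r_hi, r_lo = r_lo,
              second_division_prob = second_division_prob,
              seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$dose < 0) stop("dose must be >= 0")
  probs <- c(cfg$scb_rate_per_dimer, cfg$dscb_from_opposed,
             cfg$interhomolog_prob, cfg$patchy_repair_prob,
             cfg$restoration_prob, cfg$dscb_equal_tract_prob,
             cfg$clustered_dimer_excess, cfg$second_division_prob,
             cfg$pathway_probs)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  need <- c("sdsa", "dsbr_co", "dsbr_nco", "bir")
  if (!all(need %in% names(cfg$pathway_probs)))
    stop("pathway_probs needs entries: ", paste(need, collapse = ", "))
  if (abs(sum(cfg$pathway_probs) - 1) > 1e-8)
    stop("pathway probabilities must sum to 1")
  if (cfg$tract_median_kb <= 0 || cfg$tract_median_co_kb <= 0 ||
      cfg$tract_shape <= 0)
    stop("tract length parameters must be > 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: dose %g J/m2 (~%g dimers/diploid genome)\n",
              x$dose, x$dose * x$dimers_per_jm2))
  cat(sprintf("  SCB rate/dimer %.4g x interhomolog %.3g; DSCB from opposed pair %.3g (<=%d bp)\n",
              x$scb_rate_per_dimer, x$interhomolog_prob,
              x$dscb_from_opposed, x$closely_opposed_max_sep))
  cat("  pathways:", paste(sprintf("%s=%.3f", names(x$pathway_probs),
                                   x$pathway_probs), collapse = " "), "\n")
  cat(sprintf("  tract medians %.1f kb (NCO) / %.1f kb (CO), gamma shape %g\n",
              x$tract_median_kb, x$tract_median_co_kb, x$tract_shape))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' Only fields that differ from the defaults need to be present in the file.
#'
#' @param path YAML file
#' @return [sim_config()] for `read_sim_config`; `path` invisibly for
#'   `write_sim_config`
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$pathway_probs))
    vals$pathway_probs <- unlist(vals$pathway_probs)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()]
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$pathway_probs <- as.list(out$pathway_probs)
  yaml::write_yaml(out, path)
  invisible(path)
}
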
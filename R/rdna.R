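#' Marker phase of the chromosome XII rDNA assay strain
#'
#' One homolog (H1) carries a hygromycin-resistance insertion (*HYG*)
#' immediately centromere-proximal to the rDNA cluster and a *TRP1* insertion
#' inside the cluster; the other homolog (H2) carries *URA3* immediately
#' centromere-distal to the cluster.  Marker order along the chromosome is
#' CEN12 < HYG < rDNA(TRP1) < URA3 < telomere.
#'
#' @param cen12_hyg_kb length of the CEN12-HYG interval (kb)
#' @param hyg_ura3_kb length of the HYG-URA3 interval containing the rDNA
#'   cluster (kb)
#' @return object of class `marker_phase`
#' @export
marker_phase <- function(cen12_hyg_kb = 300, hyg_ura3_kb = 1170) {
  structure(list(
    h1 = c(HYG = 1L, TRP1 = 1L, URA3 = 0L),
    h2 = c(HYG = 0L, TRP1 = 0L, URA3 = 1L),
    intervals = c("CEN12-HYG" = 0.5, "HYG-TRP1" = 1.5, "TRP1-URA3" = 2.5),
    lengths_kb = c("CEN12-HYG" = cen12_hyg_kb,
                   "HYG-URA3" = hyg_ura3_kb)),
    class = "marker_phase")
}

#' Sector phenotype on the four test media
#'
#' Phenotypes are derived from marker copy numbers: growth on hygromycin
#' requires >= 1 *HYG* copy, Trp+ requires >= 1 *TRP1*, Ura+ >= 1 *URA3*;
#' on 5-FOA, a Ura- sector grows confluently, a *URA3* heterozygote forms
#' resistant papillae (the wild-type allele is readily lost), and a
#' *URA3/URA3* homozygote forms essentially none.
#'
#' @param hyg,trp,ura marker copy numbers (0-2)
#' @return object of class `sector_phenotype`
#' @export
sector_phenotype <- function(hyg, trp, ura) {
  hyg <- unname(as.integer(hyg)); trp <- unname(as.integer(trp))
  ura <- unname(as.integer(ura))
  stopifnot(hyg %in% 0:2, trp %in% 0:2, ura %in% 0:2)
  structure(list(hyg = hyg, trp = trp, ura = ura,
                 HygR = hyg >= 1, Trp = trp >= 1, Ura = ura >= 1,
                 FOA = c("confluent", "papillae", "none")[ura + 1L]),
            class = "sector_phenotype")
}

#' @export
print.sector_phenotype <- function(x, ...) {
  cat(sprintf("Hyg%s Trp%s Ura%s (FOA: %s)\n",
              if (x$HygR) "R" else "S", if (x$Trp) "+" else "-",
              if (x$Ura) "+" else "-", x$FOA))
  invisible(x)
}

.rdna_categories <- function() {
  ints <- c("CEN12-HYG", "HYG-TRP1", "TRP1-URA3")
  rbind(expand.grid(type = c("RCO", "BIR-U", "BIR-H"), interval = ints,
                    stringsAsFactors = FALSE),
        data.frame(type = "ICR", interval = "rDNA"))
}

#' Predict the two daughter-sector phenotypes of an event category
#'
#' Propagates marker zygosity through the event geometry: a reciprocal
#' crossover (RCO) exchanges everything distal to the exchange point between
#' the homologs; BIR replaces the recipient homolog's distal segment by a
#' copy of the donor's (BIR-U: the break is on the *URA3*-carrying homolog,
#' BIR-H: on the *HYG*-carrying homolog); an intrachromosomal event (ICR)
#' deletes *TRP1* from one chromatid only.  The returned pair is the sectored
#' segregation outcome (for crossovers, the detectable one of the two
#' equiprobable patterns).
#'
#' @param type `"RCO"`, `"BIR-U"`, `"BIR-H"` or `"ICR"`
#' @param interval `"CEN12-HYG"`, `"HYG-TRP1"` or `"TRP1-URA3"` (ignored for
#'   ICR)
#' @param phase a [marker_phase()]
#' @return list of two [sector_phenotype()] objects
#' @export
predict_phenotypes <- function(type, interval = NULL,
                               phase = marker_phase()) {
  type <- match.arg(type, c("RCO", "BIR-U", "BIR-H", "ICR"))
  h1 <- phase$h1; h2 <- phase$h2
  mpos <- c(HYG = 1, TRP1 = 2, URA3 = 3)
  if (type == "ICR") {
    h1p <- h1; h1p["TRP1"] <- 0L
    da <- h1p + h2; db <- h1 + h2
  } else {
    x <- phase$intervals[[match.arg(interval, names(phase$intervals))]]
    distal <- mpos > x
    if (type == "RCO") {
      r1 <- ifelse(distal, h2, h1)   # recombinant H1 chromatid
      r2 <- ifelse(distal, h1, h2)   # recombinant H2 chromatid
      da <- r1 + h2; db <- h1 + r2
    } else if (type == "BIR-U") {
      h2p <- ifelse(distal, h1, h2)  # H2 copies H1 from the break on
      da <- h1 + h2p; db <- h1 + h2
    } else {                         # BIR-H
      h1p <- ifelse(distal, h2, h1)
      da <- h1p + h2; db <- h1 + h2
    }
  }
  list(sector_phenotype(da["HYG"], da["TRP1"], da["URA3"]),
       sector_phenotype(db["HYG"], db["TRP1"], db["URA3"]))
}

#' Classify a sectored colony of the rDNA assay
#'
#' Inverse lookup of [predict_phenotypes()] over all event categories.  The
#' phenotype pair is matched as an unordered pair of marker copy-number
#' profiles; 5-FOA papillation is what separates the crossover-homozygous
#' *URA3/URA3* sectors from BIR-heterozygous Ura+ sectors.
#'
#' @param pheno_a,pheno_b [sector_phenotype()] objects for the two sectors
#' @param phase a [marker_phase()]
#' @return list with `type` and `interval` (both `NA` with a `diagnostic`
#'   message when no category matches)
#' @export
classify_rdna_colony <- function(pheno_a, pheno_b, phase = marker_phase()) {
  for (p in list(pheno_a, pheno_b)) {
    if (p$ura >= 1 && p$FOA == "confluent")
      stop("contradictory phenotype: Ura+ sector with confluent 5-FOA growth")
    if (p$ura == 0 && p$FOA != "confluent")
      stop("contradictory phenotype: Ura- sector without confluent 5-FOA growth")
  }
  key <- function(p) paste(p$hyg, p$trp, p$ura, sep = "/")
  obs <- sort(c(key(pheno_a), key(pheno_b)))
  cats <- .rdna_categories()
  for (i in seq_len(nrow(cats))) {
    pr <- predict_phenotypes(cats$type[i],
                             if (cats$type[i] == "ICR") NULL
                             else cats$interval[i], phase)
    if (identical(sort(c(key(pr[[1]]), key(pr[[2]]))), obs))
      return(list(type = cats$type[i], interval = cats$interval[i]))
  }
  list(type = NA_character_, interval = NA_character_,
       diagnostic = paste("no event category matches phenotype pair",
                          paste(obs, collapse = " vs ")))
}

#' Tabulate rDNA assay counts with imputation and normalization
#'
#' Builds the standard summary of the chromosome XII assay: observed counts
#' per category for treated and untreated cells, the phenotypically silent
#' BIR-H class in TRP1-URA3 imputed as equal to its BIR-U counterpart, the
#' untreated counts scaled by the ratio of colonies examined and subtracted
#' (see [normalized_induced()]), and per-kb crossover frequencies with
#' detection factor 2.
#'
#' @param observed named numeric vector of treated counts in the order
#'   RCO/BIR-U/BIR-H per interval (CEN12-HYG, HYG-TRP1, TRP1-URA3) then ICR;
#'   use `NA` for the silent BIR-H TRP1-URA3 class to request imputation
#' @param untreated same layout for untreated cells
#' @param n_treated,n_untreated colonies examined
#' @param phase a [marker_phase()] (supplies interval lengths)
#' @return object of class `rdna_table`: list with `$table` (counts by
#'   category: observed, untreated, normalized_exact, normalized (rounded)),
#'   `$per_kb` crossover frequencies for CEN12-HYG and HYG-URA3, and
#'   `$bir_totals`
#' @examples
#' tabulate_rdna(c(49, 9, 2, 77, 16, 9, 15, 8, NA, 116),
#'               c(1, 0, 0, 5, 2, 1, 0, 1, NA, 6), 3902, 5197)
#' @export
tabulate_rdna <- function(observed, untreated, n_treated, n_untreated,
                          phase = marker_phase()) {
  cats <- .rdna_categories()
  labels <- c(paste(cats$type[1:9], cats$interval[1:9], sep = " "), "ICR")
  stopifnot(length(observed) == 10, length(untreated) == 10)
  silent <- which(cats$type == "BIR-H" & cats$interval == "TRP1-URA3")
  partner <- which(cats$type == "BIR-U" & cats$interval == "TRP1-URA3")
  imputed_obs <- is.na(observed[silent])
  if (imputed_obs) observed[silent] <- observed[partner]
  if (is.na(untreated[silent])) untreated[silent] <- untreated[partner]
  if (any(is.na(observed) | is.na(untreated)))
    stop("only the silent BIR-H TRP1-URA3 class may be NA")
  if (any(observed < 0 | untreated < 0)) stop("counts must be >= 0")
  norm <- observed - untreated * (n_treated / n_untreated)
  norm[norm < 0] <- 0
  tab <- data.frame(category = labels, type = cats$type,
                    interval = cats$interval,
                    observed = observed, untreated = untreated,
                    normalized_exact = norm, normalized = round(norm),
                    imputed = seq_len(10) == silent & imputed_obs)
  rco <- cats$type == "RCO"
  per_kb <- c(
    "CEN12-HYG" = 2 * norm[rco & cats$interval == "CEN12-HYG"] /
      n_treated / phase$lengths_kb[["CEN12-HYG"]],
    "HYG-URA3" = 2 * sum(norm[rco & cats$interval %in%
                                c("HYG-TRP1", "TRP1-URA3")]) /
      n_treated / phase$lengths_kb[["HYG-URA3"]])
  bir <- cats$type %in% c("BIR-U", "BIR-H")
  bir_totals <- c(
    "CEN12-HYG" = sum(round(norm[bir & cats$interval == "CEN12-HYG"])),
    "rDNA" = sum(round(norm[bir & cats$interval %in%
                              c("HYG-TRP1", "TRP1-URA3")])))
  structure(list(table = tab, per_kb = per_kb, bir_totals = bir_totals,
                 n_treated = n_treated, n_untreated = n_untreated),
            class = "rdna_table")
}

#' @export
print.rdna_table <- function(x, ...) {
  cat(sprintf("rdna_table: %d treated / %d untreated colonies\n",
              x$n_treated, x$n_untreated))
  print(x$table[, c("category", "observed", "untreated", "normalized")])
  cat(sprintf("crossovers/kb: CEN12-HYG %.2g, HYG-URA3 %.2g\n",
              x$per_kb[["CEN12-HYG"]], x$per_kb[["HYG-URA3"]]))
  invisible(x)
}
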
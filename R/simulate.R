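#' Place UV-induced pyrimidine dimers on the diploid genome
#'
#' The number of dimers is Poisson with mean `dose * dimers_per_jm2`
#' (per diploid genome); positions are uniform over chromosomes (weighted by
#' length), homologs and strands.  A `clustered_dimer_excess` fraction is
#' instead placed within `closely_opposed_max_sep` of an already placed dimer,
#' on the opposite strand of the same homolog, emulating the dose-independent
#' excess of near-opposed dimer pairs over the uniform expectation.
#'
#' @param config a [sim_config()]
#' @param map a [snp_map()] (supplies chromosome names and lengths)
#' @return object of class `lesion_set`: data.frame with columns `chrom`,
#'   `pos`, `homolog` (1/2) and `strand` (1/2), sorted by chromosome,
#'   homolog and position
#' @export
place_dimers <- function(config, map) {
  chroms <- map$chromosomes
  n <- stats::rpois(1, config$dose * config$dimers_per_jm2)
  empty <- data.frame(chrom = character(), pos = numeric(),
                      homolog = integer(), strand = integer())
  if (n == 0) return(structure(empty, class = c("lesion_set", "data.frame")))
  n_cl <- stats::rbinom(1, n, config$clustered_dimer_excess)
  n_base <- n - n_cl
  if (n_base == 0) { n_base <- 1; n_cl <- n_cl - 1 }
  ci <- sample.int(nrow(chroms), n_base, replace = TRUE,
                   prob = chroms$length / sum(chroms$length))
  les <- data.frame(chrom = chroms$name[ci],
                    pos = floor(stats::runif(n_base, 1, chroms$length[ci] + 1)),
                    homolog = sample(1:2, n_base, replace = TRUE),
                    strand = sample(1:2, n_base, replace = TRUE))
  if (n_cl > 0) {
    s <- config$closely_opposed_max_sep
    base <- les[sample.int(n_base, n_cl, replace = TRUE), , drop = FALSE]
    off <- sample(c(-(s:1), 1:s), n_cl, replace = TRUE)
    maxp <- chroms$length[match(base$chrom, chroms$name)]
    cl <- data.frame(chrom = base$chrom,
                     pos = pmin(pmax(base$pos + off, 1), maxp),
                     homolog = base$homolog,
                     strand = 3L - base$strand)
    les <- rbind(les, cl)
  }
  les <- les[order(match(les$chrom, chroms$name), les$homolog, les$pos), ]
  rownames(les) <- NULL
  structure(les, class = c("lesion_set", "data.frame"))
}

#' Derive chromatid breaks from a lesion set
#'
#' Each closely-opposed pair (opposite strands of the same homolog, separated
#' by at most `closely_opposed_max_sep`) becomes a G1 double-strand break —
#' after replication, a double-sister-chromatid break (DSCB) at the pair
#' midpoint — with probability `dscb_from_opposed`.  Each remaining lesion
#' independently becomes a single-chromatid break (SCB) with probability
#' `scb_rate_per_dimer`; SCBs arise in S/G2 and those that would be repaired
#' silently off the sister chromatid are pruned at generation with probability
#' `1 - interhomolog_prob` (set `thin_interhomolog = FALSE` to keep them).
#' SCB counts therefore scale linearly with dose while DSCB counts scale
#' roughly quadratically, so the DSCB share of breaks rises with dose.
#'
#' @param lesions a `lesion_set` from [place_dimers()]
#' @param config a [sim_config()]
#' @param thin_interhomolog prune sister-repaired SCBs (default TRUE)
#' @return object of class `break_set`: data.frame with columns `chrom`,
#'   `pos`, `homolog`, `kind` ("SCB"/"DSCB")
#' @export
derive_breaks <- function(lesions, config, thin_interhomolog = TRUE) {
  empty <- data.frame(chrom = character(), pos = numeric(),
                      homolog = integer(), kind = character())
  if (nrow(lesions) == 0)
    return(structure(empty, class = c("break_set", "data.frame")))
  sep <- config$closely_opposed_max_sep
  n <- nrow(lesions)
  grp <- paste(lesions$chrom, lesions$homolog)
  # candidate closely-opposed pairs among first and second neighbours
  # (lesion density makes triple clusters vanishingly rare)
  cand_i <- integer(); cand_j <- integer()
  for (k in 1:2) {
    i <- seq_len(n - k)
    j <- i + k
    ok <- grp[i] == grp[j] & (lesions$pos[j] - lesions$pos[i]) <= sep &
      lesions$strand[i] != lesions$strand[j]
    cand_i <- c(cand_i, i[ok]); cand_j <- c(cand_j, j[ok])
  }
  o <- order(cand_i, cand_j)
  cand_i <- cand_i[o]; cand_j <- cand_j[o]
  used <- logical(n)
  pair_i <- integer(); pair_j <- integer()
  for (k in seq_along(cand_i)) {
    i <- cand_i[k]; j <- cand_j[k]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
    }
  }
  dscb <- NULL
  if (length(pair_i)) {
    keep <- stats::runif(length(pair_i)) < config$dscb_from_opposed
    if (any(keep)) {
      i <- pair_i[keep]; j <- pair_j[keep]
      dscb <- data.frame(chrom = lesions$chrom[i],
                         pos = floor((lesions$pos[i] + lesions$pos[j]) / 2),
                         homolog = lesions$homolog[i], kind = "DSCB")
    }
  }
  iso <- which(!used)
  p_scb <- config$scb_rate_per_dimer *
    if (thin_interhomolog) config$interhomolog_prob else 1
  iso <- iso[stats::runif(length(iso)) < p_scb]
  scb <- if (length(iso))
    data.frame(chrom = lesions$chrom[iso], pos = lesions$pos[iso],
               homolog = lesions$homolog[iso], kind = "SCB") else NULL
  out <- rbind(dscb, scb)
  if (is.null(out)) out <- empty
  out <- out[order(match(out$chrom, unique(lesions$chrom)), out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("break_set", "data.frame"))
}

#' Expected number of closely-opposed dimer pairs under uniform placement
#'
#' Closed-form expectation of the number of lesion pairs on opposite strands
#' separated by at most `max_sep`, for `n_dimers` placed uniformly and
#' independently on a genome of `genome_len` bp with random strand assignment.
#' The diploid genome is treated as a single concatenated length, so only
#' intra-homolog proximity counts.  For a pair of uniform positions the
#' probability of separation <= s is `(2*s*G - s^2)/G^2`; with random strands
#' half of all pairs are opposite-strand.
#'
#' @param n_dimers number of dimers
#' @param genome_len genome length in bp (> 0)
#' @param max_sep maximum separation in bp
#' @param strand_model `"opposite"` (pair must be on opposite strands) or
#'   `"any"` (strands ignored)
#' @return expected pair count
#' @examples
#' expected_closely_opposed(7500, 24e6, 75)
#' @export
expected_closely_opposed <- function(n_dimers, genome_len, max_sep,
                                     strand_model = c("opposite", "any")) {
  strand_model <- match.arg(strand_model)
  if (genome_len <= 0) stop("genome_len must be > 0")
  if (n_dimers < 0) stop("n_dimers must be >= 0")
  if (n_dimers < 2) return(0)
  p_close <- (2 * max_sep * genome_len - max_sep^2) / genome_len^2
  f <- if (strand_model == "opposite") 0.5 else 1
  choose(n_dimers, 2) * f * p_close
}

# ---- chromatid-level machinery ------------------------------------------

#' Initial chromatid set for one G1 cell after replication
#'
#' Four chromatids per chromosome (two sisters per homolog), each tracked as
#' the parental origin (1 = P1, 2 = P2) at every SNP plus the colour-marker
#' locus.  Columns 1-2 are the P1 sisters, 3-4 the P2 sisters.
#'
#' @param map a [snp_map()]
#' @param marker a [marker_config()]
#' @return object of class `chromatid_set`
#' @export
new_chromatid_set <- function(map, marker) {
  chrs <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
    nm <- map$chromosomes$name[i]
    pos <- map$snps$pos[map$snps$chrom == nm]
    is_marker <- rep(FALSE, length(pos))
    if (nm == marker$chrom) {
      if (marker$pos %in% pos) {
        is_marker[pos == marker$pos] <- TRUE
      } else {
        pos <- c(pos, marker$pos)
        is_marker <- c(is_marker, TRUE)
        o <- order(pos)
        pos <- pos[o]; is_marker <- is_marker[o]
      }
    }
    n <- length(pos)
    list(pos = pos, is_marker = is_marker,
         alleles = matrix(rep(c(1L, 1L, 2L, 2L), each = n), n, 4),
         length = map$chromosomes$length[i],
         centromere = map$chromosomes$centromere[i])
  })
  names(chrs) <- map$chromosomes$name
  structure(list(chrom = chrs, map = map, marker = marker),
            class = "chromatid_set")
}

.draw_tract <- function(config, pos, chrlen, co) {
  med <- 1000 * if (co) config$tract_median_co_kb else config$tract_median_kb
  scale <- med / stats::qgamma(0.5, config$tract_shape)
  len <- stats::rgamma(1, config$tract_shape, scale = scale)
  f <- stats::runif(1)
  c(lo = max(1, round(pos - f * len)),
    hi = min(chrlen, round(pos + (1 - f) * len)))
}

# convert recipient chromatid `rc` toward donor chromatid `dc` over [lo, hi];
# returns indices of loci actually converted
.apply_conversion <- function(ch, rc, dc, lo, hi, config,
                              forced_idx = NULL) {
  idx <- which(ch$pos >= lo & ch$pos <= hi)
  if (!length(idx)) return(list(ch = ch, idx = integer()))
  if (!is.null(forced_idx)) {
    sel <- forced_idx
  } else if (stats::runif(1) < config$patchy_repair_prob) {
    sel <- idx[stats::runif(length(idx)) < 0.5]
  } else if (stats::runif(1) < config$restoration_prob) {
    sel <- integer()
  } else sel <- idx
  changed <- sel[ch$alleles[sel, rc] != ch$alleles[sel, dc]]
  ch$alleles[sel, rc] <- ch$alleles[sel, dc]
  list(ch = ch, idx = changed)
}

.distal_idx <- function(ch, at, inclusive = TRUE) {
  if (at > ch$centromere) {
    if (inclusive) which(ch$pos >= at) else which(ch$pos > at)
  } else {
    if (inclusive) which(ch$pos <= at) else which(ch$pos < at)
  }
}

#' Repair one chromatid break against the homolog
#'
#' Samples a repair pathway and applies the resulting genotype edits to the
#' chromatid set.  An SCB repairs its single broken sister: SDSA and
#' double-Holliday-junction (DSBR) outcomes install a gene-conversion tract on
#' the broken (recipient) chromatid, DSBR resolved as a crossover additionally
#' exchanges everything distal to the tract with a donor chromatid, and BIR
#' copies the donor from the break to the telomere of the broken arm.  A DSCB
#' repairs both sisters: with probability `dscb_equal_tract_prob` they share
#' identical tract bounds (a 4:0 tract), otherwise each sister is repaired
#' independently (3:1/4:0 hybrids, possibly crossover- or BIR-associated).
#' Heteroduplex mismatches are repaired toward the donor (conversion-type)
#' with probability `1 - restoration_prob`, or SNP-by-SNP in random directions
#' with probability `patchy_repair_prob`.
#'
#' @param state a [new_chromatid_set()]
#' @param brk one-row data.frame or list with `chrom`, `pos`, `homolog`,
#'   `kind` ("SCB"/"DSCB")
#' @param config a [sim_config()]
#' @return list with elements `state` (updated chromatid set) and `event`
#'   (ground-truth record: kind, mechanism, pathways, recipient homolog,
#'   requested tract bounds, converted positions per sister)
#' @export
repair_break <- function(state, brk, config) {
  ch <- state$chrom[[brk$chrom]]
  if (is.null(ch)) stop("unknown chromosome: ", brk$chrom)
  if (brk$pos < 1 || brk$pos > ch$length)
    stop("break position outside chromosome")
  sisters <- if (brk$homolog == 1) 1:2 else 3:4
  donors <- if (brk$homolog == 1) 3:4 else 1:2
  pw <- config$pathway_probs
  conv <- list(numeric(), numeric())
  bir <- c(FALSE, FALSE)
  pathways <- character()
  crossover <- FALSE
  co_cols <- NULL
  tract <- c(lo = NA_real_, hi = NA_real_)
  conv_cols <- c(NA_integer_, NA_integer_)

  repair_one <- function(rc, slot) {
    path <- sample(names(pw), 1, prob = pw)
    pathways[slot] <<- path
    if (path == "bir") {
      dc <- sample(donors, 1)
      idx <- .distal_idx(ch, brk$pos)
      ch$alleles[idx, rc] <<- ch$alleles[idx, dc]
      bir[slot] <<- TRUE
    } else {
      co <- path == "dsbr_co"
      tr <- .draw_tract(config, brk$pos, ch$length, co)
      tract["lo"] <<- min(tract["lo"], tr["lo"], na.rm = TRUE)
      tract["hi"] <<- max(tract["hi"], tr["hi"], na.rm = TRUE)
      dc <- sample(donors, 1)
      res <- .apply_conversion(ch, rc, dc, tr["lo"], tr["hi"], config)
      ch <<- res$ch
      conv[[slot]] <<- ch$pos[res$idx]
      conv_cols[slot] <<- rc
      if (co) {
        at <- if (brk$pos > ch$centromere) tr["hi"] else tr["lo"]
        idx <- .distal_idx(ch, at, inclusive = FALSE)
        tmp <- ch$alleles[idx, rc]
        ch$alleles[idx, rc] <<- ch$alleles[idx, dc]
        ch$alleles[idx, dc] <<- tmp
        crossover <<- TRUE
        co_cols <<- rbind(co_cols, c(rc, dc))
      }
    }
  }

  if (brk$kind == "SCB") {
    rc <- sample(sisters, 1)
    repair_one(rc, 1L)
    used <- rc
  } else {
    if (stats::runif(1) < config$dscb_equal_tract_prob) {
      tr <- .draw_tract(config, brk$pos, ch$length, co = FALSE)
      tract <- tr
      idx <- which(ch$pos >= tr["lo"] & ch$pos <= tr["hi"])
      if (stats::runif(1) < config$restoration_prob) idx <- integer()
      for (slot in 1:2) {
        rc <- sisters[slot]; dc <- sample(donors, 1)
        res <- .apply_conversion(ch, rc, dc, tr["lo"], tr["hi"], config,
                                 forced_idx = idx)
        ch <- res$ch
        conv[[slot]] <- ch$pos[res$idx]
        conv_cols[slot] <- rc
      }
      pathways <- c("sdsa", "sdsa")
    } else {
      # the two sisters are processed to different extents: one carries the
      # full event tract, the other a tract nested inside it, giving hybrid
      # 3:1/4:0 patterns while the event-level tract length stays on the
      # calibrated distribution
      pws <- sample(names(pw), 2, replace = TRUE, prob = pw)
      if (all(pws == "bir")) {
        for (slot in 1:2) {
          rc <- sisters[slot]; dc <- sample(donors, 1)
          idx <- .distal_idx(ch, brk$pos)
          ch$alleles[idx, rc] <- ch$alleles[idx, dc]
          bir[slot] <- TRUE
        }
      } else {
        any_co <- any(pws == "dsbr_co")
        tr <- .draw_tract(config, brk$pos, ch$length, co = any_co)
        tract <- tr
        # the crossover sister (if only one) carries the full tract
        ord <- if (sum(pws == "dsbr_co") == 1) order(pws != "dsbr_co")
               else 1:2
        full <- TRUE
        for (slot in ord) {
          rc <- sisters[slot]
          if (pws[slot] == "bir") {
            dc <- sample(donors, 1)
            idx <- .distal_idx(ch, brk$pos)
            ch$alleles[idx, rc] <- ch$alleles[idx, dc]
            bir[slot] <- TRUE
            next
          }
          bounds <- if (full) tr else
            c(lo = tr[["lo"]] + stats::runif(1) * (brk$pos - tr[["lo"]]),
              hi = tr[["hi"]] - stats::runif(1) * (tr[["hi"]] - brk$pos))
          full <- FALSE
          dc <- sample(donors, 1)
          res <- .apply_conversion(ch, rc, dc, bounds[["lo"]],
                                   bounds[["hi"]], config)
          ch <- res$ch
          conv[[slot]] <- ch$pos[res$idx]
          conv_cols[slot] <- rc
          if (pws[slot] == "dsbr_co") {
            at <- if (brk$pos > ch$centromere) bounds[["hi"]]
                  else bounds[["lo"]]
            idx <- .distal_idx(ch, at, inclusive = FALSE)
            tmp <- ch$alleles[idx, rc]
            ch$alleles[idx, rc] <- ch$alleles[idx, dc]
            ch$alleles[idx, dc] <- tmp
            crossover <- TRUE
            co_cols <- rbind(co_cols, c(rc, dc))
          }
        }
      }
      pathways <- pws
    }
    used <- sisters
  }
  state$chrom[[brk$chrom]] <- ch

  kind <- if (crossover) "CO"
    else if (brk$kind == "SCB" && any(bir)) "BIR"
    else if (any(bir)) "complex"            # DSCB with one BIR sister
    else "NCO_conversion"
  event <- list(chrom = brk$chrom, pos = brk$pos,
                homolog = brk$homolog,
                recipient = c("P1", "P2")[brk$homolog],
                mechanism = brk$kind, kind = kind,
                pathways = paste(pathways, collapse = "+"),
                crossover = crossover,
                tract_lo = unname(tract["lo"]), tract_hi = unname(tract["hi"]),
                conv1 = conv[[1]], conv2 = conv[[2]],
                conv_cols = conv_cols, co_cols = co_cols,
                n_snps = length(unique(c(conv[[1]], conv[[2]]))))
  list(state = state, event = event)
}

# mechanistic truth pattern from the per-sister converted SNP positions,
# using the same one-SNP boundary tolerance as the classifier
.truth_pattern <- function(conv1, conv2) {
  n1 <- length(conv1); n2 <- length(conv2)
  if (n1 + n2 == 0) return("none")
  if (n1 == 0 || n2 == 0) return("3:1")
  both <- intersect(conv1, conv2)
  only <- setdiff(union(conv1, conv2), both)
  if (!length(both)) return("3:1")          # no shared SNP between sisters
  if (!length(only)) return("4:0")
  lo <- sum(only < min(both)); hi <- sum(only > max(both))
  mid <- length(only) - lo - hi
  if (mid == 0 && lo <= 1 && hi <= 1) "4:0" else "hybrid_3:1/4:0"
}

#' Segregate repaired chromatids into the two daughter cells
#'
#' For every chromosome, each daughter receives one of the two sister
#' chromatids of each homolog, chosen independently and uniformly — the two
#' segregation patterns relevant to a crossover are therefore equiprobable,
#' and distal reciprocal LOH appears in half of the simulations of a single
#' crossover.  Colony colour is the marker copy number per daughter
#' (0 = red, 1 = pink, 2 = white).
#'
#' @param state a [new_chromatid_set()] after repairs
#' @param events list of event records from [repair_break()]
#' @param lose optional chromosome-loss injection: list with `chrom`,
#'   `daughter` (1/2) and `homolog` (1/2); that daughter receives no chromatid
#'   of that homolog
#' @return object of class `colony_truth`: per-daughter zygosity tracks
#'   (`$daughters$a`, `$daughters$b`), `$colors`, `$color_pattern`,
#'   `$sectored`, `$selected_sectored`, `$events` (data.frame) and the
#'   per-chromosome chromatid assignment `$segregation`
#' @export
segregate <- function(state, events = list(), lose = NULL) {
  map <- state$map; marker <- state$marker
  carrier_allele <- if (marker$carrier == "P1") 1L else 2L
  tracks <- list(a = NULL, b = NULL)
  seg <- list()
  rows_a <- list(); rows_b <- list()
  marker_copies <- c(a = 0L, b = 0L)
  for (nm in names(state$chrom)) {
    ch <- state$chrom[[nm]]
    a_cols <- c(sample(1:2, 1), sample(3:4, 1))
    b_cols <- c(setdiff(1:2, a_cols[1]), setdiff(3:4, a_cols[2]))
    seg[[nm]] <- rbind(a = a_cols, b = b_cols)
    for (d in c("a", "b")) {
      cols <- if (d == "a") a_cols else b_cols
      if (!is.null(lose) && lose$chrom == nm &&
          lose$daughter == match(d, c("a", "b")))
        cols <- cols[-lose$homolog]
      al <- ch$alleles[, cols, drop = FALSE]
      st <- if (ncol(al) == 2) {
        ifelse(al[, 1] != al[, 2], "HET",
               ifelse(al[, 1] == 1L, "HOM_P1", "HOM_P2"))
      } else ifelse(al[, 1] == 1L, "HOM_P1", "HOM_P2")
      keep <- !ch$is_marker | ch$pos %in% map$snps$pos[map$snps$chrom == nm]
      df <- data.frame(chrom = nm, pos = ch$pos[keep], state = st[keep])
      if (d == "a") rows_a[[nm]] <- df else rows_b[[nm]] <- df
      mi <- which(ch$is_marker)
      if (length(mi))
        marker_copies[d] <- marker_copies[d] +
          sum(ch$alleles[mi, cols, drop = FALSE] == carrier_allele)
    }
  }
  ta <- do.call(rbind, rows_a); rownames(ta) <- NULL
  tb <- do.call(rbind, rows_b); rownames(tb) <- NULL
  ids <- map$snps$snp_id[match(paste(ta$chrom, ta$pos),
                               paste(map$snps$chrom, map$snps$pos))]
  ta$snp_id <- ids; tb$snp_id <- ids
  colors <- c("red", "pink", "white")[pmin(marker_copies, 2) + 1L]
  names(colors) <- c("a", "b")
  ev <- .events_df(events)
  structure(list(daughters = list(a = ta, b = tb),
                 colors = colors,
                 color_pattern = paste(sort(colors), collapse = "/"),
                 sectored = colors[1] != colors[2],
                 selected_sectored = setequal(colors, c("red", "white")),
                 events = ev, segregation = seg,
                 marker_copies = marker_copies),
            class = "colony_truth")
}

.events_df <- function(events) {
  if (!length(events))
    return(data.frame(chrom = character(), pos = numeric(),
                      homolog = integer(), recipient = character(),
                      mechanism = character(), kind = character(),
                      pathways = character(), crossover = logical(),
                      tract_lo = numeric(), tract_hi = numeric(),
                      n_snps = integer(), pattern = character()))
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(chrom = e$chrom, pos = e$pos, homolog = e$homolog,
               recipient = e$recipient, mechanism = e$mechanism,
               kind = e$kind, pathways = e$pathways,
               crossover = e$crossover, tract_lo = e$tract_lo,
               tract_hi = e$tract_hi, n_snps = e$n_snps,
               pattern = .truth_pattern(e$conv1, e$conv2))))
  rownames(df) <- NULL
  df
}

#' @export
print.colony_truth <- function(x, ...) {
  cat(sprintf("colony_truth: %s colony (%s/%s), %d interhomolog event(s)\n",
              if (x$sectored) "sectored" else "unsectored",
              x$colors[1], x$colors[2], nrow(x$events)))
  if (nrow(x$events)) print(utils::head(
    x$events[c("chrom", "pos", "mechanism", "kind", "pattern")], 10))
  invisible(x)
}

#' Simulate the array hybridization ratios of one sector
#'
#' Heterozygous SNPs read about 1 in both allele channels; homozygous SNPs
#' read `r_hi` for the retained and `r_lo` for the lost parental allele.
#' Gaussian noise of sd `noise_sd` is added and ratios are truncated at 0.
#'
#' @param track data.frame with columns `chrom`, `pos`, `snp_id`, `state`
#'   (HET/HOM_P1/HOM_P2), e.g. a daughter track from [segregate()]
#' @param noise_sd noise standard deviation (>= 0)
#' @param config optional [sim_config()] supplying `r_hi`/`r_lo` (and
#'   `noise_sd` when the argument is missing)
#' @return the track with `ratio_P1` and `ratio_P2` columns added
#' @export
simulate_array <- function(track, noise_sd = NULL, config = sim_config()) {
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- nrow(track)
  r1 <- ifelse(track$state == "HET", 1,
               ifelse(track$state == "HOM_P1", config$r_hi, config$r_lo))
  r2 <- ifelse(track$state == "HET", 1,
               ifelse(track$state == "HOM_P2", config$r_hi, config$r_lo))
  track$ratio_P1 <- pmax(0, r1 + stats::rnorm(n, 0, noise_sd))
  track$ratio_P2 <- pmax(0, r2 + stats::rnorm(n, 0, noise_sd))
  track
}

#' Simulate one irradiated G1 cell and its sectored colony
#'
#' Runs the full lesion → break → repair → segregation chain for a single
#' cell.  With `second_division_prob > 0`, residual damage may add one more
#' break in a daughter's next division, splitting that sector in two
#' (tri-sector colonies).
#'
#' @param config a [sim_config()]
#' @param genome list with `map` and `marker`, e.g. [make_default_genome()]
#' @param seed optional integer seed
#' @return a `colony_truth` (see [segregate()]); tri-sector colonies carry an
#'   additional `$daughters$a2` track
#' @export
simulate_colony <- function(config, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- new_chromatid_set(genome$map, genome$marker)
  lesions <- place_dimers(config, genome$map)
  breaks <- derive_breaks(lesions, config)
  events <- list()
  if (nrow(breaks)) {
    for (i in sample(nrow(breaks))) {
      res <- repair_break(state, as.list(breaks[i, ]), config)
      state <- res$state
      events[[length(events) + 1L]] <- res$event
    }
  }
  colony <- segregate(state, events)
  colony$n_dimers <- nrow(lesions)
  colony$n_breaks <- nrow(breaks)
  if (config$second_division_prob > 0 &&
      stats::runif(1) < config$second_division_prob)
    colony <- .split_second_division(colony, config, genome)
  colony
}

# tri-sector generation: damage persisting into the second division converts
# one SNP tract of daughter a in one of its two descendants
.split_second_division <- function(colony, config, genome) {
  tr <- colony$daughters$a
  het <- which(tr$state == "HET")
  if (length(het) < 4) return(colony)
  i <- sample(het, 1)
  span <- .draw_tract(config, tr$pos[i],
                      genome$map$chromosomes$length[
                        match(tr$chrom[i], genome$map$chromosomes$name)],
                      co = FALSE)
  sel <- which(tr$chrom == tr$chrom[i] & tr$pos >= span["lo"] &
                 tr$pos <= span["hi"] & tr$state == "HET")
  a2 <- tr
  a2$state[sel] <- sample(c("HOM_P1", "HOM_P2"), 1)
  colony$daughters$a2 <- a2
  colony$tri_sector <- TRUE
  colony
}

#' Simulate a plating experiment of many irradiated cells
#'
#' @param config a [sim_config()]
#' @param genome list with `map` and `marker`
#' @param n_cells number of irradiated cells (> 0)
#' @param seed root seed; per-colony child seeds are derived from it
#' @param ratios also attach simulated hybridization ratio tables for the two
#'   sectors of every colony (slower; default FALSE)
#' @return object of class `uv_experiment`: list of colonies plus summary
#'   counts (`$n_sectored`, `$n_selected_sectored`, `$sector_frequency`)
#' @export
simulate_experiment <- function(config, genome, n_cells, seed = 1,
                                ratios = FALSE) {
  if (n_cells <= 0) stop("n_cells must be > 0")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1, n_cells)
  colonies <- lapply(seq_len(n_cells), function(i) {
    col <- simulate_colony(config, genome, seed = child[i])
    if (ratios) {
      col$ratio_a <- simulate_array(col$daughters$a, config$noise_sd, config)
      col$ratio_b <- simulate_array(col$daughters$b, config$noise_sd, config)
    }
    col
  })
  sectored <- vapply(colonies, `[[`, TRUE, "sectored")
  selected <- vapply(colonies, `[[`, TRUE, "selected_sectored")
  structure(list(colonies = colonies, n_cells = n_cells,
                 n_sectored = sum(sectored),
                 n_selected_sectored = sum(selected),
                 sector_frequency = mean(selected),
                 dose = config$dose, seed = seed),
            class = "uv_experiment")
}

#' @export
print.uv_experiment <- function(x, ...) {
  ev <- sum(vapply(x$colonies, function(c) nrow(c$events), 0L))
  cat(sprintf(paste0("uv_experiment: %d cells at %g J/m2; %d sectored ",
                     "(%d red/white, frequency %.3g); %.2f events/cell\n"),
              x$n_cells, x$dose, x$n_sectored, x$n_selected_sectored,
              x$sector_frequency, ev / x$n_cells))
  invisible(x)
}
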
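#' Pair the two sectors of a colony into independent transition clusters
#'
#' SNPs that are homozygous in either sector are grouped by proximity;
#' LOH regions separated by more than `gap_kb` of shared heterozygosity are
#' assumed to derive from independent initiating lesions and receive distinct
#' `independent_group` ids.
#'
#' @param a,b `sector_call` objects for the two sectors, on the same SNP map
#' @param gap_kb independence gap in kb (default 15)
#' @return data.frame with one row per cluster: `chrom`,
#'   `independent_group`, `start_pos`, `end_pos`, `n_snps`
#' @export
pair_sectors <- function(a, b, gap_kb = 15) {
  if (nrow(a$states) != nrow(b$states) ||
      !all(a$states$snp_id == b$states$snp_id))
    stop("the two sectors are not on the same SNP map")
  hom <- function(s) s %in% c("HOM_P1", "HOM_P2")
  out <- list(); gid <- 0L
  for (nm in unique(a$states$chrom)) {
    ia <- a$states$chrom == nm
    sa <- a$states$state[ia]; sb <- b$states$state[b$states$chrom == nm]
    pos <- a$states$pos[ia]
    inv <- which(hom(sa) | hom(sb))
    if (!length(inv)) next
    brk <- c(0, which(diff(pos[inv]) > gap_kb * 1000), length(inv))
    for (k in seq_len(length(brk) - 1)) {
      sel <- inv[(brk[k] + 1):brk[k + 1]]
      gid <- gid + 1L
      out[[gid]] <- data.frame(chrom = nm, independent_group = gid,
                               start_pos = pos[min(sel)],
                               end_pos = pos[max(sel)],
                               n_snps = length(sel))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), independent_group = integer(),
                      start_pos = numeric(), end_pos = numeric(),
                      n_snps = integer()))
  do.call(rbind, out)
}

# terminal HOM segments of one sector on one chromosome: returns rows of
# segments that touch the first or last called SNP
.terminal_segs <- function(segs) {
  if (!nrow(segs)) return(segs[0, ])
  first_called <- segs$first_pos[1]; last_called <- segs$last_pos[nrow(segs)]
  hom <- segs$state != "HET"
  side <- ifelse(segs$first_pos == first_called, "left",
                 ifelse(segs$last_pos == last_called, "right", NA))
  segs$side <- side
  segs[hom & !is.na(side), , drop = FALSE]
}

#' Classify recombination events from the two sectors of a colony
#'
#' Pairs the sector calls (see [pair_sectors()]) and applies the decision
#' rules of the sectored-colony scheme to every independent cluster:
#' reciprocal terminal LOH in the two sectors is a crossover (with conversion
#' when an adjacent 3:1/4:0 tract is present); terminal LOH in exactly one
#' sector is break-induced replication; interstitial LOH in one sector is a
#' 3:1 conversion; same-direction interstitial LOH in both sectors is a 4:0
#' conversion when the tract bounds agree to within `tol_snps` SNPs per
#' boundary and a hybrid 3:1/4:0 tract otherwise; whole-chromosome LOH in one
#' sector is chromosome loss; anything else is complex.  Any 4:0 segment
#' implies a double-sister-chromatid break (DSCB), a pure 3:1 tract a
#' single-chromatid break (SCB).
#'
#' @param a,b `sector_call` objects for the two sectors
#' @param gap_kb independence gap in kb between clusters (default 15)
#' @param tol_snps boundary tolerance (SNPs) for calling the two sectors'
#'   tracts identical (default 1)
#' @return object of class `recomb_events`: data.frame with one row per
#'   event: `chrom`, `independent_group`, `kind`, `pattern`, `mechanism`,
#'   `donor`, `recipient`, `tract_start`, `tract_end`, `tract_min`,
#'   `tract_max` (bp), `n_conv_snps`, `n_trans_a`, `n_trans_b`
#' @export
classify_events <- function(a, b, gap_kb = 15, tol_snps = 1) {
  clusters <- pair_sectors(a, b, gap_kb = gap_kb)
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    rows[[i]] <- .classify_cluster(a, b, cl, tol_snps)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else .empty_events()
  rownames(ev) <- NULL
  structure(ev, class = c("recomb_events", "data.frame"))
}

.empty_events <- function() {
  data.frame(chrom = character(), independent_group = integer(),
             kind = character(), pattern = character(),
             mechanism = character(), donor = character(),
             recipient = character(), region_start = numeric(),
             region_end = numeric(), tract_start = numeric(),
             tract_end = numeric(), tract_min = numeric(),
             tract_max = numeric(), n_conv_snps = integer(),
             n_trans_a = integer(), n_trans_b = integer())
}

.classify_cluster <- function(a, b, cl, tol_snps) {
  nm <- cl$chrom
  ia <- which(a$states$chrom == nm)
  sa <- a$states$state[ia]; sb <- b$states$state[b$states$chrom == nm]
  pos <- a$states$pos[ia]
  segs_a <- a$segments[a$segments$chrom == nm, , drop = FALSE]
  segs_b <- b$segments[b$segments$chrom == nm, , drop = FALSE]
  in_cl <- pos >= cl$start_pos & pos <= cl$end_pos
  hom_a <- sa %in% c("HOM_P1", "HOM_P2")
  hom_b <- sb %in% c("HOM_P1", "HOM_P2")
  called_a <- sa != "NOCALL"; called_b <- sb != "NOCALL"

  # per-SNP joint codes within the cluster
  dir_a <- ifelse(sa == "HOM_P1", "P1", ifelse(sa == "HOM_P2", "P2", NA))
  dir_b <- ifelse(sb == "HOM_P1", "P1", ifelse(sb == "HOM_P2", "P2", NA))
  code <- rep(NA_character_, length(pos))
  code[in_cl & hom_a & hom_b & dir_a == dir_b] <- "40"
  code[in_cl & hom_a & hom_b & dir_a != dir_b] <- "CO"
  code[in_cl & xor(hom_a & called_b, hom_b & called_a) &
         (hom_a | hom_b)] <- "31"
  # one sector hom, other NOCALL: not informative for joint pattern
  code[in_cl & hom_a & !called_b] <- NA
  code[in_cl & hom_b & !called_a] <- NA

  term_a <- .terminal_segs(segs_a)
  term_b <- .terminal_segs(segs_b)
  overlaps <- function(t) t$first_pos <= cl$end_pos & t$last_pos >= cl$start_pos
  term_a <- term_a[overlaps(term_a), , drop = FALSE]
  term_b <- term_b[overlaps(term_b), , drop = FALSE]
  whole <- function(segs, s) {
    loh <- segs[segs$state != "HET", , drop = FALSE]
    nrow(segs) > 0 && nrow(loh) == 1 && nrow(segs) == 1
  }
  whole_a <- whole(segs_a); whole_b <- whole(segs_b)

  kind <- NULL; terminal_side <- NA_character_
  if (xor(whole_a, whole_b) && !(whole_a && whole_b)) {
    only <- if (whole_a) segs_b else segs_a
    if (!any(only$state != "HET")) kind <- "chromosome_loss"
  }

  co_sides <- character()
  for (s in c("left", "right")) {
    da <- term_a$state[term_a$side == s]; db <- term_b$state[term_b$side == s]
    if (length(da) == 1 && length(db) == 1 && da != db) co_sides <- c(co_sides, s)
  }
  n_term_sectors <- (nrow(term_a) > 0) + (nrow(term_b) > 0)

  conv_idx <- which(code %in% c("31", "40"))
  has_co_pts <- any(code == "CO", na.rm = TRUE)

  if (is.null(kind)) {
    if (length(co_sides)) {
      kind <- if (length(conv_idx)) "CO_with_conversion" else "CO"
      terminal_side <- co_sides[1]
    } else if (n_term_sectors == 1 && !has_co_pts) {
      kind <- "BIR"
      tseg <- if (nrow(term_a)) term_a else term_b
      terminal_side <- tseg$side[1]
      # conversion tract = LOH outside the terminal run itself
      keep <- pos[conv_idx] < min(tseg$first_pos) |
        pos[conv_idx] > max(tseg$last_pos)
      conv_idx <- conv_idx[keep]
    } else if (n_term_sectors == 0) {
      if (has_co_pts) kind <- "complex"
      else {
        dirs <- unique(stats::na.omit(c(dir_a[conv_idx], dir_b[conv_idx])))
        in_a <- any(hom_a[conv_idx]); in_b <- any(hom_b[conv_idx])
        if (length(dirs) > 1) kind <- "complex"
        else if (in_a && in_b) {
          has40 <- any(code[conv_idx] == "40")
          if (!has40) kind <- "NCO_conversion"  # hybrid via pattern below
          else kind <- "NCO_conversion"
        } else kind <- "NCO_conversion"
      }
    } else kind <- "complex"
  }

  # pattern from the conversion points
  pattern <- "none"
  if (kind == "complex") pattern <- "complex"
  else if (length(conv_idx)) {
    codes <- code[conv_idx]
    has40 <- any(codes == "40"); has31 <- any(codes == "31")
    if (has40 && !has31) pattern <- "4:0"
    else if (has40 && has31) {
      i40 <- conv_idx[codes == "40"]
      i31 <- conv_idx[codes == "31"]
      lo <- sum(i31 < min(i40)); hi <- sum(i31 > max(i40))
      mid <- length(i31) - lo - hi
      pattern <- if (mid == 0 && lo <= tol_snps && hi <= tol_snps) "4:0"
                 else "hybrid_3:1/4:0"
    } else {
      in_a <- any(hom_a[conv_idx]); in_b <- any(hom_b[conv_idx])
      pattern <- if (in_a && in_b) "hybrid_3:1/4:0" else "3:1"
    }
  }
  if (kind == "chromosome_loss") pattern <- "none"

  mechanism <- if (pattern %in% c("4:0", "hybrid_3:1/4:0")) "DSCB"
    else if (pattern == "3:1") "SCB"
    else if (pattern == "complex" &&
             any(code[in_cl] == "40", na.rm = TRUE)) "DSCB"
    else NA_character_

  # donor / recipient from the conversion direction
  donor <- NA_character_
  if (length(conv_idx)) {
    dirs <- unique(stats::na.omit(c(dir_a[conv_idx], dir_b[conv_idx])))
    if (length(dirs) == 1) donor <- dirs
  }
  recipient <- if (is.na(donor)) "ambiguous" else setdiff(c("P1", "P2"), donor)

  # tract bounds: minimal span over conversion SNPs, maximal span to the
  # nearest confidently-called flanking SNP (or the reciprocal CO boundary)
  tract_start <- tract_end <- tract_min <- tract_max <- NA_real_
  if (length(conv_idx)) {
    tract_start <- pos[min(conv_idx)]
    tract_end <- pos[max(conv_idx)]
    tract_min <- tract_end - tract_start
    flank_ok <- called_a & called_b & !(seq_along(pos) %in% conv_idx)
    left <- which(flank_ok & pos < tract_start)
    right <- which(flank_ok & pos > tract_end)
    lf <- if (length(left)) pos[max(left)] else tract_start
    rf <- if (length(right)) pos[min(right)] else tract_end
    tract_max <- rf - lf
  }

  tr_in <- function(tr) sum(tr$chrom == nm & tr$outer >= cl$start_pos &
                              tr$inner <= cl$end_pos)
  data.frame(chrom = nm, independent_group = cl$independent_group,
             kind = kind, pattern = pattern, mechanism = mechanism,
             donor = donor, recipient = recipient,
             region_start = cl$start_pos, region_end = cl$end_pos,
             tract_start = tract_start, tract_end = tract_end,
             tract_min = tract_min, tract_max = tract_max,
             n_conv_snps = length(conv_idx),
             n_trans_a = tr_in(a$transitions),
             n_trans_b = tr_in(b$transitions))
}

#' Infer the recipient homolog of a conversion event
#'
#' The homolog that received the double-strand break acts as the recipient:
#' its alleles are overwritten by the donor's, so the donor is the homolog
#' whose alleles became homozygous in the tract and the recipient is the
#' other.  Events without a conversion tract are `"ambiguous"`.
#'
#' @param events a `recomb_events` data.frame (or one row of it)
#' @return character vector of recipient labels
#' @export
infer_recipient <- function(events) {
  ifelse(is.na(events$donor), "ambiguous",
         ifelse(events$donor == "P1", "P2", "P1"))
}

#' Classify a whole simulated colony
#'
#' Convenience wrapper: simulates (or takes) the two sectors' ratio tables,
#' calls and segments each, and classifies events.
#'
#' @param ratio_a,ratio_b ratio tables for the two sectors
#' @param thresholds,min_run passed to [call_sector()]
#' @param gap_kb,tol_snps passed to [classify_events()]
#' @return a `recomb_events` data.frame
#' @export
classify_colony <- function(ratio_a, ratio_b, thresholds = list(),
                            min_run = 2, gap_kb = 15, tol_snps = 1) {
  classify_events(call_sector(ratio_a, thresholds, min_run),
                  call_sector(ratio_b, thresholds, min_run),
                  gap_kb = gap_kb, tol_snps = tol_snps)
}

#' Observable events of a simulated colony
#'
#' Classifies the colony's true (noise-free) daughter zygosity tracks,
#' giving the event list an ideal array reader would recover — the reference
#' against which the noisy ratio → call → classify pipeline is scored.
#'
#' @param colony a `colony_truth` from [simulate_colony()]
#' @param min_run,gap_kb,tol_snps classifier settings
#' @return a `recomb_events` data.frame
#' @export
observable_events <- function(colony, min_run = 2, gap_kb = 15,
                              tol_snps = 1) {
  classify_events(sector_call_from_states(colony$daughters$a, min_run),
                  sector_call_from_states(colony$daughters$b, min_run),
                  gap_kb = gap_kb, tol_snps = tol_snps)
}

#' Summarize a cohort of classified events
#'
#' Tabulates events by kind, pattern and mechanism, separating events on the
#' selected chromosome arm (whose recovery was demanded by the sectoring
#' screen) from unselected events elsewhere in the genome, and builds the
#' 2x2 SCB/DSCB-by-association contingency table for conversions.
#'
#' @param events a `recomb_events` data.frame
#' @param marker optional [marker_config()]; events on the marker
#'   chromosome's marker-bearing arm are flagged as selected
#' @param map optional [snp_map()] supplying the centromere position used to
#'   delimit the selected arm
#' @return object of class `cohort_summary`: list with `$kind_counts`,
#'   `$pattern_counts`, `$mechanism_by_association` (rows NCO / CO-associated
#'   conversions, columns SCB / DSCB), `$selected`, `$unselected`
#' @export
summarize_cohort <- function(events, marker = NULL, map = NULL) {
  sel <- rep(FALSE, nrow(events))
  if (!is.null(marker) && nrow(events)) {
    if (is.null(map)) stop("summarizing with a marker needs `map` for the centromere")
    cen <- map$chromosomes$centromere[map$chromosomes$name == marker$chrom]
    arm <- if (marker$pos < cen) c(1, cen)
           else c(cen, map$chromosomes$length[map$chromosomes$name == marker$chrom])
    p <- (events$region_start + events$region_end) / 2
    sel <- events$chrom == marker$chrom & p >= arm[1] & p <= arm[2]
  }
  tab <- function(e) list(
    kind = table(factor(e$kind, levels = c("CO", "CO_with_conversion",
                                           "NCO_conversion", "BIR",
                                           "chromosome_loss", "complex"))),
    pattern = table(factor(e$pattern,
                           levels = c("none", "3:1", "4:0",
                                      "hybrid_3:1/4:0", "complex"))),
    mechanism = table(factor(e$mechanism, levels = c("SCB", "DSCB"))))
  conv <- events[events$kind %in% c("NCO_conversion", "CO_with_conversion") &
                   events$mechanism %in% c("SCB", "DSCB"), , drop = FALSE]
  m <- matrix(0L, 2, 2, dimnames = list(c("NCO", "CO_associated"),
                                        c("SCB", "DSCB")))
  if (nrow(conv)) {
    t2 <- table(factor(ifelse(conv$kind == "NCO_conversion", "NCO",
                              "CO_associated"),
                       levels = c("NCO", "CO_associated")),
                factor(conv$mechanism, levels = c("SCB", "DSCB")))
    m[] <- as.integer(t2)
  }
  structure(list(kind_counts = tab(events)$kind,
                 pattern_counts = tab(events)$pattern,
                 mechanism_by_association = m,
                 selected = tab(events[sel, , drop = FALSE]),
                 unselected = tab(events[!sel, , drop = FALSE]),
                 n_selected = sum(sel), n_total = nrow(events)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: %d events (%d on the selected arm)\n",
              x$n_total, x$n_selected))
  print(x$kind_counts)
  cat("conversions, mechanism by crossover association:\n")
  print(x$mechanism_by_association)
  invisible(x)
}

#' Write classified events as JSON lines and their maximal tracts as BED
#'
#' @param events a `recomb_events` data.frame
#' @param prefix output prefix; writes `<prefix>.events.jsonl` and
#'   `<prefix>.tracts.bed`
#' @return paths, invisibly
#' @export
write_events <- function(events, prefix) {
  p1 <- paste0(prefix, ".events.jsonl")
  con <- file(p1, "w"); on.exit(close(con))
  for (i in seq_len(nrow(events)))
    writeLines(as.character(jsonlite::toJSON(as.list(events[i, ]),
                                             auto_unbox = TRUE,
                                             na = "null")), con)
  p2 <- paste0(prefix, ".tracts.bed")
  tr <- events[!is.na(events$tract_start), , drop = FALSE]
  if (nrow(tr))
    write_bed(data.frame(chrom = tr$chrom, start = tr$tract_start,
                         end = tr$tract_end, class = tr$kind), p2)
  else writeLines(character(), p2)
  invisible(c(p1, p2))
}
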
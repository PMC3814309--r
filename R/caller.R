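#' Call per-SNP zygosity states from allele-specific hybridization ratios
#'
#' Default rule: a SNP is `HOM_P1` when the P1 channel reads at least
#' `hom_hi` (1.4) and the P2 channel at most `hom_lo` (0.6); `HOM_P2`
#' symmetrically; `HET` when both channels lie inside the heterozygous band
#' `[het_lo, het_hi]` (0.7-1.3); anything else is `NOCALL`.
#'
#' @param ratios data.frame with columns `chrom`, `pos`, `ratio_P1`,
#'   `ratio_P2` (and optionally `snp_id`), as written by [simulate_array()]
#' @param thresholds named list overriding `hom_hi`, `hom_lo`, `het_lo`,
#'   `het_hi`
#' @return `ratios` with a `state` column added
#' @export
call_states <- function(ratios, thresholds = list()) {
  th <- utils::modifyList(list(hom_hi = 1.4, hom_lo = 0.6,
                               het_lo = 0.7, het_hi = 1.3), thresholds)
  if (!all(c("ratio_P1", "ratio_P2") %in% names(ratios)))
    stop("ratios must have columns ratio_P1 and ratio_P2")
  r1 <- ratios$ratio_P1; r2 <- ratios$ratio_P2
  if (any(r1 < 0 | r2 < 0, na.rm = TRUE)) stop("negative hybridization ratio")
  state <- rep("NOCALL", length(r1))
  state[r1 >= th$hom_hi & r2 <= th$hom_lo] <- "HOM_P1"
  state[r2 >= th$hom_hi & r1 <= th$hom_lo] <- "HOM_P2"
  het <- r1 >= th$het_lo & r1 <= th$het_hi & r2 >= th$het_lo & r2 <= th$het_hi
  state[het] <- "HET"
  ratios$state <- state
  ratios
}

#' Segment per-SNP states into LOH blocks with transition bounds
#'
#' Homozygous runs of fewer than `min_run` SNPs are relabelled `NOCALL` and
#' absorbed into their neighbours (single-SNP discordances are treated as
#' noise, so an LOH segment needs at least `min_run` supporting SNPs);
#' `NOCALL` SNPs never interrupt a run.  Each boundary
#' between segments of different state is recorded as a transition whose
#' inner bound is the position of the last SNP of the left segment and whose
#' outer bound is the position of the first SNP of the right segment — the
#' minimal/maximal localisation that the marker resolution allows.
#'
#' @param calls data.frame with columns `chrom`, `pos`, `state` (and
#'   optionally `snp_id`), SNPs ordered by position within chromosome;
#'   typically the output of [call_states()]
#' @param min_run minimum run length for a called segment (default 2)
#' @return object of class `sector_call`: list with `states` (per-SNP, after
#'   absorption), `segments` and `transitions` data.frames
#' @export
segment_states <- function(calls, min_run = 2) {
  if (nrow(calls) == 0) {
    return(structure(list(
      states = data.frame(chrom = character(), pos = numeric(),
                          snp_id = character(), raw_state = character(),
                          state = character()),
      segments = data.frame(chrom = character(), state = character(),
                            first_pos = numeric(), last_pos = numeric(),
                            n_snps = integer()),
      transitions = data.frame(chrom = character(), inner = numeric(),
                               outer = numeric(), left_state = character(),
                               right_state = character()),
      min_run = min_run), class = "sector_call"))
  }
  if (is.null(calls$snp_id)) calls$snp_id <- paste0(calls$chrom, "_", calls$pos)
  out_states <- list(); out_segs <- list(); out_trans <- list()
  for (nm in unique(calls$chrom)) {
    d <- calls[calls$chrom == nm, , drop = FALSE]
    st <- d$state
    repeat {
      idx <- which(st != "NOCALL")
      if (!length(idx)) break
      r <- rle(st[idx])
      short <- r$lengths < min_run & r$values != "HET"
      if (!any(short)) break
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(short)) st[idx[starts[k]:ends[k]]] <- "NOCALL"
    }
    idx <- which(st != "NOCALL")
    segs <- NULL; trans <- NULL
    if (length(idx)) {
      r <- rle(st[idx])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      segs <- data.frame(chrom = nm, state = r$values,
                         first_pos = d$pos[idx[starts]],
                         last_pos = d$pos[idx[ends]],
                         n_snps = r$lengths)
      if (nrow(segs) > 1) {
        k <- seq_len(nrow(segs) - 1)
        trans <- data.frame(chrom = nm,
                            inner = segs$last_pos[k],
                            outer = segs$first_pos[k + 1],
                            left_state = segs$state[k],
                            right_state = segs$state[k + 1])
      }
    }
    out_states[[nm]] <- data.frame(chrom = nm, pos = d$pos,
                                   snp_id = d$snp_id,
                                   raw_state = d$state, state = st)
    out_segs[[nm]] <- segs
    out_trans[[nm]] <- trans
  }
  bind <- function(l, proto) {
    l <- Filter(Negate(is.null), l)
    if (length(l)) { x <- do.call(rbind, l); rownames(x) <- NULL; x }
    else proto
  }
  structure(list(
    states = bind(out_states, NULL),
    segments = bind(out_segs,
                    data.frame(chrom = character(), state = character(),
                               first_pos = numeric(), last_pos = numeric(),
                               n_snps = integer())),
    transitions = bind(out_trans,
                       data.frame(chrom = character(), inner = numeric(),
                                  outer = numeric(),
                                  left_state = character(),
                                  right_state = character())),
    min_run = min_run), class = "sector_call")
}

#' Build a sector call directly from a zygosity track
#'
#' Convenience wrapper used for noise-free round trips: takes a track with a
#' `state` column (e.g. a daughter track from [segregate()]) and segments it
#' as if every SNP had been called confidently.
#'
#' @param track data.frame with `chrom`, `pos`, `state`
#' @param min_run passed to [segment_states()]
#' @return a `sector_call`
#' @export
sector_call_from_states <- function(track, min_run = 2) {
  segment_states(track[, intersect(c("chrom", "pos", "snp_id", "state"),
                                   names(track))], min_run = min_run)
}

#' Call and segment one sector in one step
#'
#' @param ratios ratio table (see [call_states()])
#' @param thresholds passed to [call_states()]
#' @param min_run passed to [segment_states()]
#' @return a `sector_call`
#' @export
call_sector <- function(ratios, thresholds = list(), min_run = 2) {
  segment_states(call_states(ratios, thresholds), min_run = min_run)
}

#' @export
print.sector_call <- function(x, ...) {
  n_loh <- sum(x$segments$state != "HET")
  cat(sprintf("sector_call: %d SNPs, %d segments (%d LOH), %d transitions\n",
              nrow(x$states), nrow(x$segments), n_loh, nrow(x$transitions)))
  if (n_loh) print(x$segments[x$segments$state != "HET", ])
  invisible(x)
}

#' Plot the zygosity track of a sector
#'
#' One horizontal track per chromosome; SNPs coloured by state (HET grey,
#' HOM_P1 red, HOM_P2 black, NOCALL pale).
#'
#' @param x a `sector_call`
#' @param chroms chromosomes to show (default: all with an LOH segment)
#' @param ... unused
#' @export
plot.sector_call <- function(x, chroms = NULL, ...) {
  if (is.null(chroms)) {
    chroms <- unique(x$segments$chrom[x$segments$state != "HET"])
    if (!length(chroms)) chroms <- unique(x$states$chrom)[1]
  }
  cols <- c(HET = "grey60", HOM_P1 = "red", HOM_P2 = "black",
            NOCALL = "grey90")
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (nm in chroms) {
    d <- x$states[x$states$chrom == nm, ]
    graphics::plot(d$pos / 1000, rep(1, nrow(d)), pch = "|",
                   col = cols[d$state], ylab = nm, xlab = "kb",
                   yaxt = "n", ylim = c(0.5, 1.5))
  }
  invisible(x)
}

#' Write sector call outputs
#'
#' Per-SNP calls as TSV, LOH segments as BED (0-based half-open) and
#' transitions as JSON.
#'
#' @param call a `sector_call`
#' @param prefix output path prefix; writes `<prefix>.calls.tsv`,
#'   `<prefix>.segments.bed`, `<prefix>.transitions.json`
#' @return the three paths, invisibly
#' @export
write_sector_call <- function(call, prefix) {
  p1 <- paste0(prefix, ".calls.tsv")
  utils::write.table(call$states, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- paste0(prefix, ".segments.bed")
  loh <- call$segments[call$segments$state != "HET", , drop = FALSE]
  if (nrow(loh)) {
    write_bed(data.frame(chrom = loh$chrom, start = loh$first_pos,
                         end = loh$last_pos, class = loh$state), p2)
  } else writeLines(character(), p2)
  p3 <- paste0(prefix, ".transitions.json")
  jsonlite::write_json(call$transitions, p3, dataframe = "rows")
  invisible(c(p1, p2, p3))
}
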
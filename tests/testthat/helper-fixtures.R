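# Small two-chromosome genome with SNPs every 2 kb, used wherever the full
# default genome would be overkill.
tiny_genome <- function() {
  chroms <- data.frame(name = c("chr1", "chr2"),
                       length = c(200000L, 150000L),
                       centromere = c(80000L, 60000L))
  snps <- rbind(
    data.frame(chrom = "chr1", pos = seq(10000L, 190000L, by = 2000L)),
    data.frame(chrom = "chr2", pos = seq(10000L, 140000L, by = 2000L)))
  map <- snp_map(chroms, snps)
  marker <- marker_config("chr1", pos = 11000L, carrier = "P1",
                          interval_start = 11000L, interval_end = 80000L)
  ann <- data.frame(chrom = "chr2", start = c(20001L, 100001L),
                    end = c(30000L, 110000L), class = "rDNA")
  list(map = map, marker = marker,
       annotations = annotation_set(ann, map))
}

# deterministic repair settings: one pathway, no patchiness/restoration
det_config <- function(pathway = "sdsa", dscb_equal = 1, tract_kb = 6,
                       ...) {
  pw <- c(sdsa = 0, dsbr_co = 0, dsbr_nco = 0, bir = 0)
  pw[pathway] <- 1
  sim_config(pathway_probs = pw, patchy_repair_prob = 0,
             restoration_prob = 0, dscb_equal_tract_prob = dscb_equal,
             tract_median_kb = tract_kb, tract_median_co_kb = tract_kb, ...)
}

# build a state track data.frame for classifier tests
states_track <- function(chrom, pos, state) {
  n <- length(pos)
  data.frame(chrom = rep(chrom, n), pos = pos, state = state,
             snp_id = if (n) paste0(rep(chrom, n), "_", pos) else character())
}

# gamma draws with an exact target median (matches the simulator's family)
rgamma_med <- function(n, median, shape = 2) {
  stats::rgamma(n, shape, scale = median / stats::qgamma(0.5, shape))
}

# exact two-sided Mann-Whitney p by complete enumeration of rank assignments
# (independent of the implementation under test; tie-free inputs only)
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  u_all <- apply(combos, 2, function(ix) sum(all_ranks[ix])) -
    n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Monte-Carlo oracle for the closely-opposed pair expectation
mc_closely_opposed <- function(n_dimers, genome_len, max_sep, reps) {
  counts <- vapply(seq_len(reps), function(r) {
    pos <- sort(floor(stats::runif(n_dimers, 1, genome_len + 1)))
    strand <- sample(1:2, n_dimers, replace = TRUE)
    hits <- 0L
    k <- 1L
    while (k < n_dimers) {   # widen the neighbour rank until out of range
      i <- seq_len(n_dimers - k); j <- i + k
      close <- pos[j] - pos[i] <= max_sep
      if (!any(close)) break
      hits <- hits + sum(close & strand[i] != strand[j])
      k <- k + 1L
    }
    hits
  }, 0L)
  list(mean = mean(counts), se = stats::sd(counts) / sqrt(reps))
}

# fraction of reference events recovered by a called event of the same kind
# and pattern (matched by chromosome and region overlap)
recovery_fraction <- function(called, ref) {
  if (!nrow(ref)) return(NA_real_)
  ok <- vapply(seq_len(nrow(ref)), function(i) {
    cand <- called[called$chrom == ref$chrom[i] &
                     called$region_start <= ref$region_end[i] &
                     called$region_end >= ref$region_start[i], , drop = FALSE]
    any(cand$kind == ref$kind[i] & cand$pattern == ref$pattern[i])
  }, TRUE)
  mean(ok)
}
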
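#' SNP map of a heterozygous diploid genome
#'
#' A `snp_map` holds the coordinate system shared by the simulator, the LOH
#' caller and the event classifier: chromosome names and lengths, centromere
#' positions, and the ordered list of heterozygous SNP markers assayed by the
#' array.  The two parents are abstract roles `P1` and `P2` (by convention
#' displayed red and black); every SNP is heterozygous `P1/P2` in the starting
#' diploid.
#'
#' Coordinates are 1-based inclusive throughout the package; BED exports are
#' converted to 0-based half-open on write.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp) and
#'   optionally `centromere` (bp; defaults to 40% of the length).
#' @param snps data.frame with columns `chrom`, `pos` (1-based bp) and
#'   optionally `snp_id` (generated when absent).
#' @return An object of class `snp_map`: a list with elements `chromosomes`
#'   and `snps` (sorted by chromosome then position).
#' @examples
#' g <- snp_map(data.frame(name = "chr1", length = 1e5),
#'              data.frame(chrom = "chr1", pos = c(1e4, 5e4, 9e4)))
#' g
#' @export
snp_map <- function(chromosomes, snps) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(snps))
  if (!all(c("name", "length") %in% names(chromosomes)))
    stop("`chromosomes` needs columns name, length")
  if (!all(c("chrom", "pos") %in% names(snps)))
    stop("`snps` needs columns chrom, pos")
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (is.null(chromosomes$centromere))
    chromosomes$centromere <- round(0.4 * chromosomes$length)
  snps$chrom <- as.character(snps$chrom)
  bad <- setdiff(unique(snps$chrom), chromosomes$name)
  if (length(bad))
    stop("SNPs on unknown chromosome(s): ", paste(bad, collapse = ", "))
  snps <- snps[order(match(snps$chrom, chromosomes$name), snps$pos), ,
               drop = FALSE]
  rownames(snps) <- NULL
  if (is.null(snps$snp_id))
    snps$snp_id <- paste0(snps$chrom, "_", snps$pos)
  len <- chromosomes$length[match(snps$chrom, chromosomes$name)]
  if (any(snps$pos < 1 | snps$pos > len))
    stop("SNP position outside chromosome bounds")
  dup <- unlist(lapply(split(snps$pos, snps$chrom), duplicated))
  if (any(dup))
    stop("duplicate SNP positions within a chromosome")
  structure(list(chromosomes = chromosomes,
                 snps = snps[, c("chrom", "pos", "snp_id")]),
            class = "snp_map")
}

#' @export
print.snp_map <- function(x, ...) {
  cat(sprintf("snp_map: %d chromosomes, %.2f Mb, %d heterozygous SNPs\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$snps)))
  sp <- mean_snp_spacing(x)
  cat(sprintf("mean inter-SNP spacing: %.2f kb\n", sp / 1000))
  invisible(x)
}

#' Mean inter-SNP spacing (bp) across chromosomes
#' @param map a [snp_map()]
#' @return mean distance in bp between adjacent SNPs on the same chromosome
#' @export
mean_snp_spacing <- function(map) {
  d <- unlist(lapply(split(map$snps$pos, map$snps$chrom), diff),
              use.names = FALSE)
  mean(d)
}

#' Read a SNP map from a tab-separated file
#'
#' The file must have a header with columns `chromosome`, `position`,
#' `snp_id` (1-based positions).  Chromosome lengths are taken from an
#' optional `lengths` data.frame or, when absent, set to the last SNP
#' position plus 20 kb.
#'
#' @param path TSV file path.
#' @param lengths optional data.frame with columns `name`, `length`,
#'   optionally `centromere`.
#' @return a [snp_map()]
#' @export
load_snp_map <- function(path, lengths = NULL) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed SNP map file '", path, "': ",
                             conditionMessage(e)))
  need <- c("chromosome", "position", "snp_id")
  if (!all(need %in% names(tab)))
    stop("SNP map file must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(tab$position) || anyNA(tab$position)) {
    bad <- which(!grepl("^[0-9]+$", as.character(tab$position)))[1]
    stop("malformed position at data line ", bad)
  }
  for (ch in unique(tab$chromosome)) {
    p <- tab$position[tab$chromosome == ch]
    if (is.unsorted(p, strictly = FALSE))
      stop("positions not sorted within chromosome ", ch)
  }
  snps <- data.frame(chrom = tab$chromosome, pos = tab$position,
                     snp_id = tab$snp_id, stringsAsFactors = FALSE)
  if (is.null(lengths)) {
    lengths <- do.call(rbind, lapply(split(snps, snps$chrom), function(s)
      data.frame(name = s$chrom[1], length = max(s$pos) + 20000L)))
    lengths <- lengths[order(lengths$name), , drop = FALSE]
  }
  snp_map(lengths, snps)
}

#' Write a SNP map to a tab-separated file
#' @param map a [snp_map()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_snp_map <- function(map, path) {
  out <- data.frame(chromosome = map$snps$chrom, position = map$snps$pos,
                    snp_id = map$snps$snp_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Colour-marker and selected-interval configuration
#'
#' Describes the terminal copy-number reporter (an ochre-suppressor-style
#' marker whose 0/1/2 copies give red/pink/white colonies) and the selected
#' centromere-to-marker interval used to score crossover sectoring.
#'
#' @param chrom chromosome carrying the marker
#' @param pos marker position (bp)
#' @param carrier homolog carrying the marker, `"P1"` or `"P2"`
#' @param interval_start,interval_end selected interval bounds (bp); by
#'   convention the centromere-proximal bound is the centromere and the distal
#'   bound is the marker.
#' @return object of class `marker_config`
#' @export
marker_config <- function(chrom, pos, carrier = "P1",
                          interval_start, interval_end) {
  carrier <- match.arg(carrier, c("P1", "P2"))
  if (!(pos <= interval_start || pos >= interval_end))
    stop("colour marker must be at or beyond the selected interval's outer bound")
  structure(list(chrom = chrom, pos = pos, carrier = carrier,
                 interval_start = interval_start,
                 interval_end = interval_end),
            class = "marker_config")
}

#' Annotation interval classes
#'
#' Interval classes (LTR, tRNA, non-coding RNA, rDNA, ...) used for element
#' enrichment and for regional expectation tests.  Intervals are 1-based
#' inclusive.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `class`
#' @param map a [snp_map()] supplying chromosome bounds
#' @return object of class `annotation_set`; `rdna_fraction` is the fraction
#'   of the genome covered by intervals of class `"rDNA"` (NA when absent)
#' @export
annotation_set <- function(intervals, map) {
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(intervals)))
  len <- map$chromosomes$length[match(intervals$chrom, map$chromosomes$name)]
  if (anyNA(len) || any(intervals$start < 1) || any(intervals$end > len) ||
      any(intervals$start > intervals$end))
    stop("annotation interval outside chromosome bounds")
  rd <- intervals$class == "rDNA"
  frac <- if (any(rd))
    sum(intervals$end[rd] - intervals$start[rd] + 1) /
      sum(map$chromosomes$length) else NA_real_
  structure(list(intervals = intervals, rdna_fraction = frac),
            class = "annotation_set")
}

#' Read annotation intervals from a BED file
#'
#' BED input is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention.  The BED `name` column supplies the class.
#'
#' @param path BED file
#' @param map a [snp_map()]
#' @return an [annotation_set()]
#' @export
load_annotations <- function(path, map) {
  gr <- rtracklayer::import(path, format = "BED")
  intervals <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    class = if (!is.null(gr$name)) gr$name else "unknown",
    stringsAsFactors = FALSE)
  annotation_set(intervals, map)
}

#' Write annotation intervals (or any interval table) as BED
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `class`/`name`
#' @param path output BED path
#' @return `path`, invisibly
#' @export
write_bed <- function(intervals, path) {
  nm <- if (!is.null(intervals$class)) intervals$class
        else if (!is.null(intervals$name)) intervals$name
        else rep(".", nrow(intervals))
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start,
                                                intervals$end),
                               name = nm)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Default chromosome lengths (kb): sixteen chromosomes totalling ~12.7 Mb,
# with one large chromosome carrying a 1.27 Mb rDNA-like cluster (~10% of the
# genome).  Lengths follow the familiar budding-yeast size spectrum.
.default_chrom_kb <- c(230, 800, 320, 1100, 577, 270, 1090, 560,
                       440, 745, 665, 2230, 920, 780, 1090, 950)

#' Build the default synthetic diploid genome
#'
#' Emulates the study system: a 16-chromosome, ~12.7 Mb diploid with ~13,000
#' heterozygous SNPs at ~1 kb mean spacing, a terminal colour marker defining
#' a ~120 kb selected interval between the centromere and the marker on one
#' chromosome, and an rDNA-like cluster occupying ~10% of the genome on one
#' large chromosome.  SNPs are excluded from 20 kb sub-telomeric ends (which
#' the array cannot assay) and from the rDNA cluster.
#'
#' @param seed integer seed; the same seed always yields the same genome
#' @param n_snps total number of SNPs to place (default 13000)
#' @return list with elements `map` ([snp_map()]), `marker`
#'   ([marker_config()]) and `annotations` ([annotation_set()])
#' @examples
#' g <- make_default_genome(seed = 1)
#' g$map
#' @export
make_default_genome <- function(seed = 1, n_snps = 13000) {
  chroms <- data.frame(
    name = sprintf("chr%02d", seq_along(.default_chrom_kb)),
    length = .default_chrom_kb * 1000L)
  chroms$centromere <- round(0.4 * chroms$length)
  # marker chromosome: centromere at 153 kb, marker at 33 kb on the left arm,
  # giving a 120 kb centromere-to-marker selected interval
  chroms$centromere[chroms$name == "chr05"] <- 153000L
  rdna <- data.frame(chrom = "chr12", start = 450001L, end = 1720000L,
                     class = "rDNA")  # 1.27 Mb
  tel_pad <- 20000L

  withr_seed <- .seed_rng(seed)
  on.exit(withr_seed(), add = TRUE)

  # SNP-eligible spans: outside sub-telomeric pads and outside the rDNA
  elig <- lapply(seq_len(nrow(chroms)), function(i) {
    s <- tel_pad + 1L
    e <- chroms$length[i] - tel_pad
    if (chroms$name[i] == rdna$chrom)
      rbind(c(s, rdna$start - 1L), c(rdna$end + 1L, e))
    else
      rbind(c(s, e))
  })
  span_len <- vapply(elig, function(m) sum(m[, 2] - m[, 1] + 1), 0)
  n_per <- stats::rmultinom(1, n_snps, span_len / sum(span_len))[, 1]
  snps <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    m <- elig[[i]]
    w <- (m[, 2] - m[, 1] + 1) / sum(m[, 2] - m[, 1] + 1)
    seg <- sample.int(nrow(m), n_per[i], replace = TRUE, prob = w)
    pos <- floor(stats::runif(n_per[i], m[seg, 1], m[seg, 2] + 1))
    pos <- sort(unique(pos))
    data.frame(chrom = chroms$name[i], pos = pos)
  }))
  map <- snp_map(chroms, snps)

  # a handful of small dispersed element annotations for enrichment analyses
  ann <- rdna
  for (cls in c("LTR", "tRNA", "ncRNA")) {
    n_el <- switch(cls, LTR = 180, tRNA = 150, ncRNA = 60)
    ch <- sample.int(nrow(chroms), n_el, replace = TRUE,
                     prob = chroms$length / sum(chroms$length))
    w <- switch(cls, LTR = 330L, tRNA = 80L, ncRNA = 600L)
    st <- floor(stats::runif(n_el, 1, chroms$length[ch] - w))
    ann <- rbind(ann, data.frame(chrom = chroms$name[ch], start = st,
                                 end = st + w - 1L, class = cls))
  }
  marker <- marker_config("chr05", pos = 33000L, carrier = "P1",
                          interval_start = 33000L, interval_end = 153000L)
  list(map = map, marker = marker,
       annotations = annotation_set(ann, map))
}

# Save and restore the RNG state around seeded construction, so building a
# default genome does not perturb an enclosing simulation's random stream.
.seed_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
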
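#' Tile a genome with sliding windows
#'
#' Builds the sliding-window lattice used throughout the package: windows of
#' `width` bp placed every `step` bp along each chromosome (the default
#' 100 kb / 50 kb grid gives 50% overlap between consecutive windows).
#' Windows are clipped at chromosome ends rather than dropped, so terminal
#' loci remain scoreable; every base of every chromosome is covered by at
#' least one window.
#'
#' @param genome A [sim_genome()], a chrom.sizes-style data.frame
#'   (`chrom`, `length`), or a named length vector.
#' @param width Window width in bp (default 100,000).
#' @param step Distance between consecutive window starts in bp
#'   (default 50,000); must satisfy `0 < step <= width`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), ordered by chromosome then start.
#' @examples
#' make_windows(c(chr1 = 250000), width = 100000, step = 50000)
#' @export
make_windows <- function(genome, width = 100000L, step = 50000L) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (step <= 0 || step > width) stop("step must be in (0, width]", call. = FALSE)
  tbl <- as_chrom_table(genome)
  pieces <- lapply(seq_len(nrow(tbl)), function(i) {
    L <- tbl$length[i]
    starts <- seq.int(0L, by = step, length.out = max(1L, ceiling(L / step)))
    starts <- starts[starts < L]
    data.frame(chrom = tbl$chrom[i],
               start = starts,
               end = pmin(starts + width, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Consensus peaks across replicates
#'
#' Reduces the replicate peak sets of one organ-sex group to the intervals
#' supported by all replicates. In `"intersect"` mode (the default) the
#' output is the genomic intersection of all replicate peak sets, i.e. the
#' intersection spans of peaks that overlap in every replicate; in `"union"`
#' mode it is the merged union. Peaks within each replicate are merged
#' before combining.
#'
#' @param peak_sets List of peak data.frames (`chrom`, `start`, `end`;
#'   0-based half-open), one per replicate.
#' @param mode `"intersect"` or `"union"`.
#' @param genome Optional genome; if supplied, peaks on chromosomes absent
#'   from the genome raise an error naming the offending records.
#' @return Peak data.frame (`chrom`, `start`, `end`), sorted.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 150, end = 250)
#' consensus_peaks(list(a, b)) # chr1:150-200
#' @export
consensus_peaks <- function(peak_sets, mode = c("intersect", "union"),
                            genome = NULL) {
  mode <- match.arg(mode)
  if (!is.list(peak_sets) || length(peak_sets) < 1L) {
    stop("need at least one replicate peak set", call. = FALSE)
  }
  if (!is.null(genome)) {
    chroms <- as_chrom_table(genome)$chrom
    for (i in seq_along(peak_sets)) {
      bad <- setdiff(unique(as.character(peak_sets[[i]]$chrom)), chroms)
      if (length(bad) > 0L) {
        stop(sprintf("replicate %d has peaks on chromosome(s) absent from the genome: %s",
                     i, paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  grs <- lapply(peak_sets, function(df) {
    stop_if_missing_cols(df, c("chrom", "start", "end"), "peak set")
    GenomicRanges::reduce(GenomicRanges::sort(intervals_to_gr(df)))
  })
  # pairwise-overlap intersection is much cheaper than the gaps-based
  # set intersection for many small peak sets
  intersect_gr <- function(x, y) {
    h <- GenomicRanges::findOverlaps(x, y)
    p <- GenomicRanges::pintersect(x[S4Vectors::queryHits(h)],
                                   y[S4Vectors::subjectHits(h)])
    S4Vectors::mcols(p) <- NULL
    GenomicRanges::reduce(p)
  }
  combine <- if (mode == "intersect") intersect_gr
             else function(x, y) GenomicRanges::reduce(c(x, y))
  out <- Reduce(combine, grs)
  gr_to_intervals(GenomicRanges::sort(out))
}

#' Count peaks per window by midpoint containment
#'
#' A peak is assigned to every window that contains its midpoint,
#' `floor((start + end) / 2)`. On the default 50%-overlap lattice every
#' midpoint therefore falls into exactly two windows, except within the
#' first `step` bases of a chromosome.
#'
#' @param windows Window data.frame from [make_windows()].
#' @param peaks Peak data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @return Integer vector of per-window peak counts, parallel to
#'   `windows` rows.
#' @export
count_peaks <- function(windows, peaks) {
  stop_if_missing_cols(windows, c("chrom", "start", "end"), "windows")
  stop_if_missing_cols(peaks, c("chrom", "start", "end"), "peaks")
  if (nrow(peaks) == 0L) return(integer(nrow(windows)))
  if (any(peaks$start < 0) || any(peaks$end <= peaks$start)) {
    stop("peaks must have 0 <= start < end", call. = FALSE)
  }
  mids <- floor((peaks$start + peaks$end) / 2)
  win_gr <- intervals_to_gr(windows)
  mid_gr <- points_to_gr(peaks$chrom, mids)
  GenomicRanges::countOverlaps(win_gr, mid_gr)
}
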
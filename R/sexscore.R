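#' Signed binomial sex-specificity score per window
#'
#' For each window, takes the median peak count across female organ-level
#' consensus sets and across male ones, rounds the medians to integers, and
#' tests the larger against the smaller with a one-sided binomial test at
#' null probability 0.5: with `f` and `m` the rounded medians,
#' `k = max(f, m)`, `n = f + m`, the p-value is the upper tail
#' `P(X >= k | n, 0.5)`. The score is `-log10(p)` signed positive when
#' females have more peaks and negative when males do; windows with equal
#' medians score 0, and windows with `f = m = 0` are additionally flagged
#' uninformative.
#'
#' @param female_counts,male_counts Matrix of per-window peak counts
#'   (rows = windows, columns = organ-level groups of that sex), or a
#'   vector for a single group.
#' @param round_mode How to integerise half-integer medians: `"half_up"`
#'   (default; 1.5 becomes 2), `"floor"` or `"ceiling"`.
#' @return data.frame with columns `f_med`, `m_med` (rounded integer
#'   medians), `p`, `score`, `uninformative`.
#' @examples
#' sex_score(3, 0) # p = 0.125, score ~ +0.903
#' @export
sex_score <- function(female_counts, male_counts,
                      round_mode = c("half_up", "floor", "ceiling")) {
  round_mode <- match.arg(round_mode)
  f_mat <- as.matrix(female_counts)
  m_mat <- as.matrix(male_counts)
  if (nrow(f_mat) != nrow(m_mat)) {
    stop("female and male count matrices must have the same number of windows",
         call. = FALSE)
  }
  if (any(f_mat < 0) || any(m_mat < 0)) {
    stop("peak counts must be non-negative", call. = FALSE)
  }
  rounder <- switch(round_mode,
                    half_up = round_half_up,
                    floor = floor,
                    ceiling = ceiling)
  f <- rounder(apply(f_mat, 1L, stats::median))
  m <- rounder(apply(m_mat, 1L, stats::median))
  n <- f + m
  k <- pmax(f, m)
  # upper-tail P(X >= k | n, 0.5); n = 0 gives p = 1 by convention
  p <- ifelse(n == 0, 1, stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE))
  score <- ifelse(f == m, 0, sign(f - m) * -log10(p))
  data.frame(f_med = f, m_med = m, p = p, score = score,
             uninformative = (f == 0 & m == 0))
}

#' Rank windows into female- and male-specific lists
#'
#' @param scores data.frame with window coordinates (`chrom`, `start`,
#'   `end`) plus the [sex_score()] columns.
#' @param top_k Number of windows to report per list (default all).
#' @return List with elements `female` (score > 0, descending by score) and
#'   `male` (score < 0, ascending by score, i.e. most male-specific first).
#'   Ties are broken by (chrom, start).
#' @export
rank_windows <- function(scores, top_k = Inf) {
  stop_if_missing_cols(scores, c("chrom", "start", "score"), "scores")
  take <- function(df, decreasing) {
    ord <- order(if (decreasing) -df$score else df$score,
                 df$chrom, df$start)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, top_k)
  }
  list(
    female = take(scores[scores$score > 0, , drop = FALSE], decreasing = TRUE),
    male = take(scores[scores$score < 0, , drop = FALSE], decreasing = FALSE)
  )
}

#' Genome-wide sex-specificity scan
#'
#' End-to-end wrapper: per organ-sex group, replicate peak sets are reduced
#' to consensus peaks; consensus peaks are counted on the sliding-window
#' lattice by midpoint containment; and each window receives the signed
#' binomial score of [sex_score()] comparing the median female count
#' against the median male count across organs.
#'
#' @param peak_sets Named list of peak data.frames, keyed by `sample_id`.
#' @param samples Sample sheet data.frame with columns `sample_id`, `sex`
#'   (`"female"`/`"male"`), `organ`, `replicate`; `sample_id` values must
#'   match `names(peak_sets)`.
#' @param genome Genome (see [make_windows()]).
#' @param width,step Window lattice parameters (defaults 100 kb / 50 kb).
#' @param consensus Replicate combination mode, see [consensus_peaks()].
#' @param round_mode Median rounding, see [sex_score()].
#' @return data.frame with window coordinates, per-window `f_med`, `m_med`,
#'   `p`, `score`, `uninformative`.
#' @export
scan_sex_specificity <- function(peak_sets, samples, genome,
                                 width = 100000L, step = 50000L,
                                 consensus = c("intersect", "union"),
                                 round_mode = "half_up") {
  consensus <- match.arg(consensus)
  stop_if_missing_cols(samples, c("sample_id", "sex", "organ", "replicate"),
                       "sample sheet")
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  if (!all(samples$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  missing_sets <- setdiff(samples$sample_id, names(peak_sets))
  if (length(missing_sets) > 0L) {
    stop(sprintf("no peak set supplied for sample(s): %s",
                 paste(missing_sets, collapse = ", ")), call. = FALSE)
  }
  if (length(unique(samples$organ[samples$sex == "female"])) < 1L ||
      length(unique(samples$organ[samples$sex == "male"])) < 1L) {
    stop("need at least one organ per sex", call. = FALSE)
  }

  windows <- make_windows(genome, width = width, step = step)
  groups <- unique(samples[, c("organ", "sex")])
  counts <- sapply(seq_len(nrow(groups)), function(i) {
    ids <- samples$sample_id[samples$organ == groups$organ[i] &
                               samples$sex == groups$sex[i]]
    cons <- consensus_peaks(peak_sets[ids], mode = consensus, genome = genome)
    count_peaks(windows, cons)
  })
  counts <- matrix(counts, nrow = nrow(windows))
  f_cols <- which(groups$sex == "female")
  m_cols <- which(groups$sex == "male")
  scores <- sex_score(counts[, f_cols, drop = FALSE],
                      counts[, m_cols, drop = FALSE],
                      round_mode = round_mode)
  cbind(windows, scores)
}
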
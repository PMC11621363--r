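#' Describe an F1 reciprocal-cross design
#'
#' @param maternal,paternal Strain labels (e.g. `"BL6"`, `"CAST"`); must
#'   differ. The cross `cross_design("BL6", "CAST")` is written BL6xCAST:
#'   mother BL6, father CAST.
#' @return Object of class `cross_design`.
#' @export
cross_design <- function(maternal, paternal) {
  if (identical(maternal, paternal)) {
    stop("maternal and paternal strains must differ", call. = FALSE)
  }
  structure(list(maternal = maternal, paternal = paternal),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("cross_design: %s (maternal) x %s (paternal)\n",
              x$maternal, x$paternal))
  invisible(x)
}

#' Orient strain-level counts to maternal/paternal columns
#'
#' Adds `maternal_count` and `paternal_count` columns by mapping the
#' strain-indexed count columns (`strain1_count`, `strain2_count`) through
#' the cross design. Counts are untouched; only the column mapping depends
#' on the cross direction.
#'
#' @param table data.frame with columns `strain1_count`, `strain2_count`.
#' @param cross A [cross_design()].
#' @param strains Character vector of length 2 naming the strains behind
#'   `strain1_count` and `strain2_count`, in that order.
#' @return `table` with `maternal_count` / `paternal_count` appended.
#' @export
orient_counts <- function(table, cross, strains) {
  stop_if_missing_cols(table, c("strain1_count", "strain2_count"),
                       "allele count table")
  if (length(strains) != 2L) stop("strains must have length 2", call. = FALSE)
  if (!setequal(strains, c(cross$maternal, cross$paternal))) {
    stop(sprintf("strain labels (%s) do not match the cross (%s x %s)",
                 paste(strains, collapse = ", "),
                 cross$maternal, cross$paternal), call. = FALSE)
  }
  if (strains[1] == cross$maternal) {
    table$maternal_count <- table$strain1_count
    table$paternal_count <- table$strain2_count
  } else {
    table$maternal_count <- table$strain2_count
    table$paternal_count <- table$strain1_count
  }
  table
}

#' Aggregate SNP-level allele counts to features
#'
#' Sums the allele counts of informative SNPs over annotation features. A
#' SNP contributes to a feature iff its total count is at least
#' `min_unit_coverage` and its position falls inside the feature interval
#' (0-based half-open, so a SNP exactly at `start` is included and one at
#' `end` is excluded). SNPs under several overlapping features contribute
#' to each, and such features are marked `ambiguous`. With a stranded
#' table, `stranded = TRUE` restricts SNPs to same-strand features.
#'
#' @param units data.frame of SNP (or other unit) counts: `chrom`, `start`
#'   (0-based position) and the two count columns named by `a_col`/`b_col`.
#' @param annotation data.frame of features: `feature_id`, `chrom`,
#'   `start`, `end` (and `strand` if `stranded`).
#' @param min_unit_coverage Minimum total count for a SNP to be informative
#'   (default 1 read).
#' @param a_col,b_col Names of the two count columns (defaults
#'   `maternal_count` / `paternal_count`, i.e. an [orient_counts()] output).
#' @param stranded Restrict SNPs to features on the same strand.
#' @return data.frame with one row per annotation feature: `feature_id`,
#'   the two summed count columns, `total`, `n_informative_units`,
#'   `ambiguous`.
#' @export
aggregate_feature_counts <- function(units, annotation, min_unit_coverage = 1,
                                     a_col = "maternal_count",
                                     b_col = "paternal_count",
                                     stranded = FALSE) {
  stop_if_missing_cols(units, c("chrom", "start", a_col, b_col), "unit table")
  stop_if_missing_cols(annotation, c("feature_id", "chrom", "start", "end"),
                       "annotation")
  if (anyDuplicated(annotation$feature_id)) {
    stop("feature_ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(units$chrom)),
                 unique(as.character(annotation$chrom)))
  if (length(bad) > 0L) {
    stop(sprintf("unit table has chromosome(s) absent from the annotation: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  a <- units[[a_col]]
  b <- units[[b_col]]
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative", call. = FALSE)
  informative <- (a + b) >= min_unit_coverage

  feat_gr <- intervals_to_gr(annotation)
  unit_gr <- points_to_gr(units$chrom, units$start)
  hits <- GenomicRanges::findOverlaps(unit_gr, feat_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (stranded) {
    if (!"strand" %in% names(units) || !"strand" %in% names(annotation)) {
      stop("stranded aggregation needs 'strand' in both tables", call. = FALSE)
    }
    same <- as.character(units$strand)[qh] == as.character(annotation$strand)[sh]
    qh <- qh[same]; sh <- sh[same]
  }
  # a SNP hitting >1 feature makes each of those features ambiguous
  multi_units <- unique(qh[duplicated(qh)])
  keep <- informative[qh]
  qh_k <- qh[keep]; sh_k <- sh[keep]

  n_feat <- nrow(annotation)
  sum_by <- function(x) {
    as.numeric(tapply(x[qh_k], factor(sh_k, levels = seq_len(n_feat)), sum,
                      default = 0))
  }
  out <- data.frame(
    feature_id = annotation$feature_id,
    stringsAsFactors = FALSE
  )
  out[[a_col]] <- sum_by(a)
  out[[b_col]] <- sum_by(b)
  out$total <- out[[a_col]] + out[[b_col]]
  out$n_informative_units <- as.integer(
    tapply(rep(1L, length(qh_k)), factor(sh_k, levels = seq_len(n_feat)), sum,
           default = 0))
  amb <- rep(FALSE, n_feat)
  amb[unique(sh[qh %in% multi_units])] <- TRUE
  out$ambiguous <- amb
  out
}

#' Allelic ratio with coverage filter and status call
#'
#' The maternal-allele fraction `r = maternal / (maternal + paternal)`,
#' reported only when the total passes the coverage filter `min_total`
#' (30 reads for gene-level RNA data, 50 for ATAC windows). By convention
#' 1 is fully maternal, 0.5 biallelic, 0 fully paternal. Status is
#' `maternal` when `r >= tau_hi`, `paternal` when `r <= tau_lo`,
#' `biallelic` in between, and `filtered` when `total < min_total`
#' (the ratio is then `NA`; a zero total never divides).
#'
#' @param maternal,paternal Non-negative count vectors.
#' @param min_total Coverage filter (default 30).
#' @param tau_hi,tau_lo Monoallelic thresholds (defaults 0.7 / 0.3,
#'   boundary inclusive).
#' @return data.frame `maternal`, `paternal`, `total`, `ratio`, `status`.
#' @examples
#' allelic_ratio(15, 15)            # ratio 0.5, biallelic
#' allelic_ratio(29, 0)             # filtered (total < 30)
#' allelic_ratio(40, 10)            # ratio 0.8, maternal
#' @export
allelic_ratio <- function(maternal, paternal, min_total = 30,
                          tau_hi = 0.7, tau_lo = 0.3) {
  if (length(maternal) != length(paternal)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (any(maternal < 0) || any(paternal < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (tau_lo >= tau_hi) stop("tau_lo must be below tau_hi", call. = FALSE)
  total <- maternal + paternal
  pass <- total >= min_total & total > 0
  ratio <- ifelse(pass, maternal / total, NA_real_)
  status <- rep("filtered", length(total))
  status[pass & ratio >= tau_hi] <- "maternal"
  status[pass & ratio <= tau_lo] <- "paternal"
  status[pass & ratio > tau_lo & ratio < tau_hi] <- "biallelic"
  data.frame(maternal = maternal, paternal = paternal, total = total,
             ratio = ratio,
             status = factor(status,
                             levels = c("maternal", "biallelic", "paternal",
                                        "filtered")))
}

#' Window-level allelic ratios
#'
#' Composition of [make_windows()], [aggregate_feature_counts()] and
#' [allelic_ratio()]: tiles the genome with 50 kb windows, sums informative
#' SNP counts per window, and reports the allelic ratio of windows with at
#' least `min_total` (default 50) reads.
#'
#' @inheritParams aggregate_feature_counts
#' @param genome Genome for [make_windows()].
#' @param width,step Window lattice (default 50 kb non-overlapping; pass
#'   `step < width` for a sliding lattice).
#' @param min_total Coverage filter per window (default 50).
#' @param min_unit_coverage Minimum SNP coverage (default 1).
#' @param tau_hi,tau_lo Status thresholds.
#' @return data.frame of windows (`chrom`, `start`, `end`) with the
#'   [allelic_ratio()] columns.
#' @export
window_allelic_ratios <- function(units, genome, width = 50000L,
                                  step = 50000L, min_total = 50,
                                  min_unit_coverage = 1,
                                  a_col = "maternal_count",
                                  b_col = "paternal_count",
                                  tau_hi = 0.7, tau_lo = 0.3) {
  windows <- make_windows(genome, width = width, step = step)
  windows$feature_id <- sprintf("%s:%d-%d", windows$chrom, windows$start,
                                windows$end)
  agg <- aggregate_feature_counts(units, windows,
                                  min_unit_coverage = min_unit_coverage,
                                  a_col = a_col, b_col = b_col)
  res <- allelic_ratio(agg[[a_col]], agg[[b_col]], min_total = min_total,
                       tau_hi = tau_hi, tau_lo = tau_lo)
  cbind(windows[, c("chrom", "start", "end", "feature_id")],
        n_informative_units = agg$n_informative_units, res)
}

#' Median allelic ratios across replicates per group
#'
#' Builds the heatmap-ready per-feature median ratio table: for each
#' feature and group (e.g. knockout strain), the median of replicate-level
#' ratios. Under `strict = TRUE` (the "informative across all strains"
#' rule) a feature that is filtered in any replicate of any group is
#' dropped from all groups.
#'
#' @param results Long data.frame with columns `feature_id`, `group`,
#'   `ratio`, `status` (one row per feature x replicate).
#' @param strict Drop features not informative everywhere (default TRUE).
#' @return Wide data.frame: `feature_id` plus one median-ratio column per
#'   group.
#' @export
median_ratios <- function(results, strict = TRUE) {
  stop_if_missing_cols(results, c("feature_id", "group", "ratio", "status"),
                       "ratio results")
  groups <- unique(as.character(results$group))
  for (g in groups) {
    if (sum(results$group == g) == 0L) stop("empty group", call. = FALSE)
  }
  if (strict) {
    bad <- unique(results$feature_id[results$status == "filtered" |
                                       is.na(results$ratio)])
    results <- results[!results$feature_id %in% bad, , drop = FALSE]
  }
  feats <- unique(results$feature_id)
  out <- data.frame(feature_id = feats, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- results[results$group == g, , drop = FALSE]
    med <- tapply(sub$ratio, factor(sub$feature_id, levels = feats),
                  stats::median, na.rm = TRUE)
    out[[g]] <- as.numeric(med)
  }
  out
}
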
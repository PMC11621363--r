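#' Configuration for synthetic sex-labeled peak sets
#'
#' Describes the ATAC-like peak experiment the scanner is meant to analyse:
#' several organs, both sexes, replicated peak calls, and a set of regions
#' where *female* samples carry an elevated peak density (the injected
#' female-specific loci).
#'
#' @param organs Character vector of organ labels (default six organs, as
#'   in a multi-organ accessibility survey).
#' @param replicates_per_sex Biological replicates per organ-sex
#'   (default 2).
#' @param baseline_rate Expected peaks per 100 kb everywhere (default 5).
#' @param enriched_windows data.frame (`chrom`, `start`, `end`, `fold`)
#'   of regions whose female peak density is multiplied by `fold`
#'   (`fold >= 1`); `NULL` for none.
#' @param peak_width_range Peak widths, drawn uniformly from this bp range
#'   (default 200-600).
#' @param jitter_sd Replicate-to-replicate positional jitter of a peak
#'   (bp, Gaussian, default 25). Replicates of one organ-sex re-emit a
#'   shared set of latent peak loci, as replicate peak calls of the same
#'   biological condition do; jitter models call-boundary wobble.
#' @param rep_reproducibility Probability that a replicate emits each
#'   latent peak (default 1: marginal per-replicate counts are exactly
#'   Poisson at `baseline_rate`).
#' @param seed Integer seed.
#' @return List of class `peak_sim_config`.
#' @export
peak_sim_config <- function(organs = c("brain", "heart", "kidney", "liver",
                                       "lung", "spleen"),
                            replicates_per_sex = 2,
                            baseline_rate = 5,
                            enriched_windows = NULL,
                            peak_width_range = c(200, 600),
                            jitter_sd = 25,
                            rep_reproducibility = 1,
                            seed = 1L) {
  if (baseline_rate <= 0) stop("baseline_rate must be positive", call. = FALSE)
  if (!is.null(enriched_windows)) {
    stop_if_missing_cols(enriched_windows, c("chrom", "start", "end", "fold"),
                         "enriched_windows")
    if (any(enriched_windows$fold < 1)) {
      stop("enrichment fold must be >= 1", call. = FALSE)
    }
  }
  if (length(peak_width_range) != 2L || any(peak_width_range <= 0) ||
      peak_width_range[1] > peak_width_range[2]) {
    stop("peak_width_range must be an increasing positive pair", call. = FALSE)
  }
  if (rep_reproducibility <= 0 || rep_reproducibility > 1) {
    stop("rep_reproducibility must be in (0, 1]", call. = FALSE)
  }
  structure(list(organs = organs, replicates_per_sex = replicates_per_sex,
                 baseline_rate = baseline_rate,
                 enriched_windows = enriched_windows,
                 peak_width_range = peak_width_range,
                 jitter_sd = jitter_sd,
                 rep_reproducibility = rep_reproducibility,
                 seed = as.integer(seed)),
            class = "peak_sim_config")
}

#' Generate sex-labeled peak sets with injected female-specific loci
#'
#' For each organ-sex group, latent peak loci are drawn from a Poisson
#' process at `baseline_rate` peaks per 100 kb; inside each enriched
#' window the rate is multiplied by `fold` for *female* groups only.
#' Each replicate re-emits the group's latent loci with positional jitter
#' (and, if `rep_reproducibility < 1`, independent dropout), so that
#' replicate-consensus intersection recovers the latent loci. Deterministic
#' given `cfg$seed`.
#'
#' @param genome A [sim_genome()].
#' @param cfg A [peak_sim_config()]; enriched windows must lie within the
#'   genome.
#' @return List with:
#'   * `peaks`: named list of peak data.frames (`chrom`, `start`, `end`),
#'     keyed `organ_sex_repN`;
#'   * `samples`: sample sheet (`sample_id`, `sex`, `organ`, `replicate`);
#'   * `truth`: list with `enriched_windows` (the injected regions) and
#'     `baseline_rate`.
#' @export
gen_peak_sets <- function(genome, cfg) {
  stopifnot(inherits(genome, "sim_genome"), inherits(cfg, "peak_sim_config"))
  chrom_tbl <- as_chrom_table(genome)
  enr <- cfg$enriched_windows
  if (!is.null(enr)) {
    idx <- match(as.character(enr$chrom), chrom_tbl$chrom)
    if (any(is.na(idx)) || any(enr$start < 0) ||
        any(enr$end > chrom_tbl$length[idx]) || any(enr$start >= enr$end)) {
      stop("enriched windows must lie within the genome", call. = FALSE)
    }
  }

  with_seed(cfg$seed, {
    peaks <- list()
    rows <- list()
    for (organ in cfg$organs) {
      for (sex in c("female", "male")) {
        latent <- sim_latent_peaks(chrom_tbl, cfg, female = (sex == "female"))
        for (rep_i in seq_len(cfg$replicates_per_sex)) {
          sample_id <- sprintf("%s_%s_rep%d", organ, sex, rep_i)
          peaks[[sample_id]] <- emit_replicate(latent, chrom_tbl, cfg)
          rows[[sample_id]] <- data.frame(sample_id = sample_id, sex = sex,
                                          organ = organ, replicate = rep_i,
                                          stringsAsFactors = FALSE)
        }
      }
    }
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
    truth <- list(enriched_windows = enr, baseline_rate = cfg$baseline_rate)
    list(peaks = peaks, samples = samples, truth = truth)
  })
}

# Latent loci for one organ-sex: Poisson baseline everywhere plus, for
# female groups, extra intensity (fold - 1) * baseline inside enriched
# windows.
sim_latent_peaks <- function(chrom_tbl, cfg, female) {
  per_chrom <- lapply(seq_len(nrow(chrom_tbl)), function(i) {
    L <- chrom_tbl$length[i]
    chrom <- chrom_tbl$chrom[i]
    n_base <- stats::rpois(1, cfg$baseline_rate * L / 1e5)
    starts <- floor(stats::runif(n_base, 0, L))
    if (female && !is.null(cfg$enriched_windows)) {
      ew <- cfg$enriched_windows
      ew <- ew[as.character(ew$chrom) == chrom, , drop = FALSE]
      for (j in seq_len(nrow(ew))) {
        lambda <- cfg$baseline_rate * (ew$fold[j] - 1) *
          (ew$end[j] - ew$start[j]) / 1e5
        n_extra <- stats::rpois(1, lambda)
        starts <- c(starts, floor(stats::runif(n_extra, ew$start[j], ew$end[j])))
      }
    }
    widths <- floor(stats::runif(length(starts), cfg$peak_width_range[1],
                                 cfg$peak_width_range[2] + 1))
    data.frame(chrom = chrom, start = starts, width = widths,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_chrom)
}

emit_replicate <- function(latent, chrom_tbl, cfg) {
  keep <- if (cfg$rep_reproducibility < 1) {
    stats::runif(nrow(latent)) < cfg$rep_reproducibility
  } else rep(TRUE, nrow(latent))
  df <- latent[keep, , drop = FALSE]
  jit <- round(stats::rnorm(nrow(df), 0, cfg$jitter_sd))
  L <- chrom_tbl$length[match(df$chrom, chrom_tbl$chrom)]
  start <- pmax(0, pmin(df$start + jit, L - df$width))
  out <- data.frame(chrom = df$chrom, start = start, end = start + df$width,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label scan windows by overlap with injected enriched regions
#'
#' @param windows Window data.frame ([make_windows()]).
#' @param regions data.frame of regions (`chrom`, `start`, `end`), e.g.
#'   the `truth$enriched_windows` of [gen_peak_sets()].
#' @return Logical vector: window overlaps at least one region.
#' @export
label_windows <- function(windows, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(rep(FALSE, nrow(windows)))
  GenomicRanges::countOverlaps(intervals_to_gr(windows),
                               intervals_to_gr(regions)) > 0
}
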
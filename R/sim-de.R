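#' Generate differential-expression tables with controlled overlap
#'
#' Builds two DE result tables (gene, chromosome, shrunk log2 fold change,
#' FDR) whose significant sets have a configured size, overlap and
#' direction concordance, plus a ground-truth direction table. Significant
#' genes receive `fdr` strictly below 0.01 and `|log2fc| >= 1` by
#' construction; null genes receive `fdr > 0.01` so the downstream
#' threshold rule has perfect recall and precision on the truth.
#'
#' @param n_genes Universe size (default 12,000).
#' @param n_de Integer vector of significant-set sizes per condition
#'   (default `c(417, 103)`, the spleen knockout set sizes the overlap
#'   arithmetic is calibrated on).
#' @param shared_fraction Fraction of the smaller set shared with the
#'   other condition (default `73/103`).
#' @param concordant_fraction Fraction of shared genes with matching
#'   direction (default 1).
#' @param effect_size Upper bound of significant |log2fc|, drawn uniformly
#'   from `[1, effect_size]` (default 3).
#' @param x_fraction Probability a gene is X-linked (default 0.037).
#' @param conditions Condition labels (default `c("TKO", "dCF")`).
#' @param seed Integer seed.
#' @return List with `tables` (named list of DE data.frames `gene_id`,
#'   `chrom`, `log2fc`, `fdr`) and `truth` (data.frame `gene_id`,
#'   `condition`, `direction` over the significant genes).
#' @export
gen_de_tables <- function(n_genes = 12000, n_de = c(417, 103),
                          shared_fraction = 73 / 103,
                          concordant_fraction = 1, effect_size = 3,
                          x_fraction = 0.037,
                          conditions = c("TKO", "dCF"), seed = 1L) {
  if (length(n_de) != 2L || length(conditions) != 2L) {
    stop("exactly two conditions are supported", call. = FALSE)
  }
  if (any(n_de > n_genes)) stop("n_de must not exceed n_genes", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1 ||
      concordant_fraction < 0 || concordant_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (effect_size < 1) stop("effect_size must be >= 1", call. = FALSE)

  with_seed(seed, {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    chrom <- ifelse(stats::runif(n_genes) < x_fraction, "chrX",
                    paste0("chr", sample(1:19, n_genes, replace = TRUE)))
    n_shared <- round(shared_fraction * min(n_de))
    n_conc <- round(concordant_fraction * n_shared)

    pool <- sample.int(n_genes)
    shared_idx <- pool[seq_len(n_shared)]
    uniq1 <- pool[n_shared + seq_len(n_de[1] - n_shared)]
    uniq2 <- pool[n_shared + (n_de[1] - n_shared) + seq_len(n_de[2] - n_shared)]

    dir_shared_1 <- sample(c("up", "down"), n_shared, replace = TRUE)
    dir_shared_2 <- dir_shared_1
    if (n_shared > n_conc) {
      flip <- seq.int(n_conc + 1L, n_shared)
      dir_shared_2[flip] <- ifelse(dir_shared_1[flip] == "up", "down", "up")
    }

    build <- function(sig_idx, sig_dir) {
      fdr <- stats::runif(n_genes, 0.02, 1)
      lfc <- stats::rnorm(n_genes, 0, 0.25)
      fdr[sig_idx] <- stats::runif(length(sig_idx), 0, 0.009)
      mag <- stats::runif(length(sig_idx), 1, effect_size)
      lfc[sig_idx] <- ifelse(sig_dir == "up", mag, -mag)
      data.frame(gene_id = gene_id, chrom = chrom, log2fc = lfc, fdr = fdr,
                 stringsAsFactors = FALSE)
    }
    dir1 <- c(dir_shared_1, sample(c("up", "down"), length(uniq1), TRUE))
    dir2 <- c(dir_shared_2, sample(c("up", "down"), length(uniq2), TRUE))
    t1 <- build(c(shared_idx, uniq1), dir1)
    t2 <- build(c(shared_idx, uniq2), dir2)

    truth <- rbind(
      data.frame(gene_id = gene_id[c(shared_idx, uniq1)],
                 condition = conditions[1], direction = dir1,
                 stringsAsFactors = FALSE),
      data.frame(gene_id = gene_id[c(shared_idx, uniq2)],
                 condition = conditions[2], direction = dir2,
                 stringsAsFactors = FALSE)
    )
    tables <- stats::setNames(list(t1, t2), conditions)
    list(tables = tables, truth = truth)
  })
}
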
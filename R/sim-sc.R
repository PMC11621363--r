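#' Configuration for synthetic single-cell allele count matrices
#'
#' Emulates an allele-resolved 10x-style experiment on F1 hybrid spleen:
#' two genotypes (wild type and a heterozygous knockout), skewed random
#' XCI, escape genes expressed from both X's, an Xist-like gene expressed
#' only from the inactive X, doublet barcodes, and a configurable fraction
#' of cells generated outside the QC bounds.
#'
#' Strain 1 plays the CAST role of the classifier (`STRAIN1_Xa` = CAST
#' Xa). `skew` is the probability that a cell carries the strain-1 X
#' active; it can be a single number or a named vector per genotype. The
#' defaults are the definite-call Xa fractions observed in F1
#' BL6xCAST spleen: 0.677 for wild type and 0.848 for the heterozygous
#' triple knockout, whose deletion lies on the BL6 X.
#'
#' @param n_cells_per_genotype Barcodes per genotype (default 1,000).
#' @param genotypes Genotype labels (default `c("WT", "TKO-het")`).
#' @param skew Probability of strain-1 Xa; scalar or named per genotype
#'   (default `c(WT = 0.677, "TKO-het" = 0.848)`).
#' @param doublet_rate Probability a barcode holds two cells (default
#'   0.03).
#' @param per_cell_depth Negative-binomial per-cell total read model,
#'   `c(mu, size)` (default 8,000 / 4).
#' @param n_genes_autosomal,n_genes_X Gene universe (defaults 2,000 /
#'   200); 13 mitochondrial genes are always added on `chrM`.
#' @param n_escape Number of X-linked escape genes expressed from both X's
#'   (default 8; gene ids `escape_1` ...).
#' @param xist_weight Expression weight multiplier of the Xist-like gene
#'   relative to the median gene (default 6: highly expressed, yet a small
#'   enough share of X-linked reads that skewed singlets stay confidently
#'   monoallelic chromosome-wide).
#' @param mito_fraction Mean fraction of reads from mitochondrial genes
#'   (default 0.04).
#' @param noise_eps Per-read allele misassignment probability (default
#'   0.02).
#' @param qc_outlier_rate Fraction of barcodes generated to violate a QC
#'   bound (too shallow, too deep, or high-mitochondrial; default 0.02).
#' @param seed Integer seed.
#' @return List of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_cells_per_genotype = 1000,
                          genotypes = c("WT", "TKO-het"),
                          skew = c("WT" = 0.677, "TKO-het" = 0.848),
                          doublet_rate = 0.03,
                          per_cell_depth = c(mu = 8000, size = 4),
                          n_genes_autosomal = 2000, n_genes_X = 200,
                          n_escape = 8, xist_weight = 6,
                          mito_fraction = 0.04, noise_eps = 0.02,
                          qc_outlier_rate = 0.02, seed = 1L) {
  if (length(skew) == 1L && is.null(names(skew))) {
    skew <- stats::setNames(rep(skew, length(genotypes)), genotypes)
  }
  if (!all(genotypes %in% names(skew))) {
    stop("skew must be scalar or named for every genotype", call. = FALSE)
  }
  if (any(skew < 0 | skew > 1)) stop("skew must be in [0, 1]", call. = FALSE)
  if (doublet_rate < 0 || doublet_rate >= 0.5) {
    stop("doublet_rate must be in [0, 0.5)", call. = FALSE)
  }
  if (n_genes_X < n_escape + 1L) {
    stop("need at least n_escape + 1 X-linked genes (escapers plus Xist)",
         call. = FALSE)
  }
  if (noise_eps < 0 || noise_eps >= 0.5) {
    stop("noise_eps must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(n_cells_per_genotype = n_cells_per_genotype,
                 genotypes = genotypes, skew = skew[genotypes],
                 doublet_rate = doublet_rate,
                 per_cell_depth = per_cell_depth,
                 n_genes_autosomal = n_genes_autosomal,
                 n_genes_X = n_genes_X, n_escape = n_escape,
                 xist_weight = xist_weight, mito_fraction = mito_fraction,
                 noise_eps = noise_eps, qc_outlier_rate = qc_outlier_rate,
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

# Gene universe: autosomal genes, X genes (escape_* and Xist first), chrM.
sc_gene_table <- function(genome, cfg) {
  autosomes <- setdiff(genome$chrom, genome$x_chrom)
  n_auto <- cfg$n_genes_autosomal
  n_x <- cfg$n_genes_X
  esc_ids <- if (cfg$n_escape > 0) paste0("escape_", seq_len(cfg$n_escape))
             else character(0)
  x_ids <- c(esc_ids, "Xist",
             sprintf("xgene_%03d", seq_len(n_x - cfg$n_escape - 1L)))
  data.frame(
    gene_id = c(sprintf("agene_%04d", seq_len(n_auto)), x_ids,
                sprintf("mt_gene_%02d", 1:13)),
    chrom = c(autosomes[(seq_len(n_auto) - 1L) %% length(autosomes) + 1L],
              rep(genome$x_chrom, n_x), rep("chrM", 13)),
    stringsAsFactors = FALSE
  )
}

# Per-gene strain-1 read probability for a cell with the given Xa strain.
# Autosomal and mitochondrial genes are biallelic; X genes follow the Xa
# except escapers (0.5) and the Xist-like gene (Xi strain).
sc_strain1_prob <- function(genes, x_chrom, xa_strain1, eps) {
  p <- rep(0.5, nrow(genes))
  on_x <- genes$chrom == x_chrom
  esc <- grepl("^escape_", genes$gene_id)
  xist <- genes$gene_id == "Xist"
  xa_p <- if (xa_strain1) 1 - eps else eps
  p[on_x] <- xa_p
  p[on_x & esc] <- 0.5
  p[on_x & xist] <- 1 - xa_p
  p
}

#' Generate a single-cell allele count matrix with ground truth
#'
#' Each barcode holds one cell (or two, for doublets): the cell draws its
#' active-X strain by the genotype's skew, a total depth from the
#' negative-binomial depth model, distributes reads over the gene universe
#' by fixed per-gene expression weights, and splits each gene's reads
#' between strains by the gene's class (see [sc_sim_config()]). Doublet
#' barcodes are additive mixtures of two independently drawn cells of the
#' same genotype. QC-outlier barcodes are drawn with an out-of-bounds
#' depth or mitochondrial load. Deterministic given `cfg$seed`.
#'
#' @param genome A [sim_genome()].
#' @param cfg An [sc_sim_config()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with assays
#'   `counts` (= `strain1 + strain2`), `strain1`, `strain2`; `rowData`
#'   column `chrom`; `colData` columns `genotype`, `n_counts`,
#'   `n_features`, `mito_pct`. `metadata(sce)$truth` is a data.frame with
#'   per-barcode `genotype`, `is_doublet`, `xa_strain1` (first cell),
#'   `xa_strain1_2` (second cell of a doublet, else `NA`) and
#'   `qc_outlier`; `metadata(sce)$escape_gene_ids` and
#'   `metadata(sce)$xist_id` name the ground-truth escape and Xist-like
#'   genes.
#' @export
gen_sc_allele_counts <- function(genome, cfg) {
  stopifnot(inherits(genome, "sim_genome"), inherits(cfg, "sc_sim_config"))
  genes <- sc_gene_table(genome, cfg)

  with_seed(cfg$seed, {
    n_genes <- nrow(genes)
    # fixed expression weights; mito genes scaled to the target mito load,
    # Xist elevated
    w <- stats::rgamma(n_genes, shape = 0.8, rate = 1) + 0.05
    mito <- genes$chrom == "chrM"
    xist_i <- which(genes$gene_id == "Xist")
    w[xist_i] <- stats::median(w) * cfg$xist_weight
    w[mito] <- w[mito] / sum(w[mito]) *
      sum(w[!mito]) * cfg$mito_fraction / (1 - cfg$mito_fraction)
    w <- w / sum(w)

    n_bar <- cfg$n_cells_per_genotype * length(cfg$genotypes)
    genotype <- rep(cfg$genotypes, each = cfg$n_cells_per_genotype)
    is_doublet <- stats::runif(n_bar) < cfg$doublet_rate
    qc_outlier <- stats::runif(n_bar) < cfg$qc_outlier_rate

    mu <- cfg$per_cell_depth[[1]]
    size <- cfg$per_cell_depth[[2]]

    draw_cell <- function(geno, outlier_mode = "none") {
      xa1 <- stats::runif(1) < cfg$skew[[geno]]
      depth <- switch(outlier_mode,
        none = stats::rnbinom(1, mu = mu, size = size),
        shallow = stats::rpois(1, 300),
        deep = stats::rpois(1, 30000),
        mito = stats::rnbinom(1, mu = mu, size = size))
      wts <- w
      if (outlier_mode == "mito") {
        wts[mito] <- wts[mito] * 6  # ~20% mitochondrial load
        wts <- wts / sum(wts)
      }
      cnt <- stats::rmultinom(1, depth, wts)[, 1]
      nz <- which(cnt > 0)
      p1 <- sc_strain1_prob(genes, genome$x_chrom, xa1, cfg$noise_eps)
      s1 <- integer(n_genes)
      s1[nz] <- stats::rbinom(length(nz), cnt[nz], p1[nz])
      list(xa1 = xa1, s1 = s1, s2 = cnt - s1)
    }

    s1_mat <- matrix(0L, n_genes, n_bar)
    s2_mat <- matrix(0L, n_genes, n_bar)
    xa_1 <- logical(n_bar)
    xa_2 <- rep(NA, n_bar)
    for (i in seq_len(n_bar)) {
      mode <- if (qc_outlier[i]) sample(c("shallow", "deep", "mito"), 1)
              else "none"
      c1 <- draw_cell(genotype[i], mode)
      xa_1[i] <- c1$xa1
      s1_mat[, i] <- c1$s1
      s2_mat[, i] <- c1$s2
      if (is_doublet[i]) {
        c2 <- draw_cell(genotype[i], mode)
        xa_2[i] <- c2$xa1
        s1_mat[, i] <- s1_mat[, i] + c2$s1
        s2_mat[, i] <- s2_mat[, i] + c2$s2
      }
    }

    barcodes <- sprintf("cell_%05d", seq_len(n_bar))
    s1 <- Matrix::Matrix(s1_mat, sparse = TRUE,
                         dimnames = list(genes$gene_id, barcodes))
    s2 <- Matrix::Matrix(s2_mat, sparse = TRUE,
                         dimnames = list(genes$gene_id, barcodes))
    counts <- s1 + s2
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts, strain1 = s1, strain2 = s2),
      rowData = S4Vectors::DataFrame(chrom = genes$chrom,
                                     row.names = genes$gene_id),
      colData = S4Vectors::DataFrame(genotype = genotype,
                                     row.names = barcodes)
    )
    sce <- ensure_cell_metrics(sce)
    S4Vectors::metadata(sce)$truth <- data.frame(
      barcode = barcodes, genotype = genotype, is_doublet = is_doublet,
      xa_strain1 = xa_1, xa_strain1_2 = xa_2, qc_outlier = qc_outlier,
      stringsAsFactors = FALSE)
    S4Vectors::metadata(sce)$escape_gene_ids <-
      grep("^escape_", genes$gene_id, value = TRUE)
    S4Vectors::metadata(sce)$xist_id <- "Xist"
    sce
  })
}
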
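#' Single-cell QC parameters
#'
#' Bounds are strict (exclusive) on both sides, so e.g. a cell with exactly
#' 500 detected features is removed.
#'
#' @param min_features,max_features Detected-gene bounds (defaults 500 /
#'   5,000, exclusive).
#' @param min_counts,max_counts Total-count bounds (defaults 2,000 /
#'   20,000, exclusive).
#' @param max_mito_pct Mitochondrial read percentage bound (default 10,
#'   exclusive).
#' @param min_cells_per_gene Genes must be expressed in strictly more than
#'   this many cells after cell filtering (default 10).
#' @return List of class `cell_qc_params`.
#' @export
cell_qc_params <- function(min_features = 500, max_features = 5000,
                           min_counts = 2000, max_counts = 20000,
                           max_mito_pct = 10, min_cells_per_gene = 10) {
  if (min_features >= max_features || min_counts >= max_counts) {
    stop("QC lower bounds must lie below upper bounds", call. = FALSE)
  }
  if (max_mito_pct < 0 || max_mito_pct > 100) {
    stop("max_mito_pct must be in [0, 100]", call. = FALSE)
  }
  structure(list(min_features = min_features, max_features = max_features,
                 min_counts = min_counts, max_counts = max_counts,
                 max_mito_pct = max_mito_pct,
                 min_cells_per_gene = min_cells_per_gene),
            class = "cell_qc_params")
}

# Compute n_counts / n_features / mito_pct from the counts assay when the
# colData does not already carry them.
ensure_cell_metrics <- function(sce, mito_chroms = c("chrM", "MT")) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$n_counts)) cd$n_counts <- Matrix::colSums(counts)
  if (is.null(cd$n_features)) cd$n_features <- Matrix::colSums(counts > 0)
  if (is.null(cd$mito_pct)) {
    mito <- as.character(SummarizedExperiment::rowData(sce)$chrom) %in% mito_chroms
    mito_counts <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
    cd$mito_pct <- ifelse(cd$n_counts > 0, 100 * mito_counts / cd$n_counts, 0)
  }
  SummarizedExperiment::colData(sce) <- cd
  sce
}

#' Quality-control filter for a cell-by-gene allele count matrix
#'
#' Cells are kept iff they lie strictly inside all QC ranges (features,
#' counts, mitochondrial percentage). Genes are then kept iff expressed
#' (total count > 0) in strictly more than `min_cells_per_gene` of the
#' surviving cells. The attached report tallies removals per criterion
#' (a cell can fail several).
#'
#' @param sce [SingleCellExperiment::SingleCellExperiment] with assays
#'   `counts` (totals), `strain1`, `strain2`, a `chrom` column in
#'   `rowData`, and (optionally precomputed) `n_counts`, `n_features`,
#'   `mito_pct` in `colData`.
#' @param params A [cell_qc_params()].
#' @param mito_chroms Chromosome labels treated as mitochondrial when
#'   metrics must be computed (default `c("chrM", "MT")`).
#' @return List with `sce` (filtered) and `report` (list of per-criterion
#'   removal counts, cells/genes before and after).
#' @export
qc_filter <- function(sce, params = cell_qc_params(),
                      mito_chroms = c("chrM", "MT")) {
  stopifnot(inherits(params, "cell_qc_params"))
  sce <- ensure_cell_metrics(sce, mito_chroms)
  cd <- SummarizedExperiment::colData(sce)
  fail_feat_lo <- cd$n_features <= params$min_features
  fail_feat_hi <- cd$n_features >= params$max_features
  fail_cnt_lo <- cd$n_counts <= params$min_counts
  fail_cnt_hi <- cd$n_counts >= params$max_counts
  fail_mito <- cd$mito_pct >= params$max_mito_pct
  keep_cell <- !(fail_feat_lo | fail_feat_hi | fail_cnt_lo | fail_cnt_hi |
                   fail_mito)
  report <- list(
    n_cells_in = ncol(sce),
    removed_low_features = sum(fail_feat_lo),
    removed_high_features = sum(fail_feat_hi),
    removed_low_counts = sum(fail_cnt_lo),
    removed_high_counts = sum(fail_cnt_hi),
    removed_high_mito = sum(fail_mito),
    n_cells_removed = sum(!keep_cell),
    n_cells_kept = sum(keep_cell),
    n_genes_in = nrow(sce)
  )
  if (report$n_cells_kept == 0L) {
    stop(paste0("no cells survive QC (removed ", report$n_cells_removed,
                " of ", report$n_cells_in, ")"), call. = FALSE)
  }
  out <- sce[, keep_cell]
  counts <- SummarizedExperiment::assay(out, "counts")
  keep_gene <- Matrix::rowSums(counts > 0) > params$min_cells_per_gene
  report$removed_genes <- sum(!keep_gene)
  report$n_genes_kept <- sum(keep_gene)
  if (report$n_genes_kept == 0L) {
    stop("no genes survive QC", call. = FALSE)
  }
  out <- out[keep_gene, ]
  list(sce = out, report = report)
}

#' Classify each cell's active X chromosome
#'
#' Sums both allele layers over X-linked genes per cell and classifies the
#' cell from the chromosome-wide allelic ratio
#' `x_ratio = strain1 X reads / total X reads`:
#' `LOW_COVERAGE` when the total is below `min_x_reads` (default 10 reads),
#' otherwise `STRAIN1_Xa` when `x_ratio >= tau_hi` (boundary inclusive),
#' `STRAIN2_Xa` when `x_ratio <= tau_lo`, and `BIALLELIC_EXCLUDED` in
#' between (two apparent active X's, the doublet signature; such cells are
#' retained in the output but excluded from pseudobulk groups).
#'
#' @param sce SingleCellExperiment with `strain1` / `strain2` assays and a
#'   `chrom` column in `rowData`.
#' @param x_chrom X chromosome label (default `"chrX"`).
#' @param tau_hi,tau_lo Classification thresholds (defaults 0.7 / 0.3).
#' @param min_x_reads Minimum allelic reads over the X (default 10).
#' @return data.frame `barcode`, `x_total`, `x_ratio`, `state`.
#' @export
call_xa_state <- function(sce, x_chrom = "chrX", tau_hi = 0.7, tau_lo = 0.3,
                          min_x_reads = 10) {
  on_x <- as.character(SummarizedExperiment::rowData(sce)$chrom) == x_chrom
  if (!any(on_x)) stop("no X-linked genes in the matrix", call. = FALSE)
  s1 <- Matrix::colSums(SummarizedExperiment::assay(sce, "strain1")[on_x, , drop = FALSE])
  s2 <- Matrix::colSums(SummarizedExperiment::assay(sce, "strain2")[on_x, , drop = FALSE])
  x_total <- s1 + s2
  x_ratio <- ifelse(x_total > 0, s1 / x_total, NA_real_)
  state <- rep("BIALLELIC_EXCLUDED", ncol(sce))
  state[x_total >= min_x_reads & x_ratio >= tau_hi] <- "STRAIN1_Xa"
  state[x_total >= min_x_reads & x_ratio <= tau_lo] <- "STRAIN2_Xa"
  state[x_total < min_x_reads] <- "LOW_COVERAGE"
  data.frame(barcode = colnames(sce), x_total = x_total, x_ratio = x_ratio,
             state = factor(state, levels = c("STRAIN1_Xa", "STRAIN2_Xa",
                                              "BIALLELIC_EXCLUDED",
                                              "LOW_COVERAGE")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' XCI skewing summary per genotype
#'
#' Fractions of each Xa state among the cells with sufficient X coverage
#' (`LOW_COVERAGE` cells are excluded from the denominator and reported
#' separately).
#'
#' @param calls Output of [call_xa_state()].
#' @param genotypes Character vector of genotype labels, parallel to
#'   `calls` rows.
#' @return data.frame `genotype`, `state`, `n`, `fraction`, `pct`; the
#'   per-genotype `LOW_COVERAGE` counts are in attribute
#'   `"n_low_coverage"`.
#' @export
skew_summary <- function(calls, genotypes) {
  if (length(genotypes) != nrow(calls)) {
    stop("genotypes must be parallel to calls", call. = FALSE)
  }
  states <- c("STRAIN1_Xa", "STRAIN2_Xa", "BIALLELIC_EXCLUDED")
  out <- list()
  lowcov <- integer(0)
  for (g in unique(genotypes)) {
    sub <- calls[genotypes == g, , drop = FALSE]
    lowcov[g] <- sum(sub$state == "LOW_COVERAGE")
    informative <- sub[sub$state != "LOW_COVERAGE", , drop = FALSE]
    n <- table(factor(informative$state, levels = states))
    denom <- nrow(informative)
    frac <- if (denom > 0) as.numeric(n) / denom else rep(NA_real_, length(states))
    out[[g]] <- data.frame(genotype = g, state = states,
                           n = as.integer(n), fraction = frac,
                           pct = round(100 * frac, 2),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_low_coverage") <- lowcov
  res
}

#' Pseudobulk aggregation of allele counts by genotype and Xa state
#'
#' Sums the two allele layers over cells of each genotype x Xa-state group
#' (definite states only; `BIALLELIC_EXCLUDED` and `LOW_COVERAGE` cells are
#' left out). With a WT / TKO-het design this yields the four groups
#' WT-STRAIN1_Xa, WT-STRAIN2_Xa, TKO-het-STRAIN1_Xa, TKO-het-STRAIN2_Xa.
#'
#' @param sce SingleCellExperiment (post-QC).
#' @param calls Output of [call_xa_state()] for the same cells, same order.
#' @param genotypes Genotype label per cell.
#' @return Named list of groups, each a list with `counts` (data.frame
#'   `gene_id`, `chrom`, `strain1`, `strain2`) and `n_cells`. Empty groups
#'   are emitted with zero counts and a warning.
#' @export
pseudobulk <- function(sce, calls, genotypes) {
  if (nrow(calls) != ncol(sce) || length(genotypes) != ncol(sce)) {
    stop("calls and genotypes must be parallel to the matrix columns",
         call. = FALSE)
  }
  s1 <- SummarizedExperiment::assay(sce, "strain1")
  s2 <- SummarizedExperiment::assay(sce, "strain2")
  genes <- data.frame(
    gene_id = rownames(sce),
    chrom = as.character(SummarizedExperiment::rowData(sce)$chrom),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (g in unique(genotypes)) {
    for (st in c("STRAIN1_Xa", "STRAIN2_Xa")) {
      sel <- genotypes == g & calls$state == st
      label <- paste(g, st, sep = "-")
      if (!any(sel)) {
        warning(sprintf("pseudobulk group '%s' is empty", label),
                call. = FALSE)
        cnt <- cbind(genes, strain1 = 0, strain2 = 0)
      } else {
        cnt <- cbind(genes,
                     strain1 = Matrix::rowSums(s1[, sel, drop = FALSE]),
                     strain2 = Matrix::rowSums(s2[, sel, drop = FALSE]))
      }
      rownames(cnt) <- NULL
      out[[label]] <- list(counts = cnt, n_cells = sum(sel))
    }
  }
  out
}

#' Gene-level allelic profiles and escape calls from pseudobulk groups
#'
#' Applies the allelic-ratio engine (ratio oriented to strain1, total-read
#' filter `min_total`, default 30) to each pseudobulk group and annotates
#' X-linked genes: a gene is `escaping` in a group when it passes the
#' filter and its ratio lies strictly between `tau_lo` and `tau_hi`
#' (expression from both X's despite XCI); it is `xi_exclusive` when its
#' ratio is beyond the threshold opposite to the group's active-X strain
#' (the Xist signature: expressed only from the inactive X).
#'
#' @param pb Output of [pseudobulk()]. Group names must end in
#'   `-STRAIN1_Xa` / `-STRAIN2_Xa`.
#' @param x_chrom X chromosome label (default `"chrX"`).
#' @param min_total Pseudobulk coverage filter (default 30).
#' @param tau_hi,tau_lo Ratio thresholds (defaults 0.7 / 0.3).
#' @return Long data.frame: `group`, `gene_id`, `chrom`, `strain1`,
#'   `strain2`, `total`, `ratio`, `status`, `escaping`, `xi_exclusive`.
#' @export
gene_allelic_profile <- function(pb, x_chrom = "chrX", min_total = 30,
                                 tau_hi = 0.7, tau_lo = 0.3) {
  rows <- lapply(names(pb), function(label) {
    cnt <- pb[[label]]$counts
    res <- allelic_ratio(cnt$strain1, cnt$strain2, min_total = min_total,
                         tau_hi = tau_hi, tau_lo = tau_lo)
    xa1 <- grepl("STRAIN1_Xa$", label)
    on_x <- cnt$chrom == x_chrom
    pass <- res$status != "filtered"
    escaping <- on_x & pass & res$ratio > tau_lo & res$ratio < tau_hi
    xi_excl <- on_x & pass &
      if (xa1) res$ratio <= tau_lo else res$ratio >= tau_hi
    data.frame(group = label, gene_id = cnt$gene_id, chrom = cnt$chrom,
               strain1 = cnt$strain1, strain2 = cnt$strain2,
               total = res$total, ratio = res$ratio, status = res$status,
               escaping = escaping, xi_exclusive = xi_excl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
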
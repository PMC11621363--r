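#' Call differentially expressed genes from a DE result table
#'
#' Threshold rule with inclusive boundaries: a gene is significant iff
#' `fdr <= alpha` and `|log2fc| >= lfc` (defaults FDR 0.01 and shrunk
#' |log2FC| 1). Direction is the sign of the fold change.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `fdr`
#'   (`chrom` is carried through when present).
#' @param alpha FDR threshold (default 0.01, inclusive).
#' @param lfc Absolute log2 fold-change threshold (default 1, inclusive).
#' @param condition Optional condition label stored in the result.
#' @return data.frame of significant genes with a `direction` column
#'   (`"up"` / `"down"`); attribute `"condition"` carries the label and
#'   `"n_tested"` the input size.
#' @export
call_de <- function(table, alpha = 0.01, lfc = 1, condition = NULL) {
  stop_if_missing_cols(table, c("gene_id", "log2fc", "fdr"), "DE table")
  if (anyDuplicated(table$gene_id)) {
    stop("gene_ids must be unique within a DE table", call. = FALSE)
  }
  if (any(table$fdr < 0 | table$fdr > 1, na.rm = TRUE)) {
    stop("fdr values must lie in [0, 1]", call. = FALSE)
  }
  sig <- !is.na(table$fdr) & table$fdr <= alpha &
    !is.na(table$log2fc) & abs(table$log2fc) >= lfc
  out <- table[sig, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "condition") <- condition
  attr(out, "n_tested") <- nrow(table)
  out
}

#' Overlap, direction concordance and fold ratios between DE sets
#'
#' Pairwise: shared genes are the intersection by `gene_id`; concordant
#' genes are shared genes whose direction agrees; the concordance
#' percentage is `100 * concordant / reference size`, where the reference
#' defaults to the smaller of the two sets; the fold ratio is
#' `size(A) / size(B)` rounded to one decimal. For two or more sets a
#' sharing histogram counts the genes present in exactly k sets.
#'
#' @param sets Named list (>= 2) of [call_de()] outputs (data.frames with
#'   `gene_id` and `direction`).
#' @param reference Concordance denominator: `"smaller"` (default),
#'   `"first"`, or `"shared"`.
#' @return List with `pairwise` (data.frame `set_a`, `set_b`, `n_a`,
#'   `n_b`, `shared`, `concordant`, `concordance_pct`, `fold_ratio`) and
#'   `sharing` (data.frame `k`, `n_genes` over k = 1..number of sets).
#'   Concordance against an empty reference set is `NA`.
#' @examples
#' a <- data.frame(gene_id = c("g1", "g2"), direction = c("up", "down"))
#' b <- data.frame(gene_id = c("g1", "g3"), direction = c("up", "up"))
#' overlap_and_concordance(list(A = a, B = b))
#' @export
overlap_and_concordance <- function(sets,
                                    reference = c("smaller", "first",
                                                  "shared")) {
  reference <- match.arg(reference)
  if (!is.list(sets) || length(sets) < 2L) {
    stop("need at least two DE sets", call. = FALSE)
  }
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  for (s in sets) stop_if_missing_cols(s, c("gene_id", "direction"), "DE set")

  combos <- utils::combn(names(sets), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    na_ <- combos[1, i]; nb_ <- combos[2, i]
    a <- sets[[na_]]; b <- sets[[nb_]]
    shared_ids <- intersect(a$gene_id, b$gene_id)
    dir_a <- a$direction[match(shared_ids, a$gene_id)]
    dir_b <- b$direction[match(shared_ids, b$gene_id)]
    concordant <- sum(dir_a == dir_b)
    ref_size <- switch(reference,
                       smaller = min(nrow(a), nrow(b)),
                       first = nrow(a),
                       shared = length(shared_ids))
    conc_pct <- if (ref_size > 0) round(100 * concordant / ref_size, 2) else NA_real_
    fold <- if (nrow(b) > 0) round(nrow(a) / nrow(b), 1) else NA_real_
    data.frame(set_a = na_, set_b = nb_, n_a = nrow(a), n_b = nrow(b),
               shared = length(shared_ids), concordant = concordant,
               concordance_pct = conc_pct, fold_ratio = fold,
               stringsAsFactors = FALSE)
  }))
  rownames(pairwise) <- NULL

  all_ids <- unlist(lapply(sets, function(s) unique(s$gene_id)))
  k_per_gene <- table(all_ids)
  sharing <- data.frame(
    k = seq_along(sets),
    n_genes = sapply(seq_along(sets), function(k) sum(k_per_gene == k))
  )
  list(pairwise = pairwise, sharing = sharing)
}

#' Autosome / X partition of DE sets
#'
#' @param sets Named list of [call_de()] outputs carrying a `chrom` column.
#' @param x_chrom X chromosome label (default `"chrX"`).
#' @return data.frame `condition`, `n`, `pct_autosome`, `pct_x`, plus a
#'   final `"mean"` row with the unweighted mean percentages across
#'   conditions.
#' @export
chrom_partition <- function(sets, x_chrom = "chrX") {
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    stop_if_missing_cols(s, c("gene_id", "chrom"), "DE set")
    if (any(is.na(s$chrom))) {
      stop(sprintf("set '%s' has genes without a chromosome: %s", nm,
                   paste(utils::head(s$gene_id[is.na(s$chrom)], 5),
                         collapse = ", ")), call. = FALSE)
    }
    n <- nrow(s)
    n_x <- sum(s$chrom == x_chrom)
    data.frame(condition = nm, n = n,
               pct_autosome = if (n > 0) 100 * (n - n_x) / n else NA_real_,
               pct_x = if (n > 0) 100 * n_x / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(condition = "mean", n = NA_integer_,
                         pct_autosome = mean(out$pct_autosome, na.rm = TRUE),
                         pct_x = mean(out$pct_x, na.rm = TRUE),
                         stringsAsFactors = FALSE)
  rbind(out, mean_row)
}

#' Transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / L_g) / sum_j(c_j / L_j)`: counts are first
#' normalised by gene length (length in bp; the rate is per-base coverage),
#' then scaled so each sample sums to one million. Accepts a vector (one
#' sample) or a genes x samples matrix.
#'
#' @param counts Numeric vector or matrix of read counts.
#' @param lengths Gene lengths in bp, parallel to rows; all positive.
#' @return TPM values with the same shape as `counts`. All-zero samples
#'   yield all-zero TPM with a warning.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  vec_in <- is.null(dim(counts))
  mat <- as.matrix(counts)
  if (length(lengths) != nrow(mat)) {
    stop("lengths must be parallel to genes", call. = FALSE)
  }
  rate <- mat / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) {
    warning("all-zero count column(s): TPM set to zero", call. = FALSE)
  }
  out <- sweep(rate, 2, ifelse(denom == 0, 1, denom), "/") * 1e6
  out[, denom == 0] <- 0
  if (vec_in) drop(out) else out
}

#' Per-group log10 mean TPM display values
#'
#' The tissue-level expression display: `log10(mean(TPM) + 1)` per gene
#' within each sample group, with the pseudocount of 1 applied after
#' averaging.
#'
#' @param tpm_mat Genes x samples TPM matrix (from [tpm()]).
#' @param groups Group label per column.
#' @return Genes x groups matrix of `log10(mean TPM + 1)`.
#' @export
tpm_log_summary <- function(tpm_mat, groups) {
  if (length(groups) != ncol(tpm_mat)) {
    stop("groups must be parallel to samples", call. = FALSE)
  }
  out <- sapply(unique(groups), function(g) {
    log10(rowMeans(tpm_mat[, groups == g, drop = FALSE]) + 1)
  })
  matrix(out, nrow = nrow(tpm_mat),
         dimnames = list(rownames(tpm_mat), unique(groups)))
}

#' Tally significant phenotyping parameters
#'
#' Phenotyping-screen parameters are significant when `p < alpha`
#' (strict, default 0.05, uncorrected). Significant parameters are tallied
#' by group (e.g. knockout-specific, female-specific, male-specific) and by
#' assay category; group and category percentages are relative to the
#' overall significant total and rounded to two decimals.
#'
#' @param table data.frame with columns `parameter`, `category`, `group`,
#'   `p_value`.
#' @param alpha Significance threshold (default 0.05, strict `<`).
#' @param groups Allowed group labels; rows with other labels raise an
#'   error. `NULL` accepts any label.
#' @return List with `total`, `by_group` and `by_category` (data.frames
#'   `group`/`category`, `n`, `pct`). With an empty significant set the
#'   percentages are `NA`.
#' @export
summarize_phenotypes <- function(table, alpha = 0.05,
                                 groups = c("TKO", "female-specific",
                                            "male-specific")) {
  stop_if_missing_cols(table, c("parameter", "category", "group", "p_value"),
                       "phenotype table")
  if (any(table$p_value < 0 | table$p_value > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(groups)) {
    bad <- setdiff(unique(as.character(table$group)), groups)
    if (length(bad) > 0L) {
      stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  sig <- table[!is.na(table$p_value) & table$p_value < alpha, , drop = FALSE]
  total <- nrow(sig)
  tally <- function(fac) {
    lv <- if (identical(fac, "group") && !is.null(groups)) groups
          else unique(as.character(table[[fac]]))
    n <- table(factor(sig[[fac]], levels = lv))
    data.frame(label = lv, n = as.integer(n),
               pct = if (total > 0) round(100 * as.integer(n) / total, 2)
                     else rep(NA_real_, length(lv)),
               stringsAsFactors = FALSE)
  }
  by_group <- tally("group"); names(by_group)[1] <- "group"
  by_category <- tally("category"); names(by_category)[1] <- "category"
  list(total = total, by_group = by_group, by_category = by_category)
}
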
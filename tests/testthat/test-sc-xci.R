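test_that("QC bounds are strict and the report enumerates removals", {
  # 10 genes x 8 cells; metrics provided directly via colData
  s1 <- matrix(5L, 10, 8); s2 <- matrix(5L, 10, 8)
  sce <- make_sce(s1, s2, chrom = rep(c("chr1", "chrX"), 5))
  cd <- SummarizedExperiment::colData(sce)
  cd$n_features <- c(500, 501, 4999, 5000, 1000, 1000, 1000, 1000)
  cd$n_counts <- c(5000, 5000, 5000, 5000, 2000, 2001, 19999, 20000)
  cd$mito_pct <- c(0, 0, 0, 0, 0, 9.9, 0, 0)
  SummarizedExperiment::colData(sce) <- cd
  qc <- qc_filter(sce, cell_qc_params(min_cells_per_gene = 1))
  # boundary cells (features exactly 500/5000, counts exactly 2000/20000)
  # are removed; mito 9.9 is kept
  expect_equal(colnames(qc$sce), c("bc002", "bc003", "bc006", "bc007"))
  expect_equal(qc$report$removed_low_features, 1)
  expect_equal(qc$report$removed_high_features, 1)
  expect_equal(qc$report$removed_low_counts, 1)
  expect_equal(qc$report$removed_high_counts, 1)
  expect_equal(qc$report$removed_high_mito, 0)
  expect_error(qc_filter(sce, cell_qc_params(min_counts = 5e4,
                                             max_counts = 6e4)),
               "no cells")
  expect_error(cell_qc_params(min_counts = 100, max_counts = 50), "bounds")
})

test_that("QC on a generated fixture removes exactly the known outliers", {
  # high outlier rate so a 100-cell draw contains forced violations
  cfg <- sc_sim_config(n_cells_per_genotype = 50, doublet_rate = 0,
                       qc_outlier_rate = 0.1, seed = 21)
  sce <- gen_sc_allele_counts(tiny_genome(), cfg)
  truth <- S4Vectors::metadata(sce)$truth
  cd <- SummarizedExperiment::colData(sce)
  in_bounds <- cd$n_features > 500 & cd$n_features < 5000 &
    cd$n_counts > 2000 & cd$n_counts < 20000 & cd$mito_pct < 10
  expect_gt(sum(truth$qc_outlier), 0)
  # every flagged outlier indeed violates a bound; expected survivors known
  expect_true(all(!in_bounds[truth$qc_outlier]))
  qc <- qc_filter(sce)
  expect_equal(qc$report$n_cells_kept, sum(in_bounds))
  expect_equal(sort(colnames(qc$sce)), sort(rownames(cd)[in_bounds]))
})

test_that("Xa classification applies inclusive thresholds and coverage cut", {
  # 1 X gene; engineer exact ratios
  s1 <- matrix(c(70, 30, 5, 50, 9), 1)  # strain1 X reads
  s2 <- matrix(c(30, 70, 5, 50, 0), 1)
  sce <- make_sce(s1, s2, chrom = "chrX")
  calls <- call_xa_state(sce)
  expect_equal(as.character(calls$state),
               c("STRAIN1_Xa",          # ratio exactly 0.70 -> inclusive
                 "STRAIN2_Xa",          # ratio exactly 0.30 -> inclusive
                 "BIALLELIC_EXCLUDED",  # ratio 0.5 at depth 10
                 "BIALLELIC_EXCLUDED",  # ratio 0.5 at depth 100
                 "LOW_COVERAGE"))       # 9 X reads regardless of ratio
  expect_error(call_xa_state(make_sce(s1, s2, chrom = "chr1")), "X-linked")
})

test_that("relabeling strains swaps the Xa states exactly", {
  set.seed(12)
  s1 <- matrix(rpois(200, 4), 10)
  s2 <- matrix(rpois(200, 2), 10)
  sce <- make_sce(s1, s2, chrom = rep(c("chrX", "chr1"), 5))
  swapped <- make_sce(s2, s1, chrom = rep(c("chrX", "chr1"), 5))
  a <- call_xa_state(sce)
  b <- call_xa_state(swapped)
  expect_equal(b$x_ratio, 1 - a$x_ratio)
  map <- c(STRAIN1_Xa = "STRAIN2_Xa", STRAIN2_Xa = "STRAIN1_Xa",
           BIALLELIC_EXCLUDED = "BIALLELIC_EXCLUDED",
           LOW_COVERAGE = "LOW_COVERAGE")
  expect_equal(as.character(b$state), unname(map[as.character(a$state)]))
  # state partition: each cell exactly one state
  expect_equal(sum(table(a$state)), ncol(sce))
})

test_that("skew summary reports fractions over confidently called cells", {
  calls <- data.frame(
    barcode = sprintf("b%d", 1:6),
    x_total = c(50, 50, 50, 50, 50, 5),
    x_ratio = c(0.9, 0.9, 0.1, 0.5, 0.9, 0.9),
    state = factor(c("STRAIN1_Xa", "STRAIN1_Xa", "STRAIN2_Xa",
                     "BIALLELIC_EXCLUDED", "STRAIN1_Xa", "LOW_COVERAGE"),
                   levels = c("STRAIN1_Xa", "STRAIN2_Xa",
                              "BIALLELIC_EXCLUDED", "LOW_COVERAGE")))
  sk <- skew_summary(calls, rep("WT", 6))
  expect_equal(sum(sk$fraction), 1)
  expect_equal(sk$n[sk$state == "STRAIN1_Xa"], 3)
  expect_equal(sk$pct[sk$state == "STRAIN1_Xa"], 60)
  expect_equal(unname(attr(sk, "n_low_coverage")["WT"]), 1L)
  # single-state population
  one <- skew_summary(calls[1:2, ], rep("WT", 2))
  expect_equal(one$pct, c(100, 0, 0))
})

test_that("simulated skew is recovered without bias across settings", {
  g <- tiny_genome()
  for (skew in c(0.5, 0.66, 0.83)) {
    recovered <- sapply(1:8, function(s) {
      cfg <- sc_sim_config(n_cells_per_genotype = 120, genotypes = "WT",
                           skew = skew, doublet_rate = 0,
                           qc_outlier_rate = 0,
                           n_genes_autosomal = 300, n_genes_X = 60,
                           per_cell_depth = c(mu = 4000, size = 4),
                           seed = 1000 + s)
      sce <- gen_sc_allele_counts(g, cfg)
      calls <- call_xa_state(sce)
      sk <- skew_summary(calls, rep("WT", ncol(sce)))
      sk$fraction[sk$state == "STRAIN1_Xa"]
    })
    n_tot <- 8 * 120
    se <- sqrt(skew * (1 - skew) / n_tot)
    expect_lt(abs(mean(recovered) - skew), 3 * se + 0.01)
  }
})

test_that("equal-depth mixed doublets are excluded as two-Xa cells", {
  # construct doublets directly: both X haplotypes at depth 100 each
  n <- 200
  s1 <- matrix(rbinom(n, 200, 0.5), 1)
  s2 <- 200 - s1
  sce <- make_sce(s1, s2, chrom = "chrX")
  calls <- call_xa_state(sce)
  expect_gte(mean(calls$state == "BIALLELIC_EXCLUDED"), 0.99)

  # and via the generator's truth labels at default depth
  cfg <- sc_sim_config(n_cells_per_genotype = 150, genotypes = "WT",
                       skew = 0.5, doublet_rate = 0.3, qc_outlier_rate = 0,
                       n_genes_autosomal = 300, n_genes_X = 60, seed = 33)
  sce2 <- gen_sc_allele_counts(tiny_genome(), cfg)
  truth <- S4Vectors::metadata(sce2)$truth
  calls2 <- call_xa_state(sce2)
  mixed <- truth$is_doublet & !is.na(truth$xa_strain1_2) &
    truth$xa_strain1 != truth$xa_strain1_2
  singlet <- !truth$is_doublet
  expect_gt(sum(mixed), 10)
  # generator doublets combine two independent depths, so strongly
  # unbalanced pairs can evade the biallelic window; the majority are
  # still caught, and at a far higher rate than singlets
  excl_mixed <- mean(calls2$state[mixed] == "BIALLELIC_EXCLUDED")
  excl_singlet <- mean(calls2$state[singlet] == "BIALLELIC_EXCLUDED")
  expect_gte(excl_mixed, 0.75)
  expect_lt(excl_singlet, 0.05)
  expect_gt(excl_mixed, 10 * excl_singlet)
})

test_that("pseudobulk sums layers per group and conserves totals", {
  s1 <- matrix(c(3, 2, 0, 1, 4, 0), 2) # 2 genes x 3 cells
  s2 <- matrix(c(0, 1, 1, 0, 2, 5), 2)
  sce <- make_sce(s1, s2, chrom = c("chrX", "chr1"),
                  genotype = rep("WT", 3))
  calls <- data.frame(
    barcode = colnames(sce), x_total = c(50, 50, 50),
    x_ratio = c(0.9, 0.9, 0.1),
    state = factor(c("STRAIN1_Xa", "STRAIN1_Xa", "STRAIN2_Xa"),
                   levels = c("STRAIN1_Xa", "STRAIN2_Xa",
                              "BIALLELIC_EXCLUDED", "LOW_COVERAGE")))
  pb <- pseudobulk(sce, calls, rep("WT", 3))
  g1 <- pb[["WT-STRAIN1_Xa"]]
  expect_equal(g1$n_cells, 2)
  expect_equal(g1$counts$strain1, c(3 + 0, 2 + 1))
  expect_equal(g1$counts$strain2, c(0 + 1, 1 + 0))
  # permutation invariance
  perm <- c(3, 1, 2)
  pb2 <- pseudobulk(sce[, perm], calls[perm, ], rep("WT", 3))
  expect_equal(pb2, pb)
  # conservation: group sums equal member-cell column sums
  tot <- Reduce(`+`, lapply(pb, function(x) sum(x$counts$strain1)))
  expect_equal(tot, sum(s1))
})

test_that("group ratio is computed from summed counts, not per-cell ratios", {
  # two cells whose mean of ratios (0.75) differs from ratio of sums (0.6)
  s1 <- matrix(c(10, 50), 1); s2 <- matrix(c(0, 40), 1)
  sce <- make_sce(s1, s2, chrom = "chrX")
  calls <- data.frame(barcode = colnames(sce), x_total = c(10, 90),
                      x_ratio = c(1, 5 / 9),
                      state = factor(rep("STRAIN1_Xa", 2),
                                     levels = c("STRAIN1_Xa", "STRAIN2_Xa",
                                                "BIALLELIC_EXCLUDED",
                                                "LOW_COVERAGE")))
  pb <- suppressWarnings(pseudobulk(sce, calls, rep("WT", 2)))
  prof <- gene_allelic_profile(pb)
  row <- prof[prof$group == "WT-STRAIN1_Xa", ]
  expect_equal(row$ratio, 60 / 100)
  expect_false(isTRUE(all.equal(row$ratio, mean(c(1, 50 / 90)))))
})

test_that("escape genes and the Xist-like gene are recovered in pseudobulk", {
  # gene universe comfortably above the 500-feature QC floor
  cfg <- sc_sim_config(n_cells_per_genotype = 250, doublet_rate = 0.02,
                       qc_outlier_rate = 0.02,
                       n_genes_autosomal = 700, n_genes_X = 80,
                       n_escape = 6, seed = 14)
  sce <- gen_sc_allele_counts(tiny_genome(), cfg)
  qc <- qc_filter(sce)
  calls <- call_xa_state(qc$sce)
  geno <- SummarizedExperiment::colData(qc$sce)$genotype
  prof <- gene_allelic_profile(pseudobulk(qc$sce, calls, geno))

  escape_ids <- S4Vectors::metadata(sce)$escape_gene_ids
  xist_id <- S4Vectors::metadata(sce)$xist_id
  on_x <- prof[prof$chrom == "chrX" & prof$status != "filtered" &
                 prof$gene_id != xist_id, ]
  truth_esc <- on_x$gene_id %in% escape_ids
  sens <- mean(on_x$escaping[truth_esc])
  specificity <- mean(!on_x$escaping[!truth_esc])
  expect_gte(sens, 0.95)
  expect_gte(specificity, 0.95)
  # Xist: expressed from the inactive X, so its ratio opposes the group Xa
  xist <- prof[prof$gene_id == xist_id & prof$status != "filtered", ]
  expect_true(all(xist$xi_exclusive))
  expect_true(all(xist$ratio[grepl("STRAIN1_Xa$", xist$group)] <= 0.3))
  expect_true(all(xist$ratio[grepl("STRAIN2_Xa$", xist$group)] >= 0.7))
})
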
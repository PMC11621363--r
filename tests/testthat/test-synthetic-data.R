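test_that("generators are deterministic given the config seed", {
  g <- tiny_genome()
  cfg <- peak_sim_config(organs = c("brain", "spleen"), seed = 8,
                         enriched_windows = data.frame(
                           chrom = "chrX", start = 2e6, end = 2.1e6,
                           fold = 4))
  a <- gen_peak_sets(g, cfg)
  b <- gen_peak_sets(g, cfg)
  expect_identical(a, b)
  # byte-identical BED output
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(a$peaks[[1]], f1); write_bed(b$peaks[[1]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  bc <- allele_sim_config(n_genes_autosomal = 100, n_genes_X = 50, seed = 4)
  expect_identical(gen_bulk_allele_counts(g, bc),
                   gen_bulk_allele_counts(g, bc))

  sc_cfg <- sc_sim_config(n_cells_per_genotype = 30,
                          n_genes_autosomal = 100, n_genes_X = 30, seed = 5)
  s1 <- gen_sc_allele_counts(g, sc_cfg)
  s2 <- gen_sc_allele_counts(g, sc_cfg)
  expect_identical(SummarizedExperiment::assay(s1, "strain1"),
                   SummarizedExperiment::assay(s2, "strain1"))

  expect_identical(gen_de_tables(n_genes = 500, n_de = c(40, 20), seed = 6),
                   gen_de_tables(n_genes = 500, n_de = c(40, 20), seed = 6))
})

test_that("every generated entity appears exactly once in the truth", {
  g <- tiny_genome()
  bulk <- gen_bulk_allele_counts(g, allele_sim_config(
    n_genes_autosomal = 200, n_genes_X = 50, seed = 2))
  expect_setequal(bulk$truth$feature_id, bulk$counts$feature_id)
  expect_equal(anyDuplicated(bulk$truth$feature_id), 0)

  sce <- gen_sc_allele_counts(g, sc_sim_config(
    n_cells_per_genotype = 40, n_genes_autosomal = 100, n_genes_X = 30,
    seed = 3))
  truth <- S4Vectors::metadata(sce)$truth
  expect_identical(truth$barcode, colnames(sce))

  de <- gen_de_tables(n_genes = 500, n_de = c(40, 20), seed = 4)
  for (cond in names(de$tables)) {
    sig <- call_de(de$tables[[cond]])
    truth_cond <- de$truth[de$truth$condition == cond, ]
    expect_setequal(sig$gene_id, truth_cond$gene_id)
    expect_equal(anyDuplicated(truth_cond$gene_id), 0)
  }
})

test_that("peak process hits its Poisson expectations (Monte Carlo)", {
  g <- sim_genome(c(chr1 = 1e6, chrX = 1e6))
  enr <- data.frame(chrom = "chrX", start = 4e5, end = 5e5, fold = 4)
  win <- data.frame(chrom = c("chrX", "chr1"), start = c(4e5, 4e5),
                    end = c(5e5, 5e5))
  n_seeds <- 1000
  counts <- t(sapply(seq_len(n_seeds), function(s) {
    sim <- gen_peak_sets(g, peak_sim_config(
      organs = "o1", replicates_per_sex = 1, baseline_rate = 5,
      enriched_windows = enr, seed = s))
    c(f_enr = count_peaks(win, sim$peaks[["o1_female_rep1"]])[1],
      m_enr = count_peaks(win, sim$peaks[["o1_male_rep1"]])[1],
      f_base = count_peaks(win, sim$peaks[["o1_female_rep1"]])[2])
  }))
  # female mean in the fold-4 window ~ 20, male ~ 5, female baseline ~ 5
  se20 <- sqrt(20 / n_seeds); se5 <- sqrt(5 / n_seeds)
  expect_lt(abs(mean(counts[, "f_enr"]) - 20), 3 * se20 + 0.1)
  expect_lt(abs(mean(counts[, "m_enr"]) - 5), 3 * se5 + 0.1)
  expect_lt(abs(mean(counts[, "f_base"]) - 5), 3 * se5 + 0.1)
})

test_that("fold-1 enrichment injects no sex difference", {
  g <- sim_genome(c(chr1 = 1e6, chrX = 1e6))
  enr <- data.frame(chrom = "chr1", start = 4e5, end = 5e5, fold = 1)
  win <- data.frame(chrom = "chr1", start = 4e5, end = 5e5)
  # with fold 1 the female window count is a plain baseline draw; compare
  # across many seeds
  f <- sapply(1:200, function(s) {
    sim <- gen_peak_sets(g, peak_sim_config(organs = "o1",
                                            replicates_per_sex = 1,
                                            enriched_windows = enr,
                                            seed = s))
    c(count_peaks(win, sim$peaks[["o1_female_rep1"]])[1],
      count_peaks(win, sim$peaks[["o1_male_rep1"]])[1])
  })
  expect_lt(abs(mean(f[1, ]) - mean(f[2, ])), 3 * sqrt(10 / 200))
})

test_that("enriched windows outside the genome are rejected", {
  g <- tiny_genome()
  bad <- data.frame(chrom = "chrX", start = 3.95e6, end = 4.2e6, fold = 4)
  expect_error(gen_peak_sets(g, peak_sim_config(enriched_windows = bad)),
               "within the genome")
  expect_error(peak_sim_config(enriched_windows = data.frame(
    chrom = "chrX", start = 0, end = 1e5, fold = 0.5)), "fold")
})

test_that("bulk allele classes produce their analytic maternal fractions", {
  g <- tiny_genome()
  # large run for tight marginals
  cfg <- allele_sim_config(n_genes_autosomal = 6000, n_genes_X = 6000,
                           noise_eps = 0.05, depth_mean = 80, seed = 11)
  sim <- gen_bulk_allele_counts(g, cfg)
  oriented <- orient_counts(sim$counts, sim$cross, sim$strains)
  merged <- merge(oriented, sim$truth, by = "feature_id")

  pooled <- function(cls) {
    sub <- merged[merged$class == cls, ]
    c(frac = sum(sub$maternal_count) /
        sum(sub$maternal_count + sub$paternal_count),
      n_reads = sum(sub$maternal_count + sub$paternal_count))
  }
  for (cls in c("biallelic", "X-silenced", "imprinted-maternal",
                "Xist-like")) {
    expected <- unique(merged$expected_obs_fraction[merged$class == cls])
    expect_length(expected, 1)
    obs <- pooled(cls)
    se <- sqrt(expected * (1 - expected) / obs["n_reads"])
    expect_lt(abs(obs["frac"] - expected), 3 * se + 1e-3)
  }
  # X-silenced expectation is 1 - eps under the maternal-Xa convention
  expect_equal(unique(merged$expected_obs_fraction[
    merged$class == "X-silenced"]), 0.95)
  # escapers: symmetric around 0.5 with per-feature fractions in (0.3, 0.7)
  esc <- merged[merged$class == "escaper", ]
  expect_true(all(esc$true_maternal_fraction > 0.3 &
                    esc$true_maternal_fraction < 0.7))
  r <- esc$maternal_count / pmax(1, esc$maternal_count + esc$paternal_count)
  expect_lt(abs(mean(r) - 0.5), 3 * sd(r) / sqrt(nrow(esc)))
})

test_that("swapping the cross direction swaps strain columns only", {
  g <- tiny_genome()
  base <- list(n_genes_autosomal = 300, n_genes_X = 100, seed = 17)
  fwd <- gen_bulk_allele_counts(g, do.call(allele_sim_config, c(
    base, list(cross = cross_design("BL6", "CAST")))))
  rev <- gen_bulk_allele_counts(g, do.call(allele_sim_config, c(
    base, list(cross = cross_design("CAST", "BL6")))))
  expect_equal(fwd$counts$strain1_count, rev$counts$strain2_count)
  expect_equal(fwd$counts$strain2_count, rev$counts$strain1_count)
  expect_identical(fwd$truth, rev$truth)
})

test_that("bulk class recovery meets the threshold-classification target", {
  g <- tiny_genome()
  sim <- gen_bulk_allele_counts(g, allele_sim_config(
    n_genes_autosomal = 2000, n_genes_X = 2000, seed = 19))
  oriented <- orient_counts(sim$counts, sim$cross, sim$strains)
  res <- allelic_ratio(oriented$maternal_count, oriented$paternal_count,
                       min_total = 30)
  merged <- cbind(sim$truth, status = res$status)
  expected_status <- c("biallelic" = "biallelic",
                       "X-silenced" = "maternal",
                       "escaper" = "biallelic",
                       "imprinted-maternal" = "maternal",
                       "Xist-like" = "paternal")
  keep <- merged[res$status != "filtered", ]
  acc <- mean(as.character(keep$status) ==
                expected_status[keep$class])
  expect_gte(acc, 0.98)
})

test_that("zero requested features yields an empty table with warning", {
  g <- tiny_genome()
  expect_warning(
    out <- gen_bulk_allele_counts(g, allele_sim_config(
      n_genes_autosomal = 0, n_genes_X = 0)),
    "empty")
  expect_equal(nrow(out$counts), 0)
})

test_that("fully skewed singlets are confidently monoallelic on the X", {
  cfg <- sc_sim_config(n_cells_per_genotype = 150, genotypes = "WT",
                       skew = 1, doublet_rate = 0, qc_outlier_rate = 0,
                       noise_eps = 0.02,
                       n_genes_autosomal = 500, n_genes_X = 150,
                       n_escape = 0, seed = 23)
  sce <- gen_sc_allele_counts(tiny_genome(), cfg)
  calls <- call_xa_state(sce)
  deep <- calls$x_total >= 50
  expect_gt(sum(deep), 100)
  expect_true(all(calls$x_ratio[deep] >= 0.9))
})

test_that("the Xist-like gene is expressed from the inactive X only", {
  cfg <- sc_sim_config(n_cells_per_genotype = 60, genotypes = "WT",
                       skew = 1, doublet_rate = 0, qc_outlier_rate = 0,
                       noise_eps = 0, n_genes_autosomal = 100,
                       n_genes_X = 30, seed = 29)
  sce <- gen_sc_allele_counts(tiny_genome(), cfg)
  xist_id <- S4Vectors::metadata(sce)$xist_id
  s1 <- SummarizedExperiment::assay(sce, "strain1")[xist_id, ]
  s2 <- SummarizedExperiment::assay(sce, "strain2")[xist_id, ]
  # all cells have strain-1 Xa, so Xist reads carry strain 2 exclusively
  expect_equal(sum(s1), 0)
  expect_gt(sum(s2), 0)
})

test_that("DE generator honors overlap and concordance settings", {
  # full sharing, full concordance
  full <- gen_de_tables(n_genes = 400, n_de = c(50, 50),
                        shared_fraction = 1, concordant_fraction = 1,
                        seed = 31)
  sets <- lapply(full$tables, call_de)
  ov <- overlap_and_concordance(sets)$pairwise
  expect_equal(ov$shared, 50)
  expect_equal(ov$concordance_pct, 100)
  # no sharing
  none <- gen_de_tables(n_genes = 400, n_de = c(50, 50),
                        shared_fraction = 0, seed = 32)
  ov0 <- overlap_and_concordance(lapply(none$tables, call_de))$pairwise
  expect_equal(ov0$shared, 0)
  expect_error(gen_de_tables(n_genes = 10, n_de = c(50, 5)), "n_de")
})
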
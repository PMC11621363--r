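# Shared fixtures and brute-force oracles used across test files.

tiny_genome <- function() {
  sim_genome(c(chr1 = 4e6, chr2 = 4e6, chrX = 4e6), x_chrom = "chrX")
}

# Quadratic oracle for midpoint-containment peak counting.
brute_count_peaks <- function(windows, peaks) {
  mids <- floor((peaks$start + peaks$end) / 2)
  sapply(seq_len(nrow(windows)), function(i) {
    sum(peaks$chrom == windows$chrom[i] &
          mids >= windows$start[i] & mids < windows$end[i])
  })
}

# Quadratic oracle for SNP-to-feature aggregation (unstranded).
brute_aggregate <- function(units, annotation, min_cov = 1) {
  t(sapply(seq_len(nrow(annotation)), function(i) {
    hit <- units$chrom == annotation$chrom[i] &
      units$start >= annotation$start[i] & units$start < annotation$end[i] &
      (units$maternal_count + units$paternal_count) >= min_cov
    c(mat = sum(units$maternal_count[hit]),
      pat = sum(units$paternal_count[hit]),
      n = sum(hit))
  }))
}

# Random SNP-level count fixture.
random_units <- function(n, chroms = c("chr1", "chrX"), max_pos = 1e5,
                         seed = 42) {
  set.seed(seed)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(max_pos, n, replace = TRUE) - 1L,
    maternal_count = rpois(n, 3),
    paternal_count = rpois(n, 3),
    stringsAsFactors = FALSE
  )
}

# A SingleCellExperiment built directly from dense allele layers.
make_sce <- function(s1, s2, chrom, genotype = rep("WT", ncol(s1)),
                     barcodes = sprintf("bc%03d", seq_len(ncol(s1))),
                     gene_ids = sprintf("g%03d", seq_len(nrow(s1)))) {
  dimnames(s1) <- dimnames(s2) <- list(gene_ids, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(s1 + s2, sparse = TRUE),
                  strain1 = Matrix::Matrix(s1, sparse = TRUE),
                  strain2 = Matrix::Matrix(s2, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(chrom = chrom, row.names = gene_ids),
    colData = S4Vectors::DataFrame(genotype = genotype,
                                   row.names = barcodes)
  )
}
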
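# Plain-text readers/writers for the pipeline's interchange formats:
# BED peaks, sample sheets, long-format allele count TSVs, MTX triplet
# matrices with sidecars, DE manifests, and JSON truth records.

#' Read / write peak intervals in BED format
#'
#' Three-column BED (0-based, half-open), tab-separated, no header.
#'
#' @param path File path.
#' @return `read_bed()`: data.frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric"))
  names(tbl) <- c("chrom", "start", "end")
  tbl
}

#' @rdname read_bed
#' @param peaks Peak data.frame (`chrom`, `start`, `end`).
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a simulated peak experiment to disk
#'
#' One BED file per sample, a sample sheet TSV (with a `path` column), a
#' chrom.sizes table and a JSON ground-truth record.
#'
#' @param sim Output of [gen_peak_sets()].
#' @param genome The [sim_genome()] the peaks were simulated on.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_peak_experiment <- function(sim, genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- sim$samples
  samples$path <- file.path(dir, paste0(samples$sample_id, ".bed"))
  for (i in seq_len(nrow(samples))) {
    write_bed(sim$peaks[[samples$sample_id[i]]], samples$path[i])
  }
  write_tsv(samples, file.path(dir, "sample_sheet.tsv"))
  write_chrom_sizes(genome, file.path(dir, "chrom.sizes"))
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a peak experiment from a sample sheet
#'
#' @param sample_sheet Path to a sample sheet TSV with columns
#'   `sample_id`, `sex`, `organ`, `replicate`, `path` (BED paths, resolved
#'   relative to the sheet's directory when not absolute).
#' @return List with `peaks` (named list of peak data.frames) and
#'   `samples` (the sheet without the path column).
#' @export
read_peak_experiment <- function(sample_sheet) {
  samples <- read_tsv(sample_sheet)
  stop_if_missing_cols(samples, c("sample_id", "sex", "organ", "replicate",
                                  "path"), "sample sheet")
  base <- dirname(sample_sheet)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", samples$path), samples$path,
                  file.path(base, samples$path))
  peaks <- stats::setNames(lapply(paths, read_bed), samples$sample_id)
  list(peaks = peaks,
       samples = samples[, c("sample_id", "sex", "organ", "replicate")])
}

#' Write / read a bulk allele count experiment
#'
#' Long-format TSV of per-feature strain counts plus a JSON record of the
#' cross orientation and ground-truth classes.
#'
#' @param sim Output of [gen_bulk_allele_counts()].
#' @param dir Output directory.
#' @return `dir` (write) / list with `counts`, `truth`, `strains`,
#'   `cross` (read).
#' @export
write_bulk_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(sim$counts, file.path(dir, "allele_counts.tsv"))
  meta <- list(strains = sim$strains,
               cross = list(maternal = sim$cross$maternal,
                            paternal = sim$cross$paternal),
               truth = sim$truth)
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bulk_experiment
#' @export
read_bulk_experiment <- function(dir) {
  counts <- read_tsv(file.path(dir, "allele_counts.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  list(counts = counts, truth = meta$truth, strains = meta$strains,
       cross = cross_design(meta$cross$maternal, meta$cross$paternal))
}

#' Write / read a single-cell allele experiment as MTX triplets
#'
#' Three MatrixMarket files (`strain1.mtx`, `strain2.mtx`, `counts.mtx`),
#' `barcodes.tsv`, `features.tsv` (gene id and chromosome), a cell
#' metadata TSV, and the JSON ground truth.
#'
#' @param sce SingleCellExperiment from [gen_sc_allele_counts()].
#' @param dir Output directory.
#' @return `dir` (write) / a reconstructed SingleCellExperiment (read).
#' @export
write_sc_experiment <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (layer in c("counts", "strain1", "strain2")) {
    Matrix::writeMM(methods::as(
      SummarizedExperiment::assay(sce, layer), "CsparseMatrix"),
      file.path(dir, paste0(layer, ".mtx")))
  }
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  write_tsv(data.frame(
    gene_id = rownames(sce),
    chrom = as.character(SummarizedExperiment::rowData(sce)$chrom)),
    file.path(dir, "features.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd <- cbind(barcode = rownames(cd), cd)
  write_tsv(cd, file.path(dir, "cell_metadata.tsv"))
  md <- S4Vectors::metadata(sce)
  jsonlite::write_json(
    list(truth = md$truth, escape_gene_ids = md$escape_gene_ids,
         xist_id = md$xist_id),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sc_experiment
#' @export
read_sc_experiment <- function(dir) {
  features <- read_tsv(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  layers <- lapply(c("counts", "strain1", "strain2"), function(layer) {
    m <- Matrix::readMM(file.path(dir, paste0(layer, ".mtx")))
    dimnames(m) <- list(features$gene_id, barcodes)
    m
  })
  names(layers) <- c("counts", "strain1", "strain2")
  cd <- read_tsv(file.path(dir, "cell_metadata.tsv"))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = layers,
    rowData = S4Vectors::DataFrame(chrom = features$chrom,
                                   row.names = features$gene_id),
    colData = S4Vectors::DataFrame(cd[, setdiff(names(cd), "barcode"),
                                      drop = FALSE],
                                   row.names = cd$barcode)
  )
  md <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  S4Vectors::metadata(sce)$truth <- md$truth
  S4Vectors::metadata(sce)$escape_gene_ids <- md$escape_gene_ids
  S4Vectors::metadata(sce)$xist_id <- md$xist_id
  sce
}

#' Write / read simulated DE tables with a condition manifest
#'
#' @param sim Output of [gen_de_tables()].
#' @param dir Output directory.
#' @return `dir` (write) / list with `tables` (named list of DE
#'   data.frames) and `truth` (read; truth is `NULL` when absent).
#' @export
write_de_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(condition = names(sim$tables),
                         path = paste0("de_", names(sim$tables), ".tsv"),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    write_tsv(sim$tables[[i]], file.path(dir, manifest$path[i]))
  }
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  jsonlite::write_json(list(truth = sim$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_de_experiment
#' @param manifest Path to a manifest TSV (`condition`, `path`).
#' @export
read_de_experiment <- function(manifest) {
  man <- read_tsv(manifest)
  stop_if_missing_cols(man, c("condition", "path"), "DE manifest")
  base <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  tables <- stats::setNames(lapply(paths, read_tsv), man$condition)
  truth_path <- file.path(base, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)$truth
  }
  list(tables = tables, truth = truth)
}
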
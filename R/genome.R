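#' Define a genome for simulation and window tiling
#'
#' A minimal genome description: named chromosome lengths with exactly one
#' chromosome flagged as the X. Used both by the synthetic-data generators
#' and by the window-tiling code (which otherwise accepts a chrom.sizes
#' table).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in base
#'   pairs; names are chromosome identifiers and must be unique.
#' @param x_chrom Name of the X chromosome; must be one of
#'   `names(chrom_lengths)`.
#' @return An object of class `sim_genome`: a list with elements `chrom`
#'   (character), `length` (numeric) and `x_chrom` (character scalar).
#' @examples
#' g <- sim_genome(c(chr1 = 5e6, chr2 = 5e6, chrX = 5e6))
#' @export
sim_genome <- function(chrom_lengths, x_chrom = "chrX") {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (!x_chrom %in% names(chrom_lengths)) {
    stop(sprintf("x_chrom '%s' is not a chromosome of this genome", x_chrom),
         call. = FALSE)
  }
  structure(
    list(chrom = names(chrom_lengths),
         length = unname(as.numeric(chrom_lengths)),
         x_chrom = x_chrom),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosomes, %.1f Mb total (X = %s)\n",
              length(x$chrom), sum(x$length) / 1e6, x$x_chrom))
  invisible(x)
}

#' Default genome used by example configurations
#'
#' Five chromosomes of 8 Mb each (four autosomes plus an X). Small enough
#' that full simulate-and-scan rounds run in seconds, large enough that the
#' 100 kb window lattice has hundreds of windows per chromosome.
#'
#' @return A [sim_genome()] object.
#' @export
default_genome <- function() {
  sim_genome(c(chr1 = 8e6, chr2 = 8e6, chr3 = 8e6, chr4 = 8e6, chrX = 8e6),
             x_chrom = "chrX")
}

# Accept a sim_genome, a chrom.sizes-style data.frame (chrom, length|size),
# or a named vector; return data.frame(chrom, length).
as_chrom_table <- function(genome) {
  if (inherits(genome, "sim_genome")) {
    return(data.frame(chrom = genome$chrom, length = genome$length,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(genome)) {
    len_col <- intersect(c("length", "size"), names(genome))[1]
    if (is.na(len_col) || !"chrom" %in% names(genome)) {
      stop("genome data.frame needs columns 'chrom' and 'length' (or 'size')",
           call. = FALSE)
    }
    tbl <- data.frame(chrom = as.character(genome$chrom),
                      length = as.numeric(genome[[len_col]]),
                      stringsAsFactors = FALSE)
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    tbl <- data.frame(chrom = names(genome), length = as.numeric(genome),
                      stringsAsFactors = FALSE)
  } else {
    stop("unsupported genome representation", call. = FALSE)
  }
  if (nrow(tbl) == 0L) stop("empty genome table", call. = FALSE)
  if (any(tbl$length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  tbl
}

#' Read / write a chrom.sizes table
#'
#' Two-column tab-separated file: chromosome name and length in bp, the
#' format emitted by `samtools faidx` / UCSC `fetchChromSizes`.
#'
#' @param path File path.
#' @return `read_chrom_sizes()`: data.frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (nrow(tbl) == 0L) stop("empty chrom.sizes file", call. = FALSE)
  tbl
}

#' @rdname read_chrom_sizes
#' @param genome A [sim_genome()] or chrom table.
#' @export
write_chrom_sizes <- function(genome, path) {
  tbl <- as_chrom_table(genome)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
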
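#' Configuration for synthetic bulk allele count tables
#'
#' Models feature-level biallelic counts from an F1 reciprocal cross in a
#' tissue with imprinted XCI (maternal X active), the setting where the
#' allelic-ratio engine is applied to placental RNA-seq. Each feature is
#' assigned an allelic class which determines its true maternal fraction:
#'
#' * `biallelic` - 0.5;
#' * `X-silenced` - 1 (expressed from the maternal Xa only);
#' * `escaper` - drawn uniformly from (0.35, 0.65), i.e. expression from
#'   both X's;
#' * `imprinted-maternal` - 1 regardless of XCI;
#' * `Xist-like` - 0 (expressed from the paternal Xi only).
#'
#' Observed fractions are attenuated by symmetric misassignment noise:
#' `p_obs = p * (1 - eps) + (1 - p) * eps`. X-specific classes
#' (`X-silenced`, `escaper`, `Xist-like`) are drawn only for X-linked
#' features, `imprinted-maternal` only for autosomal ones; the requested
#' `class_fractions` are renormalised within each chromosome type.
#'
#' @param n_genes_autosomal,n_genes_X Feature counts (defaults 2,000 /
#'   200).
#' @param class_fractions Named proportions over the five classes, summing
#'   to 1.
#' @param depth_mean,depth_dispersion Negative-binomial per-feature total
#'   read model (`mu`, `size`); defaults 60 / 2.
#' @param noise_eps Cross-contamination fraction, `0 <= eps < 0.5`
#'   (default 0.02; the off-allele signal level is a free choice, see the
#'   package vignette).
#' @param cross A [cross_design()] (default BL6xCAST: maternal BL6).
#' @param strains Strain labels behind the `strain1_count` /
#'   `strain2_count` output columns (default `c("BL6", "CAST")`).
#' @param seed Integer seed.
#' @return List of class `allele_sim_config`.
#' @export
allele_sim_config <- function(n_genes_autosomal = 2000, n_genes_X = 200,
                              class_fractions = c(
                                "biallelic" = 0.75,
                                "X-silenced" = 0.12,
                                "escaper" = 0.04,
                                "imprinted-maternal" = 0.06,
                                "Xist-like" = 0.03),
                              depth_mean = 60, depth_dispersion = 2,
                              noise_eps = 0.02,
                              cross = cross_design("BL6", "CAST"),
                              strains = c("BL6", "CAST"),
                              seed = 1L) {
  classes <- c("biallelic", "X-silenced", "escaper", "imprinted-maternal",
               "Xist-like")
  if (!setequal(names(class_fractions), classes)) {
    stop("class_fractions must be named with the five allelic classes",
         call. = FALSE)
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  if (noise_eps < 0 || noise_eps >= 0.5) {
    stop("noise_eps must be in [0, 0.5)", call. = FALSE)
  }
  if (depth_mean <= 0) stop("depth_mean must be positive", call. = FALSE)
  if (!setequal(strains, c(cross$maternal, cross$paternal))) {
    stop("strains must name the two strains of the cross", call. = FALSE)
  }
  structure(list(n_genes_autosomal = n_genes_autosomal, n_genes_X = n_genes_X,
                 class_fractions = class_fractions[classes],
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 noise_eps = noise_eps, cross = cross, strains = strains,
                 seed = as.integer(seed)),
            class = "allele_sim_config")
}

# True maternal fraction per class (escapers draw theirs per feature).
class_maternal_fraction <- function(classes) {
  p <- numeric(length(classes))
  p[classes == "biallelic"] <- 0.5
  p[classes == "X-silenced"] <- 1
  p[classes == "imprinted-maternal"] <- 1
  p[classes == "Xist-like"] <- 0
  esc <- classes == "escaper"
  p[esc] <- stats::runif(sum(esc), 0.35, 0.65)
  p
}

#' Generate a bulk allele count table with ground truth
#'
#' Features are placed on the genome (autosomes round-robin, X genes on
#' the X chromosome), assigned an allelic class, given a negative-binomial
#' total read count, and split into maternal/paternal reads by a binomial
#' draw at the noise-attenuated class fraction. The maternal counts land in
#' the strain column matching `cfg$cross$maternal`. Deterministic given
#' `cfg$seed`.
#'
#' @param genome A [sim_genome()].
#' @param cfg An [allele_sim_config()].
#' @return List with:
#'   * `counts`: data.frame `feature_id`, `chrom`, `start`, `end`,
#'     `strand`, `strain1_count`, `strain2_count`;
#'   * `truth`: data.frame `feature_id`, `class`,
#'     `true_maternal_fraction`, `expected_obs_fraction`;
#'   * `strains`, `cross`: the orientation metadata.
#' @export
gen_bulk_allele_counts <- function(genome, cfg) {
  stopifnot(inherits(genome, "sim_genome"), inherits(cfg, "allele_sim_config"))
  n_auto <- cfg$n_genes_autosomal
  n_x <- cfg$n_genes_X
  if (n_auto + n_x == 0L) {
    warning("zero features requested: returning empty table", call. = FALSE)
    empty <- data.frame(feature_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), strain1_count = integer(),
                        strain2_count = integer())
    return(list(counts = empty,
                truth = data.frame(feature_id = character(),
                                   class = character(),
                                   true_maternal_fraction = numeric(),
                                   expected_obs_fraction = numeric()),
                strains = cfg$strains, cross = cfg$cross))
  }
  autosomes <- setdiff(genome$chrom, genome$x_chrom)
  if (n_auto > 0 && length(autosomes) == 0L) {
    stop("genome has no autosomes", call. = FALSE)
  }

  with_seed(cfg$seed, {
    fr <- cfg$class_fractions
    auto_classes <- c("biallelic", "imprinted-maternal")
    x_classes <- c("biallelic", "X-silenced", "escaper", "Xist-like")
    cls <- c(
      if (n_auto > 0) sample(auto_classes, n_auto, replace = TRUE,
                             prob = fr[auto_classes]),
      if (n_x > 0) sample(x_classes, n_x, replace = TRUE,
                          prob = fr[x_classes])
    )
    chrom <- c(
      if (n_auto > 0) autosomes[(seq_len(n_auto) - 1L) %% length(autosomes) + 1L],
      rep(genome$x_chrom, n_x)
    )
    n <- n_auto + n_x
    len <- as_chrom_table(genome)
    gene_w <- 10000L
    start <- sapply(chrom, function(ch) {
      floor(stats::runif(1, 0, len$length[len$chrom == ch] - gene_w))
    })
    p_true <- class_maternal_fraction(cls)
    eps <- cfg$noise_eps
    p_obs <- p_true * (1 - eps) + (1 - p_true) * eps
    total <- stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion)
    mat <- stats::rbinom(n, total, p_obs)
    pat <- total - mat

    feature_id <- sprintf("gene_%04d", seq_len(n))
    counts <- data.frame(feature_id = feature_id, chrom = chrom,
                         start = start, end = start + gene_w,
                         strand = "+", stringsAsFactors = FALSE)
    if (cfg$strains[1] == cfg$cross$maternal) {
      counts$strain1_count <- mat
      counts$strain2_count <- pat
    } else {
      counts$strain1_count <- pat
      counts$strain2_count <- mat
    }
    rownames(counts) <- NULL
    truth <- data.frame(feature_id = feature_id, class = cls,
                        true_maternal_fraction = p_true,
                        expected_obs_fraction = p_obs,
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth, strains = cfg$strains,
         cross = cfg$cross)
  })
}
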
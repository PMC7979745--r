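#' Simulation configuration for the synthetic screen
#'
#' Bundles every tunable of the synthetic-data generators into one
#' validated object. The defaults describe the study conditions the
#' package is validated under: a small PAM-dense mini-genome, a pooled
#' CRISPRi screen sequenced to a mean depth of 500 reads per guide with
#' two replicates at day 0 and day 16, and a cohort of 128 samples with
#' a genotype effect on expression confined to the high-methylation
#' stratum.
#'
#' @param seed Integer master seed. Every generator derives its own
#'   independent sub-stream from it, so adding a generator never shifts
#'   the draws of another.
#' @param genome_length Mini-genome length in bp.
#' @param pam_rich If `TRUE`, target regions are built on a period-3
#'   scaffold that guarantees a forward-strand "GG" dinucleotide at
#'   least every 3 bp, so a candidate protospacer exists at one or more
#'   positions per 3 bp.
#' @param n_regions Number of target regions.
#' @param region_length Region width in bp (>= 100; default 400, the
#'   width regulatory elements are tiled at).
#' @param planted_effects Named numeric vector mapping region ids to the
#'   per-guide log2 fold change planted at day 16 (<= 0 for depletion).
#'   Regions not named get effect 0.
#' @param sequencing_depth Mean reads per guide at day 0.
#' @param nb_dispersion Negative-binomial dispersion alpha >= 0
#'   (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param n_replicates Replicates per timepoint.
#' @param abundance_sigma Log-normal sigma of per-guide library
#'   abundance skew.
#' @param signal_correlation Target Pearson correlation rho in [-1, 1]
#'   between per-region peak signal and the essentiality z used by
#'   [sim_signal_track()].
#' @param cohort_n Cohort size (>= 20).
#' @param maf Minor (risk) allele frequency in (0, 0.5].
#' @param beta_geno Additive genotype effect on latent expression, acting
#'   only in samples whose methylation exceeds `meth_threshold`.
#' @param meth_threshold Methylation cutoff tau in (0, 1) defining the
#'   true high-methylation stratum.
#' @param coexpression_r Target Pearson correlation between the focal
#'   gene and its co-regulated neighbor, planted only in the
#'   high-methylation stratum.
#' @param cohort_noise_sd Residual s.d. of latent (Box-Cox scale)
#'   expression.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_regions = 5, genome_length = 20000)
#' cfg$region_length
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 60000L,
                       pam_rich = TRUE,
                       n_regions = 20L,
                       region_length = 400L,
                       planted_effects = numeric(0),
                       sequencing_depth = 500,
                       nb_dispersion = 0.15,
                       n_replicates = 2L,
                       abundance_sigma = 0.5,
                       signal_correlation = 0.6,
                       cohort_n = 128L,
                       maf = 0.3,
                       beta_geno = 0.4,
                       meth_threshold = 0.5,
                       coexpression_r = 0.7,
                       cohort_noise_sd = 0.5) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  if (region_length < 100)
    stop("region_length must be >= 100")
  if (nb_dispersion < 0)
    stop("nb_dispersion must be >= 0")
  if (sequencing_depth <= 0)
    stop("sequencing_depth must be positive")
  if (abs(signal_correlation) > 1)
    stop("signal_correlation must lie in [-1, 1]")
  if (maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  if (meth_threshold <= 0 || meth_threshold >= 1)
    stop("meth_threshold must lie in (0, 1)")
  if (cohort_n < 20)
    stop("cohort_n must be >= 20")
  if (length(planted_effects) && is.null(names(planted_effects)))
    stop("planted_effects must be named by region id")
  structure(list(
    seed = seed,
    genome_length = as.integer(genome_length),
    pam_rich = isTRUE(pam_rich),
    n_regions = as.integer(n_regions),
    region_length = as.integer(region_length),
    planted_effects = planted_effects,
    sequencing_depth = sequencing_depth,
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    abundance_sigma = abundance_sigma,
    signal_correlation = signal_correlation,
    cohort_n = as.integer(cohort_n),
    maf = maf,
    beta_geno = beta_geno,
    meth_threshold = meth_threshold,
    coexpression_r = coexpression_r,
    cohort_noise_sd = cohort_noise_sd
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", x$genome_length, " bp, ", x$n_regions, " regions x ",
      x$region_length, " bp", if (x$pam_rich) " (PAM-rich)", "\n", sep = "")
  cat("  screen: depth ", x$sequencing_depth, ", dispersion ",
      x$nb_dispersion, ", ", x$n_replicates, " replicates/timepoint\n",
      sep = "")
  cat("  cohort: n ", x$cohort_n, ", maf ", x$maf, ", beta_geno ",
      x$beta_geno, ", tau ", x$meth_threshold, "\n", sep = "")
  invisible(x)
}

# Derive an independent RNG sub-stream seed from the master seed.
# Distinct small offsets per generator keep streams independent of the
# order generators are invoked in; result stays below 2^31.
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 7919) %% 2147483629)
}

with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, offset))
  expr
}
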
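#' Simulate a mini-genome with tileable target regions
#'
#' Generates a single-chromosome genome of uppercase ACGT and a set of
#' non-overlapping target regions placed at regular intervals. When
#' `config$pam_rich` is set, region sequence is built on a period-3
#' scaffold (`x G G` repeated) so every region carries a forward-strand
#' "GG" dinucleotide at least every 3 bp; the free base is drawn with an
#' AT-leaning composition so that 20-nt protospacers remain inside the
#' default GC filter and are (almost surely) unique genome-wide.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector of sequences),
#'   `regions` (BED-like data frame: chrom, start, end, region_id,
#'   class, parent_id, locus; 0-based half-open), and `config`.
#' @examples
#' g <- sim_genome(sim_config(seed = 1, n_regions = 4, genome_length = 12000))
#' nchar(g$genome)
#' g$regions
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  n <- config$n_regions
  w <- config$region_length
  if (L < n * w * 2)
    stop("infeasible packing: genome_length must be >= n_regions * region_length * 2")
  with_substream(config$seed, 11L, {
    seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    slot <- L %/% n
    starts <- (seq_len(n) - 1L) * slot + (slot - w) %/% 2L
    if (config$pam_rich) {
      # free base every 3rd position; G allowed (25%) to create extra,
      # offset PAMs; C kept rare so protospacer GC stays in range
      for (s in starts) {
        idx <- s + seq_len(w) - 1L
        pat <- rep(c("x", "G", "G"), length.out = w)
        free <- which(pat == "x")
        pat[free] <- sample(c("A", "T", "G", "C"), length(free),
                            replace = TRUE, prob = c(0.35, 0.35, 0.25, 0.05))
        seq[idx + 1L] <- pat
      }
    }
    regions <- data.frame(
      chrom = "chrS",
      start = starts,
      end = starts + w,
      region_id = sprintf("rcre_%02d", seq_len(n)),
      class = "rcre",
      parent_id = NA_character_,
      locus = ifelse(seq_len(n) <= max(1L, n %/% 4L), "locusA", "locusB"),
      stringsAsFactors = FALSE
    )
    list(genome = c(chrS = paste(seq, collapse = "")),
         regions = regions,
         config = config)
  })
}

#' Simulate day-0/day-16 guide counts with planted depletion
#'
#' Draws negative-binomial counts for every guide in a library at day 0
#' and day 16 in replicates. Per-guide library abundance is log-normal
#' around the configured depth; at day 16 the expected count of guides
#' belonging to a planted region is scaled by `2^effect`. A ground-truth
#' table of planted per-guide effects is returned alongside so
#' downstream sensitivity/FDR can be computed without inspecting
#' generator internals.
#'
#' @param library Data frame with at least `guide_id`, `region_id` and
#'   `cut_site` columns (as produced by [emit_library()]).
#' @param config A [sim_config()]; `planted_effects` maps region ids to
#'   per-guide log2 fold changes.
#' @return A [count_matrix()] with a `truth` data frame attached as
#'   element `truth` (guide_id, region_id, true_lfc).
#' @export
sim_screen_counts <- function(library, config) {
  stopifnot(inherits(config, "sim_config"))
  man <- if (is.list(library) && !is.data.frame(library)) library$manifest else library
  stopifnot(is.data.frame(man), all(c("guide_id", "region_id") %in% names(man)))
  if (!all(names(config$planted_effects) %in% man$region_id) &&
      length(config$planted_effects))
    stop("planted_effects names must be region ids present in the library")
  if (config$sequencing_depth <= 0 || config$nb_dispersion < 0)
    stop("depth must be positive and dispersion non-negative")
  ng <- nrow(man)
  r <- config$n_replicates
  alpha <- config$nb_dispersion
  with_substream(config$seed, 23L, {
    a <- stats::rlnorm(ng, meanlog = -config$abundance_sigma^2 / 2,
                       sdlog = config$abundance_sigma)
    mu0 <- config$sequencing_depth * a
    lfc <- rep(0, ng)
    if (length(config$planted_effects)) {
      hit <- match(man$region_id, names(config$planted_effects))
      lfc <- ifelse(is.na(hit), 0, config$planted_effects[hit])
    }
    mu16 <- mu0 * 2^lfc
    draw <- function(mu) {
      if (alpha == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
    }
    counts <- cbind(
      vapply(seq_len(r), function(j) draw(mu0), numeric(ng)),
      vapply(seq_len(r), function(j) draw(mu16), numeric(ng))
    )
    storage.mode(counts) <- "integer"
    samples <- data.frame(
      sample = c(sprintf("d0_r%d", seq_len(r)), sprintf("d16_r%d", seq_len(r))),
      timepoint = rep(c("day0", "day16"), each = r),
      replicate = rep(seq_len(r), 2L),
      stringsAsFactors = FALSE
    )
    colnames(counts) <- samples$sample
    rownames(counts) <- man$guide_id
    cm <- count_matrix(counts, samples)
    cm$truth <- data.frame(guide_id = man$guide_id,
                           region_id = man$region_id,
                           true_lfc = lfc,
                           stringsAsFactors = FALSE)
    cm
  })
}

#' Simulate a signal track correlated with essentiality
#'
#' Emits a piecewise-constant positive bedGraph-style track whose
#' per-region maximum has Pearson correlation approximately `rho` with a
#' supplied per-region essentiality z. Each region is covered by four
#' equal segments; the second carries the region maximum and the others
#' fixed fractions of it, which exercises interval-max extraction
#' downstream. Values are shifted by a common constant to be strictly
#' positive, which leaves the Pearson correlation untouched (and exact
#' at `|rho| = 1`).
#'
#' @param regions Region data frame (chrom, start, end, region_id).
#' @param essentiality_z Numeric vector, one value per region.
#' @param rho Target correlation in [-1, 1].
#' @param seed Integer seed.
#' @return A data frame with bedGraph columns chrom, start, end, value
#'   plus `region_id`, and the per-region maxima as attribute
#'   `region_max`.
#' @export
sim_signal_track <- function(regions, essentiality_z, rho, seed = 1L) {
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  stopifnot(nrow(regions) == length(essentiality_z))
  n <- nrow(regions)
  with_substream(seed, 37L, {
    z <- as.numeric(scale(essentiality_z))
    if (any(!is.finite(z))) z <- rep(0, n)  # constant input degenerates
    eps <- if (abs(rho) == 1) rep(0, n) else stats::rnorm(n)
    s <- rho * z + sqrt(max(0, 1 - rho^2)) * eps
    vmax <- s - min(s) + 1  # strictly positive, correlation-preserving
    frac <- c(0.5, 1, 0.75, 0.25)
    rows <- lapply(seq_len(n), function(i) {
      b <- round(seq(regions$start[i], regions$end[i], length.out = 5L))
      data.frame(chrom = regions$chrom[i],
                 start = b[1:4], end = b[2:5],
                 value = vmax[i] * frac,
                 region_id = regions$region_id[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "region_max") <- stats::setNames(vmax, regions$region_id)
    out
  })
}

# inverse Box-Cox; x = (1 + lambda * y)^(1/lambda), log branch at 0
inv_boxcox <- function(y, lambda) {
  if (lambda == 0) return(exp(y))
  (1 + lambda * y)^(1 / lambda)
}

#' Simulate a genotype/methylation/expression cohort
#'
#' Builds a cohort table in which a risk-allele dosage affects the focal
#' gene's expression only in samples whose CpG methylation exceeds the
#' configured threshold, emulating an eQTL masked by methylation-
#' dependent CTCF insulation. Methylation is a balanced
#' Beta(2,8)/Beta(8,2) mixture (bimodal on [0,1]); latent expression is
#' Gaussian on the Box-Cox scale (lambda = -0.1) and mapped through the
#' inverse transform to strictly positive values. A co-regulated
#' neighbor gene shares a latent factor with the focal gene only in the
#' high-methylation stratum; a second neighbor is independent.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of three gene column names: focal,
#'   co-regulated neighbor, independent neighbor.
#' @return A list with `cohort` (sample_id, genotype, meth, one column
#'   per gene) and `truth` (per-sample true stratum plus the planted
#'   parameters as attributes).
#' @export
sim_cohort <- function(config, genes = c("MYC", "PVT1", "CCAT1")) {
  stopifnot(inherits(config, "sim_config"), length(genes) == 3L)
  n <- config$cohort_n
  lambda <- -0.1
  with_substream(config$seed, 53L, {
    G <- stats::rbinom(n, 2L, config$maf)
    comp <- stats::runif(n) < 0.5
    meth <- ifelse(comp, stats::rbeta(n, 2, 8), stats::rbeta(n, 8, 2))
    high <- meth > config$meth_threshold
    # cohort_noise_sd is the total residual sd around the genotype
    # effect; a fraction coexpression_r of the residual variance is a
    # factor shared with the neighbor gene in the high stratum only, so
    # the in-stratum focal-neighbor Pearson r targets coexpression_r
    sigma <- config$cohort_noise_sd
    rr <- min(config$coexpression_r, 1)
    a <- sigma * sqrt(rr)
    e <- sigma * sqrt(1 - rr)
    u <- stats::rnorm(n)
    y_focal <- 1 + config$beta_geno * G * high + a * u * high +
      stats::rnorm(n, 0, 1) * ifelse(high, e, sigma)
    y_nbr <- 1 + a * u * high + stats::rnorm(n, 0, 1) * ifelse(high, e, sigma)
    y_ind <- 1 + stats::rnorm(n, 0, sigma)
    clamp <- function(y) pmin(y, 1 / abs(lambda) - 0.5)  # keep inverse defined
    cohort <- data.frame(
      sample_id = sprintf("s%03d", seq_len(n)),
      genotype = G,
      meth = meth,
      stringsAsFactors = FALSE
    )
    cohort[[genes[1]]] <- inv_boxcox(clamp(y_focal), lambda)
    cohort[[genes[2]]] <- inv_boxcox(clamp(y_nbr), lambda)
    cohort[[genes[3]]] <- inv_boxcox(clamp(y_ind), lambda)
    truth <- data.frame(sample_id = cohort$sample_id,
                        high_meth = high,
                        stringsAsFactors = FALSE)
    attr(truth, "beta_geno") <- config$beta_geno
    attr(truth, "meth_threshold") <- config$meth_threshold
    attr(truth, "coexpression_r") <- config$coexpression_r
    attr(truth, "lambda") <- lambda
    list(cohort = cohort, truth = truth)
  })
}
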
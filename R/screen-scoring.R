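#' Guide-by-sample count container
#'
#' A light container for pooled-screen counts: an integer matrix of
#' guides by samples, sample metadata (timepoint, replicate) and, once
#' computed, per-sample size factors.
#'
#' @param counts Non-negative integer matrix, guides in rows.
#' @param samples Data frame with columns `sample`, `timepoint`
#'   (`day0` / `day16`) and `replicate`, one row per count column.
#' @param size_factors Optional positive numeric vector, one per sample.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  stopifnot(nrow(samples) == ncol(counts),
            all(c("sample", "timepoint", "replicate") %in% names(samples)))
  if (!all(samples$timepoint %in% c("day0", "day16")))
    stop("timepoint must be day0 or day16")
  for (tp in c("day0", "day16"))
    if (!any(samples$timepoint == tp))
      stop("need at least one replicate per timepoint")
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
  }
  structure(list(counts = counts, samples = samples,
                 size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " guides x ", ncol(x$counts),
      " samples (", paste(x$samples$sample, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$size_factors))
    cat("  size factors: ",
        paste(sprintf("%.3f", x$size_factors), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Count reads against a guide library
#'
#' Assigns each read to exactly one guide by exact (0-mismatch) match of
#' the protospacer found at a fixed offset in the read; everything else
#' is counted as unassigned, so assigned + unassigned equals the input
#' read count per sample. Duplicate protospacers in the library are an
#' error unless they are flagged `ambiguous`.
#'
#' @param reads A named list of character vectors (one per sample), a
#'   single character vector, or paths to FASTA/FASTQ files.
#' @param library Library manifest data frame (or [emit_library()]
#'   output) with `guide_id` and `protospacer`.
#' @param samples Optional sample metadata; defaults to parsing sample
#'   names of the form `d0_r1` / `d16_r2`.
#' @param offset 0-based offset of the protospacer within each read.
#' @return A [count_matrix()] with an `unassigned` integer vector
#'   attached.
#' @export
count_guides <- function(reads, library, samples = NULL, offset = 0L) {
  man <- if (is.list(library) && !is.data.frame(library)) library$manifest else library
  dup <- duplicated(man$protospacer)
  if (any(dup)) {
    flagged <- if ("ambiguous" %in% names(man)) man$ambiguous[dup] else FALSE
    if (!all(flagged)) stop("duplicate protospacers in library")
    man <- man[!dup, , drop = FALSE]
  }
  if (is.character(reads) && length(reads) <= 8 && all(file.exists(reads))) {
    nm <- names(reads) %||% sub("\\.[^.]*$", "", basename(reads))
    reads <- lapply(reads, function(p) {
      fmt <- if (grepl("\\.f(ast)?q$", p)) "fastq" else "fasta"
      as.character(Biostrings::readDNAStringSet(p, format = fmt))
    })
    names(reads) <- nm
  }
  if (!is.list(reads)) reads <- list(sample1 = reads)
  width <- nchar(man$protospacer[1])
  counts <- vapply(reads, function(rd) {
    key <- substr(rd, offset + 1L, offset + width)
    idx <- match(key, man$protospacer)
    tabulate(idx, nbins = nrow(man))
  }, integer(nrow(man)))
  counts <- matrix(counts, nrow = nrow(man),
                   dimnames = list(man$guide_id, names(reads)))
  unassigned <- vapply(seq_along(reads), function(j)
    length(reads[[j]]) - sum(counts[, j]), integer(1))
  if (is.null(samples)) {
    nm <- names(reads)
    samples <- data.frame(
      sample = nm,
      timepoint = ifelse(grepl("16", nm), "day16", "day0"),
      replicate = as.integer(sub(".*r", "", nm)),
      stringsAsFactors = FALSE)
    if (any(is.na(samples$replicate))) samples$replicate <- seq_along(nm)
  }
  cm <- count_matrix(counts, samples)
  cm$unassigned <- stats::setNames(unassigned, names(reads))
  cm
}

#' Median-of-ratios size factors
#'
#' Computes per-sample size factors as the median, over guides, of the
#' ratio of the guide's count to its geometric mean across samples;
#' guides containing a zero are excluded from the reference. Normalized
#' counts are raw counts divided by the sample's size factor.
#'
#' @param cm A [count_matrix()].
#' @return The input with `size_factors` filled in.
#' @export
normalize_counts <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  k <- cm$counts
  if (ncol(k) < 2) stop("need at least two samples")
  if (any(colSums(k) == 0)) stop("sample with all-zero counts")
  pos <- rowSums(k == 0) == 0
  if (!any(pos)) stop("no guide observed in every sample; cannot normalize")
  lg <- log(k[pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  sf <- apply(k[pos, , drop = FALSE], 2, function(col) stats::median(col / geo))
  cm$size_factors <- sf
  cm
}

normalized <- function(cm) {
  if (is.null(cm$size_factors)) cm <- normalize_counts(cm)
  sweep(cm$counts, 2, cm$size_factors, "/")
}

#' Per-guide negative-binomial depletion test
#'
#' Tests each guide for loss of representation between day 0 and day 16.
#' A single pooled dispersion alpha is estimated from the moment
#' identity `E[s^2 - m] = alpha * mu^2` pooled across all guides and
#' timepoints, solved as a bias-corrected ratio of sums and clamped at
#' 0 (see the methods vignette), then a Wald test on the log2 fold change uses the
#' delta-method standard error under NB(mu, alpha). A pseudocount of 0.5
#' is added to the normalized means before taking logs. The one-sided
#' depletion p-value is half the two-sided p when the fold change is
#' negative and one minus that half otherwise.
#'
#' @param cm A normalized [count_matrix()] (normalized on the fly if
#'   size factors are missing).
#' @return Data frame: guide_id, mean_day0, mean_day16, log2fc, se,
#'   p_two, p_dep; pooled `alpha` as an attribute.
#' @export
guide_depletion_test <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$size_factors)) cm <- normalize_counts(cm)
  nm <- normalized(cm)
  i0 <- which(cm$samples$timepoint == "day0")
  i1 <- which(cm$samples$timepoint == "day16")
  if (length(i0) < 2 || length(i1) < 2)
    warning("single replicate in an arm; dispersion from pooled fit only")
  m0 <- rowMeans(nm[, i0, drop = FALSE])
  m1 <- rowMeans(nm[, i1, drop = FALSE])

  # pooled moment estimate of alpha: E[s^2 - kappa*m] = alpha*mu^2, with
  # kappa the Poisson part of normalized counts (var(raw/s) = mu/s +
  # alpha*mu^2). The squared sample mean overestimates mu^2 by
  # (kappa*mu + alpha*mu^2)/r, so the ratio-of-sums is solved with that
  # correction iteratively; summing before dividing avoids the
  # attenuation a per-guide regression on the noisy m^2 would suffer.
  ms <- vs <- kaps <- rs <- numeric(0)
  for (idx in list(i0, i1)) {
    if (length(idx) < 2) next
    m <- rowMeans(nm[, idx, drop = FALSE])
    v <- apply(nm[, idx, drop = FALSE], 1, stats::var)
    kap <- mean(1 / cm$size_factors[idx])
    ms <- c(ms, m); vs <- c(vs, v)
    kaps <- c(kaps, rep(kap, length(m))); rs <- c(rs, rep(length(idx), length(m)))
  }
  alpha <- 0
  if (length(ms)) {
    num <- sum(vs - kaps * ms)
    for (it in 1:20) {
      den <- sum(ms^2 - (kaps * ms + alpha * ms^2) / rs)
      a_new <- max(0, num / den)
      if (abs(a_new - alpha) < 1e-10) { alpha <- a_new; break }
      alpha <- a_new
    }
  }

  var_mean <- function(m, idx) {
    # variance of the mean of normalized replicate counts at mu ~ m
    sum(m / cm$size_factors[idx] + alpha * m^2) / length(idx)^2
  }
  v0 <- vapply(m0, var_mean, numeric(1), idx = i0)
  v1 <- vapply(m1, var_mean, numeric(1), idx = i1)
  lfc <- log2((m1 + 0.5) / (m0 + 0.5))
  se <- sqrt(v1 / ((m1 + 0.5)^2) + v0 / ((m0 + 0.5)^2)) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p_two <- 2 * stats::pnorm(-abs(z))
  p_dep <- stats::pnorm(z)
  out <- data.frame(guide_id = rownames(cm$counts) %||%
                      sprintf("g%05d", seq_along(m0)),
                    mean_day0 = m0, mean_day16 = m1,
                    log2fc = lfc, se = se, p_two = p_two, p_dep = p_dep,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

# alpha-RRA score of a window: u = library-wide rank percentiles of the
# member guides, gate = which members pass the significance gate.
rra_score <- function(u, gated) {
  m <- length(u)
  if (!any(gated)) return(1)
  o <- order(u)
  u <- u[o]; gated <- gated[o]
  k <- max(which(gated))          # gated guides occupy the best ranks first
  j <- seq_len(m)
  keep <- j <= sum(gated)
  min(stats::pbeta(u[keep], j[keep], m - j[keep] + 1))
}

#' Sliding-window rank aggregation and region essentiality
#'
#' Splits each region into 100-bp windows at a 50-bp offset (windows lie
#' wholly inside the region), assigns guides to windows by cut-site
#' containment, drops windows with fewer than `min_guides` guides, and
#' scores each window by alpha-RRA over its members' library-wide
#' depletion-rank percentiles: the score is the smallest Beta
#' order-statistic probability over the members that pass the `alpha`
#' significance gate. Window p-values come from permuting the
#' guide-to-window assignment (exact enumeration when the number of
#' member subsets is small, Monte Carlo otherwise). Each region is
#' summarized by its lowest-p window; regions sharing a parent id are
#' merged into the single most essential window. The region depletion
#' score is the representative window's RRA score (smaller = more
#' essential), reported alongside as -log10 for ranking.
#'
#' @param regions Region data frame (with parent_id for merging).
#' @param guide_stats Output of [guide_depletion_test()] for the whole
#'   library.
#' @param manifest Library manifest (guide_id, region_id, cut_site,
#'   optionally ambiguous — ambiguous guides are excluded).
#' @param window,offset Window length and offset in bp.
#' @param min_guides Minimum guides per window.
#' @param alpha Significance gate: guides with one-sided depletion p
#'   below this count toward the order statistic.
#' @param nperm Monte Carlo permutations for window p-values.
#' @param exact_limit Enumerate all member subsets exactly when
#'   `choose(n_guides, m)` is at most this (default 2e4).
#' @param seed Seed for the permutation stream.
#' @return List: `windows` (region_id, start, end, n_guides, rra_score,
#'   p_window, fold_change) and `regions` (region_id, merged_parent_id,
#'   depletion_score, score_neglog10, p_region, representative window,
#'   n_windows).
#' @export
window_aggregate <- function(regions, guide_stats, manifest,
                             window = 100L, offset = 50L, min_guides = 2L,
                             alpha = 0.25, nperm = 10000L,
                             exact_limit = 2e4, seed = 1L) {
  man <- manifest
  if ("ambiguous" %in% names(man)) man <- man[!man$ambiguous, , drop = FALSE]
  gs <- guide_stats[match(man$guide_id, guide_stats$guide_id), ]
  n_lib <- nrow(guide_stats)
  u_all <- rank(guide_stats$p_dep, ties.method = "average") / n_lib
  u <- u_all[match(man$guide_id, guide_stats$guide_id)]
  gated <- gs$p_dep < alpha

  win_rows <- list()
  for (i in seq_len(nrow(regions))) {
    rs <- regions$start[i]; re <- regions$end[i]
    ws <- seq(rs, re, by = offset)
    ws <- ws[ws + window <= re]
    if (!length(ws)) next
    memb <- man$region_id == regions$region_id[i]
    for (s in ws) {
      inw <- memb & man$cut_site >= s & man$cut_site < s + window
      m <- sum(inw)
      if (m < min_guides) next
      sc <- rra_score(u[inw], gated[inw])
      fc <- mean(gs$log2fc[inw])
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        region_id = regions$region_id[i], start = s, end = s + window,
        n_guides = m, rra_score = sc, fold_change = fc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(win_rows)) {
    windows <- data.frame(region_id = character(0), start = integer(0),
                          end = integer(0), n_guides = integer(0),
                          rra_score = numeric(0), p_window = numeric(0),
                          fold_change = numeric(0))
  } else {
    windows <- do.call(rbind, win_rows)
    # null distribution of the score shared across windows with equal m;
    # permutes the guide-to-window assignment over the whole library
    windows$p_window <- NA_real_
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(substream_seed(seed, 71L))
    for (m in unique(windows$n_guides)) {
      rows <- which(windows$n_guides == m)
      nullsc <- window_null_scores(u_all, guide_stats$p_dep < alpha, m,
                                   nperm, exact_limit)
      for (r in rows)
        windows$p_window[r] <-
          (1 + sum(nullsc <= windows$rra_score[r])) / (length(nullsc) + 1)
    }
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }

  reg_rows <- lapply(seq_len(nrow(regions)), function(i) {
    w <- windows[windows$region_id == regions$region_id[i], , drop = FALSE]
    if (!nrow(w)) {
      return(data.frame(region_id = regions$region_id[i],
                        merged_parent_id = regions$parent_id[i],
                        depletion_score = 1, score_neglog10 = 0,
                        p_region = 1, rep_start = NA_integer_,
                        rep_end = NA_integer_, n_windows = 0L,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    b <- w[order(w$p_window, w$rra_score, w$start), ][1, ]
    data.frame(region_id = regions$region_id[i],
               merged_parent_id = regions$parent_id[i],
               depletion_score = b$rra_score,
               score_neglog10 = -log10(b$rra_score),
               p_region = b$p_window,
               rep_start = b$start, rep_end = b$end,
               n_windows = nrow(w), flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, reg_rows)

  # adjacent splits of one parent interval collapse to their best window
  has_parent <- !is.na(reg$merged_parent_id)
  if (any(has_parent)) {
    keep <- !has_parent
    merged <- lapply(split(reg[has_parent, ], reg$merged_parent_id[has_parent]),
                     function(g) {
      b <- g[order(g$p_region, g$depletion_score, g$rep_start), ][1, ]
      b$region_id <- b$merged_parent_id
      b
    })
    reg <- rbind(reg[keep, ], do.call(rbind, merged))
    rownames(reg) <- NULL
  }
  list(windows = windows, regions = reg)
}

# Null alpha-RRA scores for windows of m guides drawn from a library of
# percentiles u (gate precomputed). Exact over all subsets when feasible.
window_null_scores <- function(u, gated, m, nperm, exact_limit) {
  n <- length(u)
  if (choose(n, m) <= exact_limit) {
    cmb <- utils::combn(n, m)
    apply(cmb, 2, function(ix) rra_score(u[ix], gated[ix]))
  } else {
    vapply(seq_len(nperm), function(b) {
      ix <- sample.int(n, m)
      rra_score(u[ix], gated[ix])
    }, numeric(1))
  }
}

#' Compare depletion p-value distributions between guide groups
#'
#' Computes each group's empirical CDF on a common grid and the
#' two-sample Kolmogorov-Smirnov D statistic with asymptotic p for every
#' pair of groups, e.g. promoter-control versus insensitive-control
#' versus rCRE-targeting guides.
#'
#' @param groups Named list of numeric vectors (e.g. per-guide depletion
#'   p-values), each of length at least 5.
#' @param grid Evaluation grid; defaults to the pooled sorted values.
#' @return List: `ecdf` (long data frame group/x/F) and `ks` (pairwise
#'   data frame with D and p).
#' @export
group_depletion_comparison <- function(groups, grid = NULL) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  if (any(vapply(groups, length, integer(1)) < 5))
    stop("each group needs at least 5 values")
  if (is.null(grid)) grid <- sort(unique(unlist(groups)))
  ec <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, x = grid, F = stats::ecdf(groups[[g]])(grid),
               stringsAsFactors = FALSE)))
  prs <- utils::combn(names(groups), 2)
  ks <- do.call(rbind, apply(prs, 2, function(p) {
    kt <- suppressWarnings(stats::ks.test(groups[[p[1]]], groups[[p[2]]]))
    data.frame(group_a = p[1], group_b = p[2],
               D = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(ecdf = ec, ks = ks)
}
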
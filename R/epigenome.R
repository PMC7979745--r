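#' Maximum signal per region from a bedGraph track
#'
#' For each region, returns the maximum track value over any base of the
#' region (bedGraph semantics: piecewise constant, 0-based half-open).
#' Regions with no overlapping interval get 0; overlapping track
#' intervals are an error.
#'
#' @param track bedGraph data frame (chrom, start, end, value).
#' @param regions Region data frame (chrom, start, end, region_id).
#' @return Named numeric vector of per-region maxima; the number of
#'   uncovered regions is attached as attribute `n_uncovered`.
#' @export
extract_region_signal <- function(track, regions) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  for (ch in unique(track$chrom)) {
    tt <- track[track$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    if (any(tt$start[-1] < tt$end[-nrow(tt)]))
      stop("malformed track: overlapping intervals on ", ch)
  }
  out <- vapply(seq_len(nrow(regions)), function(i) {
    hit <- track$chrom == regions$chrom[i] &
      track$start < regions$end[i] & regions$start[i] < track$end
    if (!any(hit)) 0 else max(track$value[hit])
  }, numeric(1))
  names(out) <- regions$region_id
  attr(out, "n_uncovered") <- sum(out == 0 & vapply(
    seq_len(nrow(regions)), function(i)
      !any(track$chrom == regions$chrom[i] &
             track$start < regions$end[i] & regions$start[i] < track$end),
    logical(1)))
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their rank midpoints,
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties. Order is
#' preserved, so rank correlations are invariant under the transform.
#'
#' @param values Numeric vector (n >= 2).
#' @return Transformed vector in input order.
#' @examples
#' rank_inverse_normal(c(3, 7))  # -0.6745, +0.6745
#' @export
rank_inverse_normal <- function(values) {
  n <- length(values)
  stopifnot(n >= 2)
  if (length(unique(values)) == 1L) {
    warning("all values identical; returning zeros")
    return(rep(0, n))
  }
  stats::qnorm((rank(values, ties.method = "average") - 0.5) / n)
}

#' Correlate depletion scores with epigenomic signal
#'
#' For each mark, Spearman and Pearson correlation (with p) between
#' per-region depletion scores and signal, plus a linear regression of
#' the score on the rank-inverse-normalized signal. Significance tiers
#' at 0.05 / 0.01 / 0.005 are recorded as the usual one- to three-star
#' labels.
#'
#' @param scores Named numeric vector of per-region depletion scores.
#' @param signal_matrix Matrix or data frame of per-region signal, one
#'   column per mark, rows aligned with `scores` (by name when both are
#'   named).
#' @return Data frame: mark, spearman_r, spearman_p, pearson_r,
#'   pearson_p, slope, slope_p, tier.
#' @export
correlate_depletion_epigenome <- function(scores, signal_matrix) {
  sm <- as.matrix(signal_matrix)
  if (!is.null(rownames(sm)) && !is.null(names(scores)))
    sm <- sm[names(scores), , drop = FALSE]
  stopifnot(nrow(sm) == length(scores))
  tier <- function(p) {
    if (is.na(p)) "" else if (p <= 0.005) "***" else if (p <= 0.01) "**"
    else if (p <= 0.05) "*" else ""
  }
  rows <- lapply(colnames(sm) %||% sprintf("mark%d", seq_len(ncol(sm))),
                 function(mk) {
    v <- sm[, mk]
    if (stats::sd(v) == 0)
      return(data.frame(mark = mk, spearman_r = NA, spearman_p = NA,
                        pearson_r = NA, pearson_p = NA, slope = NA,
                        slope_p = NA, tier = "", reason = "constant signal",
                        stringsAsFactors = FALSE))
    sp <- suppressWarnings(stats::cor.test(scores, v, method = "spearman"))
    pe <- stats::cor.test(scores, v, method = "pearson")
    fit <- summary(stats::lm(scores ~ rank_inverse_normal(v)))
    data.frame(mark = mk,
               spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
               pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               slope = fit$coefficients[2, 1],
               slope_p = fit$coefficients[2, 4],
               tier = tier(sp$p.value), reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Risk-SNP odds-ratio enrichment in the most essential regions
#'
#' Each region is represented by the highest odds ratio among its risk
#' SNPs falling in the region's 600-bp window (the 400-bp core plus
#' `flank` bp on each side). Regions are ranked by depletion score per
#' screen (smaller = more essential); the top `top_fraction` per screen
#' and their intersection across screens are compared with the rest by
#' median difference and a Wilcoxon rank-sum test.
#'
#' @param regions Region data frame (chrom, start, end, region_id).
#' @param snps Data frame of risk SNPs: snp_id, chrom, position,
#'   odds_ratio (> 0).
#' @param scores Matrix or data frame of per-region depletion scores,
#'   one column per screen, rows aligned with `regions`.
#' @param top_fraction Fraction called "top" (default 0.25).
#' @param flank Flank added to each side of the region core (default
#'   100 bp, giving the 600-bp window for 400-bp regions).
#' @return List: `table` (region_id, representative_or, top flags),
#'   `excluded` (regions without an OR), and per-grouping median
#'   difference + rank-sum p in `tests`.
#' @export
snp_or_enrichment <- function(regions, snps, scores, top_fraction = 0.25,
                              flank = 100L) {
  stopifnot(all(snps$odds_ratio > 0))
  sc <- as.matrix(scores)
  stopifnot(nrow(sc) == nrow(regions))
  rep_or <- vapply(seq_len(nrow(regions)), function(i) {
    hit <- snps$chrom == regions$chrom[i] &
      snps$position >= regions$start[i] - flank &
      snps$position < regions$end[i] + flank
    if (!any(hit)) NA_real_ else max(snps$odds_ratio[hit])
  }, numeric(1))
  keep <- !is.na(rep_or)
  excluded <- regions$region_id[!keep]
  tab <- data.frame(region_id = regions$region_id[keep],
                    representative_or = rep_or[keep],
                    stringsAsFactors = FALSE)
  sc <- sc[keep, , drop = FALSE]
  screens <- colnames(sc) %||% sprintf("screen%d", seq_len(ncol(sc)))
  topm <- vapply(seq_len(ncol(sc)), function(j) {
    rank(sc[, j], ties.method = "first") <= ceiling(top_fraction * nrow(sc))
  }, logical(nrow(sc)))
  colnames(topm) <- paste0("top_", screens)
  tab <- cbind(tab, topm)
  tab$top_intersection <- rowSums(topm) == ncol(topm)
  groupings <- c(paste0("top_", screens), "top_intersection")
  tests <- do.call(rbind, lapply(groupings, function(g) {
    top <- tab$representative_or[tab[[g]]]
    rest <- tab$representative_or[!tab[[g]]]
    if (!length(top) || !length(rest))
      return(data.frame(grouping = g, median_diff = NA, p = NA))
    wt <- suppressWarnings(stats::wilcox.test(top, rest))
    data.frame(grouping = g,
               median_diff = stats::median(top) - stats::median(rest),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
  list(table = tab, excluded = excluded, tests = tests)
}

#' Spearman correlation between methylation and binding signal
#'
#' Tests for (anti-)correlation between CpG methylation fractions and a
#' binding signal across cell lines or samples. The p-value uses the
#' exact Spearman null distribution for small n (n <= 10, no ties) and
#' the asymptotic approximation otherwise.
#'
#' @param meth_fractions Methylation fractions in [0, 1] (n >= 5).
#' @param binding_signals Paired binding signal values.
#' @return List: rho, p, n, method.
#' @export
methylation_binding_correlation <- function(meth_fractions, binding_signals) {
  n <- length(meth_fractions)
  stopifnot(n == length(binding_signals), n >= 5,
            all(meth_fractions >= 0 & meth_fractions <= 1))
  if (length(unique(meth_fractions)) == 1L ||
      length(unique(binding_signals)) == 1L)
    stop("ties-only input: correlation undefined")
  exact <- n <= 10
  ct <- suppressWarnings(
    stats::cor.test(meth_fractions, binding_signals,
                    method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = if (exact) "exact" else "asymptotic")
}
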
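#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda` for lambda != 0 and `log(x)` at lambda = 0;
#' strictly increasing in x for every lambda. Non-positive values are an
#' error — no silent offsets are applied.
#'
#' @param x Positive numeric vector.
#' @param lambda Power parameter (default -0.1, the value used for the
#'   cohort expression data).
#' @return Transformed vector with `lambda` attached as an attribute.
#' @examples
#' boxcox_transform(exp(1), -0.1)  # ~0.95163
#' @export
boxcox_transform <- function(x, lambda = -0.1) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  out <- if (lambda == 0) log(x) else (x^lambda - 1) / lambda
  attr(out, "lambda") <- lambda
  out
}

#' Split a cohort at the median methylation
#'
#' Labels samples `high` when methylation exceeds the median and `low`
#' otherwise (ties at the median go to `low`; deterministic).
#'
#' @param meth Methylation fractions (n >= 2).
#' @return Factor with levels `high`, `low`; the median and stratum
#'   sizes are attached as attributes.
#' @export
dichotomize_by_median <- function(meth) {
  n <- length(meth)
  stopifnot(n >= 2)
  if (max(table(meth)) > n / 2)
    warning("degenerate split: more than half the values are identical")
  med <- stats::median(meth)
  lab <- factor(ifelse(meth > med, "high", "low"), levels = c("high", "low"))
  attr(lab, "median") <- med
  attr(lab, "sizes") <- c(high = sum(lab == "high"), low = sum(lab == "low"))
  attr(lab, "tie_policy") <- "<= median -> low"
  lab
}

#' Methylation-stratified eQTL regression
#'
#' Dichotomizes the cohort at the median methylation, Box-Cox transforms
#' the gene's expression, and regresses it on additive genotype dosage
#' separately in each stratum; a pooled model with a genotype-by-stratum
#' interaction term is reported alongside. A stratum with monomorphic
#' genotype yields NA with a reason.
#'
#' @param cohort Data frame with `genotype` (dosage 0/1/2), `meth`, and
#'   one expression column per gene.
#' @param gene Name of the expression column to analyze.
#' @param lambda Box-Cox lambda (fixed input, not re-estimated).
#' @param covariates Optional character vector of covariate columns
#'   added to each model (defaults to none).
#' @return List: `strata` (data frame stratum/n/beta/se/p/
#'   transform_lambda/reason), `interaction` (beta and p of the
#'   genotype x high-stratum term), `stratum` (per-sample labels).
#' @export
stratified_eqtl <- function(cohort, gene, lambda = -0.1,
                            covariates = character(0)) {
  stopifnot(gene %in% names(cohort),
            all(c("genotype", "meth") %in% names(cohort)))
  stopifnot(all(cohort$genotype %in% 0:2))
  stratum <- dichotomize_by_median(cohort$meth)
  y <- as.numeric(boxcox_transform(cohort[[gene]], lambda))
  cov_str <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""
  one <- function(lv) {
    ix <- stratum == lv
    d <- cohort[ix, , drop = FALSE]
    d$.y <- y[ix]
    if (sum(ix) < 3 || length(unique(d$genotype)) < 2)
      return(data.frame(stratum = lv, n = sum(ix), beta = NA_real_,
                        se = NA_real_, p = NA_real_,
                        transform_lambda = lambda,
                        reason = if (sum(ix) < 3) "too few samples"
                                 else "monomorphic genotype",
                        stringsAsFactors = FALSE))
    fit <- stats::lm(stats::as.formula(paste(".y ~ genotype", cov_str)),
                     data = d)
    cf <- summary(fit)$coefficients
    data.frame(stratum = lv, n = sum(ix), beta = cf["genotype", 1],
               se = cf["genotype", 2], p = cf["genotype", 4],
               transform_lambda = lambda, reason = "",
               stringsAsFactors = FALSE)
  }
  strata <- rbind(one("high"), one("low"))
  d <- cohort
  d$.y <- y
  d$.high <- as.integer(stratum == "high")
  inter <- stats::lm(stats::as.formula(
    paste(".y ~ genotype * .high", cov_str)), data = d)
  ic <- summary(inter)$coefficients
  row <- "genotype:.high"
  interaction <- if (row %in% rownames(ic))
    list(beta = ic[row, 1], p = ic[row, 4])
  else list(beta = NA_real_, p = NA_real_)
  list(strata = strata, interaction = interaction, stratum = stratum)
}

#' Stratum-specific co-expression with a focal gene
#'
#' Pearson correlation (on the Box-Cox scale) between the focal gene and
#' each neighbor, computed separately in the high- and low-methylation
#' strata.
#'
#' @param cohort Cohort data frame (needs `meth` plus gene columns).
#' @param focal_gene Focal gene column name.
#' @param neighbors Neighbor gene columns; defaults to every other gene
#'   column.
#' @param lambda Box-Cox lambda applied to expression before
#'   correlating.
#' @return Data frame: neighbor, stratum, n, r, p (NA with reason for
#'   constant genes).
#' @export
coexpression_by_stratum <- function(cohort, focal_gene, neighbors = NULL,
                                    lambda = -0.1) {
  stopifnot(focal_gene %in% names(cohort))
  if (is.null(neighbors)) {
    known <- c("sample_id", "genotype", "meth", focal_gene)
    neighbors <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                         known)
  }
  stratum <- dichotomize_by_median(cohort$meth)
  yf <- as.numeric(boxcox_transform(cohort[[focal_gene]], lambda))
  rows <- list()
  for (nb in neighbors) {
    yn <- as.numeric(boxcox_transform(cohort[[nb]], lambda))
    for (lv in c("high", "low")) {
      ix <- stratum == lv
      if (sum(ix) < 3 || stats::sd(yn[ix]) == 0 || stats::sd(yf[ix]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          neighbor = nb, stratum = lv, n = sum(ix),
          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(yf[ix], yn[ix])
      rows[[length(rows) + 1L]] <- data.frame(
        neighbor = nb, stratum = lv, n = sum(ix),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
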
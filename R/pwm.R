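#' Build a position weight matrix object
#'
#' Validates a 4 x L weight matrix over A, C, G, T and precomputes the
#' per-column extremes used for min-max score normalization.
#'
#' @param mat Numeric 4 x L matrix with rownames A, C, G, T (L >= 4).
#' @return An object of class `pwm`.
#' @export
pwm_matrix <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4, all(is.finite(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- c("A", "C", "G", "T")
  stopifnot(setequal(rownames(mat), c("A", "C", "G", "T")))
  mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  structure(list(mat = mat,
                 col_max = apply(mat, 2, max),
                 col_min = apply(mat, 2, min)),
            class = "pwm")
}

#' Read a PWM from a 4-row tab-separated file
#'
#' Expects a header line naming the rows (A, C, G, T in the first
#' column) or a bare 4 x L numeric table in ACGT row order.
#'
#' @param path File path.
#' @return A [pwm_matrix()].
#' @export
read_pwm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (is.character(df[[1]])) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    mat <- as.matrix(df)
    rownames(mat) <- rn
  } else {
    mat <- as.matrix(df)
    rownames(mat) <- c("A", "C", "G", "T")
  }
  pwm_matrix(mat)
}

# reverse-complemented PWM: reverse columns, swap A<->T and C<->G rows
pwm_revcomp <- function(p) {
  m <- p$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(p$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm_matrix(m)
}

pwm_window_scores <- function(seq_chars, p) {
  L <- ncol(p$mat)
  n <- length(seq_chars)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  s <- numeric(nw)
  for (j in seq_len(L))
    s <- s + p$mat[cbind(idx[j:(nw + j - 1L)], j)]
  s
}

#' Scan a sequence with a PWM at a similarity threshold
#'
#' Scores every length-L window on both strands and reports hits whose
#' min-max normalized score, `(S - S_min) / (S_max - S_min)`, reaches
#' the threshold (default 0.75). Coordinates are forward-strand, 0-based
#' half-open; minus-strand hits come from scoring the
#' reverse-complemented matrix at the same forward coordinates.
#'
#' @param sequence ACGT string.
#' @param pwm A [pwm_matrix()] (or bare 4 x L matrix).
#' @param threshold Normalized-score cutoff in (0, 1].
#' @return Data frame: start, end, strand, score (normalized).
#' @export
pwm_scan <- function(sequence, pwm, threshold = 0.75) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!inherits(pwm, "pwm")) pwm <- pwm_matrix(pwm)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  stopifnot(all(ch %in% c("A", "C", "G", "T")))
  L <- ncol(pwm$mat)
  smax <- sum(pwm$col_max); smin <- sum(pwm$col_min)
  norm <- function(s) (s - smin) / (smax - smin)
  hits <- list()
  for (str in c("+", "-")) {
    p <- if (str == "+") pwm else pwm_revcomp(pwm)
    s <- pwm_window_scores(ch, p)
    ns <- norm(s)
    at <- which(ns >= threshold)
    if (length(at))
      hits[[str]] <- data.frame(start = at - 1L, end = at - 1L + L,
                                strand = str, score = ns[at],
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}
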
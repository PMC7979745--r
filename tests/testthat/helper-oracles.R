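# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (regex / per-base / enumeration) so they share no
# code path with the implementation they check.

random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all protospacer-20 + NGG sites in a sequence, both strands, via
# overlapping regex; returns protospacer strings with 0-based starts
oracle_pam_scan <- function(seq) {
  hit <- function(s, strand) {
    m <- gregexpr("(?=([ACGT]{20}[ACGT]GG))", s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(pos = as.integer(m) - 1L,
               protospacer = substring(s, m, m + 19L),
               strand = strand, stringsAsFactors = FALSE)
  }
  fwd <- hit(seq, "+")
  rc <- hit(oracle_revcomp(seq), "-")
  if (!is.null(rc) && nrow(rc)) {
    # mirror coordinates back to the forward strand: a protospacer at
    # rc-position p spans forward [n - p - 23 + 3, n - p - 23 + 23)
    n <- nchar(seq)
    rc$pos <- n - rc$pos - 23L + 3L
  }
  out <- rbind(fwd, rc)
  if (is.null(out)) out <- data.frame(pos = integer(0),
                                      protospacer = character(0),
                                      strand = character(0))
  out[order(out$pos, out$strand), , drop = FALSE]
}

# exact occurrences of protospacer+NGG on both strands by regex
oracle_genome_matches <- function(proto, genome) {
  pat <- paste0("(?=", proto, "[ACGT]GG)")
  n <- 0L
  for (s in genome) {
    for (q in c(s, oracle_revcomp(s))) {
      m <- gregexpr(pat, q, perl = TRUE)[[1]]
      n <- n + if (m[1] == -1) 0L else length(m)
    }
  }
  n
}

# per-base maximum of a bedGraph over a region
oracle_region_max <- function(track, chrom, start, end) {
  best <- 0
  covered <- FALSE
  for (b in start:(end - 1L)) {
    hit <- track$chrom == chrom & track$start <= b & b < track$end
    if (any(hit)) {
      covered <- TRUE
      best <- max(best, track$value[hit])
    }
  }
  if (!covered) 0 else best
}

# exhaustive PWM window scores (both strands), min-max normalized
oracle_pwm_hits <- function(seq, mat, threshold) {
  L <- ncol(mat)
  n <- nchar(seq)
  smax <- sum(apply(mat, 2, max)); smin <- sum(apply(mat, 2, min))
  score_at <- function(s, i) {
    w <- strsplit(substr(s, i, i + L - 1L), "")[[1]]
    sum(mat[cbind(match(w, rownames(mat)), seq_len(L))])
  }
  rows <- list()
  rcseq <- oracle_revcomp(seq)
  for (i in seq_len(n - L + 1L)) {
    ns <- (score_at(seq, i) - smin) / (smax - smin)
    if (ns >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(start = i - 1L, end = i - 1L + L,
                                              strand = "+", score = ns)
    nsr <- (score_at(rcseq, n - (i - 1L) - L + 1L) - smin) / (smax - smin)
    if (nsr >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(start = i - 1L, end = i - 1L + L,
                                              strand = "-", score = nsr)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(start = integer(0), end = integer(0),
                                      strand = character(0), score = numeric(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all permutations of 1..n (small n only)
oracle_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# a tiny saturated library for window tests: guide percentiles are
# implied by assigning p-values directly
toy_guide_stats <- function(p_dep) {
  data.frame(guide_id = sprintf("g%03d", seq_along(p_dep)),
             p_dep = p_dep, log2fc = stats::qnorm(p_dep),
             stringsAsFactors = FALSE)
}

with_seed <- function(seed, code) withr::with_seed(seed, code)
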
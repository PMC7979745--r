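#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Prepare tileable target regions
#'
#' Splits raw intervals wider than `window` bp into consecutive
#' `window`-bp regions that share a parent id (so adjacent splits can be
#' merged after scoring), builds `window`-bp promoter-control regions
#' centered on supplied TSSs, and passes through DNase-insensitive
#' control intervals. A trailing remainder shorter than `window / 2` is
#' merged into the previous window; a longer remainder becomes its own
#' (short) region.
#'
#' @param raw_intervals BED-like data frame (chrom, start, end, and
#'   optionally region_id, locus) of candidate regulatory elements.
#' @param tss_table Optional data frame (chrom, tss, gene) of
#'   transcription start sites for promoter controls.
#' @param insensitive_intervals Optional BED-like data frame of
#'   DNase-insensitive control regions.
#' @param window Region width in bp (default 400).
#' @param genome Optional named character vector; when given, intervals
#'   are validated against sequence bounds.
#' @return Data frame of regions: chrom, start, end, region_id, class
#'   (`rcre`, `promoter_control`, `insensitive_control`), parent_id,
#'   locus.
#' @examples
#' iv <- data.frame(chrom = "chr1", start = 0, end = 1200, region_id = "e1")
#' prepare_target_regions(iv)
#' @export
prepare_target_regions <- function(raw_intervals, tss_table = NULL,
                                   insensitive_intervals = NULL,
                                   window = 400L, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(raw_intervals)))
  if (any(raw_intervals$end <= raw_intervals$start))
    stop("malformed BED: end <= start")
  check_bounds <- function(chrom, start, end, what) {
    if (is.null(genome)) return(invisible())
    len <- nchar(genome)[match(chrom, names(genome))]
    if (any(is.na(len)) || any(start < 0) || any(end > len))
      stop(what, " outside genome bounds")
  }
  check_bounds(raw_intervals$chrom, raw_intervals$start, raw_intervals$end,
               "interval")
  ids <- if ("region_id" %in% names(raw_intervals)) raw_intervals$region_id
         else sprintf("iv%03d", seq_len(nrow(raw_intervals)))
  loci <- if ("locus" %in% names(raw_intervals)) raw_intervals$locus
          else NA_character_
  loci <- rep_len(loci, nrow(raw_intervals))

  split_one <- function(i) {
    s <- raw_intervals$start[i]; e <- raw_intervals$end[i]
    len <- e - s
    if (len <= window) {
      return(data.frame(chrom = raw_intervals$chrom[i], start = s, end = e,
                        region_id = ids[i], class = "rcre",
                        parent_id = NA_character_, locus = loci[i],
                        stringsAsFactors = FALSE))
    }
    k <- len %/% window
    rem <- len %% window
    starts <- s + window * (seq_len(k) - 1L)
    ends <- starts + window
    if (rem > 0 && rem < window / 2) {
      ends[k] <- e                       # absorb short remainder
    } else if (rem > 0) {
      starts <- c(starts, s + window * k)
      ends <- c(ends, e)
    }
    data.frame(chrom = raw_intervals$chrom[i], start = starts, end = ends,
               region_id = sprintf("%s_w%d", ids[i], seq_along(starts)),
               class = "rcre", parent_id = ids[i], locus = loci[i],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(raw_intervals)), split_one))

  if (!is.null(tss_table)) {
    stopifnot(all(c("chrom", "tss") %in% names(tss_table)))
    half <- window %/% 2L
    check_bounds(tss_table$chrom, tss_table$tss - half, tss_table$tss + half,
                 "TSS")
    gene <- if ("gene" %in% names(tss_table)) tss_table$gene
            else sprintf("tss%02d", seq_len(nrow(tss_table)))
    out <- rbind(out, data.frame(
      chrom = tss_table$chrom,
      start = tss_table$tss - half, end = tss_table$tss + half,
      region_id = sprintf("prom_%s", gene), class = "promoter_control",
      parent_id = NA_character_, locus = NA_character_,
      stringsAsFactors = FALSE))
  }
  if (!is.null(insensitive_intervals)) {
    ii <- insensitive_intervals
    check_bounds(ii$chrom, ii$start, ii$end, "interval")
    iid <- if ("region_id" %in% names(ii)) ii$region_id
           else sprintf("ins%02d", seq_len(nrow(ii)))
    out <- rbind(out, data.frame(
      chrom = ii$chrom, start = ii$start, end = ii$end,
      region_id = iid, class = "insensitive_control",
      parent_id = NA_character_, locus = NA_character_,
      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(out$region_id)) stop("region ids are not unique")
  rownames(out) <- NULL
  out
}

#' Scan a region for Cas9 protospacer candidates
#'
#' Finds every position where a 20-nt protospacer is immediately
#' followed by an NGG PAM, on both strands, within a region. Coordinates
#' are genomic, 0-based half-open; the cut site is the between-base
#' coordinate 3 bp 5' of the PAM (between protospacer positions 17 and
#' 18). Regions shorter than 23 bp yield an empty set.
#'
#' @param region One-row region data frame (chrom, start, end,
#'   region_id).
#' @param genome Named character vector of uppercase sequences.
#' @return Data frame of candidates: region_id, protospacer, chrom,
#'   start, end (protospacer interval), strand, cut_site, pam.
#' @export
scan_candidates <- function(region, genome) {
  stopifnot(nrow(region) == 1L)
  seq <- substr(genome[[region$chrom]], region$start + 1L, region$end)
  len <- nchar(seq)
  empty <- data.frame(region_id = character(0), protospacer = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      cut_site = integer(0), pam = character(0),
                      stringsAsFactors = FALSE)
  if (len < 23L) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  gg <- which(ch[-len] == "G" & ch[-1L] == "G")  # 1-based start of "GG"
  # forward: PAM = N GG at 1-based pam_start p, protospacer = [p-20, p-1]
  pf <- (gg - 1L)[gg - 1L >= 21L & gg + 1L <= len]
  # reverse: "CC" at 1-based p..p+1, PAM = CCN, protospacer = [p+3, p+22]
  cc <- which(ch[-len] == "C" & ch[-1L] == "C")
  pr <- cc[cc + 22L <= len]
  rows <- list()
  if (length(pf)) {
    proto <- substring(seq, pf - 20L, pf - 1L)
    g0 <- region$start + pf - 21L  # 0-based protospacer start
    rows$fwd <- data.frame(
      region_id = region$region_id, protospacer = proto,
      chrom = region$chrom, start = g0, end = g0 + 20L, strand = "+",
      cut_site = g0 + 17L, pam = substring(seq, pf, pf + 2L),
      stringsAsFactors = FALSE)
  }
  if (length(pr)) {
    proto <- revcomp(substring(seq, pr + 3L, pr + 22L))
    g0 <- region$start + pr + 2L  # 0-based protospacer start on + strand
    rows$rev <- data.frame(
      region_id = region$region_id, protospacer = proto,
      chrom = region$chrom, start = g0, end = g0 + 20L, strand = "-",
      cut_site = g0 + 3L, pam = revcomp(substring(seq, pr - 1L + 1L, pr + 2L)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates on efficiency and genome-wide specificity
#'
#' Applies hard efficiency rules (GC fraction within `gc_range`, no
#' "TTTT" Pol III terminator, no homopolymer longer than
#' `max_homopolymer`) and counts exact (0-mismatch) genome-wide
#' occurrences of protospacer + NGG on both strands. A candidate passes
#' only if all rules hold and it matches the genome exactly once. When
#' annotation intervals (exons / open chromatin) are given, non-target
#' exact matches overlapping them are counted per candidate.
#'
#' @param candidates Candidate data frame from [scan_candidates()].
#' @param genome Named character vector of sequences (the same genome
#'   candidates were scanned from).
#' @param annotations Optional BED-like data frame of exon /
#'   open-chromatin intervals.
#' @param gc_range Allowed GC fraction, inclusive.
#' @param max_homopolymer Longest allowed single-base run.
#' @return The input with columns efficiency_pass, fail_reasons,
#'   genome_matches, offtarget_annotation_hits, pass.
#' @export
filter_candidates <- function(candidates, genome, annotations = NULL,
                              gc_range = c(0.20, 0.80),
                              max_homopolymer = 5L) {
  if (!nrow(candidates)) {
    candidates$efficiency_pass <- logical(0)
    candidates$fail_reasons <- character(0)
    candidates$genome_matches <- integer(0)
    candidates$offtarget_annotation_hits <- integer(0)
    candidates$pass <- logical(0)
    return(candidates)
  }
  proto <- candidates$protospacer
  gc <- vapply(strsplit(proto, ""), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
  reasons <- vector("list", length(proto))
  bad_gc <- gc < gc_range[1] | gc > gc_range[2]
  bad_t4 <- grepl("TTTT", proto, fixed = TRUE)
  hp <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                max_homopolymer + 1L, max_homopolymer + 1L,
                max_homopolymer + 1L, max_homopolymer + 1L)
  bad_hp <- grepl(hp, proto)
  bad_len <- !(nchar(proto) %in% c(19L, 20L))
  for (i in seq_along(proto)) {
    r <- character(0)
    if (bad_gc[i]) r <- c(r, "gc_out_of_range")
    if (bad_t4[i]) r <- c(r, "polyT")
    if (bad_hp[i]) r <- c(r, "homopolymer")
    if (bad_len[i]) r <- c(r, "bad_length")
    reasons[[i]] <- r
  }
  eff <- !(bad_gc | bad_t4 | bad_hp | bad_len)

  subj <- Biostrings::DNAStringSet(genome)
  uniq <- unique(proto)
  hits_of <- function(p) {
    pat <- Biostrings::DNAString(paste0(p, "NGG"))
    rcp <- Biostrings::reverseComplement(pat)
    fw <- lapply(seq_along(subj), function(k)
      Biostrings::matchPattern(pat, subj[[k]], fixed = FALSE))
    rv <- lapply(seq_along(subj), function(k)
      Biostrings::matchPattern(rcp, subj[[k]], fixed = FALSE))
    list(fw = fw, rv = rv,
         n = sum(vapply(fw, length, integer(1))) +
             sum(vapply(rv, length, integer(1))))
  }
  found <- lapply(uniq, hits_of)
  names(found) <- uniq
  gm <- vapply(found, `[[`, integer(1), "n")[match(proto, uniq)]

  ann_hits <- integer(length(proto))
  if (!is.null(annotations) && nrow(annotations)) {
    chroms <- names(genome)
    overlaps_ann <- function(chrom, s, e) {
      a <- annotations[annotations$chrom == chrom, , drop = FALSE]
      any(a$start < e & s < a$end)
    }
    for (i in seq_along(proto)) {
      f <- found[[proto[i]]]
      cnt <- 0L
      for (k in seq_along(subj)) {
        for (m in list(f$fw[[k]], f$rv[[k]])) {
          if (!length(m)) next
          st <- BiocGenerics::start(m) - 1L   # 0-based, includes PAM/CCN
          en <- BiocGenerics::end(m)
          for (j in seq_along(st)) {
            own <- chroms[k] == candidates$chrom[i] &&
              st[j] <= candidates$start[i] && en[j] >= candidates$end[i]
            if (!own && overlaps_ann(chroms[k], st[j], en[j]))
              cnt <- cnt + 1L
          }
        }
      }
      ann_hits[i] <- cnt
    }
  }
  candidates$efficiency_pass <- eff
  candidates$fail_reasons <- vapply(seq_along(reasons), function(i) {
    r <- reasons[[i]]
    if (gm[i] != 1L) r <- c(r, "genome_matches")
    paste(r, collapse = ",")
  }, character(1))
  candidates$genome_matches <- as.integer(gm)
  candidates$offtarget_annotation_hits <- ann_hits
  candidates$pass <- eff & gm == 1L
  candidates
}

#' Select equidistantly spaced guides across a region
#'
#' Lays an ideal grid of anchor points at interval `spacing` across the
#' region and assigns each anchor the passing candidate whose cut site
#' is nearest, each candidate used at most once, via a bottleneck
#' (minimax-deviation) assignment between the sorted anchors and sorted
#' cut sites, with total deviation minimized among bottleneck-optimal
#' assignments (ties broken deterministically toward each anchor's own
#' nearest candidate). The result is the declustered tiling set,
#' sorted by position, with its density in guides per 100 bp attached.
#'
#' @param candidates Filtered candidate data frame (needs `pass` and
#'   `cut_site`).
#' @param region One-row region data frame.
#' @param spacing Anchor interval in bp (> 0; default 20, which yields
#'   5 guides per 100 bp on saturated input).
#' @return Selected subset with `selected = TRUE`, sorted by cut site;
#'   attributes `density_per_100bp` and, when nothing passes, `warning`.
#' @export
select_tiling <- function(candidates, region, spacing = 20L) {
  stopifnot(spacing > 0, nrow(region) == 1L)
  len <- region$end - region$start
  pool <- candidates[candidates$pass %||% TRUE, , drop = FALSE]
  if ("pass" %in% names(candidates))
    pool <- candidates[candidates$pass, , drop = FALSE]
  # canonical order makes selection invariant to input permutation
  pool <- pool[order(pool$cut_site, pool$protospacer), , drop = FALSE]
  n_anchor <- max(1L, len %/% spacing)
  anchors <- region$start + spacing * (seq_len(n_anchor) - 1L) + spacing / 2
  if (!nrow(pool)) {
    out <- pool
    out$selected <- logical(0)
    attr(out, "density_per_100bp") <- 0
    attr(out, "warning") <- sprintf("no passing candidates in %s",
                                    region$region_id)
    return(out)
  }
  take <- assign_anchors(anchors, pool$cut_site)
  out <- pool[sort(take), , drop = FALSE]
  out$selected <- TRUE
  rownames(out) <- NULL
  attr(out, "density_per_100bp") <- nrow(out) / len * 100
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assignment of sorted anchors to sorted cut sites, each candidate used
# at most once. First the bottleneck deviation d* (the smallest d such
# that every anchor can claim a distinct candidate within d) is found by
# binary search with greedy interval matching; then, restricted to
# pairs within d*, a non-crossing DP minimizes the total deviation.
# Whenever some assignment keeps every guide within spacing/2 of its
# anchor, the bottleneck solution does too, which bounds adjacent
# selected-guide gaps by twice the spacing. When candidates are fewer
# than anchors every candidate is used. Returns indices into `cuts`
# (which must be sorted ascending).
assign_anchors <- function(anchors, cuts) {
  A <- length(anchors); C <- length(cuts)
  if (C == 0) return(integer(0))
  if (C <= A) return(seq_len(C))
  feasible_within <- function(d) {
    j <- 1L
    for (i in seq_len(A)) {
      while (j <= C && cuts[j] < anchors[i] - d) j <- j + 1L
      if (j > C || cuts[j] > anchors[i] + d) return(FALSE)
      j <- j + 1L
    }
    TRUE
  }
  devs <- sort(unique(as.vector(abs(outer(cuts, anchors, "-")))))
  lo <- 1L; hi <- length(devs)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (feasible_within(devs[mid])) hi <- mid else lo <- mid + 1L
  }
  dstar <- devs[lo]
  f <- matrix(Inf, A + 1L, C + 1L)
  f[1L, ] <- 0
  for (i in seq_len(A)) {
    cost <- abs(cuts - anchors[i])
    cost[cost > dstar] <- Inf
    f[i + 1L, -1L] <- cummin(f[i, -(C + 1L)] + cost)
  }
  # backtrack; on ties the match (later candidate) is preferred, which
  # keeps each anchor's own nearest candidate and is deterministic
  take <- integer(A)
  i <- A; j <- C
  while (i >= 1L) {
    ci <- abs(cuts[j] - anchors[i])
    if (ci <= dstar && f[i, j] + ci == f[i + 1L, j + 1L]) {
      take[i] <- j; i <- i - 1L; j <- j - 1L
    } else {
      j <- j - 1L
    }
  }
  take
}

#' Assemble the sgRNA library and synthesis oligos
#'
#' Combines per-region selections into one library, builds each guide's
#' synthesis oligo as the exact concatenation `flank5 + protospacer +
#' flank3`, de-duplicates protospacers that were selected in more than
#' one region (kept once, flagged ambiguous, event logged) and reports
#' regions left with no guide.
#'
#' @param selected Named list of per-region selection data frames (from
#'   [select_tiling()]), or one combined data frame.
#' @param regions Region data frame (for class labels and the dropped-
#'   regions report).
#' @param flank5,flank3 Fixed vector arms placed around the protospacer
#'   in the synthesis oligo.
#' @return List: `manifest` (guide_id, region_id, class, protospacer,
#'   chrom, start, end, strand, cut_site, ambiguous, oligo), `oligos`
#'   (named character), `dropped_regions`, `duplicates`.
#' @export
emit_library <- function(selected, regions,
                         flank5 = "GAAAGGACGAAACACCG",
                         flank3 = "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC") {
  stopifnot(grepl("^[ACGT]+$", flank5), grepl("^[ACGT]+$", flank3))
  df <- if (is.data.frame(selected)) selected else do.call(rbind, selected)
  rownames(df) <- NULL
  dup <- duplicated(df$protospacer)
  duplicates <- unique(df$protospacer[dup])
  df$ambiguous <- df$protospacer %in% duplicates
  df <- df[!dup, , drop = FALSE]  # emitted once, first region kept
  df$guide_id <- sprintf("%s_g%02d", df$region_id,
                         stats::ave(seq_len(nrow(df)), df$region_id,
                                    FUN = seq_along))
  df$class <- regions$class[match(df$region_id, regions$region_id)]
  df$oligo <- paste0(flank5, df$protospacer, flank3)
  manifest <- df[, c("guide_id", "region_id", "class", "protospacer",
                     "chrom", "start", "end", "strand", "cut_site",
                     "ambiguous", "oligo")]
  dropped <- setdiff(regions$region_id, manifest$region_id)
  list(manifest = manifest,
       oligos = stats::setNames(manifest$oligo, manifest$guide_id),
       dropped_regions = dropped,
       duplicates = duplicates)
}

#' Design a tiling library for a set of regions in one call
#'
#' Convenience wrapper: scan, filter and decluster every region, then
#' assemble the library.
#'
#' @inheritParams filter_candidates
#' @inheritParams select_tiling
#' @param regions Region data frame from [prepare_target_regions()] or
#'   [sim_genome()].
#' @param genome Named character vector of sequences.
#' @param ... Passed to [emit_library()].
#' @return See [emit_library()]; additionally `candidates` (all scanned
#'   candidates with filter outcomes) and `selection_warnings`.
#' @export
design_library <- function(regions, genome, annotations = NULL,
                           spacing = 20L, ...) {
  all_cand <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    scan_candidates(regions[i, ], genome)))
  all_cand <- filter_candidates(all_cand, genome, annotations)
  warns <- character(0)
  sel <- lapply(seq_len(nrow(regions)), function(i) {
    s <- select_tiling(all_cand[all_cand$region_id == regions$region_id[i], ],
                       regions[i, ], spacing)
    if (!is.null(attr(s, "warning"))) warns <<- c(warns, attr(s, "warning"))
    s
  })
  lib <- emit_library(do.call(rbind, sel), regions, ...)
  lib$candidates <- all_cand
  lib$selection_warnings <- warns
  lib
}
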
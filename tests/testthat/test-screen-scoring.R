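make_lib <- function(n = 6) {
  data.frame(guide_id = sprintf("g%02d", 1:n),
             region_id = "r1",
             protospacer = vapply(1:n, function(i)
               with_seed(1000 + i, random_dna(20)), character(1)),
             cut_site = seq(10, by = 30, length.out = n),
             ambiguous = FALSE, stringsAsFactors = FALSE)
}

test_that("read counting is exact-match with conserved totals", {
  lib <- make_lib()
  reads <- list(d0_r1 = rep(lib$protospacer, 3),
                d16_r1 = c(lib$protospacer, "AAAAAAAAAAAAAAAAAAAA"))
  cm <- count_guides(reads, lib)
  expect_true(all(cm$counts[, "d0_r1"] == 3))
  expect_equal(unname(cm$unassigned["d0_r1"]), 0L)
  expect_true(all(cm$counts[, "d16_r1"] == 1))
  expect_equal(unname(cm$unassigned["d16_r1"]), 1L)
  expect_equal(sum(cm$counts[, "d16_r1"]) + cm$unassigned[["d16_r1"]],
               length(reads$d16_r1))

  # one mismatch -> unassigned
  mm <- lib$protospacer[1]
  substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mm, 5, 5))[1]
  cm2 <- count_guides(list(d0_r1 = mm, d16_r1 = mm), lib)
  expect_true(all(cm2$counts == 0))

  # protospacer embedded at a fixed offset
  cm3 <- count_guides(list(d0_r1 = paste0("TTGGA", lib$protospacer, "CGT"),
                           d16_r1 = lib$protospacer[1]),
                      lib, offset = 5)
  expect_true(all(cm3$counts[, "d0_r1"] == 1))

  # duplicate protospacers error unless flagged ambiguous
  bad <- lib; bad$protospacer[2] <- bad$protospacer[1]
  expect_error(count_guides(reads, bad), "duplicate")
  bad$ambiguous[2] <- TRUE
  expect_silent(count_guides(reads, bad))
})

test_that("FASTA read files round-trip through counting", {
  lib <- make_lib()
  d0 <- tempfile(fileext = ".fa"); d16 <- tempfile(fileext = ".fa")
  write_fasta(setNames(rep(lib$protospacer, 2),
                       sprintf("read%02d", 1:12)), d0)
  write_fasta(setNames(lib$protospacer[1:3], sprintf("read%02d", 1:3)), d16)
  cm <- count_guides(c(d0_r1 = d0, d16_r1 = d16), lib)
  expect_true(all(cm$counts[, "d0_r1"] == 2))
  expect_equal(sum(cm$counts[, "d16_r1"]), 3)
})

test_that("median-ratio normalization matches its definition", {
  samples <- data.frame(sample = c("d0_r1", "d0_r2", "d16_r1", "d16_r2"),
                        timepoint = rep(c("day0", "day16"), each = 2),
                        replicate = c(1, 2, 1, 2))
  k <- with_seed(3, matrix(rnbinom(400, mu = 300, size = 5), ncol = 4,
                           dimnames = list(sprintf("g%03d", 1:100), samples$sample)))
  cm <- normalize_counts(count_matrix(k, samples))
  # brute force from the definition
  pos <- apply(k > 0, 1, all)
  geo <- apply(k[pos, ], 1, function(r) exp(mean(log(r))))
  want <- apply(k[pos, ], 2, function(col) median(col / geo))
  expect_equal(cm$size_factors, want)

  # identical samples -> unit factors; doubling one sample doubles its
  # factor relative to the others
  same <- cbind(k[, 1], k[, 1], k[, 1], k[, 1])
  colnames(same) <- samples$sample
  expect_equal(unname(normalize_counts(count_matrix(same, samples))$size_factors),
               rep(1, 4))
  kk <- cbind(k[, 1], k[, 1], k[, 1], 2 * k[, 1])
  colnames(kk) <- samples$sample
  sf <- normalize_counts(count_matrix(kk, samples))$size_factors
  expect_equal(unname(sf[4] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(unname(sf[2] / sf[1]), 1, tolerance = 1e-12)

  zero <- k; zero[, 2] <- 0L
  expect_error(normalize_counts(count_matrix(zero, samples)), "all-zero")
})

test_that("median-ratio factors agree with the DESeq reference", {
  skip_if_not_installed("DESeq2")
  samples <- data.frame(sample = c("d0_r1", "d0_r2", "d16_r1", "d16_r2"),
                        timepoint = rep(c("day0", "day16"), each = 2),
                        replicate = c(1, 2, 1, 2))
  k <- with_seed(8, matrix(rnbinom(2000, mu = 500, size = 6), ncol = 4,
                           dimnames = list(NULL, samples$sample)))
  sf <- normalize_counts(count_matrix(k, samples))$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  # same statistic up to rescaling; DESeq takes the median on the log
  # scale, which differs only in how an even-count median interpolates
  expect_equal(sf / exp(mean(log(sf))), ref / exp(mean(log(ref))),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("guide test is null-centered and matches a Poisson oracle at alpha 0", {
  samples <- data.frame(sample = c("d0_r1", "d0_r2", "d16_r1", "d16_r2"),
                        timepoint = rep(c("day0", "day16"), each = 2),
                        replicate = c(1, 2, 1, 2))
  # identical arms: log2fc exactly 0, one-sided depletion p >= 0.5
  k0 <- with_seed(2, matrix(rnbinom(200, mu = 400, size = 8), ncol = 2))
  cm0 <- count_matrix(cbind(k0, k0), samples)
  gs0 <- guide_depletion_test(cm0)
  expect_true(all(gs0$log2fc == 0))
  expect_true(all(gs0$p_dep >= 0.5))

  # Poisson data: Wald p close to the exact conditional Poisson test
  man <- data.frame(guide_id = sprintf("g%04d", 1:500), region_id = "r",
                    cut_site = 1:500)
  cfg <- sim_config(seed = 4, nb_dispersion = 0, sequencing_depth = 4000,
                    abundance_sigma = 0)
  cm <- sim_screen_counts(man, cfg)
  cm$size_factors <- rep(1, 4)
  gs <- guide_depletion_test(cm)
  expect_lt(attr(gs, "alpha"), 0.005)
  # oracle: conditional on the total, day-16 reads are Binomial(n, 1/2);
  # central two-sided exact p
  s0 <- rowSums(cm$counts[, 1:2]); s1 <- rowSums(cm$counts[, 3:4])
  p_oracle <- vapply(seq_along(s0), function(i) {
    n <- s0[i] + s1[i]
    min(1, 2 * min(pbinom(s1[i], n, 0.5), 1 - pbinom(s1[i] - 1, n, 0.5)))
  }, numeric(1))
  expect_lt(max(abs(gs$p_two - p_oracle)), 0.01)
})

test_that("dispersion recovery and scaling invariance of guide p-values", {
  man <- data.frame(guide_id = sprintf("g%04d", 1:2000), region_id = "r",
                    cut_site = 1:2000)
  cm <- sim_screen_counts(man, sim_config(seed = 12))
  gs <- guide_depletion_test(cm)
  expect_lt(abs(attr(gs, "alpha") - 0.15), 0.05)

  # multiplying one sample's counts by a constant is absorbed by the
  # size factors; p-values move only through the fixed pseudocount,
  # which is negligible at screen depth
  cm3 <- cm
  cm3$counts[, 3] <- cm3$counts[, 3] * 3L
  gs3 <- guide_depletion_test(cm3)
  expect_lt(max(abs(gs$p_dep - gs3$p_dep)), 2e-3)
  expect_lt(max(abs(gs$log2fc - gs3$log2fc)), 5e-3)
})

test_that("single-replicate arms warn but still test", {
  samples <- data.frame(sample = c("d0_r1", "d16_r1"),
                        timepoint = c("day0", "day16"), replicate = c(1, 1))
  k <- with_seed(5, matrix(rnbinom(100, mu = 400, size = 8), ncol = 2,
                           dimnames = list(sprintf("g%02d", 1:50), samples$sample)))
  cm <- count_matrix(k, samples)
  expect_warning(gs <- guide_depletion_test(cm), "single replicate")
  expect_true(all(is.finite(gs$p_dep)))
})

test_that("sliding windows tile regions as specified", {
  # 400 bp region: candidate starts 0,50,...,300 (7 windows) given
  # enough guides everywhere
  reg <- data.frame(chrom = "c", start = 0, end = 400, region_id = "R1",
                    parent_id = NA_character_, stringsAsFactors = FALSE)
  cuts <- seq(2, 398, by = 12)
  man <- data.frame(guide_id = sprintf("g%03d", seq_along(cuts)),
                    region_id = "R1", cut_site = cuts,
                    stringsAsFactors = FALSE)
  gs <- toy_guide_stats(with_seed(6, runif(length(cuts))))
  gs$guide_id <- man$guide_id
  wa <- window_aggregate(reg, gs, man, nperm = 100, seed = 1)
  expect_equal(wa$windows$start, seq(0, 300, by = 50))
  expect_true(all(wa$windows$end - wa$windows$start == 100))
  expect_true(all(wa$windows$n_guides >= 2))
  # region p equals the minimum window p
  expect_equal(wa$regions$p_region, min(wa$windows$p_window))
})

test_that("the window holding the best-ranked guides scores lowest", {
  reg <- data.frame(chrom = "c", start = 0, end = 300, region_id = "R1",
                    parent_id = NA_character_)
  man <- data.frame(guide_id = sprintf("g%03d", 1:30), region_id = "R1",
                    cut_site = c(seq(5, 95, by = 10), seq(105, 195, by = 10),
                                 seq(205, 295, by = 10)))
  p <- c(seq(0.001, 0.01, length.out = 10),   # best ranks in [0,100)
         seq(0.3, 0.5, length.out = 10),
         seq(0.6, 0.9, length.out = 10))
  gs <- toy_guide_stats(p); gs$guide_id <- man$guide_id
  wa <- window_aggregate(reg, gs, man, offset = 100, window = 100,
                         nperm = 200, seed = 1)
  first <- wa$windows$start == 0
  expect_equal(min(wa$windows$rra_score), wa$windows$rra_score[first])
  expect_equal(wa$regions$rep_start, 0)
})

test_that("window permutation p matches exhaustive enumeration on a toy library", {
  # 30 guides, one region of 3 disjoint windows with 2-3 members each
  reg <- data.frame(chrom = "c", start = 0, end = 300, region_id = "R1",
                    parent_id = NA_character_)
  cuts <- c(10, 60, 110, 140, 170, 210, 260)
  man <- data.frame(guide_id = sprintf("g%03d", 1:30), region_id = "R1",
                    cut_site = c(cuts, seq(301, length.out = 23)))
  man$region_id[8:30] <- "R2"  # off-region guides still rank in library
  regs <- rbind(reg, data.frame(chrom = "c", start = 300, end = 700,
                                region_id = "R2", parent_id = NA_character_))
  p <- with_seed(13, runif(30))
  gs <- toy_guide_stats(p); gs$guide_id <- man$guide_id
  wa <- window_aggregate(regs, gs, man, offset = 100, window = 100,
                         min_guides = 2, nperm = 100, exact_limit = 1e5,
                         seed = 1)
  # independent oracle: enumerate all member subsets and re-derive the
  # order-statistic score from first principles
  u <- rank(p) / 30
  gate <- p < 0.25
  oracle_score <- function(ix) {
    uu <- sort(u[ix]); gg <- gate[ix][order(u[ix])]
    kk <- sum(gg)
    if (kk == 0) return(1)
    mm <- length(ix)
    min(pbeta(uu[seq_len(kk)], seq_len(kk), mm - seq_len(kk) + 1))
  }
  for (w in seq_len(nrow(wa$windows[wa$windows$region_id == "R1", ]))) {
    row <- wa$windows[wa$windows$region_id == "R1", ][w, ]
    null <- combn(30, row$n_guides, FUN = oracle_score)
    p_exh <- mean(null <= row$rra_score + 1e-12)
    expect_lt(abs(row$p_window - p_exh), 0.01)
  }
})

test_that("rra score is monotone in member ranks and bounded", {
  for (s in 1:50) {
    p <- with_seed(2000 + s, runif(40))
    u <- rank(p) / 40
    memb <- with_seed(3000 + s, sample(40, 5))
    sc <- crescreen:::rra_score(u[memb], p[memb] < 0.25)
    expect_gte(sc, 0); expect_lte(sc, 1)
    # improve the worst member's rank: score cannot increase
    worst <- memb[which.max(u[memb])]
    u2 <- u; u2[worst] <- min(u[memb]) / 2
    p2 <- p; p2[worst] <- min(p[memb]) / 2
    sc2 <- crescreen:::rra_score(u2[memb], p2[memb] < 0.25)
    expect_lte(sc2, sc + 1e-12)
  }
})

test_that("adjacent sibling regions merge into the most essential window", {
  regs <- data.frame(chrom = "c", start = c(0, 400), end = c(400, 800),
                     region_id = c("e1_w1", "e1_w2"),
                     parent_id = c("e1", "e1"), stringsAsFactors = FALSE)
  man <- data.frame(guide_id = sprintf("g%03d", 1:32),
                    region_id = rep(c("e1_w1", "e1_w2"), each = 16),
                    cut_site = c(seq(10, 390, length.out = 16),
                                 seq(410, 790, length.out = 16)))
  p <- c(with_seed(21, runif(16, 0.3, 1)), with_seed(22, runif(16, 0, 0.05)))
  gs <- toy_guide_stats(p); gs$guide_id <- man$guide_id
  wa <- window_aggregate(regs, gs, man, nperm = 300, seed = 2)
  expect_equal(nrow(wa$regions), 1)
  expect_equal(wa$regions$region_id, "e1")
  expect_gte(wa$regions$rep_start, 400)  # best window in the second sibling
  expect_equal(wa$regions$p_region,
               min(wa$windows$p_window[wa$windows$region_id == "e1_w2"]))
})

test_that("ECDF comparison and KS statistics match brute force", {
  g <- list(a = with_seed(31, runif(200)),
            b = with_seed(32, runif(200, 0, 0.5)))
  gc <- group_depletion_comparison(g)
  self <- group_depletion_comparison(list(a = g$a, a2 = g$a))
  expect_equal(self$ks$D, 0)
  # brute-force sup-difference of the two ECDFs
  grid <- sort(unique(c(g$a, g$b)))
  D <- max(abs(ecdf(g$a)(grid) - ecdf(g$b)(grid)))
  expect_equal(gc$ks$D, D)
  expect_lt(gc$ks$p, 1e-6)
  expect_error(group_depletion_comparison(list(a = 1:10)), "two groups")
  expect_error(group_depletion_comparison(list(a = 1:10, b = c(1, 2))),
               "at least 5")
})

test_that("planted promoter-control depletion separates guide classes by KS", {
  man <- data.frame(guide_id = sprintf("g%04d", 1:600),
                    region_id = rep(c("prom", "ins", "cre"), each = 200),
                    cut_site = 1:600)
  cfg <- sim_config(seed = 14, planted_effects = c(prom = -2))
  cm <- normalize_counts(sim_screen_counts(man, cfg))
  gs <- guide_depletion_test(cm)
  groups <- split(gs$p_dep, man$region_id)
  ks <- group_depletion_comparison(groups)$ks
  pk <- ks$p[(ks$group_a == "ins" & ks$group_b == "prom") |
             (ks$group_a == "prom" & ks$group_b == "ins")]
  expect_lt(pk, 0.05)
})
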
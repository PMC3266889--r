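test_that("pileup parsing handles markers, indels and quality filtering", {
  path <- tempfile(fileext = ".pileup")
  writeLines(c("2L\t1\tA\t4\t.,Cc\tIIII",
               "2L\t2\tG\t5\t^F..$,T*\tIIIII",
               "2L\t3\tT\t4\t.+2AC.,A\tIIII",
               "2L\t4\tC\t5\t....A\tIIII!"), path)
  pile <- read_pileup(path)
  expect_equal(pile$pos, 0:3)
  expect_equal(nchar(pile$bases), nchar(pile$quals))
  counts <- subsample_pileup(pile, target = 4, max_cov = 250, min_bq = 20,
                             seed = 42)
  expect_equal(counts$A, c(2L, 0L, 1L, 0L))
  expect_equal(counts$C, c(2L, 0L, 0L, 4L))
  expect_equal(counts$G, c(0L, 3L, 0L, 0L))
  expect_equal(counts$T, c(0L, 1L, 3L, 0L))
})

test_that("subsampling enforces the coverage window and uniform target", {
  path <- tempfile(fileext = ".pileup")
  writeLines(c(sprintf("2L\t1\tA\t45\t%s\t%s", strrep(".", 45),
                       strrep("I", 45)),
               sprintf("2L\t2\tA\t20\t%s\t%s", strrep(".", 20),
                       strrep("I", 20)),
               sprintf("2L\t3\tA\t300\t%s\t%s", strrep(".", 300),
                       strrep("I", 300))), path)
  pile <- read_pileup(path)
  counts <- subsample_pileup(pile, target = 30, seed = 42)
  expect_equal(nrow(counts), 1L)
  expect_equal(rowSums(counts[, c("A", "C", "G", "T")]), 30)
  rej <- attr(counts, "rejected")
  expect_equal(rej$reason[rej$pos == 1L], "below_target")
  expect_equal(rej$reason[rej$pos == 2L], "above_max_coverage")
})

test_that("subsampling is reproducible under a fixed seed", {
  path <- tempfile(fileext = ".pileup")
  writeLines(sprintf("2L\t%d\tA\t50\t%s\t%s", 1:50,
                     paste0(strrep(".", 35), strrep("C", 15)),
                     strrep("I", 50)), path)
  pile <- read_pileup(path)
  c1 <- subsample_pileup(pile, target = 30, seed = 7)
  c2 <- subsample_pileup(pile, target = 30, seed = 7)
  expect_identical(c1, c2)
})

test_that("windowed Tajima's D matches the brute-force oracle", {
  set.seed(42)
  n <- 10L
  m <- t(rmultinom(1000, n, c(0.7, 0.1, 0.1, 0.1)))
  counts <- data.frame(contig = "2L", pos = 0:999, A = m[, 1], C = m[, 2],
                       G = m[, 3], T = m[, 4], n = n)
  ws <- tajima_d_windows(counts, window = 50, lengths = c(`2L` = 1000L))
  expect_true(all(ws$valid))
  for (w in seq_len(nrow(ws))) {
    rows <- counts$pos >= ws$wstart[w] & counts$pos < ws$wend[w]
    o <- oracle_tajima_d(m[rows, , drop = FALSE], n)
    expect_equal(ws$S[w], o$S)
    expect_equal(ws$pi[w], o$pi, tolerance = 1e-9)
    expect_equal(ws$D[w], o$D, tolerance = 1e-6)
  }
})

test_that("a monomorphic window has S = 0 and undefined D", {
  counts <- data.frame(contig = "2L", pos = 0:49, A = 30L, C = 0L, G = 0L,
                       T = 0L, n = 30L)
  ws <- tajima_d_windows(counts, window = 50, lengths = c(`2L` = 50L))
  expect_equal(ws$S, 0L)
  expect_true(is.na(ws$D))
  expect_equal(ws$pi, 0)
})

test_that("the small-sample worked case gives D near 0.59", {
  counts <- data.frame(contig = "2L", pos = 0:1,
                       A = c(3L, 2L), C = c(1L, 2L), G = 0L, T = 0L, n = 4L)
  ws <- tajima_d_windows(counts, window = 500, lengths = c(`2L` = 500L),
                         strict = FALSE)
  o <- oracle_tajima_d(as.matrix(counts[, c("A", "C", "G", "T")]), 4L)
  expect_equal(ws$S, 2L)
  expect_equal(ws$pi, 0.5 + 2 / 3, tolerance = 1e-9)
  expect_equal(ws$D, o$D, tolerance = 1e-9)
  expect_equal(round(ws$D, 2), 0.59)
})

test_that("windowed diversity follows the closed form", {
  counts <- data.frame(contig = "2L", pos = 0:49, A = 30L, C = 0L, G = 0L,
                       T = 0L, n = 30L)
  counts$A[10] <- 29L; counts$C[10] <- 1L
  pw <- pi_windows(counts, window = 50, lengths = c(`2L` = 50L))
  expect_equal(pw$pi, 2 * 1 * 29 / (30 * 29), tolerance = 1e-12)
})

test_that("strict windows require complete subsampled coverage", {
  counts <- data.frame(contig = "2L", pos = c(0:20, 22:49), A = 30L,
                       C = 0L, G = 0L, T = 0L, n = 30L)
  ws <- tajima_d_windows(counts, window = 50, lengths = c(`2L` = 50L))
  expect_false(ws$valid)
  ws2 <- tajima_d_windows(counts, window = 50, lengths = c(`2L` = 50L),
                          strict = FALSE)
  expect_true(ws2$valid)
})

test_that("quantile thresholds use the lower empirical quantile", {
  ws <- data.frame(contig = "2L", wstart = 0:19 * 500L,
                   wend = 1:20 * 500L, n_sites = 500L, S = 5L, pi = 1,
                   D = c(-3, -2, -1, 0:16), valid = TRUE)
  th <- td_quantile_threshold(ws, q = 0.05)
  expect_equal(unname(th["autosome"]), -3)
  ws$D <- 1.5
  expect_equal(unname(td_quantile_threshold(ws, 0.05)["autosome"]), 1.5)

  set.seed(42)
  d <- rnorm(10000)
  ws3 <- data.frame(contig = "X", wstart = 0, wend = 500, n_sites = 500,
                    S = 1, pi = 1, D = d, valid = TRUE)
  th3 <- td_quantile_threshold(ws3, q = 0.05)
  expect_equal(unname(th3["X"]), sort(d)[ceiling(0.05 * 10000)])
  # monotone in q
  expect_lte(unname(td_quantile_threshold(ws3, 0.01)["X"]),
             unname(td_quantile_threshold(ws3, 0.10)["X"]))
})

test_that("recombination regions classify by rate and chromosome end", {
  track <- data.frame(contig = "2L", start = 0:5 * 100000L,
                      end = 1:6 * 100000L,
                      rate = c(0.5, 0.8, 1.5, 2.0, 1.0, 0.6))
  cls <- classify_recombination_region(track,
                                       centromere_end = c(`2L` = "right"))
  expect_equal(cls$region_class,
               c("telomere_proximal", "telomere_proximal", "normal",
                 "normal", "normal", "centromere_proximal"))
  expect_false(cls$low[5])          # exactly 1 cM/Mb is normal (strict)

  allhigh <- data.frame(contig = "2L", start = 0:2 * 100000L,
                        end = 1:3 * 100000L, rate = c(1, 2, 3))
  expect_true(all(classify_recombination_region(allhigh)$region_class ==
                    "normal"))

  # interior low runs default to centromere-proximal and are flagged
  mid <- data.frame(contig = "2L", start = 0:4 * 100000L,
                    end = 1:5 * 100000L, rate = c(2, 2, 0.5, 2, 2))
  cm <- classify_recombination_region(mid)
  expect_equal(cm$region_class[3], "centromere_proximal")
  expect_true(cm$interior_low[3])

  expect_equal(region_class_at(cls, c("2L", "2L"), c(50000L, 350000L)),
               c("telomere_proximal", "normal"))
})

test_that("feature annotation applies the constraint-priority rule", {
  gr <- GenomicRanges::GRanges(
    "2L", IRanges::IRanges(start = c(1001, 1201, 1301, 1901),
                           end = c(2000, 1300, 1900, 2000)))
  S4Vectors::mcols(gr)$type <- c("gene", "CDS", "intron",
                                 "three_prime_UTR")
  ann <- annotate_features("2L", c(1250L, 1500L, 1950L, 2500L, 500L), gr)
  expect_equal(ann$feature,
               c("CDS", "intron", "3'-UTR", "intergenic", "intergenic"))
  expect_equal(ann$gene_distance, c(0L, 0L, 0L, 500L, 499L))

  # same answers when the annotation arrives as a GFF file
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "2L\ttest\tgene\t1001\t2000\t.\t+\t.\tID=g1",
               "2L\ttest\tCDS\t1201\t1300\t.\t+\t.\tID=c1",
               "2L\ttest\tintron\t1301\t1900\t.\t+\t.\tID=i1",
               "2L\ttest\tthree_prime_UTR\t1901\t2000\t.\t+\t.\tID=u1"),
             gff)
  ann2 <- annotate_features("2L", c(1250L, 2500L), gff)
  expect_equal(ann2$feature, c("CDS", "intergenic"))
})

test_that("candidate selection is the conjunction of all sweep criteria", {
  h <- te_hierarchy(data.frame(id = c("roo-1", "ine-1a"),
                               family = c("roo", "INE-1"),
                               order = c("LTR", "TIR")))
  ws <- data.frame(contig = "2R", wstart = 0:99 * 500L, wend = 1:100 * 500L,
                   n_sites = 500L, S = 5L, pi = 1, D = -1, valid = TRUE)
  ws$D[30] <- -2.5                      # window at offset -1 of pos 15250
  th <- c(autosome = -2)
  freqs <- data.frame(call_id = 1:3, contig = "2R",
                      position = c(15250L, 25250L, 15250L),
                      family = c("roo", "roo", "INE-1"),
                      f = c(1.0, 1.0, 1.0))
  cand <- scan_candidates(freqs, ws, th, recomb_track = NULL, hierarchy = h)
  expect_equal(cand$call_id, 1L)
  expect_equal(cand$qualifying_offsets, "-1")
  expect_equal(cand$`D_-1`, -2.5)

  # sub-threshold frequency is excluded
  freqs$f[1] <- 0.8
  expect_equal(nrow(scan_candidates(freqs, ws, th, NULL, h)), 0L)

  # low-recombination regions are excluded
  freqs$f[1] <- 1.0
  low <- classify_recombination_region(
    data.frame(contig = "2R", start = 0L, end = 50000L, rate = 0.5))
  expect_equal(nrow(scan_candidates(freqs, ws, th, low, h)), 0L)
})

test_that("summary tables conserve counts and compute density and fractions", {
  group <- c(rep("2L", 4), rep("X", 2))
  f <- c(1.0, 0.5, NA, 0.97, 0.2, NA)
  tab <- summarize_insertions(group, f, lengths_mb = c(`2L` = 2, X = 1))
  expect_equal(sum(tab$n), 6L)
  r <- tab[tab$group == "2L", ]
  expect_equal(r$density, 2)
  expect_equal(r$n_fe, 3L)
  expect_equal(r$n_fixed, 2L)
  expect_equal(r$fixed_pct, 100 * 2 / 3)
  # empty estimate category yields NA fractions
  tab2 <- summarize_insertions(c("a", "a"), c(NA, NA))
  expect_true(is.na(tab2$fixed_pct))
  expect_true(is.na(tab2$median_f))
})
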
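# Shared simulated fixtures, built once per test run and cached.
# All seeds are fixed at 42; simulation conditions (pool size 226
# haplotypes, read length 74 bp, fragment length 225 +/- 15 bp, ~31-fold
# site coverage) mirror the sequencing design the package targets.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# run the full caller + estimator pipeline on a simulated pool
run_pipeline <- function(cfg, min_coverage = 10) {
  ref <- simulate_reference_and_library(cfg)
  pool <- simulate_pool(cfg, ref)
  masked <- mask_from_annotation(ref$genome, ref$annotation)
  cr <- build_combined_reference(masked,
                                 filter_te_sequences(ref$te_seqs),
                                 ref$hierarchy)
  frags <- classify_fragments(pool$pairs, cr)
  cl <- cluster_directional(frags)
  calls <- join_forward_reverse(cl, cr)
  calls <- estimate_position(calls, contig_lengths(cr))
  calls <- match_to_reference_annotation(calls, ref$annotation)
  est <- suppressMessages(apply_site_filters(
    estimate_frequencies(calls, frags, contig_lengths(cr),
                         min_coverage = min_coverage)))
  list(ref = ref, pool = pool, cr = cr, frags = frags, clusters = cl,
       calls = calls, est = est)
}

# map frequency estimates back to simulated truth (same family, nearest
# breakpoint midpoint; sites are 1 kb apart so assignment is unambiguous)
assign_truth <- function(est, truth) {
  mid <- ifelse(truth$in_reference,
                (truth$span_start + truth$span_end) %/% 2L,
                truth$ref_position)
  idx <- rep(NA_integer_, nrow(est))
  for (i in seq_len(nrow(est))) {
    cand <- which(tolower(truth$family) == tolower(est$family[i]))
    if (!length(cand)) next
    d <- abs(mid[cand] - est$position[i])
    if (min(d) < 3000) idx[i] <- cand[which.min(d)]
  }
  idx
}

# small three-insertion pool exercised by several unit tests
small_sim <- function() .cached("small_sim", function() {
  ins <- data.frame(position = c(20000, 50000, 80000),
                    family = c("fam01", "fam02", "fam01"),
                    frequency = c(1.0, 0.5, 0.3),
                    in_reference = c(TRUE, FALSE, FALSE))
  cfg <- simulation_config(genome_length = 100000, insertions = ins,
                           physical_coverage = 40, seed = 42)
  run_pipeline(cfg)
})

# 200 insertions (100 known/novel pairs at matched frequencies drawn
# uniformly on [0.05, 1]) at ~31-fold site coverage
recovery_sim <- function() .cached("recovery_sim", function() {
  set.seed(42)
  n_pair <- 100L
  q <- runif(n_pair, 0.05, 1)
  fams <- sprintf("fam%02d", 1:6)
  ins <- data.frame(position = seq_len(2L * n_pair) * 1000L,
                    family = fams[(seq_len(2L * n_pair) - 1L) %% 6L + 1L],
                    frequency = rep(q, each = 2L),
                    in_reference = rep(c(TRUE, FALSE), n_pair))
  # 35-fold physical coverage puts the mean tally coverage per insertion
  # site (two 100 bp ranges out of a 225 bp fragment span) near 31-fold
  cfg <- simulation_config(genome_length = 2L * n_pair * 1000L + 1000L,
                           insertions = ins, family_names = fams,
                           physical_coverage = 35, seed = 42)
  run_pipeline(cfg)
})

# detection-floor contrast: 40 sites at 2% vs 40 sites at 20% frequency
floor_sim <- function() .cached("floor_sim", function() {
  fams <- sprintf("fam%02d", 1:4)
  ins <- data.frame(position = seq_len(80L) * 1000L,
                    family = fams[(seq_len(80L) - 1L) %% 4L + 1L],
                    frequency = rep(c(0.02, 0.2), each = 40L),
                    in_reference = FALSE)
  cfg <- simulation_config(genome_length = 82000L, insertions = ins,
                           family_names = fams, physical_coverage = 31,
                           seed = 42)
  run_pipeline(cfg)
})

# sweep-scan scenario: one swept region containing a fixed non-ancient
# insertion and a fixed INE-1 insertion, one fixed insertion outside
sweep_sim <- function() .cached("sweep_sim", function() {
  ins <- data.frame(position = c(13500, 15000, 45000),
                    family = c("INE-1", "fam01", "fam02"),
                    frequency = 1.0, in_reference = FALSE)
  cfg <- simulation_config(genome_length = 100000, insertions = ins,
                           family_names = c("INE-1", "fam01", "fam02"),
                           physical_coverage = 31, seed = 42)
  pl <- run_pipeline(cfg)
  sweep <- data.frame(start = 12000L, end = 18000L)
  pile_lines <- simulate_pileup("2R", 100000, depth_mean = 60,
                                polymorphism_rate = 0.01,
                                sweep_regions = sweep,
                                singleton_prob = 0.95, seed = 42)
  pfile <- tempfile(fileext = ".pileup")
  writeLines(pile_lines, pfile)
  pile <- read_pileup(pfile)
  counts <- subsample_pileup(pile, target = 30, max_cov = 250, min_bq = 20,
                             seed = 42)
  wstats <- tajima_d_windows(counts, window = 500,
                             lengths = c(`2R` = 100000L))
  thresholds <- td_quantile_threshold(wstats, q = 0.05)
  recomb <- classify_recombination_region(
    data.frame(contig = "2R", start = 0L, end = 100000L, rate = 2.5))
  c(pl, list(sweep = sweep, wstats = wstats, thresholds = thresholds,
             recomb = recomb))
})

# synthetic fragment rows for unit tests of the caller/estimator
make_presence <- function(anchor, direction = "forward", family = "roo",
                          contig = "2L", mq = 20, read_length = 74) {
  fwd <- rep_len(direction == "forward", length(anchor))
  data.frame(qname = sprintf("p%07d", seq_along(anchor) +
                               sample.int(1e6, 1)),
             kind = "PRESENCE", direction = direction, family = family,
             order = "LTR", contig = contig,
             g_start = ifelse(fwd, anchor - read_length, anchor),
             g_end = ifelse(fwd, anchor, anchor + read_length),
             anchor = anchor,
             qualifying = ifelse(fwd, anchor - read_length,
                                 anchor + read_length - 1L),
             mq = mq, span_start = NA_integer_, span_end = NA_integer_,
             stringsAsFactors = FALSE)
}

make_proper <- function(span_start, span_end, contig = "2L") {
  data.frame(qname = sprintf("a%07d", seq_along(span_start) +
                               sample.int(1e6, 1)),
             kind = "PROPER_PAIR", direction = NA_character_,
             family = NA_character_, order = NA_character_,
             contig = contig, g_start = NA_integer_, g_end = NA_integer_,
             anchor = NA_integer_, qualifying = NA_integer_,
             mq = NA_integer_, span_start = span_start,
             span_end = span_end, stringsAsFactors = FALSE)
}

# unmasked single-contig genome helper
plain_genome <- function(len = 200000L, contig = "2L") {
  g <- Biostrings::DNAStringSet(strrep("A", len))
  names(g) <- contig
  mask_from_annotation(g, data.frame(contig = character(),
                                     start = integer(), end = integer()))
}
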
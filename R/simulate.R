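# Seeded simulator of a pooled population sample over a reference with TE
# insertions at configured frequencies. Alignments are truth alignments
# (no external mapper): a read overlapping an insertion junction is
# resolved the way a local aligner resolves it — assigned to the side
# holding the majority of its bases, clipped at the junction.

#' Simulation configuration
#'
#' Captures the sequencing design being emulated: a pool of `n_haplotypes`
#' chromosomes (emulating 113 isofemale lines x 2), paired-end fragments of
#' normally distributed length with a fixed read length, and a set of TE
#' insertions segregating at given population frequencies, some of them
#' present in the reference genome (`in_reference`).
#'
#' @param genome_length Background genome length in bp.
#' @param contig Name of the simulated contig.
#' @param insertions data.frame with columns `position` (0-based background
#'   coordinate), `family`, `frequency` in `[0,1]`, `in_reference`
#'   (logical). Positions must be at least `read_length` apart.
#' @param family_names Families in the TE library (families used by
#'   `insertions` are added automatically).
#' @param te_length_range Range of TE sequence lengths in bp; must exceed
#'   the fragment length so a fragment never spans a whole element.
#' @param n_haplotypes Haplotypes in the pool.
#' @param physical_coverage Expected number of fragments covering a
#'   position.
#' @param read_length Read length in bp.
#' @param fragment_length_mean,fragment_length_sd Fragment size
#'   distribution in bp.
#' @param base_error_rate Per-base error rate for emitted FASTQ (alignments
#'   are unaffected).
#' @param mq_genome,mq_te Mapping qualities given to genome- and TE-mapped
#'   reads.
#' @param min_anchor Minimum aligned bases for a junction-straddling read to
#'   anchor on a side.
#' @param seed Integer seed; fully determines all output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(genome_length = 100000, contig = "2R",
                              insertions = NULL,
                              family_names = c("fam01", "fam02", "fam03"),
                              te_length_range = c(800, 1500),
                              n_haplotypes = 226, physical_coverage = 30,
                              read_length = 74, fragment_length_mean = 225,
                              fragment_length_sd = 15, base_error_rate = 0,
                              mq_genome = 40, mq_te = 30, min_anchor = 20,
                              seed = 1) {
  if (is.null(insertions))
    insertions <- data.frame(position = integer(), family = character(),
                             frequency = numeric(), in_reference = logical())
  .stopifnot_cols(insertions, c("position", "family", "frequency",
                                "in_reference"), "insertions")
  insertions <- insertions[order(insertions$position), , drop = FALSE]
  rownames(insertions) <- NULL
  if (any(insertions$frequency < 0 | insertions$frequency > 1))
    stop("insertion frequencies must lie in [0, 1]")
  if (any(insertions$position < 0 |
          insertions$position >= genome_length))
    stop("insertion positions must lie within the genome")
  if (nrow(insertions) > 1L &&
      any(diff(insertions$position) < read_length))
    stop("insertion positions must be at least one read length apart")
  if (te_length_range[1] <= fragment_length_mean + 4 * fragment_length_sd)
    stop("TE sequences must be longer than the largest fragments")
  family_names <- union(family_names, unique(insertions$family))
  structure(list(genome_length = as.integer(genome_length), contig = contig,
                 insertions = insertions, family_names = family_names,
                 te_length_range = as.integer(te_length_range),
                 n_haplotypes = as.integer(n_haplotypes),
                 physical_coverage = physical_coverage,
                 read_length = as.integer(read_length),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 base_error_rate = base_error_rate,
                 mq_genome = as.integer(mq_genome),
                 mq_te = as.integer(mq_te),
                 min_anchor = as.integer(min_anchor),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the reference, TE library and annotation
#'
#' Generates a random background genome and one canonical TE sequence per
#' family, inserts the `in_reference` insertions into the emitted reference
#' (so "known" insertions exist with annotated spans), and builds the
#' matching hierarchy. The reference length equals the background length
#' plus the lengths of the inserted elements; an `INE-1` family, if present,
#' is flagged ancient by the hierarchy as usual.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `sim_reference`: `genome` (reference
#'   `DNAStringSet`), `te_seqs`, `hierarchy`, `annotation` (spans of
#'   in-reference insertions, 0-based half-open), `insertions` (truth table
#'   with background and reference breakpoint coordinates), `cfg`.
#' @export
simulate_reference_and_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derive_seed(cfg$seed, 1L))
  bg <- .random_dna(cfg$genome_length)
  orders <- c("TIR", "LTR", "non-LTR")
  fams <- cfg$family_names
  te_len <- as.integer(round(runif(length(fams), cfg$te_length_range[1],
                                   cfg$te_length_range[2])))
  te_seqs <- Biostrings::DNAStringSet(vapply(te_len, .random_dna,
                                             character(1)))
  names(te_seqs) <- paste0(fams, "-1")
  hierarchy <- te_hierarchy(data.frame(
    id = names(te_seqs), family = fams,
    order = orders[(seq_along(fams) - 1L) %% 3L + 1L]))

  ins <- cfg$insertions
  ins$id <- if (nrow(ins)) paste0("ins", seq_len(nrow(ins))) else character(0)
  ins$te_length <- te_len[match(ins$family, fams)]
  inref <- ins$in_reference
  cum_before <- cumsum(ifelse(inref, ins$te_length, 0L)) -
    ifelse(inref, ins$te_length, 0L)
  ins$ref_position <- ins$position + cum_before
  ins$span_start <- ifelse(inref, ins$ref_position, NA_integer_)
  ins$span_end <- ifelse(inref, ins$ref_position + ins$te_length,
                         NA_integer_)
  # assemble the reference with in-reference TE copies inserted
  pieces <- character(0); cursor <- 0L
  for (i in seq_len(nrow(ins))) {
    if (!inref[i]) next
    pieces <- c(pieces, substr(bg, cursor + 1L, ins$position[i]),
                as.character(te_seqs[[match(ins$family[i], fams)]]))
    cursor <- ins$position[i]
  }
  pieces <- c(pieces, substr(bg, cursor + 1L, cfg$genome_length))
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- cfg$contig
  annotation <- data.frame(
    contig = rep(cfg$contig, sum(inref)), start = ins$span_start[inref],
    end = ins$span_end[inref], family = ins$family[inref],
    id = ins$id[inref], stringsAsFactors = FALSE)
  structure(list(genome = genome, background = bg, te_seqs = te_seqs,
                 hierarchy = hierarchy, annotation = annotation,
                 insertions = ins, cfg = cfg),
            class = "sim_reference")
}

# map background coordinates to reference coordinates (in-reference TE
# copies shift everything downstream of their insertion point)
.bg_to_ref <- function(x, inref_pos, inref_len) {
  if (!length(inref_pos)) return(x)
  x + c(0, cumsum(inref_len))[findInterval(x, inref_pos) + 1L]
}

#' Simulate a pooled paired-end sample
#'
#' Haplotypes carry each insertion independently with its configured
#' frequency (Bernoulli draws fixed by the seed); fragments are drawn
#' uniformly across haplotypes and positions. Fragments spanning an
#' insertion junction on a carrier haplotype emit genome+TE read pairs
#' (direction given by which read falls in the TE); fragments elsewhere
#' emit proper pairs. Emitted alignments are truth alignments in combined
#' reference coordinates.
#'
#' @param cfg A [simulation_config()].
#' @param ref Output of [simulate_reference_and_library()] for `cfg`.
#' @return List of class `sim_pool`: `pairs` (paired alignment data.frame
#'   as from [restore_pairs()]), `truth_fragments` (`qname`, `haplotype`,
#'   `kind`, `direction`, `insertion`), `truth_insertions` (per insertion:
#'   truth coordinates plus `freq_empirical`, the realized carrier
#'   fraction), `carriers` (insertion x haplotype matrix).
#' @export
simulate_pool <- function(cfg, ref) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ref, "sim_reference"))
  set.seed(.derive_seed(cfg$seed, 2L))
  ins <- ref$insertions
  n_ins <- nrow(ins); nh <- cfg$n_haplotypes
  carriers <- matrix(rbinom(n_ins * nh, 1L, rep(ins$frequency, nh)),
                     nrow = n_ins)
  ins$freq_empirical <- if (n_ins) rowMeans(carriers) else numeric(0)

  rl <- cfg$read_length
  # fragments are budgeted by mean haplotype length and drawn proportional
  # to haplotype length, so physical_coverage holds per sequenced base
  hap_lens <- cfg$genome_length +
    (if (n_ins) as.numeric(crossprod(carriers, ins$te_length)) else
       rep(0, nh))
  n_frag <- as.integer(round(mean(hap_lens) * cfg$physical_coverage /
                               cfg$fragment_length_mean))
  hap <- sample.int(nh, n_frag, replace = TRUE, prob = hap_lens)
  flen <- pmax(as.integer(round(rnorm(n_frag, cfg$fragment_length_mean,
                                      cfg$fragment_length_sd))),
               2L * rl + 2L)
  inref_pos <- ins$position[ins$in_reference]
  inref_len <- ins$te_length[ins$in_reference]
  te_ids <- names(ref$te_seqs)[match(ins$family, sub("-1$", "",
                                                     names(ref$te_seqs)))]

  out_contig1 <- out_contig2 <- character(n_frag)
  out_s1 <- out_e1 <- out_s2 <- out_e2 <- integer(n_frag)
  out_mq1 <- out_mq2 <- integer(n_frag)
  truth_kind <- character(n_frag); truth_dir <- rep(NA_character_, n_frag)
  truth_ins <- rep(NA_integer_, n_frag)

  for (h in seq_len(nh)) {
    fi <- which(hap == h)
    if (!length(fi)) next
    carried <- if (n_ins) which(carriers[, h] == 1L) else integer(0)
    pc <- ins$position[carried]; lc <- ins$te_length[carried]
    k <- length(carried)
    hap_len <- cfg$genome_length + sum(lc)
    s <- as.integer(floor(runif(length(fi)) * (hap_len - flen[fi])))
    # haplotype segment table: genome / TE alternating
    te_hs <- pc + c(0L, cumsum(lc))[seq_len(k)]
    te_he <- te_hs + lc
    seg_start <- c(0L, as.vector(rbind(te_hs, te_he)))
    seg_end <- c(seg_start[-1L], hap_len)
    seg_is_te <- c(rbind(rep(FALSE, k + 1L),
                         c(rep(TRUE, k), FALSE)))[seq_along(seg_start)]
    seg_te <- integer(length(seg_start)); seg_off <- integer(length(seg_start))
    if (k) {
      seg_te[seq_len(k) * 2L] <- carried
      seg_off[seq(1L, 2L * k + 1L, by = 2L)] <- c(0L, cumsum(lc))
    }
    resolve <- function(rs, re) {
      j <- findInterval(rs, seg_start)
      cross <- re > seg_end[j]
      p1 <- pmin(re, seg_end[j]) - rs
      p2 <- re - pmin(re, seg_end[j])
      use2 <- cross & p2 > p1
      jj <- ifelse(use2, j + 1L, j)
      a <- ifelse(use2, seg_end[j], rs)
      b <- ifelse(cross & !use2, seg_end[j], re)
      is_te <- seg_is_te[jj]
      contig <- rep(cfg$contig, length(jj))
      contig[is_te] <- te_ids[seg_te[jj[is_te]]]
      a_out <- ifelse(is_te, a - seg_start[jj], a - seg_off[jj])
      b_out <- ifelse(is_te, b - seg_start[jj], b - seg_off[jj])
      # genome reads crossing a non-carried in-reference span split again
      if (length(inref_pos)) {
        gi <- which(!is_te)
        if (length(gi)) {
          lo <- findInterval(a_out[gi], inref_pos)
          hi <- findInterval(b_out[gi] - 1L, inref_pos)
          splitters <- which(hi > lo &
                               inref_pos[pmax(hi, 1L)] > a_out[gi])
          for (m in splitters) {
            i <- gi[m]
            p <- inref_pos[hi[m]]
            left <- p - a_out[i]; right <- b_out[i] - p
            if (left >= right) b_out[i] <- p else a_out[i] <- p
          }
        }
      }
      ra <- ifelse(is_te, a_out, .bg_to_ref(a_out, inref_pos, inref_len))
      list(contig = contig, start = as.integer(ra),
           end = as.integer(ra + (b_out - a_out)), is_te = is_te,
           te_idx = ifelse(is_te, seg_te[jj], NA_integer_))
    }
    r1 <- resolve(s, s + rl)
    r2 <- resolve(s + flen[fi] - rl, s + flen[fi])
    out_contig1[fi] <- r1$contig; out_s1[fi] <- r1$start
    out_e1[fi] <- r1$end
    out_contig2[fi] <- r2$contig; out_s2[fi] <- r2$start
    out_e2[fi] <- r2$end
    out_mq1[fi] <- ifelse(r1$is_te, cfg$mq_te, cfg$mq_genome)
    out_mq2[fi] <- ifelse(r2$is_te, cfg$mq_te, cfg$mq_genome)
    pres <- xor(r1$is_te, r2$is_te)
    truth_kind[fi] <- ifelse(r1$is_te & r2$is_te, "UNINFORMATIVE",
                             ifelse(pres, "PRESENCE", "PROPER_PAIR"))
    # direction follows the genome read: read1 is +, read2 is -
    truth_dir[fi] <- ifelse(pres, ifelse(r2$is_te, "forward", "reverse"),
                            NA_character_)
    truth_ins[fi] <- ifelse(r1$is_te, r1$te_idx,
                            ifelse(r2$is_te, r2$te_idx, NA_integer_))
    # a genome-genome pair broken by a non-reference TE is discordant
    gg <- !r1$is_te & !r2$is_te
    bad <- gg & (r1$end > r2$start)
    truth_kind[fi][bad] <- "UNINFORMATIVE"
  }
  qname <- sprintf("frag%07d", seq_len(n_frag))
  pairs <- data.frame(qname = qname,
                      r1_contig = out_contig1, r1_start = out_s1,
                      r1_end = out_e1, r1_strand = "+", r1_mapq = out_mq1,
                      r2_contig = out_contig2, r2_start = out_s2,
                      r2_end = out_e2, r2_strand = "-", r2_mapq = out_mq2,
                      stringsAsFactors = FALSE)
  truth_fragments <- data.frame(qname = qname, haplotype = hap,
                                kind = truth_kind, direction = truth_dir,
                                insertion = ifelse(is.na(truth_ins), NA,
                                                   ins$id[truth_ins]),
                                stringsAsFactors = FALSE)
  structure(list(pairs = pairs, truth_fragments = truth_fragments,
                 truth_insertions = ins, carriers = carriers, cfg = cfg),
            class = "sim_pool")
}

#' Simulate a pooled pileup
#'
#' Neutral polymorphic sites receive a population minor-allele count `k`
#' drawn from the equilibrium neutral spectrum (probability proportional to
#' `1/k`); read counts at a site are binomial in `k/n_haplotypes`
#' (haplotypes sampled with replacement, as in pooled sequencing). Inside
#' `sweep_regions` the spectrum is skewed toward singletons, producing the
#' excess of rare variants that drives windowed Tajima's D negative. A
#' fraction of calls carries a low base quality to exercise the quality
#' filter.
#'
#' @param contig Contig name.
#' @param length Contig length in bp.
#' @param n_haplotypes Haplotypes in the pool.
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param polymorphism_rate Per-bp probability of a polymorphic site.
#' @param sweep_regions Optional data.frame (`start`, `end`, 0-based
#'   half-open) of swept intervals.
#' @param singleton_prob Probability that a swept site is a singleton.
#' @param base_qual,low_qual,low_qual_frac Base quality model (phred).
#' @param seed Integer seed.
#' @param path Optional output file; when `NULL` the pileup lines are
#'   returned invisibly.
#' @return The path (or the pileup lines, invisibly).
#' @export
simulate_pileup <- function(contig, length, n_haplotypes = 226,
                            depth_mean = 60, polymorphism_rate = 0.01,
                            sweep_regions = NULL, singleton_prob = 0.85,
                            base_qual = 40, low_qual = 10,
                            low_qual_frac = 0.05, seed = 1, path = NULL) {
  set.seed(.derive_seed(seed, 3L))
  L <- as.integer(length)
  nh <- n_haplotypes
  depth <- rpois(L, depth_mean)
  poly <- runif(L) < polymorphism_rate
  in_sweep <- rep(FALSE, L)
  if (!is.null(sweep_regions))
    for (i in seq_len(nrow(sweep_regions)))
      in_sweep[(sweep_regions$start[i] + 1L):sweep_regions$end[i]] <- TRUE
  k <- integer(L)
  neu <- which(poly & !in_sweep)
  if (length(neu)) {
    kk <- seq_len(nh - 1L)
    k[neu] <- sample(kk, length(neu), replace = TRUE, prob = 1 / kk)
  }
  swp <- which(poly & in_sweep)
  if (length(swp)) {
    singles <- runif(length(swp)) < singleton_prob
    k[swp] <- ifelse(singles, 1L, sample(2:5, length(swp), replace = TRUE))
  }
  nalt <- rbinom(L, depth, ifelse(poly, k / nh, 0))
  nref <- depth - nalt
  bases <- c("A", "C", "G", "T")
  refb <- sample(bases, L, replace = TRUE)
  altb <- vapply(refb, function(r) sample(setdiff(bases, r), 1L),
                 character(1))
  nrl <- rbinom(L, nref, low_qual_frac)
  nal <- rbinom(L, nalt, low_qual_frac)
  hi <- intToUtf8(base_qual + 33L); lo <- intToUtf8(low_qual + 33L)
  base_str <- paste0(strrep(".", nref), strrep(altb, nalt))
  qual_str <- paste0(strrep(lo, nrl), strrep(hi, nref - nrl),
                     strrep(lo, nal), strrep(hi, nalt - nal))
  keep <- depth > 0L
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%s", contig, which(keep),
                   refb[keep], depth[keep], base_str[keep], qual_str[keep])
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  invisible(lines)
}

#' Emit simulated reads as FASTQ
#'
#' Optional companion to [simulate_pool()] for integration tests with a
#' real mapper: reconstructs each read's sequence from the reference and TE
#' sequences (read 2 reverse-complemented), applying `base_error_rate`
#' substitutions.
#'
#' @param pool Output of [simulate_pool()].
#' @param ref Output of [simulate_reference_and_library()].
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return Character vector of the two paths, invisibly.
#' @export
emit_fastq <- function(pool, ref, prefix) {
  stopifnot(inherits(pool, "sim_pool"), inherits(ref, "sim_reference"))
  set.seed(.derive_seed(pool$cfg$seed, 4L))
  seqs <- c(ref$genome, ref$te_seqs)
  get_seq <- function(contig, s, e) {
    as.character(Biostrings::subseq(seqs[[contig]], s + 1L, e))
  }
  p <- pool$pairs
  write_one <- function(contigs, ss, ee, strands, path) {
    sq <- mapply(get_seq, contigs, ss, ee)
    rc <- strands == "-"
    sq[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(sq[rc])))
    err <- pool$cfg$base_error_rate
    if (err > 0) {
      sq <- vapply(sq, function(x) {
        n <- nchar(x)
        hit <- which(runif(n) < err)
        for (i in hit)
          substr(x, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(x, i, i)), 1L)
        x
      }, character(1), USE.NAMES = FALSE)
    }
    writeLines(paste0("@", p$qname, "\n", sq, "\n+\n",
                      strrep("I", nchar(sq))), path)
  }
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  write_one(p$r1_contig, p$r1_start, p$r1_end, p$r1_strand, f1)
  write_one(p$r2_contig, p$r2_start, p$r2_end, p$r2_strand, f2)
  invisible(c(f1, f2))
}
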
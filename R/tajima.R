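# Windowed Tajima's D and nucleotide diversity from pooled pileups.
# The pooled route is: subsample every position to a uniform coverage n,
# then treat the n retained reads as n sampled chromosomes and apply the
# classic Tajima (1989) estimators — no pooled-specific variance
# corrections are applied.

#' Read a samtools-style text pileup
#'
#' Parses the six-column samtools text pileup dialect (contig, 1-based
#' position, reference base, depth, base string, quality string). Read-start
#' (`^` + mapping quality), read-end (`$`) and indel (`+n`/`-n` + sequence)
#' markers are stripped; deletion (`*`) and reference-skip placeholders are
#' kept aligned with their quality characters and ignored when counting.
#'
#' @param path Pileup text file.
#' @return data.frame with `contig`, `pos` (0-based), `ref`, `depth`,
#'   `bases`, `quals`.
#' @export
read_pileup <- function(path) {
  cols <- read.delim(path, header = FALSE, colClasses = "character",
                     quote = "", stringsAsFactors = FALSE)
  if (ncol(cols) < 6L) stop("pileup file must have 6 tab-separated columns")
  bases <- cols[[5L]]
  dirty <- grepl("[\\^$+-]", bases)
  if (any(dirty)) bases[dirty] <- vapply(bases[dirty], .clean_pileup_bases,
                                         character(1), USE.NAMES = FALSE)
  data.frame(contig = cols[[1L]], pos = as.integer(cols[[2L]]) - 1L,
             ref = toupper(cols[[3L]]), depth = as.integer(cols[[4L]]),
             bases = bases, quals = cols[[6L]], stringsAsFactors = FALSE)
}

# strip markers that do not consume a quality character
.clean_pileup_bases <- function(s) {
  s <- gsub("\\^.", "", s)
  s <- gsub("\\$", "", s)
  repeat {
    m <- regexpr("[+-][0-9]+", s)
    if (m < 0L) break
    len <- attr(m, "match.length")
    n <- as.integer(substr(s, m + 1L, m + len - 1L))
    s <- paste0(substr(s, 1L, m - 1L),
                substr(s, m + len + n, nchar(s)))
  }
  s
}

# byte -> allele code lookup: A=1 C=2 G=3 T=4, '.'/',' = 5 (reference),
# everything else 0 (dropped)
.base_code_table <- local({
  tab <- integer(256)
  tab[utf8ToInt("A") + 1L] <- 1L; tab[utf8ToInt("a") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L; tab[utf8ToInt("c") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L; tab[utf8ToInt("g") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L; tab[utf8ToInt("t") + 1L] <- 4L
  tab[utf8ToInt(".") + 1L] <- 5L; tab[utf8ToInt(",") + 1L] <- 5L
  tab
})

#' Subsample pileup columns to uniform coverage
#'
#' Base calls below `min_bq` are removed; positions whose remaining depth
#' exceeds `max_cov` (suspect copy-number artefacts) or falls below `target`
#' are rejected; every surviving position is subsampled to exactly `target`
#' calls by random sampling without replacement. Subsampling to a uniform
#' coverage makes window statistics comparable across the genome and lets
#' the retained calls be treated as a fixed-size sample of chromosomes.
#'
#' @param pile Output of [read_pileup()].
#' @param target Uniform coverage after subsampling.
#' @param max_cov Maximum retained depth before subsampling.
#' @param min_bq Minimum base quality (phred).
#' @param seed Optional integer seed making the subsample reproducible.
#' @return data.frame of allele counts per retained position: `contig`,
#'   `pos`, `A`, `C`, `G`, `T`, `n` (= `target`). Attribute `rejected` is a
#'   data.frame of rejected positions with a `reason` column.
#' @export
subsample_pileup <- function(pile, target = 30, max_cov = 250, min_bq = 20,
                             seed = NULL) {
  target <- .assert_scalar_int(target, "target")
  if (!is.null(seed)) set.seed(seed)
  nb <- nchar(pile$bases)
  if (!all(nchar(pile$quals) == nb))
    stop("base and quality strings differ in length (malformed pileup)")
  col <- rep.int(seq_len(nrow(pile)), nb)
  codes <- .base_code_table[as.integer(charToRaw(paste(pile$bases,
                                                       collapse = ""))) + 1L]
  quals <- as.integer(charToRaw(paste(pile$quals, collapse = ""))) - 33L
  refcode <- match(pile$ref, c("A", "C", "G", "T"))
  is_ref <- codes == 5L
  codes[is_ref] <- refcode[col[is_ref]]
  keep <- !is.na(codes) & codes >= 1L & codes <= 4L & quals >= min_bq
  idx <- (col[keep] - 1L) * 4L + codes[keep]
  counts <- matrix(tabulate(idx, nbins = nrow(pile) * 4L), ncol = 4L,
                   byrow = TRUE)
  depth <- rowSums(counts)
  reason <- ifelse(depth > max_cov, "above_max_coverage",
                   ifelse(depth < target, "below_target", NA))
  ok <- is.na(reason)
  cnt <- counts[ok, , drop = FALSE]
  # sequential multivariate hypergeometric draw of `target` calls
  remaining <- rowSums(cnt); need <- rep.int(target, nrow(cnt))
  sub <- matrix(0L, nrow(cnt), 4L)
  for (a in 1:4) {
    k <- rhyper(nrow(cnt), cnt[, a], remaining - cnt[, a], need)
    sub[, a] <- k
    remaining <- remaining - cnt[, a]
    need <- need - k
  }
  out <- data.frame(contig = pile$contig[ok], pos = pile$pos[ok],
                    A = sub[, 1L], C = sub[, 2L], G = sub[, 3L],
                    T = sub[, 4L], n = target, stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(contig = pile$contig[!ok],
                                      pos = pile$pos[!ok],
                                      reason = reason[!ok],
                                      stringsAsFactors = FALSE)
  out
}

#' Tajima (1989) coefficients for sample size n
#'
#' The a1..e2 coefficient chain entering the variance of `pi - S/a1`.
#'
#' @param n Sample size (number of sequences).
#' @return Named list with `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_coefficients <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# per-column heterozygosity sums and segregating flags
.column_stats <- function(counts, min_count) {
  cm <- as.matrix(counts[, c("A", "C", "G", "T")])
  n <- counts$n
  seg <- (n - apply(cm, 1L, max)) >= min_count & rowSums(cm > 0L) >= 2L
  pi_col <- (n^2 - rowSums(cm^2)) / (n * (n - 1))
  list(seg = seg, pi_col = pi_col)
}

.window_frame <- function(counts, window, lengths, rejected, strict) {
  wid <- paste(counts$contig, counts$pos %/% window, sep = "\r")
  stats_contig <- sub("\r.*", "", unique(wid))
  grid <- do.call(rbind, lapply(names(lengths), function(ct) {
    nw <- ceiling(lengths[[ct]] / window)
    if (nw == 0L) return(NULL)
    data.frame(contig = ct, wstart = (seq_len(nw) - 1L) * window,
               stringsAsFactors = FALSE)
  }))
  grid$wend <- pmin(grid$wstart + window, lengths[grid$contig])
  grid$key <- paste(grid$contig, grid$wstart %/% window, sep = "\r")
  m <- match(wid, grid$key)
  bad_keys <- character(0)
  if (strict && !is.null(rejected) && nrow(rejected))
    bad_keys <- unique(paste(rejected$contig, rejected$pos %/% window,
                             sep = "\r"))
  list(grid = grid, wid = wid, bad_keys = bad_keys)
}

#' Windowed Tajima's D from subsampled allele counts
#'
#' Non-overlapping windows of `window` bp. Per window, `S` counts positions
#' carrying at least `min_count` copies of a non-major allele and `pi` sums
#' the per-position pairwise-difference proportion; Tajima's D is
#' `(pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`, undefined (`NA`) when `S = 0`.
#' A window is `valid` only when every position in it was subsampled to the
#' uniform coverage (strict mode): positions rejected by
#' [subsample_pileup()] or absent from the pileup invalidate their window.
#' With `strict = FALSE` a window is valid whenever it has at least one
#' subsampled position.
#'
#' @param counts Output of [subsample_pileup()].
#' @param window Window size in bp.
#' @param min_count Minimum copies of a non-major allele for a segregating
#'   site.
#' @param lengths Named contig lengths (windows are laid over the full
#'   contigs).
#' @param strict Require complete subsampled coverage per window.
#' @return data.frame per window: `contig`, `wstart`, `wend`, `n_sites`,
#'   `S`, `pi`, `D`, `valid`.
#' @export
tajima_d_windows <- function(counts, window = 500, min_count = 1, lengths,
                             strict = TRUE) {
  cs <- .column_stats(counts, min_count)
  wf <- .window_frame(counts, window, lengths, attr(counts, "rejected"),
                      strict)
  grid <- wf$grid
  idx <- match(wf$wid, grid$key)
  if (anyNA(idx))
    stop("pileup position beyond the supplied contig lengths")
  grid$n_sites <- tabulate(idx, nbins = nrow(grid))
  grid$S <- 0L
  grid$pi <- 0
  if (length(idx)) {
    s_by <- rowsum(as.integer(cs$seg), idx)
    p_by <- rowsum(cs$pi_col, idx)
    at <- as.integer(rownames(s_by))
    grid$S[at] <- as.integer(s_by[, 1L])
    grid$pi[at] <- p_by[, 1L]
  }
  n <- if (nrow(counts)) counts$n[1L] else 2L
  co <- tajima_coefficients(n)
  varS <- co$e1 * grid$S + co$e2 * grid$S * (grid$S - 1L)
  grid$D <- ifelse(grid$S > 0L & varS > 0,
                   (grid$pi - grid$S / co$a1) / sqrt(varS), NA_real_)
  grid$valid <- if (strict)
    grid$n_sites == (grid$wend - grid$wstart) & !(grid$key %in% wf$bad_keys)
  else grid$n_sites > 0L
  grid$key <- NULL
  rownames(grid) <- NULL
  grid
}

#' Windowed nucleotide diversity (pi)
#'
#' As [tajima_d_windows()] but reporting only diversity, in wider windows
#' (default 2,500 bp), for inspecting variability troughs around candidate
#' sweeps.
#'
#' @inheritParams tajima_d_windows
#' @return data.frame per window: `contig`, `wstart`, `wend`, `n_sites`,
#'   `S`, `pi`, `pi_per_site`, `valid`.
#' @export
pi_windows <- function(counts, window = 2500, min_count = 1, lengths,
                       strict = TRUE) {
  w <- tajima_d_windows(counts, window = window, min_count = min_count,
                        lengths = lengths, strict = strict)
  w$pi_per_site <- ifelse(w$n_sites > 0L, w$pi / w$n_sites, NA_real_)
  w$D <- NULL
  w
}

#' Empirical quantile thresholds of windowed Tajima's D
#'
#' Lower empirical (type-1) quantile of the defined D values among valid
#' windows, per partition (by default the X chromosome versus the
#' autosomes, reflecting their different effective population sizes). The
#' thresholds are data products of the window scan, not constants.
#'
#' @param window_stats Output of [tajima_d_windows()].
#' @param q Quantile (fraction).
#' @param partition Named character vector mapping contig to partition
#'   label; contigs not named fall in `"autosome"`, a contig named `"X"`
#'   defaults to its own partition.
#' @return Named numeric vector of thresholds per partition.
#' @export
td_quantile_threshold <- function(window_stats, q = 0.05, partition = NULL) {
  part <- .partition_of(window_stats$contig, partition)
  ok <- window_stats$valid & !is.na(window_stats$D)
  vapply(split(window_stats$D[ok], part[ok]),
         function(d) unname(quantile(d, q, type = 1, names = FALSE)),
         numeric(1))
}

.partition_of <- function(contig, partition = NULL) {
  if (is.null(partition))
    return(ifelse(contig == "X", "X", "autosome"))
  out <- unname(partition[contig])
  out[is.na(out)] <- "autosome"
  out
}
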
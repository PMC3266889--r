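# Sweep scan: recombination-region classes, genomic feature annotation,
# candidate selection among fixed insertions, and the summary tables.

#' Read a recombination-rate track
#'
#' Tab-separated windows (typically 100 kb): `contig`, `start`, `end`
#' (0-based half-open), `rate` in cM/Mb. A header row is auto-detected.
#'
#' @param path Track file.
#' @return data.frame with `contig`, `start`, `end`, `rate`.
#' @export
read_recombination_track <- function(path) {
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 4L) stop("recombination track needs 4 columns")
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L]))))
    raw <- raw[-1L, , drop = FALSE]
  data.frame(contig = raw[[1L]], start = as.integer(raw[[2L]]),
             end = as.integer(raw[[3L]]), rate = as.numeric(raw[[4L]]),
             stringsAsFactors = FALSE)
}

#' Classify recombination regions
#'
#' Windows with a rate below `low_threshold` (default 1 cM/Mb, strict) are
#' low-recombination. Contiguous low runs touching the centromere-proximal
#' end of a chromosome arm are classified `centromere_proximal`, runs
#' touching the telomere-proximal end `telomere_proximal`; interior low
#' runs default to `centromere_proximal` and are flagged. All other
#' windows are `normal`.
#'
#' @param track data.frame with `contig`, `start`, `end`, `rate`.
#' @param centromere_end Named character vector per contig: `"left"` or
#'   `"right"` — which end of the window sequence is centromere-proximal
#'   (e.g. `c(`2L` = "right", `2R` = "left")`). Contigs not named default
#'   to `"right"`.
#' @param low_threshold Rate below which a window is low-recombination.
#' @return `track` with `low`, `region_class` and `interior_low` columns.
#' @export
classify_recombination_region <- function(track, centromere_end = NULL,
                                          low_threshold = 1) {
  .stopifnot_cols(track, c("contig", "start", "end", "rate"), "track")
  track$low <- track$rate < low_threshold
  track$region_class <- "normal"
  track$interior_low <- FALSE
  for (ct in unique(track$contig)) {
    i <- which(track$contig == ct)
    i <- i[order(track$start[i])]
    low <- track$low[i]
    if (!any(low)) next
    cend <- (centromere_end[ct] %||% NA)
    if (is.na(cend)) cend <- "right"
    r <- rle(low)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- i[starts[k]:ends[k]]
      touches_left <- starts[k] == 1L
      touches_right <- ends[k] == length(i)
      cls <- if ((cend == "left" && touches_left) ||
                 (cend == "right" && touches_right)) "centromere_proximal"
      else if (touches_left || touches_right) "telomere_proximal"
      else "centromere_proximal"
      track$region_class[run] <- cls
      track$interior_low[run] <- !touches_left && !touches_right
    }
  }
  track
}

#' Recombination region class at positions
#'
#' @param track Output of [classify_recombination_region()].
#' @param contig,position Vectors of query positions (0-based).
#' @return Character vector of region classes (`NA` outside the track).
#' @export
region_class_at <- function(track, contig, position) {
  out <- rep(NA_character_, length(position))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    tw <- track[track$contig == ct, , drop = FALSE]
    if (!nrow(tw)) next
    tw <- tw[order(tw$start), , drop = FALSE]
    j <- findInterval(position[i], tw$start)
    hit <- j >= 1L & position[i] < tw$end[pmax(j, 1L)]
    out[i[hit]] <- tw$region_class[j[hit]]
  }
  out
}

# feature priority: stronger functional constraint takes precedence
.feature_priority <- c(CDS = 1, five_prime_UTR = 2, three_prime_UTR = 3,
                       exon = 4, ncRNA = 5, regulatory = 6, intron = 7)
.feature_label <- c(CDS = "CDS", five_prime_UTR = "5'-UTR",
                    three_prime_UTR = "3'-UTR", exon = "exon",
                    ncRNA = "ncRNA", regulatory = "regulatory",
                    intron = "intron")

.normalize_feature_type <- function(type) {
  type <- as.character(type)
  map <- c(cds = "CDS", five_prime_utr = "five_prime_UTR",
           `5'utr` = "five_prime_UTR", `5utr` = "five_prime_UTR",
           three_prime_utr = "three_prime_UTR", `3'utr` = "three_prime_UTR",
           `3utr` = "three_prime_UTR", exon = "exon", ncrna = "ncRNA",
           ncrna_gene = "ncRNA", regulatory_region = "regulatory",
           regulatory = "regulatory", intron = "intron", gene = "gene")
  out <- unname(map[tolower(type)])
  ifelse(is.na(out), type, out)
}

#' Annotate positions with genomic features
#'
#' Assigns each position the highest-priority overlapping feature, with
#' categories expected to carry stronger functional constraint taking
#' precedence: CDS > 5'-UTR > 3'-UTR > exon > ncRNA > regulatory > intron;
#' positions overlapping nothing are `intergenic`. Also reports the distance
#' to the nearest annotated gene (0 when inside one).
#'
#' @param contig,position Vectors of query positions (0-based).
#' @param annotation A GFF file path or a `GRanges` with a `type` column
#'   (GFF-style feature types; `gene` features are used for distances).
#' @return data.frame with `feature` and `gene_distance`.
#' @export
annotate_features <- function(contig, position, annotation) {
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  stopifnot(inherits(annotation, "GRanges"))
  type <- .normalize_feature_type(S4Vectors::mcols(annotation)$type)
  qry <- GenomicRanges::GRanges(contig,
                                IRanges::IRanges(start = position + 1L,
                                                 width = 1L))
  feat_idx <- which(type %in% names(.feature_priority))
  feature <- rep("intergenic", length(position))
  if (length(feat_idx)) {
    hits <- GenomicRanges::findOverlaps(qry, annotation[feat_idx])
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      prio <- .feature_priority[type[feat_idx][S4Vectors::subjectHits(hits)]]
      best <- tapply(prio, qh, min)
      feature[as.integer(names(best))] <-
        .feature_label[names(.feature_priority)[best]]
    }
  }
  gene_distance <- rep(NA_integer_, length(position))
  genes <- annotation[type == "gene"]
  if (length(genes)) {
    d <- GenomicRanges::distanceToNearest(qry, genes)
    gene_distance[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  }
  data.frame(feature = feature, gene_distance = gene_distance,
             stringsAsFactors = FALSE)
}

#' Scan for candidate positively selected insertions
#'
#' A fixed insertion (frequency above `fixed_threshold`) in a normally
#' recombining region, from a family that is not flagged ancient, is a sweep
#' candidate when the lowest defined Tajima's D among the windows at the
#' qualifying offsets (the window containing the insertion and its
#' immediate neighbours by default) falls below the partition's genome-wide
#' quantile threshold. D values at offsets -2..+2 are reported for context.
#'
#' @param freqs Frequency estimates ([estimate_frequencies()] /
#'   [apply_site_filters()]) with `position` filled in.
#' @param window_stats Output of [tajima_d_windows()].
#' @param thresholds Output of [td_quantile_threshold()].
#' @param recomb_track Output of [classify_recombination_region()], or
#'   `NULL` to treat everything as normal recombination.
#' @param hierarchy A [te_hierarchy()] (ancient-family flags).
#' @param offsets Window offsets reported.
#' @param qualifying Offsets at which a low D qualifies a candidate.
#' @param fixed_threshold Frequency above which an insertion counts as
#'   fixed.
#' @param partition Contig-to-partition map (see
#'   [td_quantile_threshold()]).
#' @return data.frame of candidates: call fields, `region_class`,
#'   `threshold`, one `D_<offset>` column per offset, and
#'   `qualifying_offsets`.
#' @export
scan_candidates <- function(freqs, window_stats, thresholds,
                            recomb_track = NULL, hierarchy,
                            offsets = -2:2, qualifying = -1:1,
                            fixed_threshold = 0.95, partition = NULL) {
  stopifnot(inherits(hierarchy, "te_hierarchy"))
  window <- window_stats$wend[1L] - window_stats$wstart[1L]
  f <- freqs[!is.na(freqs$f) & freqs$f > fixed_threshold, , drop = FALSE]
  if (nrow(f)) f <- f[!te_is_ancient(hierarchy, f$family), , drop = FALSE]
  if (nrow(f) && !is.null(recomb_track)) {
    rc <- region_class_at(recomb_track, f$contig, f$position)
    f$region_class <- rc
    f <- f[!is.na(rc) & rc == "normal", , drop = FALSE]
  } else if (nrow(f)) f$region_class <- "normal"
  if (!nrow(f)) {
    out <- f
    for (o in offsets) out[[paste0("D_", o)]] <- numeric(0)
    out$threshold <- numeric(0); out$qualifying_offsets <- character(0)
    return(out)
  }
  part <- .partition_of(f$contig, partition)
  f$threshold <- unname(thresholds[part])
  key <- paste(window_stats$contig, window_stats$wstart %/% window,
               sep = "\r")
  wbase <- f$position %/% window
  dmat <- matrix(NA_real_, nrow(f), length(offsets),
                 dimnames = list(NULL, paste0("D_", offsets)))
  for (j in seq_along(offsets)) {
    m <- match(paste(f$contig, wbase + offsets[j], sep = "\r"), key)
    d <- window_stats$D[m]
    d[!is.na(m) & !window_stats$valid[m]] <- NA_real_
    dmat[, j] <- d
  }
  for (cn in colnames(dmat)) f[[cn]] <- dmat[, cn]
  qcols <- paste0("D_", intersect(qualifying, offsets))
  qd <- dmat[, qcols, drop = FALSE]
  pass <- matrix(!is.na(qd) & qd < f$threshold, nrow = nrow(f))
  f$qualifying_offsets <- apply(pass, 1L, function(x)
    paste(intersect(qualifying, offsets)[x], collapse = ","))
  cand <- f[rowSums(pass) > 0L, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Summary table of insertion abundance and frequencies
#'
#' Per category: number of insertions, density per Mb, number with a
#' frequency estimate (`n_fe`), number fixed (frequency above
#' `fixed_threshold`), percent fixed, and median frequency. Categories with
#' no frequency estimates report `NA` fractions. Counts are conserved: rows
#' sum to the totals of the input.
#'
#' @param group Character vector assigning each insertion to a category.
#' @param f Numeric vector of frequency estimates (`NA` = no estimate).
#' @param lengths_mb Named numeric vector: category length in Mb (for
#'   density); categories not named get `NA` density.
#' @param fixed_threshold Fixed-insertion frequency threshold.
#' @return data.frame with `group`, `n`, `length_mb`, `density`, `n_fe`,
#'   `n_fixed`, `fixed_pct`, `median_f`.
#' @export
summarize_insertions <- function(group, f, lengths_mb = NULL,
                                 fixed_threshold = 0.95) {
  stopifnot(length(group) == length(f))
  groups <- sort(unique(group))
  rows <- lapply(groups, function(g) {
    sel <- group == g
    fe <- f[sel][!is.na(f[sel])]
    len <- if (!is.null(lengths_mb)) unname(lengths_mb[g]) else NA_real_
    data.frame(group = g, n = sum(sel), length_mb = len,
               density = if (!is.na(len) && len > 0) sum(sel) / len
                         else NA_real_,
               n_fe = length(fe),
               n_fixed = sum(fe > fixed_threshold),
               fixed_pct = if (length(fe)) 100 * sum(fe > fixed_threshold) /
                 length(fe) else NA_real_,
               median_f = if (length(fe)) median(fe) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
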
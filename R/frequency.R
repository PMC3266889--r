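# Population frequency estimation from presence/absence fragment tallies in
# 100 bp ranges, plus the binomial detection model for reference insertions
# missed by detection. No code path here branches on whether a call is
# known or novel — that is what keeps the estimator free of reference
# ascertainment bias.

#' Define 100 bp tally ranges for insertion calls
#'
#' For each available side of a call, a range of at most `width` bp is
#' anchored at the extreme qualifying position of the supporting reads (the
#' outermost start of a forward read, the outermost end of a reverse read)
#' and extends away from the insertion. Truncating to `width` bp avoids
#' inflating the range — and hence the absence tally — with fragments of
#' unrepresentatively large insert size. Presence and absence fragments are
#' later tallied against the same range using the same qualifying-position
#' rule, so both are counted on identical footing.
#'
#' @param calls Output of [join_forward_reverse()].
#' @param lengths Optional named contig lengths for clamping.
#' @param width Range width in bp.
#' @return data.frame with one row per call side: `call_id`, `side`
#'   (`fwd`/`rev`), `contig`, `direction`, `family`, `start`, `end`
#'   (0-based half-open).
#' @export
tally_ranges <- function(calls, lengths = NULL, width = 100) {
  width <- .assert_scalar_int(width, "width")
  rows <- list()
  has_f <- calls$support %in% c("F", "FR")
  if (any(has_f)) {
    q <- calls$fwd_outer[has_f]              # max qualifying start
    rows$f <- data.frame(call_id = calls$call_id[has_f], side = "fwd",
                         contig = calls$contig[has_f], direction = "forward",
                         family = calls$family[has_f],
                         start = q - width + 1L, end = q + 1L,
                         stringsAsFactors = FALSE)
  }
  has_r <- calls$support %in% c("R", "FR")
  if (any(has_r)) {
    q <- calls$rev_outer[has_r] - 1L         # min qualifying end (inclusive)
    rows$r <- data.frame(call_id = calls$call_id[has_r], side = "rev",
                         contig = calls$contig[has_r], direction = "reverse",
                         family = calls$family[has_r],
                         start = q, end = q + width,
                         stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) return(data.frame(call_id = integer(), side = character(),
                                      contig = character(),
                                      direction = character(),
                                      family = character(), start = integer(),
                                      end = integer()))
  out$start <- pmax(out$start, 0L)
  if (!is.null(lengths))
    out$end <- pmin(out$end, as.integer(lengths[out$contig]))
  rownames(out) <- NULL
  out
}

# count, per range, sorted positions falling inside [start, end)
.count_in_ranges <- function(pos_sorted, start, end) {
  findInterval(end - 0.5, pos_sorted) - findInterval(start - 0.5, pos_sorted)
}

#' Tally presence and absence fragments in a range
#'
#' Presence fragments of the range's family and direction are counted when
#' their qualifying genome-read position (start of the genome read for
#' forward evidence, end for reverse) lies in the range. Absence fragments
#' are proper pairs whose qualifying read position (start of the 5' read for
#' forward-side ranges, end of the 3' read for reverse-side ranges) lies in
#' the same range. Everything else is ignored.
#'
#' @param range One row of [tally_ranges()] (or a list with the same
#'   fields).
#' @param fragments Output of [classify_fragments()].
#' @return Named integer vector `c(presence = , absence = )`.
#' @export
tally_fragments <- function(range, fragments) {
  pres <- fragments$kind == "PRESENCE" &
    fragments$contig == range$contig &
    fragments$direction == range$direction &
    .fam_key(fragments$family) == .fam_key(range$family) &
    fragments$qualifying >= range$start & fragments$qualifying < range$end
  qa <- if (range$side == "fwd") fragments$span_start
        else fragments$span_end - 1L
  abs_ <- fragments$kind == "PROPER_PAIR" &
    fragments$contig == range$contig &
    qa >= range$start & qa < range$end
  c(presence = sum(pres, na.rm = TRUE), absence = sum(abs_, na.rm = TRUE))
}

#' Estimate per-insertion population frequencies
#'
#' Per side, the frequency is presence / (presence + absence); the combined
#' frequency is the unweighted mean of the available sides (each side is an
#' independent assessment of the same insertion), or the coverage-weighted
#' pooled ratio with `combine = "weighted"`. Coverage is the total of
#' presence and absence fragments over both sides; sites below
#' `min_coverage` are flagged `low_coverage` (strictly fewer than 10 by
#' default; exactly 10 is kept).
#'
#' @param calls Output of [join_forward_reverse()] (after
#'   [estimate_position()] / [match_to_reference_annotation()] if desired).
#' @param fragments Output of [classify_fragments()].
#' @param lengths Optional named contig lengths.
#' @param min_coverage Minimum total coverage.
#' @param combine `"mean"` (unweighted mean of sides) or `"weighted"`.
#' @param width Tally range width in bp.
#' @return `calls` with tally columns (`p_fwd`, `a_fwd`, `p_rev`, `a_rev`),
#'   per-side frequencies (`f_fwd`, `f_rev`), combined frequency `f`,
#'   `coverage` and `status` (`estimated`/`low_coverage`). Attribute
#'   `ranges` carries the tally ranges used.
#' @export
estimate_frequencies <- function(calls, fragments, lengths = NULL,
                                 min_coverage = 10,
                                 combine = c("mean", "weighted"),
                                 width = 100) {
  combine <- match.arg(combine)
  ranges <- tally_ranges(calls, lengths = lengths, width = width)

  pres <- fragments[fragments$kind == "PRESENCE", , drop = FALSE]
  prop <- fragments[fragments$kind == "PROPER_PAIR", , drop = FALSE]
  pkey <- paste(pres$contig, pres$direction, .fam_key(pres$family),
                sep = "\r")
  pres_idx <- split(pres$qualifying, pkey)
  pres_idx <- lapply(pres_idx, sort)
  span_start <- lapply(split(prop$span_start, prop$contig), sort)
  span_last <- lapply(split(prop$span_end - 1L, prop$contig), sort)

  np <- na_ <- integer(nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    k <- paste(ranges$contig[i], ranges$direction[i],
               .fam_key(ranges$family[i]), sep = "\r")
    ps <- pres_idx[[k]]
    np[i] <- if (is.null(ps)) 0L else
      .count_in_ranges(ps, ranges$start[i], ranges$end[i])
    qs <- if (ranges$side[i] == "fwd") span_start[[ranges$contig[i]]]
          else span_last[[ranges$contig[i]]]
    na_[i] <- if (is.null(qs)) 0L else
      .count_in_ranges(qs, ranges$start[i], ranges$end[i])
  }
  ranges$presence <- np; ranges$absence <- na_

  get <- function(side, what) {
    v <- rep(NA_integer_, nrow(calls))
    sel <- ranges$side == side
    v[match(ranges$call_id[sel], calls$call_id)] <- ranges[[what]][sel]
    v
  }
  calls$p_fwd <- get("fwd", "presence"); calls$a_fwd <- get("fwd", "absence")
  calls$p_rev <- get("rev", "presence"); calls$a_rev <- get("rev", "absence")
  den_f <- calls$p_fwd + calls$a_fwd
  den_r <- calls$p_rev + calls$a_rev
  calls$f_fwd <- ifelse(!is.na(den_f) & den_f > 0L, calls$p_fwd / den_f, NA)
  calls$f_rev <- ifelse(!is.na(den_r) & den_r > 0L, calls$p_rev / den_r, NA)
  if (combine == "mean") {
    calls$f <- rowMeans(cbind(calls$f_fwd, calls$f_rev), na.rm = TRUE)
    calls$f[is.nan(calls$f)] <- NA
  } else {
    tp <- rowSums(cbind(calls$p_fwd, calls$p_rev), na.rm = TRUE)
    td <- rowSums(cbind(den_f, den_r), na.rm = TRUE)
    calls$f <- ifelse(td > 0, tp / td, NA)
  }
  calls$coverage <- rowSums(cbind(den_f, den_r), na.rm = TRUE)
  calls$status <- ifelse(calls$coverage < min_coverage | is.na(calls$f),
                         "low_coverage", "estimated")
  attr(calls, "ranges") <- ranges
  calls
}

#' Apply site-level filters to frequency estimates
#'
#' Discards insertion sites with coverage below `min_coverage` and sites
#' whose tally ranges overlap another call's ranges on the same contig
#' (frequency estimates at overlapping or nested insertions are unreliable;
#' both members of an overlapping pair are removed). Removals are reported
#' with reasons in the `removed` attribute.
#'
#' @param estimates Output of [estimate_frequencies()].
#' @param min_coverage Minimum total coverage (strict: exactly
#'   `min_coverage` is kept).
#' @return Filtered estimates; attribute `removed` holds the dropped rows
#'   with a `filter_reason` column.
#' @export
apply_site_filters <- function(estimates, min_coverage = 10) {
  ranges <- attr(estimates, "ranges")
  if (is.null(ranges)) stop("estimates must come from estimate_frequencies()")
  reason <- rep(NA_character_, nrow(estimates))
  if (nrow(ranges)) {
    ir <- IRanges::IRanges(start = ranges$start + 1L, end = ranges$end)
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    diff_call <- ranges$call_id[qh] != ranges$call_id[sh] &
      ranges$contig[qh] == ranges$contig[sh]
    bad_calls <- unique(ranges$call_id[qh[diff_call]])
    reason[estimates$call_id %in% bad_calls] <- "overlapping_range"
  }
  low <- is.na(reason) & (estimates$coverage < min_coverage |
                            is.na(estimates$f))
  reason[low] <- "low_coverage"
  removed <- estimates[!is.na(reason), , drop = FALSE]
  removed$filter_reason <- reason[!is.na(reason)]
  kept <- estimates[is.na(reason), , drop = FALSE]
  if (nrow(kept)) kept$status <- "estimated"
  if (nrow(removed))
    message(sum(removed$filter_reason == "low_coverage"), " low-coverage and ",
            sum(removed$filter_reason == "overlapping_range"),
            " overlapping-range site(s) removed")
  attr(kept, "ranges") <- ranges[ranges$call_id %in% kept$call_id, ,
                                 drop = FALSE]
  attr(kept, "removed") <- removed
  kept
}

#' Solve the binomial detection model for missed reference insertions
#'
#' If each side (forward/reverse) of a reference insertion present in the
#' sample is detected independently with probability `p`, the numbers of
#' insertions identified from a single direction (`n1`) and from both
#' directions (`n2`) follow `n1 = 2p(1-p)*nT` and `n2 = p^2*nT`, where `nT`
#' is the total number of reference insertions present. Inverting:
#' `p = 2*n2 / (n1 + 2*n2)`, `nT = n2 / p^2`, and the number missed is
#' `n0 = nT - n1 - n2`. Estimates are kept at full precision and also
#' reported rounded to the nearest integer.
#'
#' @param n1 Count of single-direction identifications.
#' @param n2 Count of dual-direction identifications (must be positive: with
#'   `n2 = 0` the model has no solution).
#' @return List of class `detection_model`: `n1`, `n2`, `p`, `nT`, `n0`,
#'   `nT_rounded`, `n0_rounded`.
#' @export
solve_detection_model <- function(n1, n2) {
  if (length(n1) != 1L || length(n2) != 1L || is.na(n1) || is.na(n2) ||
      n1 < 0 || n2 < 0)
    stop("'n1' and 'n2' must be single non-negative counts")
  if (n2 == 0)
    stop("detection model unsolvable: n2 = 0 leaves p undefined")
  p <- 2 * n2 / (n1 + 2 * n2)
  nT <- n2 / p^2
  n0 <- nT - n1 - n2
  structure(list(n1 = n1, n2 = n2, p = p, nT = nT, n0 = n0,
                 nT_rounded = as.integer(round(nT)),
                 n0_rounded = as.integer(round(n0))),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf(paste0("detection model: n1 = %d, n2 = %d -> p = %.4f, ",
                     "nT = %.1f (%d), n0 = %.1f (%d)\n"),
              x$n1, x$n2, x$p, x$nT, x$nT_rounded, x$n0, x$n0_rounded))
  invisible(x)
}

#' Detection model per TE order
#'
#' Counts single- and dual-direction identifications among calls matched to
#' the reference (`known_novel == "known"`) and solves the detection model for
#' each TE order separately, plus the overall total.
#'
#' @param calls Calls with `known_novel` and `support` columns
#'   ([match_to_reference_annotation()]).
#' @return data.frame with one row per order (and an `all` row): `order`,
#'   `n1`, `n2`, `p`, `nT`, `n0`, `nT_rounded`, `n0_rounded`. Orders with
#'   `n2 = 0` are reported with `NA` estimates.
#' @export
solve_detection_model_by_order <- function(calls) {
  known <- calls[calls$known_novel == "known", , drop = FALSE]
  grp <- c(sort(unique(known$order)), "all")
  rows <- lapply(grp, function(g) {
    sel <- if (g == "all") rep(TRUE, nrow(known)) else known$order == g
    n1 <- sum(known$support[sel] %in% c("F", "R"))
    n2 <- sum(known$support[sel] == "FR")
    if (n2 == 0L)
      return(data.frame(order = g, n1 = n1, n2 = n2, p = NA_real_,
                        nT = NA_real_, n0 = NA_real_,
                        nT_rounded = NA_integer_, n0_rounded = NA_integer_))
    m <- solve_detection_model(n1, n2)
    data.frame(order = g, n1 = n1, n2 = n2, p = m$p, nT = m$nT, n0 = m$n0,
               nT_rounded = m$nT_rounded, n0_rounded = m$n0_rounded)
  })
  do.call(rbind, rows)
}
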
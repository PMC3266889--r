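# Insertion caller: directional clustering of presence fragments, F/R
# joining with masked-aware distances, position approximation, and matching
# against a reference TE annotation.

#' Cluster presence fragments into directional insertion signals
#'
#' Single-linkage clustering per (contig, direction, family): anchors are
#' sorted and the chain is broken wherever consecutive anchors are separated
#' by `max_gap` or more ("separated by less than 225 bp" joins, so a gap of
#' exactly 225 splits). Clusters supported by fewer than `min_support`
#' fragments are discarded; fragments below `min_mq` never enter. The result
#' is deterministic and invariant to input order.
#'
#' Each cluster records two boundary positions: `boundary`, the edge of the
#' read hull nearest the insertion (max anchor for forward clusters, min for
#' reverse) used for position estimates and tally ranges, and `outer`, the
#' outer edge of that same junction-adjacent read (its start for forward,
#' its end for reverse) used for forward/reverse joining.
#'
#' @param fragments Output of [classify_fragments()].
#' @param max_gap Gap (bp) at or above which a cluster is split.
#' @param min_support Minimum supporting fragments per cluster.
#' @param min_mq Minimum genome-read mapping quality.
#' @return data.frame of clusters: `cluster_id`, `contig`, `direction`,
#'   `family`, `order`, `n_fragments`, `boundary`, `outer`, `amin`, `amax`
#'   (read hull). Attribute `assignment` maps retained presence fragments
#'   (by `qname`) to cluster ids (`NA` = discarded).
#' @export
cluster_directional <- function(fragments, max_gap = 225, min_support = 3,
                                min_mq = 15) {
  f <- fragments[fragments$kind == "PRESENCE" & !is.na(fragments$mq) &
                   fragments$mq >= min_mq, , drop = FALSE]
  if (nrow(f) == 0L) {
    out <- data.frame(cluster_id = integer(), contig = character(),
                      direction = character(), family = character(),
                      order = character(), n_fragments = integer(),
                      boundary = integer(), outer = integer(),
                      amin = integer(), amax = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "assignment") <- data.frame(qname = character(),
                                          cluster_id = integer())
    return(out)
  }
  key <- paste(f$contig, f$direction, .fam_key(f$family), sep = "\r")
  o <- order(key, f$anchor)
  f <- f[o, , drop = FALSE]; key <- key[o]
  new_grp <- c(TRUE, key[-1L] != key[-length(key)])
  gap_split <- c(FALSE, diff(f$anchor) >= max_gap) & !new_grp
  cid <- cumsum(new_grp | gap_split)
  n_by <- tabulate(cid)
  keep_cl <- which(n_by >= min_support)
  keep <- cid %in% keep_cl
  cidk <- match(cid[keep], keep_cl)
  fk <- f[keep, , drop = FALSE]
  agg <- function(x, fun) as.integer(tapply(x, cidk, fun))
  first <- !duplicated(cidk)
  fwd <- fk$direction[first] == "forward"
  clusters <- data.frame(
    cluster_id = seq_along(keep_cl),
    contig = fk$contig[first],
    direction = fk$direction[first],
    family = fk$family[first],
    order = fk$order[first],
    n_fragments = as.integer(n_by[keep_cl]),
    boundary = ifelse(fwd, agg(fk$anchor, max), agg(fk$anchor, min)),
    outer = ifelse(fwd, agg(fk$g_start, max), agg(fk$g_end, min)),
    amin = agg(fk$g_start, min),
    amax = agg(fk$g_end, max),
    stringsAsFactors = FALSE)
  attr(clusters, "assignment") <- data.frame(qname = fk$qname,
                                             cluster_id = cidk,
                                             stringsAsFactors = FALSE)
  clusters
}

#' Join forward and reverse clusters into insertion calls
#'
#' A forward and a reverse cluster of the same family join into one
#' dual-direction (`FR`) call when the masked-aware distance between the
#' outer edges of their junction-adjacent reads (start of the last forward
#' read to end of the first reverse read) lies within `[min_dist, max_dist]`
#' inclusive. For a clean junction that distance is about two read lengths
#' plus the junction gap; its theoretical floor is one read length, and
#' masked sequence (a reference TE span between the two signals) does not
#' count, so insertions in and not in the reference are joined on the same
#' scale. Each cluster joins at most one partner — nearest by masked
#' distance, ties broken toward the smaller coordinate. Unjoined clusters
#' become single-direction (`F`/`R`) calls.
#'
#' @param clusters Output of [cluster_directional()].
#' @param masked A `masked_genome` or `combined_reference`.
#' @param min_dist,max_dist Inclusive joining window in masked-aware bp.
#' @return data.frame of insertion calls: `call_id`, `contig`, `family`,
#'   `order`, `support` (`F`, `R`, `FR`), `n_fwd`, `n_rev`, boundary and
#'   outer positions per side, `amin`, `amax`, `join_distance`, `position`
#'   (`NA` until [estimate_position()]).
#' @export
join_forward_reverse <- function(clusters, masked, min_dist = 74,
                                 max_dist = 250) {
  cl <- clusters
  empty_call <- function() data.frame(
    call_id = integer(), contig = character(), family = character(),
    order = character(), support = character(), n_fwd = integer(),
    n_rev = integer(), fwd_boundary = integer(), rev_boundary = integer(),
    fwd_outer = integer(), rev_outer = integer(), amin = integer(),
    amax = integer(), join_distance = integer(), position = integer(),
    fwd_cluster = integer(), rev_cluster = integer(),
    stringsAsFactors = FALSE)
  if (nrow(cl) == 0L) return(empty_call())

  fwd <- cl[cl$direction == "forward", , drop = FALSE]
  rev <- cl[cl$direction == "reverse", , drop = FALSE]
  cand <- NULL
  if (nrow(fwd) && nrow(rev)) {
    keyf <- paste(fwd$contig, .fam_key(fwd$family), sep = "\r")
    keyr <- paste(rev$contig, .fam_key(rev$family), sep = "\r")
    common <- intersect(keyf, keyr)
    cand_list <- lapply(common, function(k) {
      fi <- which(keyf == k); ri <- which(keyr == k)
      g <- expand.grid(fi = fi, ri = ri)
      g[fwd$boundary[g$fi] <= rev$boundary[g$ri] &
          fwd$outer[g$fi] <= rev$outer[g$ri], , drop = FALSE]
    })
    cand <- do.call(rbind, cand_list)
  }
  pair_f <- integer(0); pair_r <- integer(0); pair_d <- integer(0)
  if (!is.null(cand) && nrow(cand)) {
    d <- masked_distance(masked, fwd$contig[cand$fi],
                         fwd$outer[cand$fi], rev$outer[cand$ri])
    ok <- d >= min_dist & d <= max_dist
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    if (nrow(cand)) {
      o <- order(d, fwd$boundary[cand$fi], rev$boundary[cand$ri])
      cand <- cand[o, , drop = FALSE]; d <- d[o]
      used_f <- logical(nrow(fwd)); used_r <- logical(nrow(rev))
      for (i in seq_len(nrow(cand))) {
        if (!used_f[cand$fi[i]] && !used_r[cand$ri[i]]) {
          used_f[cand$fi[i]] <- TRUE; used_r[cand$ri[i]] <- TRUE
          pair_f <- c(pair_f, cand$fi[i]); pair_r <- c(pair_r, cand$ri[i])
          pair_d <- c(pair_d, d[i])
        }
      }
    }
  }
  mk <- function(contig, family, ord, support, n_fwd, n_rev, fb, rb, fo, ro,
                 amin, amax, jd, fc, rc)
    data.frame(contig = contig, family = family, order = ord,
               support = support, n_fwd = n_fwd, n_rev = n_rev,
               fwd_boundary = fb, rev_boundary = rb, fwd_outer = fo,
               rev_outer = ro, amin = amin, amax = amax, join_distance = jd,
               position = NA_integer_, fwd_cluster = fc, rev_cluster = rc,
               stringsAsFactors = FALSE)
  parts <- list()
  if (length(pair_f))
    parts$fr <- mk(fwd$contig[pair_f], fwd$family[pair_f], fwd$order[pair_f],
                   "FR", fwd$n_fragments[pair_f], rev$n_fragments[pair_r],
                   fwd$boundary[pair_f], rev$boundary[pair_r],
                   fwd$outer[pair_f], rev$outer[pair_r],
                   pmin(fwd$amin[pair_f], rev$amin[pair_r]),
                   pmax(fwd$amax[pair_f], rev$amax[pair_r]), pair_d,
                   fwd$cluster_id[pair_f], rev$cluster_id[pair_r])
  lone_f <- setdiff(seq_len(nrow(fwd)), pair_f)
  if (length(lone_f))
    parts$f <- mk(fwd$contig[lone_f], fwd$family[lone_f], fwd$order[lone_f],
                  "F", fwd$n_fragments[lone_f], 0L, fwd$boundary[lone_f],
                  NA_integer_, fwd$outer[lone_f], NA_integer_,
                  fwd$amin[lone_f], fwd$amax[lone_f], NA_integer_,
                  fwd$cluster_id[lone_f], NA_integer_)
  lone_r <- setdiff(seq_len(nrow(rev)), pair_r)
  if (length(lone_r))
    parts$r <- mk(rev$contig[lone_r], rev$family[lone_r], rev$order[lone_r],
                  "R", 0L, rev$n_fragments[lone_r], NA_integer_,
                  rev$boundary[lone_r], NA_integer_, rev$outer[lone_r],
                  rev$amin[lone_r], rev$amax[lone_r], NA_integer_,
                  NA_integer_, rev$cluster_id[lone_r])
  calls <- do.call(rbind, unname(parts))
  calls <- calls[order(calls$contig, ifelse(is.na(calls$fwd_boundary),
                                            calls$rev_boundary,
                                            calls$fwd_boundary)), ,
                 drop = FALSE]
  calls$call_id <- seq_len(nrow(calls))
  rownames(calls) <- NULL
  calls[, c("call_id", setdiff(names(calls), "call_id"))]
}

#' Approximate insertion positions
#'
#' Dual-direction calls take the midpoint between the forward and reverse
#' boundaries (rounded down); single-direction calls take the last (first)
#' position occupied by a forward (reverse) read plus (minus) `offset` bp,
#' the expected gap between the innermost read and the insertion point
#' (one third of the inner mate distance). Positions are clamped to contig
#' bounds; they are approximations, not breakpoints.
#'
#' @param calls Output of [join_forward_reverse()].
#' @param lengths Optional named contig lengths for clamping.
#' @param offset Single-direction offset in bp.
#' @return `calls` with `position` filled in.
#' @export
estimate_position <- function(calls, lengths = NULL, offset = 26) {
  pos <- ifelse(calls$support == "FR",
                (calls$fwd_boundary + calls$rev_boundary) %/% 2L,
                ifelse(calls$support == "F", calls$fwd_boundary + offset,
                       calls$rev_boundary - offset))
  pos <- pmax(pos, 0L)
  if (!is.null(lengths))
    pos <- pmin(pos, as.integer(lengths[calls$contig]) - 1L)
  calls$position <- as.integer(pos)
  calls
}

#' Match insertion calls to a reference TE annotation
#'
#' A call corresponds to a reference insertion when both belong to the same
#' family and the reads supporting the call map to within `max_dist` bp
#' (inclusive, nearest edge) of the annotated span. Assignment is
#' one-to-one, preferring the smallest distance, ties broken toward the
#' smaller coordinate. Matched calls are labelled `known`, others `novel`.
#'
#' @param calls Output of [join_forward_reverse()].
#' @param annotation Reference TE insertions: data.frame with columns
#'   `contig`, `start`, `end` (0-based half-open), `family`, `id`, or a
#'   `GRanges` with `family` and `id` metadata columns.
#' @param max_dist Matching distance in bp (inclusive).
#' @return `calls` with `known_novel` (`known`/`novel`), `reference_id` and
#'   `reference_distance` columns.
#' @export
match_to_reference_annotation <- function(calls, annotation, max_dist = 300) {
  if (inherits(annotation, "GRanges")) {
    mc <- S4Vectors::mcols(annotation)
    annotation <- data.frame(
      contig = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation) - 1L,
      end = GenomicRanges::end(annotation),
      family = as.character(mc$family), id = as.character(mc$id),
      stringsAsFactors = FALSE)
  }
  .stopifnot_cols(annotation, c("contig", "start", "end", "family", "id"),
                  "annotation")
  calls$known_novel <- "novel"
  calls$reference_id <- NA_character_
  calls$reference_distance <- NA_integer_
  if (nrow(calls) == 0L || nrow(annotation) == 0L) return(calls)
  keyc <- paste(calls$contig, .fam_key(calls$family), sep = "\r")
  keya <- paste(annotation$contig, .fam_key(annotation$family), sep = "\r")
  cand <- do.call(rbind, lapply(intersect(keyc, keya), function(k) {
    expand.grid(ci = which(keyc == k), ai = which(keya == k))
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(calls)
  d <- pmax(0L, annotation$start[cand$ai] - calls$amax[cand$ci],
            calls$amin[cand$ci] - annotation$end[cand$ai])
  ok <- d <= max_dist
  cand <- cand[ok, , drop = FALSE]; d <- d[ok]
  if (nrow(cand) == 0L) return(calls)
  o <- order(d, annotation$start[cand$ai], calls$amin[cand$ci])
  cand <- cand[o, , drop = FALSE]; d <- d[o]
  used_c <- logical(nrow(calls)); used_a <- logical(nrow(annotation))
  for (i in seq_len(nrow(cand))) {
    ci <- cand$ci[i]; ai <- cand$ai[i]
    if (!used_c[ci] && !used_a[ai]) {
      used_c[ci] <- TRUE; used_a[ai] <- TRUE
      calls$known_novel[ci] <- "known"
      calls$reference_id[ci] <- annotation$id[ai]
      calls$reference_distance[ci] <- d[i]
    }
  }
  calls
}
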
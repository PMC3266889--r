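#' Classify paired-end fragments as presence, proper-pair or uninformative
#'
#' A fragment with one read anchored in the genome and its mate in a TE
#' contig is TE-presence evidence (`PRESENCE`); the signal is *forward* when
#' the genome-mapped read is on the `+` strand (the insertion lies 3' of it)
#' and *reverse* when on the `-` strand. A genome-genome pair in proper
#' orientation (`+` read upstream of the `-` read, reads non-overlapping) is
#' potential absence evidence (`PROPER_PAIR`). Everything else (TE-TE pairs,
#' discordant genome pairs, unmapped mates) is `UNINFORMATIVE`.
#'
#' For `PRESENCE` fragments the per-fragment mapping quality used by
#' downstream filters is that of the genome-mapped read (a mapping quality on
#' a multi-copy TE library carries no information). Two positions of the
#' genome read are carried along: `anchor` (its end for forward, start for
#' reverse — the edge nearest the insertion, used for clustering and
#' boundaries) and `qualifying` (its start for forward, its last occupied
#' position for reverse — the same positions the absence rule uses, so
#' presence and absence fragments are tallied on identical footing).
#'
#' @param pairs Paired alignment data.frame ([restore_pairs()] or
#'   [simulate_pool()]).
#' @param ref A `combined_reference` (or a named `contig_class` vector).
#' @param hierarchy A [te_hierarchy()]; defaults to the one embedded in
#'   `ref`.
#' @return data.frame with one row per fragment: `qname`, `kind`,
#'   `direction`, `family`, `order`, `contig`, `g_start`, `g_end`, `anchor`,
#'   `qualifying`, `mq` (PRESENCE fields), `span_start`, `span_end`
#'   (PROPER_PAIR fields).
#' @export
classify_fragments <- function(pairs, ref, hierarchy = NULL) {
  .stopifnot_cols(pairs, .pair_cols(), "pairs")
  if (inherits(ref, "combined_reference")) {
    contig_class <- ref$contig_class
    hierarchy <- hierarchy %||% ref$hierarchy
  } else contig_class <- ref
  if (is.null(hierarchy)) stop("a te_hierarchy is required")

  cls1 <- unname(contig_class[pairs$r1_contig])
  cls2 <- unname(contig_class[pairs$r2_contig])
  if (anyNA(cls1) || anyNA(cls2))
    stop("alignment on contig absent from the combined reference: ",
         paste(unique(c(pairs$r1_contig[is.na(cls1)],
                        pairs$r2_contig[is.na(cls2)])), collapse = ", "))

  n <- nrow(pairs)
  kind <- rep("UNINFORMATIVE", n)
  direction <- family <- ord <- contig <- rep(NA_character_, n)
  g_start <- g_end <- anchor <- qualifying <- mq <- rep(NA_integer_, n)
  span_start <- span_end <- rep(NA_integer_, n)

  pres <- (cls1 == "genome" & cls2 == "TE") | (cls1 == "TE" & cls2 == "genome")
  if (any(pres)) {
    g1 <- cls1[pres] == "genome"
    te_contig <- ifelse(g1, pairs$r2_contig[pres], pairs$r1_contig[pres])
    fam <- te_family(hierarchy, te_contig)
    kind[pres] <- "PRESENCE"
    family[pres] <- fam
    ord[pres] <- te_order(hierarchy, fam)
    contig[pres] <- ifelse(g1, pairs$r1_contig[pres], pairs$r2_contig[pres])
    gs <- ifelse(g1, pairs$r1_start[pres], pairs$r2_start[pres])
    ge <- ifelse(g1, pairs$r1_end[pres], pairs$r2_end[pres])
    gstrand <- ifelse(g1, pairs$r1_strand[pres], pairs$r2_strand[pres])
    g_start[pres] <- gs; g_end[pres] <- ge
    mq[pres] <- ifelse(g1, pairs$r1_mapq[pres], pairs$r2_mapq[pres])
    fwd <- gstrand == "+"
    direction[pres] <- ifelse(fwd, "forward", "reverse")
    anchor[pres] <- ifelse(fwd, ge, gs)
    qualifying[pres] <- ifelse(fwd, gs, ge - 1L)
  }

  gg <- cls1 == "genome" & cls2 == "genome" &
    pairs$r1_contig == pairs$r2_contig & pairs$r1_strand != pairs$r2_strand
  if (any(gg)) {
    p_start <- ifelse(pairs$r1_strand[gg] == "+", pairs$r1_start[gg],
                      pairs$r2_start[gg])
    p_end <- ifelse(pairs$r1_strand[gg] == "+", pairs$r1_end[gg],
                    pairs$r2_end[gg])
    m_start <- ifelse(pairs$r1_strand[gg] == "-", pairs$r1_start[gg],
                      pairs$r2_start[gg])
    m_end <- ifelse(pairs$r1_strand[gg] == "-", pairs$r1_end[gg],
                    pairs$r2_end[gg])
    proper <- p_end <= m_start      # + read upstream, no overlap
    idx <- which(gg)[proper]
    kind[idx] <- "PROPER_PAIR"
    contig[idx] <- pairs$r1_contig[idx]
    span_start[idx] <- p_start[proper]
    span_end[idx] <- m_end[proper]
  }

  data.frame(qname = pairs$qname, kind = kind, direction = direction,
             family = family, order = ord, contig = contig,
             g_start = g_start, g_end = g_end, anchor = anchor,
             qualifying = qualifying, mq = mq,
             span_start = span_start, span_end = span_end,
             stringsAsFactors = FALSE)
}

#' Summarize fragment classification
#'
#' Counts per kind and direction, plus the forward:reverse ratio of presence
#' fragments (an imbalance is reported, not corrected).
#'
#' @param fragments Output of [classify_fragments()].
#' @return data.frame of counts, with attribute `fr_ratio`.
#' @export
classification_summary <- function(fragments) {
  key <- ifelse(fragments$kind == "PRESENCE",
                paste0("PRESENCE_", fragments$direction), fragments$kind)
  tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(tab) <- c("class", "n")
  nf <- sum(fragments$kind == "PRESENCE" & fragments$direction == "forward")
  nr <- sum(fragments$kind == "PRESENCE" & fragments$direction == "reverse")
  ratio <- if (nr > 0L) nf / nr else NA_real_
  message(sprintf("presence fragments forward:reverse = %d:%d (ratio %.3f)",
                  nf, nr, ratio))
  attr(tab, "fr_ratio") <- ratio
  tab
}
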
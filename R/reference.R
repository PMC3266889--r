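# Combined reference: repeat-masked genome + TE sequences as extra contigs.
# Masked intervals are tracked explicitly so masked-aware distances never
# count assembly gaps (pre-existing N runs) as TE sequence.

.spans_to_df <- function(spans) {
  if (inherits(spans, "GRanges")) {
    data.frame(contig = as.character(GenomicRanges::seqnames(spans)),
               start = GenomicRanges::start(spans) - 1L,
               end = GenomicRanges::end(spans),
               stringsAsFactors = FALSE)
  } else {
    .stopifnot_cols(spans, c("contig", "start", "end"), "span table")
    data.frame(contig = as.character(spans$contig),
               start = as.integer(spans$start), end = as.integer(spans$end),
               stringsAsFactors = FALSE)
  }
}

.reduce_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

.n_runs <- function(seq) {
  ir <- IRanges::reduce(as(Biostrings::matchPattern("N", seq), "IRanges"))
  list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Mask TE spans in a reference genome
#'
#' Coordinate-preserving masking: every base inside a span is replaced by `N`
#' while sequence lengths and all downstream coordinates are unchanged.
#' Overlapping spans are merged. Pre-existing N runs (assembly gaps) are
#' recorded separately and excluded from the masked intervals, so
#' [masked_distance()] never treats an assembly gap as masked repeat.
#'
#' This is a coordinate-preserving substitute for an external repeat-masking
#' engine: users with a TE annotation (e.g. a GFF of TE spans) can build the
#' masked genome directly from it.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param spans TE spans to mask: a data.frame with columns `contig`,
#'   `start`, `end` (0-based, half-open) or a `GRanges`.
#' @return An object of class `masked_genome`: list with `seq` (the masked
#'   `DNAStringSet`), `masked` and `assembly_n` (per-contig sorted
#'   non-overlapping 0-based half-open intervals).
#' @export
mask_from_annotation <- function(genome, spans) {
  stopifnot(inherits(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome contigs must have unique names")
  sp <- .spans_to_df(spans)
  unknown <- setdiff(sp$contig, names(genome))
  if (length(unknown))
    stop("span on unknown contig(s): ", paste(unique(unknown), collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(sp$start < 0L) || any(sp$end > lens[sp$contig]))
    stop("TE span beyond contig bounds")
  if (any(sp$end < sp$start)) stop("span end before start")

  masked <- list(); assembly_n <- list()
  out <- genome
  for (ct in names(genome)) {
    assembly_n[[ct]] <- .n_runs(genome[[ct]])
    rows <- sp$contig == ct & sp$end > sp$start
    if (any(rows)) {
      red <- .reduce_intervals(sp$start[rows], sp$end[rows])
      at <- IRanges::IRanges(start = red$start + 1L, end = red$end)
      out[[ct]] <- Biostrings::replaceAt(
        genome[[ct]], at,
        vapply(IRanges::width(at), function(w) strrep("N", w), character(1)))
      # introduced masking = spans minus pre-existing N runs
      pre <- IRanges::IRanges(start = assembly_n[[ct]]$start + 1L,
                              end = assembly_n[[ct]]$end)
      intro <- IRanges::setdiff(at, pre)
      masked[[ct]] <- list(start = IRanges::start(intro) - 1L,
                           end = IRanges::end(intro))
    } else {
      masked[[ct]] <- list(start = integer(), end = integer())
    }
  }
  structure(list(seq = out, masked = masked, assembly_n = assembly_n),
            class = "masked_genome")
}

#' Treat an already-masked genome as a `masked_genome`
#'
#' For genomes masked by an external engine where the masked intervals are
#' supplied alongside the sequence (rather than applied by
#' [mask_from_annotation()]).
#'
#' @param genome A named [Biostrings::DNAStringSet] whose masked bases are N.
#' @param masked_spans The intervals that were masked (data.frame or
#'   `GRanges`); N runs not listed here are recorded as assembly gaps.
#' @return A `masked_genome`.
#' @export
masked_genome <- function(genome, masked_spans = NULL) {
  if (is.null(masked_spans))
    masked_spans <- data.frame(contig = character(), start = integer(),
                               end = integer())
  sp <- .spans_to_df(masked_spans)
  masked <- list(); assembly_n <- list()
  for (ct in names(genome)) {
    runs <- .n_runs(genome[[ct]])
    run_ir <- IRanges::IRanges(start = runs$start + 1L, end = runs$end)
    rows <- sp$contig == ct & sp$end > sp$start
    sp_ir <- IRanges::IRanges(start = sp$start[rows] + 1L, end = sp$end[rows])
    m <- IRanges::reduce(IRanges::intersect(run_ir, sp_ir))
    a <- IRanges::setdiff(run_ir, sp_ir)
    masked[[ct]] <- list(start = IRanges::start(m) - 1L, end = IRanges::end(m))
    assembly_n[[ct]] <- list(start = IRanges::start(a) - 1L,
                             end = IRanges::end(a))
  }
  structure(list(seq = genome, masked = masked, assembly_n = assembly_n),
            class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  nm <- sum(vapply(x$masked, function(m) sum(m$end - m$start), numeric(1)))
  cat(sprintf("masked_genome: %d contig(s), %.0f masked bp\n",
              length(x$seq), nm))
  invisible(x)
}

#' Masked-aware distance between two positions
#'
#' Returns `(b - a)` minus the number of masked bases strictly inside
#' `[a, b)`. Masking introduced by [mask_from_annotation()] is subtracted;
#' assembly gaps are not. Used when joining forward and reverse insertion
#' signals so that insertions present in the (masked) reference and novel
#' insertions are measured on the same scale.
#'
#' @param masked A `masked_genome` (or `combined_reference`).
#' @param contig Contig name (recycled).
#' @param a,b Integer vectors of 0-based positions, `a <= b`.
#' @return Integer vector of masked-aware distances in bp.
#' @export
masked_distance <- function(masked, contig, a, b) {
  if (inherits(masked, "combined_reference")) masked <- masked$genome
  stopifnot(inherits(masked, "masked_genome"))
  n <- max(length(contig), length(a), length(b))
  contig <- rep_len(as.character(contig), n)
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  if (any(a > b)) stop("'a' must be <= 'b'")
  lens <- setNames(Biostrings::width(masked$seq), names(masked$seq))
  if (anyNA(lens[contig])) stop("unknown contig in masked_distance()")
  if (any(a < 0) || any(b > lens[contig])) stop("position out of contig bounds")
  out <- numeric(n)
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    m <- masked$masked[[ct]]
    if (length(m$start) == 0L) { out[i] <- b[i] - a[i]; next }
    cumw <- cumsum(m$end - m$start)
    cov <- function(x) {
      j <- findInterval(x, m$start)
      jj <- pmax(j, 1L)
      full <- c(0, cumw)[jj] + pmin(x - m$start[jj], (m$end - m$start)[jj])
      ifelse(j == 0L, 0, full)
    }
    out[i] <- (b[i] - a[i]) - (cov(b[i]) - cov(a[i]))
  }
  as.integer(out)
}

#' Build the combined reference
#'
#' Concatenates the repeat-masked genome and the length-filtered TE library
#' into one reference (genome contigs first, TE contigs after) and records
#' which contig is which. Paired-end reads mapped against this reference can
#' then anchor one mate in the unique genome and the other in a TE sequence.
#'
#' @param masked A `masked_genome`.
#' @param tes Filtered TE library ([filter_te_sequences()]).
#' @param hierarchy A [te_hierarchy()]; every TE contig must resolve to a
#'   family.
#' @param min_length Minimum TE sequence length enforced here (sequences must
#'   be pre-filtered).
#' @return An object of class `combined_reference`: list with `genome`
#'   (`masked_genome`), `te` (`DNAStringSet`) and `contig_class` (named
#'   character vector, values `"genome"`/`"TE"`).
#' @export
build_combined_reference <- function(masked, tes, hierarchy, min_length = 40) {
  stopifnot(inherits(masked, "masked_genome"), inherits(tes, "DNAStringSet"),
            inherits(hierarchy, "te_hierarchy"))
  clash <- intersect(names(masked$seq), names(tes))
  if (length(clash))
    stop("contig name collision between genome and TE library: ",
         paste(clash, collapse = ", "))
  min_applied <- attr(tes, "min_length_applied") %||% min_length
  if (any(Biostrings::width(tes) < min_applied))
    stop("TE sequence(s) shorter than ", min_applied,
         " bp present; run filter_te_sequences() first")
  te_family(hierarchy, names(tes))  # errors on unresolvable ids
  contig_class <- setNames(c(rep("genome", length(masked$seq)),
                             rep("TE", length(tes))),
                           c(names(masked$seq), names(tes)))
  structure(list(genome = masked, te = tes, contig_class = contig_class,
                 hierarchy = hierarchy),
            class = "combined_reference")
}

#' @export
print.combined_reference <- function(x, ...) {
  cat(sprintf("combined_reference: %d genome contig(s) + %d TE contig(s)\n",
              sum(x$contig_class == "genome"), sum(x$contig_class == "TE")))
  invisible(x)
}

#' Write a combined reference as FASTA plus a contig-class sidecar table
#'
#' @param ref A `combined_reference`.
#' @param fasta_path Output FASTA (genome contigs first, TE contigs after).
#' @param class_path Output tab-separated table (`contig`, `class`); default
#'   `<fasta_path>.classes.tsv`.
#' @return `fasta_path`, invisibly.
#' @export
write_combined_reference <- function(ref, fasta_path,
                                     class_path = paste0(fasta_path,
                                                         ".classes.tsv")) {
  stopifnot(inherits(ref, "combined_reference"))
  all_seq <- c(ref$genome$seq, ref$te)
  Biostrings::writeXStringSet(all_seq, fasta_path)
  write.table(data.frame(contig = names(ref$contig_class),
                         class = unname(ref$contig_class)),
              class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Lengths of all contigs in a combined reference
#'
#' @param ref A `combined_reference` or `masked_genome`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(ref) {
  if (inherits(ref, "combined_reference"))
    return(setNames(c(Biostrings::width(ref$genome$seq),
                      Biostrings::width(ref$te)),
                    c(names(ref$genome$seq), names(ref$te))))
  if (inherits(ref, "masked_genome"))
    return(setNames(Biostrings::width(ref$seq), names(ref$seq)))
  stop("unsupported object")
}
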
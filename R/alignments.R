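# Alignment I/O. Single-end alignment records are plain data.frames with
# columns qname, contig, start, end (0-based half-open, CIGAR-aware),
# strand, mapq, first (first-of-pair flag where known). Paired records use
# the same columns prefixed r1_/r2_ plus a shared qname.

.pair_cols <- function() {
  c("qname",
    paste0("r1_", c("contig", "start", "end", "strand", "mapq")),
    paste0("r2_", c("contig", "start", "end", "strand", "mapq")))
}

#' Read single-end alignment records from SAM/BAM
#'
#' SAM text is converted to BAM internally; alignments are read CIGAR-aware,
#' so `start`/`end` span the reference bases actually aligned (soft-clipped
#' bases excluded). Secondary and supplementary alignments are dropped with a
#' counter (`attr(x, "n_secondary")`); only primary alignments take part in
#' pair restoration. Unmapped records never appear (they surface as orphans
#' in [restore_pairs()], counted there).
#'
#' @param path A SAM (`.sam`) or BAM file.
#' @return data.frame with columns `qname`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `mapq`, `first`.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag_all <- Rsamtools::scanBamFlag()
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq"),
                                         flag = flag_all))
  mc <- S4Vectors::mcols(ga)
  sec <- bitwAnd(mc$flag, 0x100L) > 0L | bitwAnd(mc$flag, 0x800L) > 0L
  ga <- ga[!sec]; mc <- S4Vectors::mcols(ga)
  out <- data.frame(
    qname = mc$qname,
    contig = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    mapq = as.integer(mc$mapq),
    first = ifelse(bitwAnd(mc$flag, 0x1L) > 0L,
                   bitwAnd(mc$flag, 0x40L) > 0L, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_secondary") <- sum(sec)
  out
}

#' Write paired alignment records as SAM text
#'
#' Minimal valid SAM: one primary record per mate, CIGAR `<width>M`,
#' placeholder sequence. Coordinates are converted from the package's
#' 0-based half-open convention to SAM's 1-based convention here.
#'
#' @param pairs Paired alignment data.frame (see [restore_pairs()]).
#' @param path Output SAM path.
#' @param lengths Named integer vector of contig lengths for the `@SQ`
#'   header (e.g. [contig_lengths()]).
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, path, lengths) {
  .stopifnot_cols(pairs, .pair_cols(), "pairs")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), as.integer(lengths)))
  rec <- function(qname, contig, start, end, strand, mapq,
                  m_contig, m_start, m_strand, is_first) {
    flag <- 1L + ifelse(is_first, 64L, 128L) +
      ifelse(strand == "-", 16L, 0L) + ifelse(m_strand == "-", 32L, 0L)
    w <- end - start
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t%s\t*",
            qname, flag, contig, start + 1L, mapq, w,
            ifelse(m_contig == contig, "=", m_contig), m_start + 1L,
            strrep("N", w))
  }
  lines <- c(hdr,
             rec(pairs$qname, pairs$r1_contig, pairs$r1_start, pairs$r1_end,
                 pairs$r1_strand, pairs$r1_mapq, pairs$r2_contig,
                 pairs$r2_start, pairs$r2_strand, TRUE),
             rec(pairs$qname, pairs$r2_contig, pairs$r2_start, pairs$r2_end,
                 pairs$r2_strand, pairs$r2_mapq, pairs$r1_contig,
                 pairs$r1_start, pairs$r1_strand, FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Restore read-pair information from single-end alignment records
#'
#' Joins mates by read name (read-name suffixes `/1`, `/2` and first-of-pair
#' flags are both honoured). Reads without a mate are counted as orphans and
#' not emitted. Three or more primary records sharing one name are an error:
#' secondary/supplementary alignments must be filtered out first (they are by
#' [read_alignments()]).
#'
#' @param aln Single-end alignment data.frame ([read_alignments()]).
#' @return Paired data.frame with columns `qname`, `r1_*`, `r2_*`; attribute
#'   `n_orphans` counts mate-less reads.
#' @export
restore_pairs <- function(aln) {
  .stopifnot_cols(aln, c("qname", "contig", "start", "end", "strand", "mapq"),
                  "alignments")
  base <- sub("/[12]$", "", aln$qname)
  suffix <- ifelse(grepl("/1$", aln$qname), 1L,
                   ifelse(grepl("/2$", aln$qname), 2L, NA))
  ord <- order(base)
  aln <- aln[ord, , drop = FALSE]
  base <- base[ord]; suffix <- suffix[ord]
  cnt <- rle(base)
  if (any(cnt$lengths > 2L))
    stop("more than two primary alignment records share read name(s): ",
         paste(head(cnt$values[cnt$lengths > 2L], 5L), collapse = ", "))
  n_orphans <- sum(cnt$lengths == 1L)
  if (n_orphans > 0L)
    message(n_orphans, " orphan read(s) without a mate dropped")
  paired <- rep(cnt$lengths, cnt$lengths) == 2L
  aln <- aln[paired, , drop = FALSE]
  base <- base[paired]; suffix <- suffix[paired]
  if (nrow(aln) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 11L), .pair_cols()))
    attr(out, "n_orphans") <- n_orphans
    return(out)
  }
  i1 <- seq(1L, nrow(aln), by = 2L); i2 <- i1 + 1L
  # put the designated first-of-pair read in slot 1 where known
  is_first1 <- if (!is.null(aln$first) && !all(is.na(aln$first)))
    ifelse(is.na(aln$first[i1]), suffix[i1] %in% c(NA, 1L), aln$first[i1])
  else suffix[i1] %in% c(NA, 1L)
  swap <- !is_first1
  a <- ifelse(swap, i2, i1); b <- ifelse(swap, i1, i2)
  out <- data.frame(
    qname = base[i1],
    r1_contig = aln$contig[a], r1_start = aln$start[a], r1_end = aln$end[a],
    r1_strand = aln$strand[a], r1_mapq = aln$mapq[a],
    r2_contig = aln$contig[b], r2_start = aln$start[b], r2_end = aln$end[b],
    r2_strand = aln$strand[b], r2_mapq = aln$mapq[b],
    stringsAsFactors = FALSE)
  attr(out, "n_orphans") <- n_orphans
  out
}
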
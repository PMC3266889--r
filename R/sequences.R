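#' Read a TE sequence library from FASTA
#'
#' @param path FASTA file with one record per individual TE sequence.
#' @return A [Biostrings::DNAStringSet] with names taken from the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_te_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in TE library: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Filter a TE library by minimum sequence length
#'
#' Short TE sequences cannot host a confidently mapped read and are removed
#' before the combined reference is built (default minimum 40 bp).
#'
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param min_length Minimum retained length in bp.
#' @return The filtered `DNAStringSet`, with attribute `min_length_applied`.
#' @export
filter_te_sequences <- function(seqs, min_length = 40) {
  min_length <- .assert_scalar_int(min_length, "min_length")
  keep <- Biostrings::width(seqs) >= min_length
  if (any(!keep))
    message(sum(!keep), " TE sequence(s) shorter than ", min_length,
            " bp removed")
  out <- seqs[keep]
  attr(out, "min_length_applied") <- min_length
  out
}

#' Validate a TE library against a hierarchy
#'
#' Checks that every sequence id resolves to a family. Unresolvable ids are
#' returned (and reported) rather than silently defaulted.
#'
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param hierarchy A [te_hierarchy()].
#' @return Character vector of ids absent from the hierarchy (empty when the
#'   library is fully resolvable), invisibly.
#' @export
validate_te_library <- function(seqs, hierarchy) {
  stopifnot(inherits(hierarchy, "te_hierarchy"))
  missing <- setdiff(names(seqs), names(hierarchy$by_id))
  if (length(missing))
    warning(length(missing), " TE sequence id(s) absent from the hierarchy: ",
            paste(head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ...")
  invisible(missing)
}
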
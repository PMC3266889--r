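#' Parse a TE hierarchy table
#'
#' Reads the three-level nested TE classification (insertion id -> family ->
#' order) used to resolve any TE-mapped read to a family. The file is
#' tab-separated with columns `id`, `family`, `order` in that order; extra
#' columns are ignored and a header row is auto-detected. Rows with a missing
#' family or order are assigned `"unclassified"`.
#'
#' Families are matched case-insensitively everywhere in the package;
#' sequence ids are kept verbatim. Families listed in `ancient_families`
#' (by default INE-1, an ancient and essentially fixed family) are flagged so
#' the sweep scan can exclude them.
#'
#' @param path Path to a tab-separated hierarchy file.
#' @param ancient_families Character vector of family names (case-insensitive)
#'   flagged as ancient.
#' @return An object of class `te_hierarchy`: a list with `table` (data.frame
#'   with columns `id`, `family`, `order`, `ancient`) and derived lookup
#'   indexes.
#' @seealso [te_family()], [te_order()], [write_te_hierarchy()]
#' @export
read_te_hierarchy <- function(path, ancient_families = "INE-1") {
  raw <- tryCatch(
    read.delim(path, header = FALSE, colClasses = "character",
               stringsAsFactors = FALSE, quote = "", comment.char = "#",
               blank.lines.skip = TRUE),
    error = function(e) data.frame())
  if (nrow(raw) == 0L)
    return(te_hierarchy(data.frame(id = character(), family = character(),
                                   order = character())))
  if (ncol(raw) < 3L)
    stop("hierarchy file must have at least 3 columns: id, family, order")
  # header detection: a first row naming any of the expected columns is not data
  first <- tolower(trimws(as.character(raw[1L, 1:3])))
  if (any(first %in% c("id", "insertion", "insertion_id", "sequence_id",
                       "family", "order", "name", "te")))
    raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L)
    return(te_hierarchy(data.frame(id = character(), family = character(),
                                   order = character())))
  te_hierarchy(data.frame(id = trimws(raw[[1L]]), family = trimws(raw[[2L]]),
                          order = trimws(raw[[3L]]),
                          stringsAsFactors = FALSE),
               ancient_families = ancient_families)
}

#' Construct a TE hierarchy from a data frame
#'
#' @param table data.frame with columns `id`, `family`, `order`.
#' @inheritParams read_te_hierarchy
#' @return A `te_hierarchy` object.
#' @export
te_hierarchy <- function(table, ancient_families = "INE-1") {
  .stopifnot_cols(table, c("id", "family", "order"), "hierarchy table")
  tab <- data.frame(id = as.character(table$id),
                    family = as.character(table$family),
                    order = as.character(table$order),
                    stringsAsFactors = FALSE)
  blank_fam <- is.na(tab$family) | tab$family == ""
  blank_ord <- is.na(tab$order) | tab$order == ""
  if (any(blank_fam | blank_ord))
    message(sum(blank_fam | blank_ord),
            " hierarchy row(s) with missing family/order assigned 'unclassified'")
  tab$family[blank_fam] <- "unclassified"
  tab$order[blank_ord] <- "unclassified"
  tab <- unique(tab)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    stop("duplicate sequence id(s) with conflicting classification: ",
         paste(unique(dup), collapse = ", "))
  # each family must map to exactly one order (case-insensitive family key)
  fk <- .fam_key(tab$family)
  ord_by_fam <- tapply(tab$order, fk, function(x) length(unique(x)))
  if (any(ord_by_fam > 1L))
    stop("family mapped to more than one order: ",
         paste(names(ord_by_fam)[ord_by_fam > 1L], collapse = ", "))
  tab$ancient <- fk %in% .fam_key(ancient_families)
  fam_first <- !duplicated(fk)
  obj <- list(
    table = tab,
    by_id = setNames(tab$family, tab$id),
    order_by_family = setNames(tab$order[fam_first], fk[fam_first]),
    ancient_by_family = setNames(tab$ancient[fam_first], fk[fam_first]))
  class(obj) <- "te_hierarchy"
  obj
}

#' @export
print.te_hierarchy <- function(x, ...) {
  cat(sprintf("te_hierarchy: %d insertion ids, %d families, %d orders\n",
              nrow(x$table), length(unique(.fam_key(x$table$family))),
              length(unique(x$table$order))))
  invisible(x)
}

#' Look up the family of TE sequence ids
#'
#' @param hierarchy A `te_hierarchy`.
#' @param id Character vector of sequence ids.
#' @return Character vector of family names. Unknown ids are an error, never
#'   a silent default.
#' @export
te_family <- function(hierarchy, id) {
  stopifnot(inherits(hierarchy, "te_hierarchy"))
  fam <- unname(hierarchy$by_id[as.character(id)])
  if (anyNA(fam))
    stop("unknown TE sequence id(s): ",
         paste(unique(id[is.na(fam)]), collapse = ", "))
  fam
}

#' Look up the order of TE families
#'
#' @param hierarchy A `te_hierarchy`.
#' @param family Character vector of family names (case-insensitive).
#' @return Character vector of order names (`TIR`, `LTR`, `non-LTR`,
#'   `unclassified`). Unknown families are an error.
#' @export
te_order <- function(hierarchy, family) {
  stopifnot(inherits(hierarchy, "te_hierarchy"))
  ord <- unname(hierarchy$order_by_family[.fam_key(family)])
  if (anyNA(ord))
    stop("unknown TE family(s): ",
         paste(unique(family[is.na(ord)]), collapse = ", "))
  ord
}

#' Is a family flagged as ancient?
#'
#' @inheritParams te_order
#' @return Logical vector.
#' @export
te_is_ancient <- function(hierarchy, family) {
  stopifnot(inherits(hierarchy, "te_hierarchy"))
  anc <- unname(hierarchy$ancient_by_family[.fam_key(family)])
  anc[is.na(anc)] <- FALSE
  anc
}

#' Write a TE hierarchy back to a tab-separated file
#'
#' The written file round-trips through [read_te_hierarchy()] to an identical
#' hierarchy.
#'
#' @param hierarchy A `te_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "te_hierarchy"))
  out <- hierarchy$table[, c("id", "family", "order")]
  write.table(rbind(c("id", "family", "order"), as.matrix(out)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
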
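# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Family names are matched case-insensitively throughout (FlyBase-style
# naming is inconsistent in case); ids are kept verbatim.
.fam_key <- function(x) tolower(trimws(as.character(x)))

.assert_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    stop(sprintf("'%s' must be a single integer value", name), call. = FALSE)
  as.integer(x)
}

# Deterministic sub-seed derivation so one user seed drives several
# independent random streams without reuse. Kept below 2^31.
.derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 1664525 * k) %% 2147483647
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
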
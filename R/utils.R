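#' @keywords internal
"_PACKAGE"

# Gene symbol from a "Symbol|UniProtAccession" protein id: symbol prefix,
# first symbol wins on multi-symbol entries, uppercased.
symbol_of <- function(ids) {
  s <- sub("\\|.*$", "", ids)
  s <- sub("[;,].*$", "", s)
  toupper(trimws(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# row-wise stats ignoring NA, returning 0-length-safe vectors
row_sds <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  v[n < 2L] <- NA_real_
  sqrt(v)
}

check_abundance_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix (proteins x samples)", arg),
         call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("'%s' must carry protein row names and sample column names", arg),
         call. = FALSE)
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop(sprintf("duplicate protein ids in '%s': %s", arg,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop(sprintf("duplicate sample ids in '%s': %s", arg,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  if (any(!is.finite(x[!is.na(x)])))
    stop(sprintf("non-finite values present in '%s'", arg), call. = FALSE)
  invisible(x)
}

# deterministic per-stage seed derived from a global seed and a stage name
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}
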
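#' Two-way median-polish batch correction against pooled standards
#'
#' Removes TMT batch effects from a log2 abundance matrix by iterating a
#' two-way median polish in which the protein-wise (row) centering is
#' anchored on each batch's denominator samples -- the pooled global
#' internal standard (GIS) channels by default, or all non-GIS samples when
#' `use_all_non_gis = TRUE`.  Working in log2 space makes the polish
#' equivalent to the sample/GIS abundance-ratio formulation on the raw
#' scale.
#'
#' Each full pass (a) subtracts, per protein and batch, the median over
#' that batch's denominator samples from all of the batch's entries, then
#' (b) subtracts each sample's median over proteins.  Iteration stops when
#' the largest absolute adjustment applied in a pass falls below
#' `tolerance` or after `max_iterations` passes.  Finally the
#' pre-correction grand per-protein median is added back so corrected
#' values remain interpretable log2 abundances (fold changes are
#' unaffected).  Missing values are ignored by every median; GIS columns
#' are carried through the correction.
#'
#' @param x Log2 abundance matrix (proteins x samples), GIS columns
#'   included.
#' @param design Data frame with columns `sample`, `batch`, `is_gis`
#'   covering every column of `x`.
#' @param use_all_non_gis If `TRUE`, denominators are all non-GIS samples
#'   of the batch instead of the GIS channels.
#' @param tolerance Convergence threshold on the maximum absolute
#'   adjustment per pass (log2 units).
#' @param max_iterations Upper bound on polish passes.
#' @return A `tampor_fit` list: `corrected` matrix, `n_iterations`,
#'   `convergence_trace` (max |adjustment| per pass), `converged`,
#'   `denominators_used` (per batch), and `flagged_proteins` (all-missing
#'   within some batch's denominators; their batch term is treated as 0).
#' @export
tampor_correct <- function(x, design, use_all_non_gis = FALSE,
                           tolerance = 1e-8, max_iterations = 250L) {
  check_abundance_matrix(x)
  if (!all(colnames(x) %in% design$sample))
    stop("design does not cover samples: ",
         paste(setdiff(colnames(x), design$sample), collapse = ", "))
  design <- design[match(colnames(x), design$sample), ]
  batches <- unique(design$batch)
  denom <- lapply(batches, function(b) {
    inb <- design$batch == b
    d <- if (use_all_non_gis) which(inb & !design$is_gis) else which(inb & design$is_gis)
    if (!length(d))
      stop(sprintf("batch '%s' has no %s denominator samples", b,
                   if (use_all_non_gis) "non-GIS" else "GIS"))
    d
  })
  names(denom) <- batches
  batch_cols <- lapply(batches, function(b) which(design$batch == b))

  # grand per-protein median over the denominator samples: the pooled
  # standard is the natural abundance reference, and anchoring the add-back
  # on it makes the correction an exact fixed point (idempotence)
  denom_all <- sort(unique(unlist(denom)))
  grand_med <- apply(x[, denom_all, drop = FALSE], 1L, stats::median, na.rm = TRUE)
  grand_med[!is.finite(grand_med)] <-
    apply(x, 1L, stats::median, na.rm = TRUE)[!is.finite(grand_med)]
  work <- x - grand_med   # polish deviations; grand protein median added back at the end
  trace <- numeric(0)
  flagged <- character(0)
  for (it in seq_len(max_iterations)) {
    max_adj <- 0
    for (bi in seq_along(batches)) {
      med <- apply(work[, denom[[bi]], drop = FALSE], 1L,
                   stats::median, na.rm = TRUE)
      miss <- !is.finite(med)
      if (any(miss)) {
        flagged <- union(flagged, rownames(work)[miss])
        med[miss] <- 0
      }
      work[, batch_cols[[bi]]] <- work[, batch_cols[[bi]], drop = FALSE] - med
      max_adj <- max(max_adj, max(abs(med)))
    }
    cmed <- apply(work, 2L, stats::median, na.rm = TRUE)
    cmed[!is.finite(cmed)] <- 0
    work <- sweep(work, 2L, cmed, "-")
    max_adj <- max(max_adj, max(abs(cmed)))
    trace <- c(trace, max_adj)
    if (max_adj < tolerance) break
  }
  corrected <- work + grand_med
  res <- list(corrected = corrected,
              n_iterations = length(trace),
              convergence_trace = trace,
              converged = trace[length(trace)] < tolerance,
              denominators_used = lapply(denom, function(d) colnames(x)[d]),
              flagged_proteins = flagged,
              use_all_non_gis = use_all_non_gis,
              tolerance = tolerance)
  class(res) <- "tampor_fit"
  res
}

#' @export
print.tampor_fit <- function(x, ...) {
  cat(sprintf("TAMPOR batch correction: %d proteins x %d samples\n",
              nrow(x$corrected), ncol(x$corrected)))
  cat(sprintf("  denominators: %s; %d iteration(s), final max adjustment %.3g (%s)\n",
              if (x$use_all_non_gis) "all non-GIS" else "GIS only",
              x$n_iterations, x$convergence_trace[x$n_iterations],
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$flagged_proteins))
    cat(sprintf("  %d protein(s) had all-missing denominators in some batch\n",
                length(x$flagged_proteins)))
  invisible(x)
}
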
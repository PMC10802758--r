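#' Per-sample cell-type marker enrichment scores
#'
#' For every protein a z-score across samples is computed (missing values
#' ignored; zero-variance proteins score 0).  A sample's raw score for a
#' cell type is the mean z over that type's marker proteins; raw scores
#' are then standardized across samples so each cell type's scores have
#' cohort mean ~0 and SD ~1.  The standardization uses the median and
#' MAD (Gaussian-consistent) so that the very fractionation outliers the
#' scores are meant to expose do not mask themselves by inflating the
#' scale.  Markers are matched on the gene-symbol prefix
#' of the protein ids; cell types with fewer than `min_markers` matched
#' markers are excluded with a warning.
#'
#' @param x Abundance matrix (proteins x samples).
#' @param markers Named list of marker symbol sets (e.g. from
#'   [read_marker_gmt()]).
#' @param min_markers Minimum matched markers per cell type.
#' @return Samples x cell-types matrix of enrichment z-scores.
#' @export
score_cell_types <- function(x, markers, min_markers = 3L) {
  check_abundance_matrix(x)
  sym <- symbol_of(rownames(x))
  m <- rowMeans(x, na.rm = TRUE)
  s <- row_sds(x)
  z <- (x - m) / ifelse(!is.finite(s) | s == 0, Inf, s)  # degenerate SD -> 0
  z[!is.finite(z)] <- 0
  z[is.na(x)] <- NA
  scores <- matrix(NA_real_, ncol(x), 0, dimnames = list(colnames(x), NULL))
  for (ct in names(markers)) {
    hit <- sym %in% toupper(markers[[ct]])
    if (sum(hit) < min_markers) {
      warning(sprintf("cell type '%s' has %d matched markers (< %d); excluded",
                      ct, sum(hit), min_markers))
      next
    }
    raw <- colMeans(z[hit, , drop = FALSE], na.rm = TRUE)
    s_raw <- stats::mad(raw)
    if (!is.finite(s_raw) || s_raw == 0) s_raw <- stats::sd(raw)
    scores <- cbind(scores, if (is.finite(s_raw) && s_raw > 0)
      (raw - stats::median(raw)) / s_raw else raw * 0)
    colnames(scores)[ncol(scores)] <- ct
  }
  if (!ncol(scores)) stop("no cell type had enough matched markers")
  scores
}

#' Flag fractionation outlier samples
#'
#' A vascular preparation is flagged when it shows depleted endothelial
#' signal (`z < endothelial_floor_z`) AND elevated neuronal signal
#' (`z > neuronal_ceiling_z`), the signature of a failed vessel
#' enrichment contaminated by parenchyma.
#'
#' @param scores Samples x cell-types score matrix from
#'   [score_cell_types()].
#' @param endothelial_floor_z,neuronal_ceiling_z Thresholds.
#' @param endothelial,neuronal Score column names.
#' @return Character vector of flagged sample ids.
#' @export
flag_outliers <- function(scores, endothelial_floor_z = -2,
                          neuronal_ceiling_z = 2,
                          endothelial = "endothelial", neuronal = "neuron") {
  if (!all(c(endothelial, neuronal) %in% colnames(scores)))
    stop("scores must contain columns '", endothelial, "' and '", neuronal, "'")
  bad <- scores[, endothelial] < endothelial_floor_z &
    scores[, neuronal] > neuronal_ceiling_z
  rownames(scores)[which(bad)]
}

#' Bootstrap covariate regression with protected diagnosis effects
#'
#' Per protein, fits a linear model of log2 abundance on the nuisance
#' covariates (neuronal score, age, sex, PMI and TMT batch by default)
#' plus the protected terms (diagnosis).  The model is refit on `n_boot`
#' case-resampled bootstrap replicates and the per-term median
#' coefficient across replicates is taken.  The product of each nuisance
#' covariate with its median coefficient is subtracted from the matrix;
#' protected-term contributions are retained, so diagnosis differences
#' survive the cleanup.
#'
#' @param x Abundance matrix (proteins x samples; GIS columns excluded by
#'   the caller).
#' @param traits Data frame with a `sample` column and the modeled
#'   covariates.
#' @param scores Optional samples x cell-types matrix supplying the
#'   `neuronal` covariate (column `neuron`).
#' @param design Optional design data frame supplying `batch`.
#' @param nuisance Covariate names to subtract.
#' @param protected Covariate names modeled but never subtracted.
#' @param n_boot Bootstrap replicates (the published analysis used 1000).
#' @param seed RNG seed.
#' @return List with `corrected` matrix and `report` (a
#'   `regression_report`: per-protein median coefficients, bootstrap
#'   settings, protected terms, excluded samples).
#' @export
bootstrap_regress <- function(x, traits, scores = NULL, design = NULL,
                              nuisance = c("neuronal", "age", "sex", "PMI", "batch"),
                              protected = "diagnosis",
                              n_boot = 1000L, seed = 1L) {
  check_abundance_matrix(x)
  cov <- traits[match(colnames(x), traits$sample), , drop = FALSE]
  if (any(is.na(match(colnames(x), traits$sample))))
    stop("traits missing for samples: ",
         paste(setdiff(colnames(x), traits$sample), collapse = ", "))
  if ("neuronal" %in% nuisance) {
    if (is.null(scores) || !"neuron" %in% colnames(scores))
      stop("'neuronal' covariate requested but no neuron scores supplied")
    cov$neuronal <- scores[match(colnames(x), rownames(scores)), "neuron"]
  }
  if ("batch" %in% nuisance) {
    if (!is.null(design))
      cov$batch <- design$batch[match(colnames(x), design$sample)]
    if (is.null(cov$batch)) stop("'batch' covariate requested but not available")
  }
  terms <- c(nuisance, protected)
  missing_cov <- !stats::complete.cases(cov[, terms, drop = FALSE])
  excluded <- colnames(x)[missing_cov]
  if (length(excluded)) {
    x <- x[, !missing_cov, drop = FALSE]
    cov <- cov[!missing_cov, , drop = FALSE]
  }
  for (tm in terms)
    if (is.character(cov[[tm]])) cov[[tm]] <- factor(cov[[tm]])
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, data = cov)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  n <- ncol(x)
  # assignment of design columns to covariate terms (column 1 = intercept)
  asgn <- attr(X, "assign")
  term_of_col <- c("(Intercept)", terms)[asgn + 1L]
  set.seed(seed)
  coef_arr <- array(NA_real_, c(ncol(X), nrow(x), n_boot))
  has_na <- apply(x, 1L, anyNA)
  Yt <- t(x)
  for (b in seq_len(n_boot)) {
    idx <- if (n_boot == 1L) seq_len(n) else sample.int(n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    if (any(!has_na)) {
      fit <- stats::lm.fit(Xb, Yt[idx, !has_na, drop = FALSE])
      coef_arr[, !has_na, b] <- fit$coefficients[colnames(X), , drop = FALSE]
    }
    for (i in which(has_na)) {
      yy <- Yt[idx, i]
      ok <- !is.na(yy)
      if (sum(ok) <= ncol(X)) next
      fi <- stats::lm.fit(Xb[ok, , drop = FALSE], yy[ok])
      coef_arr[, i, b] <- fi$coefficients[colnames(X)]
    }
  }
  med_coef <- apply(coef_arr, c(1, 2), stats::median, na.rm = TRUE)
  dimnames(med_coef) <- list(colnames(X), rownames(x))
  nuis_cols <- which(term_of_col %in% nuisance)
  corrected <- x - t(X[, nuis_cols, drop = FALSE] %*%
                       med_coef[nuis_cols, , drop = FALSE])
  report <- structure(list(coefficients = t(med_coef),
                           n_boot = n_boot, seed = seed,
                           protected = protected, nuisance = nuisance,
                           excluded_samples = excluded,
                           term_of_col = term_of_col),
                      class = "regression_report")
  list(corrected = corrected, report = report)
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Bootstrap regression report: %d proteins, %d bootstrap fits\n",
              nrow(x$coefficients), x$n_boot))
  cat("  nuisance (subtracted):", paste(x$nuisance, collapse = ", "), "\n")
  cat("  protected (retained): ", paste(x$protected, collapse = ", "), "\n")
  if (length(x$excluded_samples))
    cat("  excluded samples:", paste(x$excluded_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Per-protein variance fractions attributable to each covariate
#'
#' Order-independent attribution: for each protein, the share of total
#' variance explained by every covariate term is the Shapley value of
#' that term's contribution to the model R-squared, averaged over all
#' term orderings (computed exactly over the subset lattice).  The
#' fractions plus the residual fraction sum to 1.
#'
#' @param x Abundance matrix.
#' @param traits Data frame with a `sample` column and trait columns; all
#'   non-`sample` columns become terms.
#' @param scores Optional score matrix; its `neuron` column is added as
#'   the `neuronal` term.
#' @param design Optional design data frame contributing a `batch` term.
#' @return Proteins x (terms + residual) matrix of fractions.
#' @export
variance_partition <- function(x, traits, scores = NULL, design = NULL) {
  check_abundance_matrix(x)
  cov <- traits[match(colnames(x), traits$sample), , drop = FALSE]
  cov$sample <- NULL
  if (!is.null(scores))
    cov$neuronal <- scores[match(colnames(x), rownames(scores)), "neuron"]
  if (!is.null(design))
    cov$batch <- design$batch[match(colnames(x), design$sample)]
  for (tm in names(cov))
    if (is.character(cov[[tm]])) cov[[tm]] <- factor(cov[[tm]])
  terms <- names(cov)
  nt <- length(terms)
  if (nt > 8L) stop("Shapley attribution supports at most 8 terms")
  subsets <- lapply(0:(2^nt - 1L), function(b) which(bitwAnd(b, 2^(0:(nt - 1L))) > 0))
  key <- vapply(subsets, function(s) paste(s, collapse = ","), character(1))

  design_for <- function(s) {
    if (!length(s)) return(matrix(1, ncol(x), 1))
    f <- stats::as.formula(paste("~", paste(terms[s], collapse = " + ")))
    stats::model.matrix(f, data = cov)
  }
  n <- ncol(x)
  has_na <- apply(x, 1L, anyNA)
  Yc <- t(x) - rep(colMeans(t(x), na.rm = TRUE), each = n)

  # R^2 for every subset; complete proteins vectorized, others per protein
  r2 <- matrix(NA_real_, nrow(x), length(subsets),
               dimnames = list(rownames(x), key))
  sst_all <- colSums(Yc^2, na.rm = TRUE)
  for (j in seq_along(subsets)) {
    Q <- qr.Q(qr(design_for(subsets[[j]])))
    if (any(!has_na)) {
      # columns of Yc are centered, so the intercept direction contributes 0
      proj <- crossprod(Q, Yc[, !has_na, drop = FALSE])
      r2[!has_na, j] <- colSums(proj^2) / sst_all[!has_na]
    }
    for (i in which(has_na)) {
      ok <- !is.na(Yc[, i])
      Xi <- design_for(subsets[[j]])[ok, , drop = FALSE]
      yi <- Yc[ok, i]; yi <- yi - mean(yi)
      Qi <- qr.Q(qr(Xi))
      r2[i, j] <- sum(crossprod(Qi, yi)^2) / sum(yi^2)
    }
  }
  r2[!is.finite(r2)] <- 0
  r2[r2 > 1] <- 1

  w <- function(s) factorial(s) * factorial(nt - s - 1L) / factorial(nt)
  out <- matrix(0, nrow(x), nt + 1L,
                dimnames = list(rownames(x), c(terms, "residual")))
  full_key <- paste(seq_len(nt), collapse = ",")
  for (t_i in seq_len(nt)) {
    phi <- 0
    for (j in seq_along(subsets)) {
      s <- subsets[[j]]
      if (t_i %in% s) next
      with_key <- paste(sort(c(s, t_i)), collapse = ",")
      phi <- phi + w(length(s)) * (r2[, with_key] - r2[, j])
    }
    out[, t_i] <- phi
  }
  out[, "residual"] <- 1 - r2[, full_key]
  # Shapley values sum exactly to R^2(full); tidy tiny negatives
  out[out < 0 & out > -1e-12] <- 0
  out
}
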
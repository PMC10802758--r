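#' Permutation Zsummary module preservation
#'
#' Quantifies how well modules defined in a reference (template) network
#' are preserved in a test (target) network.  For each module the
#' following statistics are computed in the test data: three density
#' statistics -- mean within-module correlation, mean within-module signed
#' adjacency, and proportion of variance explained by the module
#' eigenprotein -- and three connectivity statistics -- the correlation
#' between reference and test intramodular connectivity, between
#' reference and test kME, and between the reference and test
#' within-module correlation entries.  A permutation null replaces the
#' module with random same-size protein sets; each statistic is
#' standardized as `Z = (observed - null mean) / null SD`.  `Zdensity`
#' and `Zconnectivity` are the medians of their statistic groups and
#' `Zsummary` is their mean; the one-sided p-value is the upper normal
#' tail of `Zsummary`.
#'
#' @param ref Reference abundance matrix (proteins x samples).
#' @param labels Module labels on the reference proteins.
#' @param test Test abundance matrix; evaluated on the protein
#'   intersection with `ref`.
#' @param n_permutations Random same-size draws for the null
#'   (the published analysis used 500).
#' @param seed RNG seed.
#' @param beta Soft power for the signed adjacency statistic.
#' @param min_module_size Modules with fewer intersecting proteins are
#'   skipped with a warning.
#' @return A `module_preservation` data frame: per module the observed
#'   statistics, null means/SDs, `Zdensity`, `Zconnectivity`, `Zsummary`,
#'   one-sided `p`, and `n_permutations`.
#' @export
module_preservation <- function(ref, labels, test, n_permutations = 500L,
                                seed = 1L, beta = 9,
                                min_module_size = 3L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1 (null undefined)")
  labels <- .norm_labels(labels, rownames(ref))
  common <- intersect(rownames(ref), rownames(test))
  if (length(common) < 10L) stop("protein universes barely overlap")
  ref <- ref[common, , drop = FALSE]
  test <- test[common, , drop = FALSE]
  labels <- labels[common]

  cor_ref <- suppressWarnings(bicor_matrix(ref)); cor_ref[is.na(cor_ref)] <- 0
  cor_test <- suppressWarnings(bicor_matrix(test)); cor_test[is.na(cor_test)] <- 0
  adj_test <- signed_adjacency(cor_test, beta)

  mods <- setdiff(sort(unique(labels)), "M0")
  keep <- vapply(mods, function(m) sum(labels == m) >= min_module_size, logical(1))
  if (any(!keep))
    warning("skipping modules with < ", min_module_size, " shared proteins: ",
            paste(mods[!keep], collapse = ", "))
  mods <- mods[keep]
  if (!length(mods)) stop("no evaluable modules")

  stat_names <- c("mean_cor", "mean_adj", "pve",
                  "cor_kIM", "cor_kME", "cor_cor")
  module_stats <- function(idx) {
    cr <- cor_ref[idx, idx, drop = FALSE]
    ct <- cor_test[idx, idx, drop = FALSE]
    at <- adj_test[idx, idx, drop = FALSE]
    off <- upper.tri(ct)
    eig_t <- .set_eigen(test[idx, , drop = FALSE])
    eig_r <- .set_eigen(ref[idx, , drop = FALSE])
    kme_t <- suppressWarnings(bicor_matrix(test[idx, , drop = FALSE],
                                           matrix(eig_t$e, 1)))[, 1L]
    kme_r <- suppressWarnings(bicor_matrix(ref[idx, , drop = FALSE],
                                           matrix(eig_r$e, 1)))[, 1L]
    c(mean_cor = mean(ct[off]),
      mean_adj = mean(at[off]),
      pve = eig_t$pve,
      cor_kIM = .safe_cor(rowSums(signed_adjacency(cr, beta)), rowSums(at)),
      cor_kME = .safe_cor(kme_r, kme_t),
      cor_cor = .safe_cor(cr[off], ct[off]))
  }

  obs <- vapply(mods, function(m) module_stats(which(labels == m)),
                numeric(length(stat_names)))
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))

  set.seed(seed)
  n <- length(common)
  null_arr <- array(NA_real_, c(length(stat_names), length(mods), n_permutations),
                    dimnames = list(stat_names, mods, NULL))
  for (b in seq_len(n_permutations)) {
    for (j in seq_along(mods)) {
      idx <- sample.int(n, sizes[j])
      null_arr[, j, b] <- module_stats(idx)
    }
  }
  null_mean <- apply(null_arr, c(1, 2), mean)
  null_sd <- apply(null_arr, c(1, 2), stats::sd)
  z <- (obs - null_mean) / null_sd
  z[!is.finite(z)] <- 0
  zden <- apply(z[1:3, , drop = FALSE], 2L, stats::median)
  zcon <- apply(z[4:6, , drop = FALSE], 2L, stats::median)
  zsum <- (zden + zcon) / 2

  out <- data.frame(module = mods, size = sizes,
                    t(obs), Zdensity = zden, Zconnectivity = zcon,
                    Zsummary = zsum, p = z_to_p(zsum),
                    n_permutations = as.integer(n_permutations),
                    row.names = NULL, check.names = FALSE)
  attr(out, "null_mean") <- null_mean
  attr(out, "null_sd") <- null_sd
  class(out) <- c("module_preservation", "data.frame")
  out
}

.set_eigen <- function(sub) {
  z <- .standardize_rows(sub)
  if (nrow(z) == 1L) return(list(e = as.numeric(z), pve = 1))
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1L]
  if (stats::sd(e) > 0) e <- e / stats::sd(e)
  mc <- mean(z %*% e)
  if (is.finite(mc) && mc < 0) e <- -e
  list(e = e, pve = sv$d[1L]^2 / sum(sv$d^2))
}

.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' One-sided upper-tail standard normal probability
#'
#' `p = 1 - Phi(z)`, computed via the complementary tail at full double
#' precision so far-tail values (e.g. `z = 10`, p near 1e-23) do not
#' suffer catastrophic cancellation.
#'
#' @param z Z score(s).
#' @export
z_to_p <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Classify module preservation strength
#'
#' `Zsummary < 1.96` (p > 0.05): not preserved; `1.96 <= Zsummary <= 10`:
#' moderately preserved; `Zsummary > 10` (p < 1e-23): highly preserved.
#'
#' @param result A [module_preservation()] result (or numeric Zsummary).
#' @return Character vector of categories.
#' @export
classify_preservation <- function(result) {
  z <- if (is.data.frame(result)) result$Zsummary else result
  out <- ifelse(z < 1.96, "not preserved",
                ifelse(z > 10, "high", "moderate"))
  if (is.data.frame(result)) names(out) <- result$module
  out
}

#' @export
print.module_preservation <- function(x, ...) {
  cat(sprintf("Module preservation (%d permutations):\n", x$n_permutations[1L]))
  df <- data.frame(module = x$module, size = x$size,
                   Zsummary = round(x$Zsummary, 2),
                   category = classify_preservation(x))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
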
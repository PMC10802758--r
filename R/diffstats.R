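#' One-way ANOVA with Tukey post hoc and Bonferroni fallback
#'
#' Per protein: overall one-way ANOVA p across the diagnosis groups,
#' Tukey HSD (Tukey-Kramer for unequal group sizes) p for each pairwise
#' comparison, and -- whenever a Tukey p falls below `10^-8.5`, where the
#' studentized-range tail is evaluated imprecisely -- substitution by
#' `min(1, 3 x two-tailed unequal-variance t-test p)` (Bonferroni over
#' the three comparisons), with a flag marking the substitution.
#' Proteins lacking two non-missing values in some group, or with zero
#' within-group variance, are skipped and reported.
#'
#' @param x Abundance matrix (proteins x samples).
#' @param groups Factor/character vector of group labels per sample
#'   (CTL/AD/PSP).
#' @param fallback_threshold Tukey p below which the fallback fires.
#' @return A `diff_result` data frame: group means, log2 fold changes,
#'   overall `anova_p`, pairwise p-values, fallback flags and a
#'   `skipped` flag.
#' @export
anova_tukey <- function(x, groups, fallback_threshold = 10^-8.5) {
  check_abundance_matrix(x)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(x))
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) < 2L) stop("need at least 2 diagnosis groups")
  k <- length(lev)
  ns <- ms <- vs <- matrix(NA_real_, nrow(x), k, dimnames = list(rownames(x), lev))
  for (g in lev) {
    sub <- x[, groups == g & !is.na(groups), drop = FALSE]
    ns[, g] <- rowSums(!is.na(sub))
    ms[, g] <- rowMeans(sub, na.rm = TRUE)
    vs[, g] <- row_sds(sub)^2
  }
  skipped <- apply(ns, 1L, function(r) any(r < 2))
  N <- rowSums(ns)
  grand <- rowSums(ns * ms) / N
  ssb <- rowSums(ns * (ms - grand)^2)
  ssw <- rowSums((ns - 1) * vs)
  df1 <- k - 1L
  df2 <- N - k
  msw <- ssw / df2
  zero_var <- msw <= 0 | !is.finite(msw)
  skipped <- skipped | zero_var
  f <- (ssb / df1) / msw
  anova_p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  anova_p[skipped] <- NA_real_

  pairs <- utils::combn(lev, 2L)
  res <- data.frame(protein = rownames(x), row.names = NULL,
                    stringsAsFactors = FALSE)
  for (g in lev) res[[paste0("mean_", g)]] <- ms[, g]
  res$anova_p <- anova_p
  n_pairs <- ncol(pairs)
  for (j in seq_len(n_pairs)) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    diffm <- ms[, g2] - ms[, g1]
    se <- sqrt(msw / 2 * (1 / ns[, g1] + 1 / ns[, g2]))
    qstat <- abs(diffm) / se
    tukey_p <- stats::ptukey(qstat, k, df2, lower.tail = FALSE)
    # Welch unequal-variance t, Bonferroni x number of pairs
    tse <- sqrt(vs[, g1] / ns[, g1] + vs[, g2] / ns[, g2])
    tt <- abs(diffm) / tse
    wdf <- tse^4 / ((vs[, g1] / ns[, g1])^2 / (ns[, g1] - 1) +
                      (vs[, g2] / ns[, g2])^2 / (ns[, g2] - 1))
    welch_p <- 2 * stats::pt(tt, wdf, lower.tail = FALSE)
    fb <- !skipped & is.finite(tukey_p) & tukey_p < fallback_threshold
    p <- tukey_p
    p[fb] <- pmin(1, n_pairs * welch_p[fb])
    p[skipped] <- NA_real_
    cmp <- paste0(g2, "_vs_", g1)
    res[[paste0("log2FC_", cmp)]] <- diffm
    res[[paste0("p_", cmp)]] <- p
    res[[paste0("fallback_", cmp)]] <- fb
  }
  res$skipped <- skipped
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Module eigenprotein x trait correlations
#'
#' Biweight midcorrelation between every module eigenprotein and every
#' (numeric or 0/1-coded) trait, with the two-sided Student-t p-value
#' `t = r sqrt((n-2) / (1-r^2))`.  Ordinal neuropathology scores are
#' correlated as numeric scores.  Constant traits yield `NA` with a
#' warning.
#'
#' @param eigenproteins Modules x samples matrix.
#' @param traits Data frame with a `sample` column and trait columns;
#'   character traits with two levels are coded 0/1.
#' @return A `trait_correlation` data frame of `module`, `trait`,
#'   `bicor`, `p`, `n`.
#' @export
module_trait_correlation <- function(eigenproteins, traits) {
  tr <- traits[match(colnames(eigenproteins), traits$sample), , drop = FALSE]
  tr$sample <- NULL
  out <- list()
  for (nm in names(tr)) {
    v <- tr[[nm]]
    if (is.character(v) || is.factor(v)) {
      lv <- unique(stats::na.omit(as.character(v)))
      if (length(lv) != 2L) next
      v <- as.numeric(as.character(v) == lv[2L])
    }
    v <- as.numeric(v)
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warning("constant trait '", nm, "': correlation undefined")
      out[[nm]] <- data.frame(module = rownames(eigenproteins), trait = nm,
                              bicor = NA_real_, p = NA_real_,
                              n = sum(!is.na(v)))
      next
    }
    r <- vapply(seq_len(nrow(eigenproteins)), function(i)
      suppressWarnings(bicor(eigenproteins[i, ], v)), numeric(1))
    n <- vapply(seq_len(nrow(eigenproteins)), function(i)
      sum(is.finite(eigenproteins[i, ]) & is.finite(v)), numeric(1))
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
    out[[nm]] <- data.frame(module = rownames(eigenproteins), trait = nm,
                            bicor = r, p = p, n = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trait_correlation", "data.frame")
  res
}

#' Mean log2 vascular/bulk enrichment per protein and module
#'
#' For proteins present in both fractions, the mean over paired samples
#' of (vascular log2 - bulk log2).  Proteins detected in only one
#' fraction are flagged `"vascular"`/`"bulk"` unique.  Module-level means
#' are reported when labels are supplied.
#'
#' @param vascular,bulk Log2 abundance matrices with paired sample ids.
#' @param pairing Optional named vector mapping vascular sample ids to
#'   bulk sample ids (defaults to identical ids).
#' @param labels Optional module labels for module-level means.
#' @return List with `proteins` (protein, mean_log2_ratio, uniqueness)
#'   and, if labels given, `modules` (module, mean_log2_ratio).
#' @export
log2_enrichment <- function(vascular, bulk, pairing = NULL, labels = NULL) {
  if (is.null(pairing)) {
    shared_s <- intersect(colnames(vascular), colnames(bulk))
    pairing <- stats::setNames(shared_s, shared_s)
  }
  if (!length(pairing)) stop("no paired samples between fractions")
  v_detect <- rownames(vascular)[rowSums(!is.na(vascular)) > 0]
  b_detect <- rownames(bulk)[rowSums(!is.na(bulk)) > 0]
  all_ids <- union(v_detect, b_detect)
  uniq <- ifelse(all_ids %in% v_detect & all_ids %in% b_detect, "shared",
                 ifelse(all_ids %in% v_detect, "vascular", "bulk"))
  shared_ids <- all_ids[uniq == "shared"]
  dmat <- vascular[shared_ids, names(pairing), drop = FALSE] -
    bulk[shared_ids, pairing, drop = FALSE]
  ratio <- stats::setNames(rep(NA_real_, length(all_ids)), all_ids)
  ratio[shared_ids] <- rowMeans(dmat, na.rm = TRUE)
  proteins <- data.frame(protein = all_ids, mean_log2_ratio = as.numeric(ratio),
                         uniqueness = uniq, row.names = NULL,
                         stringsAsFactors = FALSE)
  out <- list(proteins = proteins)
  if (!is.null(labels)) {
    labels <- .norm_labels(labels)
    mm <- tapply(ratio[names(labels)[names(labels) %in% all_ids]],
                 labels[names(labels) %in% all_ids],
                 mean, na.rm = TRUE)
    out$modules <- data.frame(module = names(mm),
                              mean_log2_ratio = as.numeric(mm),
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Select supervised-clustering classifier proteins
#'
#' Proteins that are unique to the vascular fraction OR at least
#' `min_fold`-fold enriched in vasculature over bulk, AND differentially
#' abundant (pairwise p < `alpha`) in all three group comparisons.
#'
#' @param diff An [anova_tukey()] result.
#' @param enrichment The `proteins` table from [log2_enrichment()].
#' @param min_fold Fold-enrichment threshold (3 in the published
#'   analysis; compared as log2 enrichment >= log2(min_fold)).
#' @param alpha Pairwise significance threshold.
#' @return Character vector of selected protein ids.
#' @export
select_classifier_proteins <- function(diff, enrichment, min_fold = 3,
                                       alpha = 0.05) {
  pcols <- grep("^p_", names(diff), value = TRUE)
  sig <- rep(TRUE, nrow(diff))
  for (pc in pcols) sig <- sig & !is.na(diff[[pc]]) & diff[[pc]] < alpha
  en <- enrichment[match(diff$protein, enrichment$protein), ]
  eligible <- (!is.na(en$uniqueness) & en$uniqueness == "vascular") |
    (!is.na(en$mean_log2_ratio) & en$mean_log2_ratio >= log2(min_fold))
  diff$protein[sig & eligible]
}

#' Equalize TMT reporter channel totals
#'
#' Scales each channel (column) of a raw linear-scale peptide intensity
#' matrix by `max(column sums) / (its column sum)` so that, after
#' scaling, every channel's summed reporter intensity equals the
#' pre-scaling maximum.
#'
#' @param x Linear-scale peptide intensity matrix (peptides x channels).
#' @return Scaled matrix.
#' @export
normalize_reporter_channels <- function(x) {
  cs <- colSums(x, na.rm = TRUE)
  if (any(cs == 0))
    stop("zero summed intensity in channel(s): ",
         paste(colnames(x)[cs == 0] %||% which(cs == 0), collapse = ", "))
  sweep(x, 2L, max(cs) / cs, "*")
}

#' Amyloid-beta peptide ratios
#'
#' Extracts the C-terminal tryptic reporter peptides of Abeta40
#' (`GAIIGLMVGGVV`) and Abeta42 (`GAIIGLMVGGVVIA`) by exact row-id match
#' from batch-corrected log2 peptide matrices and returns per-sample
#' log2(Abeta40/Abeta42) in each fraction plus the per-peptide
#' log2(vascular/bulk) ratios over paired samples.
#'
#' @param vascular,bulk Log2 peptide matrices with the two peptide
#'   sequences among their row ids.
#' @param pairing Optional vascular-to-bulk sample id map.
#' @return List with `ab40_ab42` (per fraction) and `vascular_over_bulk`
#'   (per peptide).
#' @export
abeta_ratios <- function(vascular, bulk, pairing = NULL) {
  pep40 <- "GAIIGLMVGGVV"; pep42 <- "GAIIGLMVGGVVIA"
  for (m in list(vascular = vascular, bulk = bulk))
    for (pep in c(pep40, pep42))
      if (!pep %in% rownames(m))
        stop("peptide row '", pep, "' not found in matrix")
  if (is.null(pairing)) {
    shared <- intersect(colnames(vascular), colnames(bulk))
    pairing <- stats::setNames(shared, shared)
  }
  list(
    ab40_ab42 = list(
      vascular = vascular[pep40, ] - vascular[pep42, ],
      bulk = bulk[pep40, ] - bulk[pep42, ]),
    vascular_over_bulk = rbind(
      Abeta40 = vascular[pep40, names(pairing)] - bulk[pep40, pairing],
      Abeta42 = vascular[pep42, names(pairing)] - bulk[pep42, pairing]))
}
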
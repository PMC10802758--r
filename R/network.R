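#' Network construction parameters
#'
#' Bundles the signed co-expression network settings.  Defaults are the
#' published vascular-network build: soft power 9, deep split 4, minimum
#' module size 20, merge cut height 0.07, mean-denominator TOM, signed
#' adjacency from biweight midcorrelation, PAM staging respecting the
#' dendrogram, and iterative kME reassignment with assignment threshold
#' 0.30, maximum kME gap 0.10, and at most 30 iterations.
#'
#' @param soft_power Soft-thresholding exponent (beta >= 1).
#' @param deep_split Branch-splitting sensitivity, 0 (coarse) to 4
#'   (most aggressive).
#' @param min_module_size Smallest allowed module.
#' @param merge_cut_height Eigenprotein dissimilarity (1 - cor) below
#'   which modules are merged.
#' @param tom_denominator `"mean"` or `"min"` TOM normalization.
#' @param pam_stage Run the medoid-style assignment of leftover proteins.
#' @param pam_respects_dendro Restrict PAM candidates to
#'   dendrogram-adjacent modules.
#' @param kme_assign_min kME above which membership must be assigned.
#' @param kme_max_gap Largest tolerated gap to the best module's kME.
#' @param reassign_max_iter Iteration cap for kME reassignment.
#' @return A `network_params` list.
#' @export
network_params <- function(soft_power = 9, deep_split = 4,
                           min_module_size = 20L, merge_cut_height = 0.07,
                           tom_denominator = c("mean", "min"),
                           pam_stage = TRUE, pam_respects_dendro = TRUE,
                           kme_assign_min = 0.30, kme_max_gap = 0.10,
                           reassign_max_iter = 30L) {
  stopifnot(soft_power >= 1, merge_cut_height > 0, merge_cut_height < 1,
            kme_assign_min >= 0, kme_assign_min <= 1,
            kme_max_gap >= 0, kme_max_gap <= 1,
            deep_split %in% 0:4)
  p <- list(soft_power = soft_power, deep_split = deep_split,
            min_module_size = as.integer(min_module_size),
            merge_cut_height = merge_cut_height,
            tom_denominator = match.arg(tom_denominator),
            pam_stage = pam_stage, pam_respects_dendro = pam_respects_dendro,
            kme_assign_min = kme_assign_min, kme_max_gap = kme_max_gap,
            reassign_max_iter = as.integer(reassign_max_iter))
  class(p) <- "network_params"
  p
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ beta`; the diagonal is set to 0 so
#' connectivity sums exclude self-edges.
#'
#' @param cor_mat Correlation matrix with entries in `[-1, 1]`.
#' @param beta Soft-thresholding power.
#' @export
signed_adjacency <- function(cor_mat, beta = 9) {
  if (any(abs(cor_mat) > 1 + 1e-8, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' Mean-denominator TOM: with `k_i = sum_u a_iu` and
#' `L_ij = sum_{u != i,j} a_iu a_uj`,
#' `TOM_ij = (L_ij + a_ij) / ((k_i + k_j)/2 + 1 - a_ij)` (for the `"min"`
#' denominator, `min(k_i, k_j)` replaces the mean).  `TOM_ii = 1`.
#'
#' @param a Symmetric adjacency with zero diagonal, entries in `[0, 1]`.
#' @param denominator `"mean"` or `"min"`.
#' @export
tom_similarity <- function(a, denominator = c("mean", "min")) {
  denominator <- match.arg(denominator)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have zero diagonal")
  k <- colSums(a)
  l <- a %*% a            # zero diagonal makes u = i, j terms vanish
  den <- if (denominator == "mean") outer(k, k, function(x, y) (x + y) / 2)
         else outer(k, k, pmin)
  tom <- (l + a) / (den + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Average-linkage clustering of a dissimilarity matrix
#'
#' Thin wrapper around [stats::hclust()] (UPGMA) on `1 - TOM`-style
#' dissimilarities; ties are broken deterministically by lowest merge
#' index.
#'
#' @param diss Symmetric dissimilarity matrix with zero diagonal.
#' @return An `hclust` tree.
#' @export
cluster_dendrogram <- function(diss) {
  if (any(!is.finite(diss))) stop("non-finite dissimilarities")
  if (!isSymmetric(unname(diss), tol = 1e-10)) stop("dissimilarity must be symmetric")
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Adaptive dendrogram cut with minimum module size and PAM stage
#'
#' Dynamic-hybrid-style branch cutting: the tree is cut at an adaptive
#' height `h = h_min + q (h_max - h_min)` over the merge-height range,
#' where the fraction `q` is indexed by `deep_split` (presets 0.99, 0.97, 0.95,
#' 0.93, 0.91 from coarse to most aggressive; deeper splits cut lower and
#' so resolve more, finer branches).  Branches
#' smaller than `min_module_size` are left unassigned (label 0).  The PAM
#' stage then assigns each unassigned object to the cluster with smallest
#' average dissimilarity, provided that average is below the cut height;
#' when `pam_respects_dendro` is set, candidate clusters are restricted to
#' those in the smallest enclosing dendrogram branch that contains any
#' assigned cluster.
#'
#' @param tree `hclust` tree from [cluster_dendrogram()].
#' @param diss The dissimilarity matrix the tree was built from.
#' @param params A [network_params()] list.
#' @return Integer labels (0 = unassigned), named by object.
#' @export
dynamic_hybrid_cut <- function(tree, diss, params = network_params()) {
  n <- length(tree$order)
  presets <- c(0.99, 0.97, 0.95, 0.93, 0.91)
  q <- presets[params$deep_split + 1L]
  hmin <- min(tree$height); hmax <- max(tree$height)
  cut_h <- hmin + q * (hmax - hmin)
  raw <- stats::cutree(tree, h = cut_h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= params$min_module_size])
  labels <- ifelse(raw %in% keep, match(raw, keep), 0L)
  names(labels) <- tree$labels %||% as.character(seq_len(n))

  if (params$pam_stage && any(labels == 0L) && any(labels > 0L)) {
    members <- lapply(sort(unique(labels[labels > 0L])),
                      function(m) which(labels == m))
    subtrees <- if (params$pam_respects_dendro) .subtree_members(tree) else NULL
    for (i in which(labels == 0L)) {
      cand <- seq_along(members)
      if (params$pam_respects_dendro) {
        cand <- .dendro_adjacent_modules(i, labels, tree, subtrees)
        if (!length(cand)) next
      }
      avg <- vapply(cand, function(m) mean(diss[i, members[[m]]]), numeric(1))
      best <- cand[which.min(avg)]
      if (min(avg) < cut_h) labels[i] <- best
    }
  }
  labels
}

# leaves under each internal node of an hclust tree
.subtree_members <- function(tree) {
  n <- nrow(tree$merge) + 1L
  out <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[k, ]
    get <- function(j) if (j < 0) -j else out[[j]]
    out[[k]] <- c(get(kids[1L]), get(kids[2L]))
  }
  out
}

# walk up from leaf i to the smallest enclosing branch containing an
# assigned module; returns the module indices present there
.dendro_adjacent_modules <- function(i, labels, tree, subtrees) {
  parent <- integer(nrow(tree$merge))
  leaf_parent <- integer(length(labels))
  for (k in seq_len(nrow(tree$merge))) {
    for (j in tree$merge[k, ]) {
      if (j < 0) leaf_parent[-j] <- k else parent[j] <- k
    }
  }
  node <- leaf_parent[i]
  while (node > 0L) {
    mods <- unique(labels[subtrees[[node]]])
    mods <- mods[mods > 0L]
    if (length(mods)) return(sort(mods))
    node <- parent[node]
  }
  integer(0)
}

#' Module eigenproteins and proportion of variance explained
#'
#' Per module, member rows are standardized (mean 0, SD 1 across samples;
#' missing cells are mean-imputed for this computation only) and the
#' eigenprotein is the first principal-component score vector over
#' samples, scaled to unit variance and sign-aligned so the average
#' member correlation with it is positive.  Proportion of variance
#' explained is the leading eigenvalue over the total.
#'
#' @param x Abundance matrix (proteins x samples).
#' @param labels Module labels per protein (character `"M1"`... or
#'   integer; 0/"M0" = unassigned, skipped).
#' @return List with `eigenproteins` (modules x samples), `pve` (named
#'   numeric) and `singleton` flags.
#' @export
module_eigenproteins <- function(x, labels) {
  labels <- .norm_labels(labels, rownames(x))
  mods <- setdiff(sort(unique(labels)), "M0")
  if (!length(mods)) stop("no assigned modules")
  eig <- matrix(NA_real_, length(mods), ncol(x),
                dimnames = list(mods, colnames(x)))
  pve <- stats::setNames(numeric(length(mods)), mods)
  singleton <- stats::setNames(logical(length(mods)), mods)
  for (m in mods) {
    sub <- x[labels == m, , drop = FALSE]
    z <- .standardize_rows(sub)
    if (nrow(z) == 1L) {
      e <- as.numeric(z); pve[m] <- 1; singleton[m] <- TRUE
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      e <- sv$v[, 1L]
      pve[m] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    if (stats::sd(e) > 0) e <- e / stats::sd(e)
    mc <- mean(apply(z, 1L, function(r) suppressWarnings(stats::cor(r, e))),
               na.rm = TRUE)
    if (is.finite(mc) && mc < 0) e <- -e
    eig[m, ] <- e
  }
  list(eigenproteins = eig, pve = pve, singleton = singleton)
}

.standardize_rows <- function(x) {
  m <- rowMeans(x, na.rm = TRUE)
  s <- row_sds(x)
  s[!is.finite(s) | s == 0] <- 1
  z <- (x - m) / s
  z[!is.finite(z)] <- 0   # mean imputation after standardization
  z
}

.norm_labels <- function(labels, ids = NULL) {
  if (is.numeric(labels)) labels <- paste0("M", labels)
  labels <- as.character(labels)
  if (!is.null(ids) && is.null(names(labels))) names(labels) <- ids
  labels
}

# rename labels M1..Mk by decreasing member count (ties by old label order)
.rank_labels <- function(labels) {
  assigned <- labels[labels != "M0"]
  if (!length(assigned)) return(labels)
  sizes <- sort(table(assigned), decreasing = TRUE)
  map <- stats::setNames(paste0("M", seq_along(sizes)), names(sizes))
  out <- ifelse(labels == "M0", "M0", map[labels])
  stats::setNames(out, names(labels))
}

#' Merge modules with highly correlated eigenproteins
#'
#' Iteratively clusters eigenproteins by `1 - cor`, merges every group
#' below `merge_cut_height`, recomputes eigenproteins, and repeats until
#' no eigenprotein dissimilarity falls below the threshold.
#'
#' @param x Abundance matrix.
#' @param labels Module labels.
#' @param merge_cut_height Dissimilarity threshold (default 0.07).
#' @return Merged labels, renamed `M1..Mk` by decreasing size.
#' @export
merge_close_modules <- function(x, labels, merge_cut_height = 0.07) {
  labels <- .norm_labels(labels, rownames(x))
  repeat {
    mods <- setdiff(sort(unique(labels)), "M0")
    if (length(mods) < 2L) break
    eig <- module_eigenproteins(x, labels)$eigenproteins
    d <- 1 - stats::cor(t(eig))
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(tree, h = merge_cut_height)
    if (max(table(grp)) == 1L) break
    map <- stats::setNames(paste0("G", grp), rownames(eig))
    labels <- ifelse(labels == "M0", "M0", map[labels])
  }
  .rank_labels(.norm_labels(labels, rownames(x)))
}

#' kME table: module membership strength
#'
#' `kME[p, m]` is the biweight midcorrelation between protein `p`'s
#' profile and module `m`'s eigenprotein (pairwise-complete).
#'
#' @param x Abundance matrix.
#' @param eigenproteins Modules x samples matrix.
#' @return Proteins x modules kME matrix.
#' @export
kme_table <- function(x, eigenproteins) {
  bicor_matrix(x, eigenproteins)
}

#' Iterative kME-based module reassignment
#'
#' Repeats (at most `reassign_max_iter` times): recompute eigenproteins
#' and kME, then for every protein (1) unassign to M0 if all kME fall
#' below `kme_assign_min`; (2) assign an unassigned protein to its
#' best-kME module if that kME exceeds `kme_assign_min`; (3) move a
#' protein whose current-module kME trails the best module's kME by more
#' than `kme_max_gap` to that best module.  Stops at the first iteration
#' that changes no label.  Final labels are renamed `M1..Mk` by
#' decreasing size.
#'
#' @param x Abundance matrix.
#' @param labels Starting labels (from [merge_close_modules()]).
#' @param params A [network_params()] list.
#' @return A `module_partition` object.
#' @export
iterative_reassignment <- function(x, labels, params = network_params()) {
  labels <- .norm_labels(labels, rownames(x))
  converged <- FALSE
  it <- 0L
  eig <- NULL; kme <- NULL
  while (it < params$reassign_max_iter) {
    it <- it + 1L
    if (!any(labels != "M0")) break
    eig <- module_eigenproteins(x, labels)
    kme <- suppressWarnings(kme_table(x, eig$eigenproteins))
    mods <- rownames(eig$eigenproteins)
    best <- max.col(replace(kme, is.na(kme), -Inf), ties.method = "first")
    best_kme <- kme[cbind(seq_len(nrow(kme)), best)]
    best_mod <- mods[best]
    new_labels <- labels
    all_low <- apply(kme, 1L, function(r) all(is.na(r) | r < params$kme_assign_min))
    new_labels[all_low] <- "M0"
    idx_un <- !all_low & labels == "M0" & best_kme > params$kme_assign_min
    new_labels[idx_un] <- best_mod[idx_un]
    cur_kme <- rep(NA_real_, nrow(kme))
    has <- labels %in% mods
    cur_kme[has] <- kme[cbind(which(has), match(labels[has], mods))]
    idx_mv <- !all_low & has &
      (best_kme - ifelse(is.na(cur_kme), -Inf, cur_kme)) > params$kme_max_gap
    new_labels[idx_mv] <- best_mod[idx_mv]
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
  }
  labels <- .rank_labels(labels)
  if (any(labels != "M0")) {
    eig <- module_eigenproteins(x, labels)
    kme <- suppressWarnings(kme_table(x, eig$eigenproteins))
  }
  structure(list(labels = labels,
                 eigenproteins = if (is.null(eig)) NULL else eig$eigenproteins,
                 pve = if (is.null(eig)) NULL else eig$pve,
                 kme = kme,
                 n_iterations = it,
                 converged = converged,
                 params = params),
            class = "module_partition")
}

#' Build the signed co-expression network and its module partition
#'
#' Orchestrates, in a single block: biweight midcorrelation of all protein
#' pairs, signed soft-thresholded adjacency, mean-denominator topological
#' overlap, average-linkage clustering of `1 - TOM`, adaptive branch
#' cutting with a minimum module size and PAM stage, eigenprotein-based
#' module merging, and iterative kME reassignment.
#'
#' @param x Filtered, batch-corrected, regressed log2 abundance matrix
#'   (proteins x samples).
#' @param params A [network_params()] list.
#' @return A `module_partition` with labels, eigenproteins, kME table,
#'   proportion of variance explained, reassignment iteration count, and
#'   the parameters used.
#' @export
build_network <- function(x, params = network_params()) {
  check_abundance_matrix(x)
  cor_mat <- suppressWarnings(bicor_matrix(x))
  cor_mat[is.na(cor_mat)] <- 0
  a <- signed_adjacency(cor_mat, params$soft_power)
  tom <- tom_similarity(a, params$tom_denominator)
  diss <- 1 - tom
  tree <- cluster_dendrogram(diss)
  labels0 <- dynamic_hybrid_cut(tree, diss, params)
  if (!any(labels0 > 0L)) {
    return(structure(list(labels = stats::setNames(rep("M0", nrow(x)), rownames(x)),
                          eigenproteins = NULL, pve = NULL, kme = NULL,
                          n_iterations = 0L, converged = TRUE, params = params),
                     class = "module_partition"))
  }
  merged <- merge_close_modules(x, labels0, params$merge_cut_height)
  part <- iterative_reassignment(x, merged, params)
  part$dendrogram <- tree
  part
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- module_sizes(x)
  cat(sprintf("Co-expression module partition: %d proteins, %d modules, %d unassigned\n",
              length(x$labels), length(sizes), sum(x$labels == "M0")))
  if (length(sizes))
    cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "), "\n")
  cat(sprintf("  kME reassignment: %d iteration(s), converged: %s\n",
              x$n_iterations, x$converged))
  invisible(x)
}

#' @export
summary.module_partition <- function(object, ...) {
  sizes <- module_sizes(object)
  data.frame(module = names(sizes), size = as.integer(sizes),
             pve = as.numeric(object$pve[names(sizes)]),
             row.names = NULL)
}

#' Module sizes in rank order
#' @param partition A `module_partition`.
#' @export
module_sizes <- function(partition) {
  tab <- table(partition$labels[partition$labels != "M0"])
  if (!length(tab)) return(integer(0))
  tab[order(as.integer(sub("M", "", names(tab))))]
}

#' Adjusted Rand index between two labelings
#'
#' Used to compare recovered module labels with planted truth; unassigned
#' proteins can be excluded by subsetting beforehand.
#'
#' @param a,b Label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
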
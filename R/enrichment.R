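#' One-tailed Fisher overrepresentation of category sets in modules
#'
#' For every (module, category) pair a 2x2 table is built on the stated
#' background universe and the one-tailed (greater) hypergeometric
#' p-value is computed, with the odds ratio Haldane-corrected (+0.5 per
#' cell) whenever any cell is zero.  Benjamini-Hochberg FDR is adjusted
#' across all rows of the call.
#'
#' @param module_sets Named list of module member ids (or a
#'   `module_partition`, whose labels are converted with gene symbols).
#' @param category_sets Named list of category member ids.
#' @param background Character vector: the background universe (e.g. all
#'   network proteins).
#' @param alternative Only `"greater"` (overrepresentation) is
#'   implemented.
#' @return An `enrichment_table` data frame: module, category, overlap,
#'   module_size, category_size, background_size, odds_ratio, p, fdr.
#' @export
fisher_set_enrichment <- function(module_sets, category_sets, background,
                                  alternative = "greater") {
  stopifnot(alternative == "greater")
  if (!length(background)) stop("empty background universe")
  background <- unique(background)
  if (inherits(module_sets, "module_partition"))
    module_sets <- partition_gene_sets(module_sets)
  module_sets <- lapply(module_sets, function(s) intersect(unique(s), background))
  category_sets <- lapply(category_sets, function(s) intersect(unique(s), background))
  N <- length(background)
  rows <- list()
  for (m in names(module_sets)) {
    for (ct in names(category_sets)) {
      a <- length(intersect(module_sets[[m]], category_sets[[ct]]))
      ms <- length(module_sets[[m]])
      cs <- length(category_sets[[ct]])
      p <- stats::phyper(a - 1L, cs, N - cs, ms, lower.tail = FALSE)
      b <- ms - a; cc <- cs - a; d <- N - ms - cs + a
      if (min(a, b, cc, d) == 0) {
        or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      } else {
        or <- (a * d) / (b * cc)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, category = ct, overlap = a,
                   module_size = ms, category_size = cs,
                   background_size = N, odds_ratio = or, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Gene sets per module from a partition
#'
#' Module member protein ids mapped to uppercase gene symbols (one count
#' per gene); the unassigned M0 proteins are excluded.
#'
#' @param partition A `module_partition`.
#' @export
partition_gene_sets <- function(partition) {
  labels <- partition$labels
  mods <- setdiff(sort(unique(labels)), "M0")
  sets <- lapply(mods, function(m) unique(symbol_of(names(labels)[labels == m])))
  stats::setNames(sets, mods)
}

#' Permutation enrichment of GWAS risk genes in modules
#'
#' Gene-level p-values from one or more studies are combined into an
#' ensemble score (per gene, the mean of -log10 p over the studies in
#' which the gene appears).  A module's observed score is the mean
#' -log10 ensemble p over its member genes with ensemble p below
#' `nominal_cut`, normalized by module size (non-significant members
#' contribute zero, so the score measures the module's net nominal risk
#' burden, not just the strength of its single best gene); modules with
#' no such genes get NES 0 and are reported non-enriched.  The null
#' re-scores random same-size gene sets drawn from the network
#' background; `NES = (observed - null mean)/null SD`.
#' Permutation FDR compares each observed NES against the pooled
#' standardized null NES distribution, BH-adjusted across modules.
#'
#' @param partition A `module_partition` (or named list of gene sets).
#' @param p_tables List of `data.frame`s with columns `GENE`, `P` (one
#'   per study).
#' @param nominal_cut Nominal significance threshold for contributing
#'   genes.
#' @param n_perm Permutations (the published analysis used 10,000).
#' @param seed RNG seed.
#' @return A `gwas_enrichment` data frame: module, n_genes,
#'   n_contributing, observed score, null mean/SD, NES, permutation
#'   p/FDR, flags at 5 and 10 percent FDR, plus a `contributing`
#'   attribute listing genes per module.
#' @export
gwas_permutation_enrichment <- function(partition, p_tables,
                                        nominal_cut = 0.05,
                                        n_perm = 10000L, seed = 1L) {
  if (!length(p_tables)) stop("at least one gene-level study table required")
  if (is.data.frame(p_tables)) p_tables <- list(p_tables)
  sets <- if (inherits(partition, "module_partition"))
    partition_gene_sets(partition) else partition

  # ensemble: per gene, mean -log10 p over the studies containing it
  tab <- list()
  for (st in p_tables) {
    st$GENE <- toupper(st$GENE)
    tab[[length(tab) + 1L]] <- st
  }
  all_genes <- unique(unlist(lapply(tab, `[[`, "GENE")))
  acc <- stats::setNames(numeric(length(all_genes)), all_genes)
  cnt <- stats::setNames(integer(length(all_genes)), all_genes)
  for (st in tab) {
    v <- -log10(pmax(st$P, .Machine$double.xmin))
    acc[st$GENE] <- acc[st$GENE] + v
    cnt[st$GENE] <- cnt[st$GENE] + 1L
  }
  ens_nlp <- acc / cnt                     # ensemble -log10 p
  network_genes <- unique(unlist(sets))
  bg <- intersect(network_genes, all_genes)
  if (!length(bg)) stop("no network genes found in the study tables")
  nlp <- ens_nlp[bg]
  hit <- nlp > -log10(nominal_cut)

  score_of <- function(idx) {
    h <- idx[hit[idx]]
    if (!length(h)) 0 else sum(nlp[h]) / length(idx)
  }
  mods <- names(sets)
  mem_idx <- lapply(sets, function(s) which(bg %in% s))
  obs <- vapply(mem_idx, score_of, numeric(1))
  sizes <- lengths(mem_idx)

  set.seed(seed)
  nullm <- matrix(NA_real_, n_perm, length(mods), dimnames = list(NULL, mods))
  nbg <- length(bg)
  for (b in seq_len(n_perm))
    for (j in seq_along(mods))
      nullm[b, j] <- score_of(sample.int(nbg, sizes[j]))
  mu <- colMeans(nullm)
  sdv <- apply(nullm, 2L, stats::sd)
  nes <- (obs - mu) / sdv
  nes[!is.finite(nes)] <- 0
  nes[obs == 0] <- 0
  null_nes <- sweep(sweep(nullm, 2L, mu, "-"), 2L, sdv, "/")
  null_nes <- null_nes[is.finite(null_nes)]
  perm_p <- vapply(nes, function(z)
    (1 + sum(null_nes >= z)) / (1 + length(null_nes)), numeric(1))
  perm_p[obs == 0] <- 1
  fdr <- stats::p.adjust(perm_p, method = "BH")
  contributing <- lapply(mem_idx, function(idx) bg[idx][hit[idx]])
  out <- data.frame(module = mods, n_genes = as.integer(sizes),
                    n_contributing = vapply(contributing, length, integer(1)),
                    observed = obs, null_mean = mu, null_sd = sdv,
                    NES = nes, perm_p = perm_p, fdr = fdr,
                    significant_fdr05 = fdr < 0.05 & obs > 0,
                    significant_fdr10 = fdr < 0.10 & obs > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contributing") <- contributing
  attr(out, "seed") <- seed
  class(out) <- c("gwas_enrichment", "data.frame")
  out
}

#' Module overlap with biofluid differential-abundance sets
#'
#' Builds biofluid category sets -- all detected fluid proteins, those
#' significantly increased (p < `alpha`, log2FC > 0) and significantly
#' decreased -- and tests each against every module by one-tailed Fisher
#' exact test on the full network background.
#'
#' @param partition A `module_partition` (or named gene-set list).
#' @param fluid_tables Named list of biofluid DE `data.frame`s
#'   (`protein`, `log2FC`, `p`).
#' @param direction `"all"`, `"increased"`, `"decreased"`, or several.
#' @param alpha Significance threshold defining the directional sets.
#' @param background Background universe; defaults to all network gene
#'   symbols.
#' @return An `enrichment_table` (empty-category combinations are
#'   reported in the `untestable` attribute).
#' @export
biofluid_overlap <- function(partition, fluid_tables,
                             direction = c("all", "increased", "decreased"),
                             alpha = 0.05, background = NULL) {
  direction <- match.arg(direction, several.ok = TRUE)
  sets <- if (inherits(partition, "module_partition"))
    partition_gene_sets(partition) else partition
  if (is.null(background)) background <- unique(unlist(sets))
  if (is.data.frame(fluid_tables)) fluid_tables <- list(fluid = fluid_tables)
  cats <- list()
  untestable <- character(0)
  for (nm in names(fluid_tables)) {
    ft <- fluid_tables[[nm]]
    ft$protein <- toupper(ft$protein)
    pool <- list(
      all = ft$protein,
      increased = ft$protein[ft$p < alpha & ft$log2FC > 0],
      decreased = ft$protein[ft$p < alpha & ft$log2FC < 0])
    for (d in direction) {
      s <- intersect(unique(pool[[d]]), background)
      lab <- paste(nm, d, sep = ".")
      if (!length(s)) untestable <- c(untestable, lab) else cats[[lab]] <- s
    }
  }
  if (!length(cats))
    stop("no testable biofluid categories (", paste(untestable, collapse = ", "), ")")
  out <- fisher_set_enrichment(sets, cats, background)
  attr(out, "untestable") <- untestable
  out
}

#' Partition two id universes into unique and shared sets
#'
#' @param a,b Character vectors of ids (after symbol normalization).
#' @return List with counts `n_unique_a`, `n_unique_b`, `n_shared` and
#'   the corresponding id vectors.
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- intersect(a, b)
  list(n_unique_a = length(setdiff(a, b)),
       n_unique_b = length(setdiff(b, a)),
       n_shared = length(shared),
       unique_a = setdiff(a, b),
       unique_b = setdiff(b, a),
       shared = shared)
}
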
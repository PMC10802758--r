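#' Configuration for the synthetic TMT cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a
#' three-group (CTL/AD/PSP) multi-batch TMT experiment with pooled global
#' internal standard (GIS) channels, paired vascular and bulk fractions,
#' planted co-expression modules, nuisance covariate effects, diagnosis
#' effects on selected modules, per-protein vascular enrichment, cell-type
#' marker identities, GWAS risk signal and biofluid concordance.
#'
#' Default scale is 1,000 proteins x 60 samples (20 per group) x 3 batches
#' with 8 planted modules at within-module correlation 0.6 -- small enough
#' for routine testing while keeping the shape of a real four-batch,
#' 62-sample TMT study.
#'
#' @param n_proteins Total proteins simulated.
#' @param n_samples_per_group Samples per diagnosis group (CTL, AD, PSP).
#' @param n_batches Number of TMT batches.
#' @param gis_per_batch Pooled-standard channels per batch.
#' @param module_sizes Planted module sizes (largest first); their sum must
#'   not exceed `n_proteins`.  Remaining proteins are unstructured noise.
#' @param within_module_cor Mean pairwise correlation planted between
#'   members of the same module, in (0, 1).
#' @param loading_spread Relative spread of per-protein factor loadings
#'   around `sqrt(within_module_cor)`, giving modules hub structure
#'   (heterogeneous kME); 0 makes all members equivalent.
#' @param batch_offsets Per-batch additive log2 shifts, recycled to
#'   `n_batches`.
#' @param covariate_effects Named numeric vector of nuisance slopes on the
#'   log2 scale per unit of covariate (`age` in years, `sex` 0/1, `PMI`
#'   hours).
#' @param covariate_affected_fraction Fraction of proteins carrying each
#'   covariate effect.
#' @param disease_effects Named list mapping module labels to named log2
#'   shifts per diagnosis group, e.g. `list(M1 = c(AD = 0.5))`.
#' @param vascular_enrichment Optional per-protein log2 vascular/bulk
#'   shift (length `n_proteins`); `NULL` draws module-graded defaults.
#' @param marker_assignment Named character vector mapping cell-type names
#'   to module labels (9 brain/vascular cell types by default).
#' @param n_markers_per_type Markers recorded per cell type.
#' @param gwas_enriched_modules Module labels whose genes carry planted
#'   GWAS risk signal.
#' @param missing_rate Fraction of entries made missing.
#' @param missingness_mode `"mcar"` (default) or `"intensity"` for a
#'   low-abundance-biased mechanism.
#' @param gis_noise_sd SD (log2) of the GIS channel around its batch mean.
#' @param residual_sd Per-protein biological + technical SD on the log2
#'   scale (splits into shared module factor and independent noise).
#' @param baseline_mean,baseline_sd Distribution of per-protein baseline
#'   log2 abundance.
#' @param n_unique_vascular,n_unique_bulk Proteins detected in only one
#'   fraction (entirely missing in the other).
#' @param n_contaminated_samples Vascular samples planted as fractionation
#'   outliers (neuron-module up, endothelial-module down).
#' @param contamination_shift Log2 shift applied to marker modules in
#'   contaminated samples.
#' @param seed Integer RNG seed; the cohort is fully reproducible from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_proteins = 1000L,
                             n_samples_per_group = 20L,
                             n_batches = 3L,
                             gis_per_batch = 1L,
                             module_sizes = c(120L, 100L, 90L, 80L, 70L, 60L, 50L, 40L),
                             within_module_cor = 0.6,
                             loading_spread = 0.25,
                             batch_offsets = c(1, -1, 0),
                             covariate_effects = c(age = 0.02, sex = 0.10, PMI = 0.01),
                             covariate_affected_fraction = 0.3,
                             disease_effects = list(M2 = c(AD = 0.5),
                                                    M8 = c(AD = 0.5),
                                                    M4 = c(AD = -0.5),
                                                    M6 = c(AD = -0.5),
                                                    M3 = c(PSP = 0.4),
                                                    M5 = c(PSP = -0.4)),
                             vascular_enrichment = NULL,
                             marker_assignment = c(endothelial = "M1",
                                                   pericyte = "M2",
                                                   SMC = "M3",
                                                   fibroblast = "M4",
                                                   astrocyte = "M5",
                                                   "microglia/macrophage" = "M6",
                                                   neuron = "M7",
                                                   oligodendrocyte = "M8",
                                                   OPC = "M8"),
                             n_markers_per_type = 15L,
                             gwas_enriched_modules = "M1",
                             missing_rate = 0.05,
                             missingness_mode = c("mcar", "intensity"),
                             gis_noise_sd = 0.05,
                             residual_sd = 0.4,
                             baseline_mean = 12,
                             baseline_sd = 1,
                             n_unique_vascular = 50L,
                             n_unique_bulk = 30L,
                             n_contaminated_samples = 0L,
                             contamination_shift = 2.5,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_batches = as.integer(n_batches),
              gis_per_batch = as.integer(gis_per_batch),
              n_modules = length(module_sizes),
              module_sizes = as.integer(module_sizes),
              within_module_cor = within_module_cor,
              loading_spread = loading_spread,
              batch_offsets = rep_len(batch_offsets, n_batches),
              covariate_effects = covariate_effects,
              covariate_affected_fraction = covariate_affected_fraction,
              disease_effects = disease_effects,
              vascular_enrichment = vascular_enrichment,
              marker_assignment = marker_assignment,
              n_markers_per_type = as.integer(n_markers_per_type),
              gwas_enriched_modules = gwas_enriched_modules,
              missing_rate = missing_rate,
              missingness_mode = match.arg(missingness_mode),
              gis_noise_sd = gis_noise_sd,
              residual_sd = residual_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              n_unique_vascular = as.integer(n_unique_vascular),
              n_unique_bulk = as.integer(n_unique_bulk),
              n_contaminated_samples = as.integer(n_contaminated_samples),
              contamination_shift = contamination_shift,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L) stop_cfg("n_proteins", "must be >= 1")
  if (cfg$n_samples_per_group < 2L) stop_cfg("n_samples_per_group", "must be >= 2")
  if (cfg$n_batches < 1L) stop_cfg("n_batches", "must be >= 1")
  if (cfg$gis_per_batch < 0L) stop_cfg("gis_per_batch", "must be >= 0")
  if (sum(cfg$module_sizes) > cfg$n_proteins)
    stop_cfg("module_sizes", "sum of module sizes exceeds n_proteins")
  if (any(cfg$module_sizes < 2L)) stop_cfg("module_sizes", "modules need >= 2 proteins")
  if (!is.numeric(cfg$loading_spread) || cfg$loading_spread < 0 ||
      cfg$loading_spread >= 1)
    stop_cfg("loading_spread", "must be in [0, 1)")
  for (f in c("within_module_cor", "missing_rate", "covariate_affected_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_cfg(f, "must be a fraction in [0, 1]")
  }
  if (!is.null(cfg$vascular_enrichment) &&
      length(cfg$vascular_enrichment) != cfg$n_proteins)
    stop_cfg("vascular_enrichment", "must have one value per protein")
  mods <- paste0("M", seq_along(cfg$module_sizes))
  if (missing(disease_effects)) {
    # default effect map trimmed to the modules that exist
    cfg$disease_effects <- cfg$disease_effects[names(cfg$disease_effects) %in% mods]
  } else {
    bad <- setdiff(names(cfg$disease_effects), mods)
    if (length(bad))
      stop_cfg("disease_effects",
               paste("unknown module(s):", paste(bad, collapse = ", ")))
  }
  if (missing(marker_assignment))
    cfg$marker_assignment <- cfg$marker_assignment[cfg$marker_assignment %in% mods]
  if (missing(gwas_enriched_modules))
    cfg$gwas_enriched_modules <- intersect(cfg$gwas_enriched_modules, mods)
  if (cfg$n_contaminated_samples > 0L) {
    if (!all(cfg$marker_assignment[c("endothelial", "neuron")] %in% mods))
      stop_cfg("marker_assignment",
               "contaminated samples need endothelial and neuron modules")
  }
  if (cfg$n_unique_vascular + cfg$n_unique_bulk >
      cfg$n_proteins - sum(cfg$module_sizes))
    stop_cfg("n_unique_vascular", "fraction-unique proteins exceed background pool")
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a paired vascular/bulk synthetic cohort
#'
#' Simulates log2 abundance matrices for a vascular fraction and its paired
#' bulk fraction under a module factor model: for protein *i* in module *m*,
#' `x = mu_i + s * (sqrt(r) f_m + sqrt(1-r) e) + batch + covariates +
#' diagnosis + enrichment`, where `f_m` is a per-module latent factor shared
#' between the paired fractions, `r` the planted within-module correlation
#' and `s` the residual SD.  GIS channels are each batch's mean biological
#' channel plus small noise; missingness is inserted completely at random by
#' default.  The returned `truth` element records every planted signal.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_cohort` list with elements `vascular`, `bulk`
#'   (matrices including GIS columns), `design`, `traits` (data frames) and
#'   `truth`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  set.seed(config$seed)
  groups <- c("CTL", "AD", "PSP")
  npg <- config$n_samples_per_group
  n_bio <- 3L * npg
  sample_ids <- unlist(lapply(groups, function(g) sprintf("%s.%02d", g, seq_len(npg))))
  diagnosis <- rep(groups, each = npg)
  batch <- unlist(lapply(groups, function(g)
    rep_len(seq_len(config$n_batches), npg)))   # balanced within group

  gis_ids <- character(0); gis_batch <- integer(0)
  if (config$gis_per_batch > 0L) {
    for (b in seq_len(config$n_batches)) {
      for (k in seq_len(config$gis_per_batch)) {
        gis_ids <- c(gis_ids, sprintf("GIS%d.b%d", k, b))
        gis_batch <- c(gis_batch, b)
      }
    }
  }

  traits <- data.frame(
    sample = sample_ids,
    diagnosis = diagnosis,
    age = round(stats::runif(n_bio, 60, 95)),
    sex = stats::rbinom(n_bio, 1L, 0.5),
    PMI = round(stats::runif(n_bio, 4, 24), 1),
    CERAD = NA_integer_, Braak = NA_integer_, CAA = NA_integer_,
    gliosis = sample(0:3, n_bio, replace = TRUE),
    APOE4 = NA_integer_,
    stringsAsFactors = FALSE)
  traits$CERAD <- ifelse(diagnosis == "AD", sample(2:3, n_bio, TRUE),
                         ifelse(diagnosis == "CTL", sample(0:1, n_bio, TRUE),
                                sample(0:2, n_bio, TRUE)))
  traits$Braak <- ifelse(diagnosis == "AD", sample(4:6, n_bio, TRUE),
                         ifelse(diagnosis == "CTL", sample(0:2, n_bio, TRUE),
                                sample(2:4, n_bio, TRUE)))
  traits$CAA <- ifelse(diagnosis == "AD", sample(1:3, n_bio, TRUE),
                       sample(0:1, n_bio, TRUE))
  traits$APOE4 <- ifelse(diagnosis == "AD",
                         sample(0:2, n_bio, TRUE, prob = c(0.4, 0.4, 0.2)),
                         sample(0:2, n_bio, TRUE, prob = c(0.7, 0.25, 0.05)))

  p <- config$n_proteins
  protein_ids <- sprintf("GENE%04d|P%05d", seq_len(p), seq_len(p))
  modules <- rep("M0", p)
  pos <- 1L
  for (m in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[m]
    modules[pos:(pos + sz - 1L)] <- paste0("M", m)
    pos <- pos + sz
  }
  names(modules) <- protein_ids

  r <- config$within_module_cor
  s <- config$residual_sd
  mu <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
  f <- matrix(stats::rnorm(config$n_modules * n_bio), config$n_modules, n_bio)
  # per-protein loadings shared between fractions: hub structure with mean
  # pairwise within-module correlation = within_module_cor
  loadings <- stats::setNames(rep(NA_real_, p), protein_ids)
  in_mod <- modules != "M0"
  loadings[in_mod] <- pmin(1, sqrt(r) *
    stats::runif(sum(in_mod), 1 - config$loading_spread,
                 1 + config$loading_spread))

  build_fraction <- function() {
    z <- matrix(stats::rnorm(p * n_bio), p, n_bio)
    for (m in seq_len(config$n_modules)) {
      idx <- modules == paste0("M", m)
      lam <- loadings[idx]
      z[idx, ] <- lam * matrix(f[m, ], sum(idx), n_bio, byrow = TRUE) +
        sqrt(1 - lam^2) * z[idx, ]
    }
    mu + s * z
  }
  vasc <- build_fraction()
  bulk <- build_fraction()
  dimnames(vasc) <- dimnames(bulk) <- list(protein_ids, sample_ids)

  # batch offsets (same batches label both fractions)
  off <- config$batch_offsets[batch]
  vasc <- vasc + matrix(off, p, n_bio, byrow = TRUE)
  bulk <- bulk + matrix(off, p, n_bio, byrow = TRUE)

  # nuisance covariate effects on a recorded subset of proteins, both fractions
  cov_sets <- list()
  for (cv in names(config$covariate_effects)) {
    idx <- sort(sample.int(p, round(config$covariate_affected_fraction * p)))
    cov_sets[[cv]] <- protein_ids[idx]
    x <- traits[[cv]]
    xc <- x - mean(x)
    term <- config$covariate_effects[[cv]] *
      matrix(xc, length(idx), n_bio, byrow = TRUE)
    vasc[idx, ] <- vasc[idx, ] + term
    bulk[idx, ] <- bulk[idx, ] + term
  }

  # protected diagnosis effects on module proteins, both fractions
  for (m in names(config$disease_effects)) {
    idx <- modules == m
    for (g in names(config$disease_effects[[m]])) {
      cols <- diagnosis == g
      vasc[idx, cols] <- vasc[idx, cols] + config$disease_effects[[m]][[g]]
      bulk[idx, cols] <- bulk[idx, cols] + config$disease_effects[[m]][[g]]
    }
  }

  # per-protein vascular/bulk enrichment (vascular fraction only)
  enrich <- config$vascular_enrichment
  if (is.null(enrich)) {
    module_shift <- seq(2, -1, length.out = config$n_modules)
    enrich <- stats::rnorm(p, 0, 0.5)
    for (m in seq_len(config$n_modules)) {
      idx <- modules == paste0("M", m)
      enrich[idx] <- module_shift[m] + stats::rnorm(sum(idx), 0, 0.25)
    }
  }
  names(enrich) <- protein_ids
  vasc <- vasc + enrich

  # planted fractionation outliers (vascular fraction artifact)
  contaminated <- character(0)
  if (config$n_contaminated_samples > 0L) {
    contaminated <- sort(sample(sample_ids, config$n_contaminated_samples))
    cc <- colnames(vasc) %in% contaminated
    neu <- modules == config$marker_assignment[["neuron"]]
    endo <- modules == config$marker_assignment[["endothelial"]]
    vasc[neu, cc] <- vasc[neu, cc] + config$contamination_shift
    vasc[endo, cc] <- vasc[endo, cc] - config$contamination_shift
  }

  # GIS channels: per-batch mean of biological channels plus small noise
  add_gis <- function(mat) {
    if (!length(gis_ids)) return(mat)
    g <- sapply(seq_along(gis_ids), function(k) {
      cols <- batch == gis_batch[k]
      rowMeans(mat[, cols, drop = FALSE]) +
        stats::rnorm(p, 0, config$gis_noise_sd)
    })
    colnames(g) <- gis_ids
    cbind(mat, g)
  }
  vasc <- add_gis(vasc); bulk <- add_gis(bulk)

  # fraction-unique proteins, then random missingness
  bg <- which(modules == "M0")
  uniq_v <- uniq_b <- character(0)
  if (config$n_unique_vascular > 0L || config$n_unique_bulk > 0L) {
    pick <- sample(bg, config$n_unique_vascular + config$n_unique_bulk)
    uniq_v <- protein_ids[pick[seq_len(config$n_unique_vascular)]]
    uniq_b <- protein_ids[setdiff(pick, pick[seq_len(config$n_unique_vascular)])]
    bulk[uniq_v, ] <- NA_real_
    vasc[uniq_b, ] <- NA_real_
  }
  punch <- function(mat) {
    if (config$missing_rate <= 0) return(mat)
    # GIS channels are exempt: a pooled standard present in every batch is
    # always quantified
    bio_cols <- which(!colnames(mat) %in% gis_ids)
    nb <- length(bio_cols)
    if (config$missingness_mode == "mcar") {
      drop <- matrix(stats::runif(p * nb) < config$missing_rate, p, nb)
    } else {
      # intensity-dependent: low-baseline proteins lose entries more often
      pr <- config$missing_rate * 2 *
        (1 - stats::pnorm(mu, config$baseline_mean, config$baseline_sd))
      drop <- matrix(stats::runif(p * nb) < matrix(pr, p, nb), p, nb)
    }
    mat[, bio_cols][drop] <- NA_real_
    mat
  }
  vasc <- punch(vasc); bulk <- punch(bulk)

  design <- data.frame(sample = c(sample_ids, gis_ids),
                       batch = paste0("b", c(batch, gis_batch)),
                       is_gis = c(rep(FALSE, n_bio), rep(TRUE, length(gis_ids))),
                       stringsAsFactors = FALSE)

  # cell-type marker sets drawn from the assigned modules
  marker_sets <- list()
  for (ct in names(config$marker_assignment)) {
    mem <- protein_ids[modules == config$marker_assignment[[ct]]]
    if (length(mem)) {
      take <- utils::head(mem, config$n_markers_per_type)
      marker_sets[[ct]] <- symbol_of(take)
    }
  }

  truth <- list(modules = modules,
                factors = f,
                loadings = loadings,
                baseline = stats::setNames(mu, protein_ids),
                covariate_effects = config$covariate_effects,
                covariate_affected = cov_sets,
                disease_effects = config$disease_effects,
                vascular_enrichment = enrich,
                unique_vascular = uniq_v,
                unique_bulk = uniq_b,
                marker_sets = marker_sets,
                marker_assignment = config$marker_assignment,
                contaminated_samples = contaminated,
                gwas_enriched_modules = config$gwas_enriched_modules,
                neuronal_level = {
                  nm <- match(config$marker_assignment["neuron"],
                              paste0("M", seq_len(config$n_modules)))
                  if (is.na(nm)) NULL else f[nm, ]
                })

  cohort <- list(vascular = vasc, bulk = bulk, design = design,
                 traits = traits, truth = truth, config = config)
  class(cohort) <- "synthetic_cohort"

  cohort$truth$gwas_tables <- generate_gwas_stats(
    truth, n_background_genes = 4000L, enrichment_pshift = 0.1,
    n_studies = 3L, seed = derive_seed(config$seed, "gwas"))
  cohort$truth$biofluid_tables <- list(
    CSF = generate_biofluid_table(truth, echo_module = "M1",
                                  seed = derive_seed(config$seed, "csf")),
    plasma = generate_biofluid_table(truth, echo_module = "M2",
                                     seed = derive_seed(config$seed, "plasma")))
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic paired TMT cohort: %d proteins x %d samples (+%d GIS), %d batches\n",
              nrow(x$vascular), sum(!x$design$is_gis), sum(x$design$is_gis),
              length(unique(x$design$batch))))
  cat(sprintf("  planted modules: %s\n",
              paste(sprintf("M%d(%d)", seq_along(x$config$module_sizes),
                            x$config$module_sizes), collapse = " ")))
  invisible(x)
}

#' Generate gene-level GWAS association tables with planted module risk
#'
#' Background genes draw p-values from Uniform(0,1); genes belonging to the
#' enriched modules draw from Beta(`enrichment_pshift`, 1), a left-shifted
#' distribution (at `enrichment_pshift = 1` the shift vanishes and all genes
#' are uniform).
#'
#' @param truth The `truth` element of a [generate_cohort()] result (or any
#'   list with `modules` and `gwas_enriched_modules`).
#' @param n_background_genes Extra non-network genes per study.
#' @param enrichment_pshift Beta shape `a` for enriched-module genes
#'   (`a < 1` shifts p toward 0).
#' @param n_studies Number of simulated studies.
#' @param seed RNG seed.
#' @return List of `data.frame`s with columns `GENE` and `P`, one per study.
#' @export
generate_gwas_stats <- function(truth, n_background_genes = 4000L,
                                enrichment_pshift = 0.1, n_studies = 3L,
                                seed = 1L) {
  enr <- truth$gwas_enriched_modules
  if (length(enr) && !all(enr %in% truth$modules))
    stop("enriched modules absent from truth: ",
         paste(setdiff(enr, truth$modules), collapse = ", "))
  set.seed(seed)
  genes <- symbol_of(names(truth$modules))
  enriched_gene <- truth$modules %in% enr
  bg <- sprintf("BG%05d", seq_len(n_background_genes))
  all_genes <- c(genes, bg)
  is_enr <- c(enriched_gene, rep(FALSE, n_background_genes))
  lapply(seq_len(n_studies), function(i) {
    p <- stats::runif(length(all_genes))
    if (enrichment_pshift != 1 && any(is_enr))
      p[is_enr] <- stats::rbeta(sum(is_enr), enrichment_pshift, 1)
    data.frame(GENE = all_genes, P = p, stringsAsFactors = FALSE)
  })
}

#' Generate a biofluid differential-abundance table echoing a brain module
#'
#' Proteins of the chosen module appear in the table as significantly
#' increased (p < 0.05, positive log2FC); the remainder of the table is
#' null background.
#'
#' @param truth Cohort `truth` list (needs `modules`).
#' @param echo_module Module whose members the fluid echoes.
#' @param echo_fraction Fraction of the module's members detected in fluid.
#' @param n_background Additional null fluid proteins.
#' @param seed RNG seed.
#' @return `data.frame` with columns `protein`, `log2FC`, `p`.
#' @export
generate_biofluid_table <- function(truth, echo_module = "M1",
                                    echo_fraction = 0.8,
                                    n_background = 300L, seed = 1L) {
  set.seed(seed)
  mem <- symbol_of(names(truth$modules)[truth$modules == echo_module])
  take <- sample(mem, round(echo_fraction * length(mem)))
  other <- symbol_of(names(truth$modules)[truth$modules != echo_module])
  bg <- c(sample(other, min(n_background, length(other))),
          sprintf("FLUID%04d", seq_len(50L)))
  data.frame(
    protein = c(take, bg),
    log2FC = c(stats::runif(length(take), 0.3, 1.5),
               stats::rnorm(length(bg), 0, 0.3)),
    p = c(stats::runif(length(take), 1e-6, 0.04),
          stats::runif(length(bg))),
    stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk in the pipeline's file formats
#'
#' Emits the TSV/GMT files consumed by the readers in this package so the
#' whole pipeline can be run end-to-end from files.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
simulate_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vascular = file.path(dir, "vascular.tsv"),
    bulk = file.path(dir, "bulk.tsv"),
    design = file.path(dir, "design.tsv"),
    traits = file.path(dir, "traits.tsv"),
    markers = file.path(dir, "markers.gmt"))
  write_abundance_matrix(cohort$vascular, paths$vascular)
  write_abundance_matrix(cohort$bulk, paths$bulk)
  write_table(cohort$design, paths$design)
  write_table(cohort$traits, paths$traits)
  write_marker_gmt(cohort$truth$marker_sets, paths$markers)
  for (i in seq_along(cohort$truth$gwas_tables)) {
    p <- file.path(dir, sprintf("gwas_study%d.tsv", i))
    write_table(cohort$truth$gwas_tables[[i]], p)
    paths[[sprintf("gwas_study%d", i)]] <- p
  }
  for (nm in names(cohort$truth$biofluid_tables)) {
    p <- file.path(dir, sprintf("biofluid_%s.tsv", nm))
    write_table(cohort$truth$biofluid_tables[[nm]], p)
    paths[[paste0("biofluid_", nm)]] <- p
  }
  paths
}
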
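#' Assemble and validate a pipeline configuration
#'
#' @param inputs Named list of input paths: `vascular`, `bulk`, `design`,
#'   `traits`, `markers`, optionally `gwas` (vector of study tables) and
#'   `biofluid` (named vector of DE tables).
#' @param out_dir Output directory.
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   from it by stage-name hashing, so stages are individually
#'   reproducible.
#' @param max_missing_fraction Missingness filter threshold.
#' @param use_all_non_gis TAMPOR denominator choice.
#' @param n_boot Bootstrap regression fits (published default 1000).
#' @param n_preservation_perm Preservation permutations (published
#'   default 500).
#' @param n_gwas_perm GWAS enrichment permutations (published default
#'   10,000).
#' @param network A [network_params()] list.
#' @param endothelial_floor_z,neuronal_ceiling_z Outlier thresholds.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(inputs, out_dir, seed = 1L,
                            max_missing_fraction = 0.50,
                            use_all_non_gis = FALSE,
                            n_boot = 1000L,
                            n_preservation_perm = 500L,
                            n_gwas_perm = 10000L,
                            network = network_params(),
                            endothelial_floor_z = -2,
                            neuronal_ceiling_z = 2) {
  need <- c("vascular", "bulk", "design", "traits", "markers")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing input paths: ", paste(miss, collapse = ", "))
  for (nm in setdiff(names(inputs), c("gwas", "biofluid"))) {
    if (!file.exists(inputs[[nm]]))
      stop("input file not found (", nm, "): ", inputs[[nm]])
  }
  for (p in c(inputs$gwas, inputs$biofluid))
    if (!file.exists(p)) stop("input file not found: ", p)
  cfg <- list(inputs = inputs, out_dir = out_dir, seed = as.integer(seed),
              max_missing_fraction = max_missing_fraction,
              use_all_non_gis = use_all_non_gis,
              n_boot = as.integer(n_boot),
              n_preservation_perm = as.integer(n_preservation_perm),
              n_gwas_perm = as.integer(n_gwas_perm),
              network = network,
              endothelial_floor_z = endothelial_floor_z,
              neuronal_ceiling_z = neuronal_ceiling_z)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  net <- do.call(network_params, y$network %||% list())
  args <- y[setdiff(names(y), "network")]
  args$network <- net
  do.call(pipeline_config, args)
}

#' Run the full vascular-proteome network pipeline
#'
#' Executes, in order: missingness filter, TAMPOR batch correction,
#' cell-type scoring and fractionation-outlier removal, bootstrap
#' covariate regression with protected diagnosis effects, signed
#' bicor/TOM network construction with iterative kME reassignment,
#' module preservation against the paired bulk fraction, module-trait
#' and group differential statistics, and cell-type / GWAS / biofluid
#' enrichment.  Every intermediate table is written to the output
#' directory along with a machine-readable run manifest and a log.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return Invisibly, the output directory; the returned value also
#'   carries a `results` attribute with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  stages_done <- character(0)
  results <- list()
  stage <- function(name, fun) {
    logf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name)
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages_done <<- c(stages_done, name)
    res
  }

  vasc <- read_abundance_matrix(config$inputs$vascular)
  bulk <- read_abundance_matrix(config$inputs$bulk)
  design <- read_batch_design(config$inputs$design)
  traits <- read_sample_traits(config$inputs$traits)
  markers <- read_marker_gmt(config$inputs$markers)

  results$filter <- stage("filter", function() {
    list(vascular = filter_missingness(vasc, config$max_missing_fraction),
         bulk = filter_missingness(bulk, config$max_missing_fraction))
  })
  results$tampor <- stage("tampor", function() {
    v <- tampor_correct(results$filter$vascular, design,
                        use_all_non_gis = config$use_all_non_gis)
    b <- tampor_correct(results$filter$bulk, design,
                        use_all_non_gis = config$use_all_non_gis)
    write_abundance_matrix(v$corrected,
                           file.path(config$out_dir, "vascular_corrected.tsv"))
    write_abundance_matrix(b$corrected,
                           file.path(config$out_dir, "bulk_corrected.tsv"))
    list(vascular = v, bulk = b)
  })
  bio <- design$sample[!design$is_gis]
  vc <- results$tampor$vascular$corrected
  vc <- vc[, colnames(vc) %in% bio, drop = FALSE]
  bc <- results$tampor$bulk$corrected
  bc <- bc[, colnames(bc) %in% bio, drop = FALSE]

  results$qc <- stage("qc_flag", function() {
    scores <- suppressWarnings(score_cell_types(vc, markers))
    flags <- flag_outliers(scores,
                           endothelial_floor_z = config$endothelial_floor_z,
                           neuronal_ceiling_z = config$neuronal_ceiling_z)
    write_table(data.frame(sample = rownames(scores), scores,
                           check.names = FALSE),
                file.path(config$out_dir, "celltype_scores.tsv"))
    write_table(data.frame(sample = flags),
                file.path(config$out_dir, "outlier_flags.tsv"))
    list(scores = scores, flags = flags)
  })
  keep <- setdiff(colnames(vc), results$qc$flags)
  vc <- vc[, keep, drop = FALSE]

  results$regress <- stage("regress", function() {
    rr <- bootstrap_regress(vc, traits, scores = results$qc$scores,
                            design = design, n_boot = config$n_boot,
                            seed = derive_seed(config$seed, "regress"))
    write_abundance_matrix(rr$corrected,
                           file.path(config$out_dir, "vascular_regressed.tsv"))
    write_table(data.frame(protein = rownames(rr$report$coefficients),
                           rr$report$coefficients, check.names = FALSE),
                file.path(config$out_dir, "regression_coefficients.tsv"))
    rr
  })
  reg <- results$regress$corrected

  results$network <- stage("network", function() {
    part <- build_network(reg, config$network)
    write_table(data.frame(protein = names(part$labels), module = part$labels),
                file.path(config$out_dir, "module_labels.tsv"))
    if (!is.null(part$kme))
      write_table(data.frame(protein = rownames(part$kme), part$kme,
                             check.names = FALSE),
                  file.path(config$out_dir, "kme.tsv"))
    if (!is.null(part$eigenproteins))
      write_table(data.frame(module = rownames(part$eigenproteins),
                             part$eigenproteins, check.names = FALSE),
                  file.path(config$out_dir, "eigenproteins.tsv"))
    part
  })
  part <- results$network

  results$preservation <- stage("preservation", function() {
    pres <- module_preservation(reg, part$labels,
                                bc[, intersect(colnames(bc), colnames(reg)),
                                   drop = FALSE],
                                n_permutations = config$n_preservation_perm,
                                seed = derive_seed(config$seed, "preservation"),
                                beta = config$network$soft_power)
    pres$category <- classify_preservation(pres)
    write_table(pres, file.path(config$out_dir, "module_preservation.tsv"))
    pres
  })

  results$diffstats <- stage("diffstats", function() {
    grp <- traits$diagnosis[match(colnames(reg), traits$sample)]
    diff <- anova_tukey(reg, grp)
    tc <- module_trait_correlation(part$eigenproteins, traits)
    enr <- log2_enrichment(vc, bc, labels = part$labels)
    write_table(diff, file.path(config$out_dir, "differential_abundance.tsv"))
    write_table(tc, file.path(config$out_dir, "module_trait_correlation.tsv"))
    write_table(enr$proteins, file.path(config$out_dir, "vascular_enrichment.tsv"))
    sel <- select_classifier_proteins(diff, enr$proteins)
    write_table(data.frame(protein = sel),
                file.path(config$out_dir, "classifier_proteins.tsv"))
    list(diff = diff, trait_cor = tc, enrichment = enr, classifier = sel)
  })

  results$enrichment <- stage("enrichment", function() {
    bg <- unique(symbol_of(rownames(reg)))
    ct <- fisher_set_enrichment(part, markers, bg)
    write_table(ct, file.path(config$out_dir, "celltype_enrichment.tsv"))
    out <- list(celltype = ct)
    if (!is.null(config$inputs$gwas)) {
      tabs <- lapply(config$inputs$gwas, read_gene_pvalues)
      gw <- gwas_permutation_enrichment(part, tabs,
                                        n_perm = config$n_gwas_perm,
                                        seed = derive_seed(config$seed, "gwas"))
      write_table(gw, file.path(config$out_dir, "gwas_enrichment.tsv"))
      out$gwas <- gw
    }
    if (!is.null(config$inputs$biofluid)) {
      fl <- lapply(config$inputs$biofluid, read_biofluid_table)
      if (is.null(names(fl)))
        names(fl) <- tools::file_path_sans_ext(basename(unlist(config$inputs$biofluid)))
      bo <- biofluid_overlap(part, fl, background = bg)
      write_table(bo, file.path(config$out_dir, "biofluid_overlap.tsv"))
      out$biofluid <- bo
    }
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("vasculonet")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = c("regress", "preservation", "gwas")),
                         function(s) derive_seed(config$seed, s)),
    stages = stages_done,
    parameters = config[setdiff(names(config), "inputs")],
    input_checksums = lapply(config$inputs, function(p)
      unname(tools::md5sum(unlist(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  logf("[%s] pipeline complete (%d stages)", format(Sys.time(), "%H:%M:%S"),
       length(stages_done))
  out <- config$out_dir
  attr(out, "results") <- results
  invisible(out)
}
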
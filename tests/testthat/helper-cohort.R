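# Shared small cohorts, generated once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# default-shape cohort used by several files
test_cohort <- function() cached("cohort", generate_cohort(generator_config(seed = 101)))

# its TAMPOR-corrected vascular matrix restricted to biological samples
test_corrected <- function() cached("corrected", {
  co <- test_cohort()
  tf <- tampor_correct(filter_missingness(co$vascular), co$design)
  bio <- co$design$sample[!co$design$is_gis]
  tf$corrected[, bio]
})

# small matched vascular/bulk pair for preservation-style tests
small_pair <- function() cached("pair", {
  co <- generate_cohort(generator_config(
    seed = 55, n_proteins = 400,
    module_sizes = c(60L, 50L, 45L, 40L, 35L, 30L, 25L, 20L),
    n_unique_vascular = 0L, n_unique_bulk = 0L))
  bio <- co$design$sample[!co$design$is_gis]
  list(
    vascular = tampor_correct(filter_missingness(co$vascular), co$design)$corrected[, bio],
    bulk = tampor_correct(filter_missingness(co$bulk), co$design)$corrected[, bio],
    truth = co$truth, design = co$design, traits = co$traits)
})
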
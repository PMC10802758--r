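test_that("Fisher enrichment matches the hypergeometric tail-sum oracle", {
  set.seed(71)
  bg <- sprintf("G%04d", 1:1000)
  for (i in 1:20) {
    ms <- sample(30:200, 1); cs <- sample(30:200, 1)
    mod <- sample(bg, ms)
    cat_ <- c(sample(mod, sample(0:min(ms, cs), 1)),
              sample(setdiff(bg, mod), cs))[seq_len(cs)]
    res <- fisher_set_enrichment(list(M = mod), list(C = unique(cat_)), bg)
    a <- res$overlap
    expect_equal(res$p,
                 oracle_hyper_tail(a, res$module_size, res$category_size, 1000),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(c(a, res$module_size - a,
                               res$category_size - a,
                               1000 - res$module_size - res$category_size + a),
                             2, 2), alternative = "greater")
    expect_equal(res$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher enrichment handles containment and empty overlap", {
  bg <- sprintf("G%04d", 1:1000)
  mod <- bg[1:50]
  res <- fisher_set_enrichment(list(M = mod), list(C = mod), bg)
  expect_equal(res$p, oracle_hyper_tail(50, 50, 50, 1000), tolerance = 1e-12)
  expect_lt(res$p, 1e-80)
  expect_gt(res$odds_ratio, 1000)   # Haldane-corrected, maximal under correction
  res0 <- fisher_set_enrichment(list(M = bg[1:50]), list(C = bg[51:100]), bg)
  expect_gte(res0$p, 0.99)
  expect_error(fisher_set_enrichment(list(M = mod), list(C = mod), character(0)),
               "empty background")
})

test_that("Fisher enrichment is exchangeable in module and category", {
  set.seed(72)
  bg <- sprintf("G%04d", 1:500)
  a <- sample(bg, 60); b <- sample(bg, 90)
  p1 <- fisher_set_enrichment(list(S = a), list(C = b), bg)$p
  p2 <- fisher_set_enrichment(list(S = b), list(C = a), bg)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("BH FDR is monotone under elementwise p-value increase", {
  set.seed(73)
  p <- runif(30)
  q <- pmin(1, p + runif(30, 0, 0.2))
  expect_true(all(p.adjust(q, "BH") >= p.adjust(p, "BH") - 1e-12))
})

test_that("planted cell-type modules are flagged at BH FDR < 0.05", {
  co <- test_cohort()
  sets <- split(vasculonet:::symbol_of(names(co$truth$modules)),
                co$truth$modules)
  sets <- sets[names(sets) != "M0"]
  bg <- unique(vasculonet:::symbol_of(names(co$truth$modules)))
  res <- fisher_set_enrichment(sets, co$truth$marker_sets, bg)
  for (ct in names(co$truth$marker_assignment)) {
    target <- co$truth$marker_assignment[[ct]]
    row <- res[res$module == target & res$category == ct, ]
    expect_lt(row$fdr, 0.05)
    best <- res[res$category == ct, ]
    expect_identical(best$module[which.min(best$p)], target)
  }
})

test_that("GWAS permutation enrichment flags the planted risk module only", {
  co <- test_cohort()
  sets <- split(vasculonet:::symbol_of(names(co$truth$modules)),
                co$truth$modules)
  sets <- sets[names(sets) != "M0"]
  gw <- gwas_permutation_enrichment(sets, co$truth$gwas_tables,
                                    n_perm = 500, seed = 12)
  expect_true(gw$significant_fdr05[gw$module == "M1"])
  expect_gt(gw$NES[gw$module == "M1"], max(gw$NES[gw$module != "M1"]))
  # a module with no nominally significant genes gets NES 0, never flagged
  expect_true(all(gw$NES[gw$n_contributing == 0] == 0))
  expect_false(any(gw$significant_fdr05[gw$n_contributing == 0]))
  expect_error(gwas_permutation_enrichment(sets, list(), n_perm = 10), "study")
})

test_that("GWAS NES is invariant to monotone gene relabeling", {
  co <- test_cohort()
  sets <- split(vasculonet:::symbol_of(names(co$truth$modules)),
                co$truth$modules)
  sets <- sets[c("M1", "M2", "M3")]
  tabs <- co$truth$gwas_tables
  relabel <- function(g) paste0("X", g)
  sets2 <- lapply(sets, relabel)
  tabs2 <- lapply(tabs, function(t) { t$GENE <- relabel(t$GENE); t })
  g1 <- gwas_permutation_enrichment(sets, tabs, n_perm = 300, seed = 5)
  g2 <- gwas_permutation_enrichment(sets2, tabs2, n_perm = 300, seed = 5)
  expect_equal(g1$NES, g2$NES, tolerance = 1e-12)
})

test_that("uniform gene-level p-values rarely flag any module", {
  co <- test_cohort()
  sets <- split(vasculonet:::symbol_of(names(co$truth$modules)),
                co$truth$modules)
  sets <- sets[names(sets) != "M0"]
  genes <- unique(unlist(sets))
  flagged <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(900 + s)
    tab <- data.frame(GENE = c(genes, sprintf("BG%04d", 1:2000)),
                      P = runif(length(genes) + 2000))
    gn <- gwas_permutation_enrichment(sets, list(tab), n_perm = 300, seed = s)
    flagged <- flagged + sum(gn$significant_fdr05)
    total <- total + nrow(gn)
  }
  expect_lte(flagged / total, 0.10)
})

test_that("biofluid overlap flags the echoed module and handles degeneracy", {
  co <- test_cohort()
  sets <- split(vasculonet:::symbol_of(names(co$truth$modules)),
                co$truth$modules)
  sets <- sets[names(sets) != "M0"]
  bg <- unique(vasculonet:::symbol_of(names(co$truth$modules)))
  res <- biofluid_overlap(sets, co$truth$biofluid_tables["CSF"],
                          direction = "increased", background = bg)
  hit <- res[res$module == "M1", ]   # CSF echoes M1's increased proteins
  expect_lt(hit$fdr, 0.05)

  # direction with an empty category is reported untestable
  dec_only <- list(fluid = data.frame(protein = bg[1:50],
                                      log2FC = -abs(rnorm(50)) - 0.1,
                                      p = rep(0.001, 50)))
  expect_error(biofluid_overlap(sets, dec_only, direction = "increased",
                                background = bg), "untestable|no testable")

  # direction = all: overlap counts equal brute-force set intersection
  res_all <- biofluid_overlap(sets, co$truth$biofluid_tables["CSF"],
                              direction = "all", background = bg)
  csf <- intersect(unique(co$truth$biofluid_tables$CSF$protein), bg)
  for (m in c("M1", "M5")) {
    expect_equal(res_all$overlap[res_all$module == m],
                 length(intersect(sets[[m]], csf)))
  }
})

test_that("set overlap partitions the union exactly", {
  got <- set_overlap(c("P1", "P2", "P3"), c("P2", "P3", "P4"))
  expect_equal(got[c("n_unique_a", "n_unique_b", "n_shared")],
               list(n_unique_a = 1L, n_unique_b = 1L, n_shared = 2L))
  same <- set_overlap(letters, letters)
  expect_equal(same$n_shared, 26L)
  expect_equal(same$n_unique_a + same$n_unique_b, 0L)
  set.seed(74)
  a <- sample(sprintf("G%05d", 1:5000), 1000)
  b <- sample(sprintf("G%05d", 1:5000), 1000)
  got2 <- set_overlap(a, b)
  expect_equal(got2$n_shared, length(intersect(a, b)))
  expect_equal(got2$n_unique_a, length(setdiff(a, b)))
  expect_equal(got2$n_unique_a + got2$n_unique_b + got2$n_shared,
               length(union(a, b)))
})
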
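test_that("signed adjacency follows its closed form", {
  cm <- matrix(c(1, 1, -1, 0,
                 1, 1, 0, 0.5,
                 -1, 0, 1, 0,
                 0, 0.5, 0, 1), 4, 4)
  a <- signed_adjacency(cm, beta = 9)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.5^9)
  expect_equal(diag(a), rep(0, 4))
  expect_error(signed_adjacency(matrix(c(1, 2, 2, 1), 2), 9), "\\[-1, 1\\]")
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # 3 nodes, all pairwise adjacency 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  tom3 <- tom_similarity(a3)
  expect_equal(tom3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5), tolerance = 1e-15)

  # empty network
  a0 <- matrix(0, 4, 4)
  expect_equal(tom_similarity(a0)[upper.tri(a0)], rep(0, 6))

  set.seed(41)
  for (i in 1:3) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(tom_similarity(a), oracle_tom(a), tolerance = 1e-12)
  }
  expect_error(tom_similarity(matrix(c(0, 1, 0.5, 0), 2)), "symmetric")
})

test_that("average-linkage tree matches a hand-rolled UPGMA oracle", {
  set.seed(42)
  d <- matrix(runif(225, 0.1, 1), 15, 15)
  d <- (d + t(d)) / 2; diag(d) <- 0
  tree <- cluster_dendrogram(d)
  expect_equal(sort(tree$height), oracle_average_linkage_heights(d),
               tolerance = 1e-12)
  # two perfect blocks split at the top at the between-block height
  db <- matrix(1, 10, 10); db[1:5, 1:5] <- 0; db[6:10, 6:10] <- 0; diag(db) <- 0
  tb <- cluster_dendrogram(db)
  expect_equal(max(tb$height), 1)
  expect_setequal(cutree(tb, 2)[1:5], 1)
  # equal dissimilarities merge deterministically in index order
  de <- matrix(0.5, 3, 3); diag(de) <- 0
  te <- cluster_dendrogram(de)
  expect_equal(te$merge[1, ], c(-1, -2))
  expect_error(cluster_dendrogram(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("dynamic cut recovers planted blocks and respects the minimum size", {
  set.seed(43)
  blocks <- function(sizes, within = 0.1, between = 0.9) {
    n <- sum(sizes)
    d <- matrix(between, n, n)
    at <- cumsum(c(0, sizes))
    for (k in seq_along(sizes)) {
      idx <- (at[k] + 1):at[k + 1]
      d[idx, idx] <- within
    }
    d <- d + matrix(runif(n * n, 0, 0.01), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("o", seq_len(n)), paste0("o", seq_len(n)))
    d
  }
  d3 <- blocks(c(50, 50, 50))
  lab <- dynamic_hybrid_cut(cluster_dendrogram(d3), d3)
  expect_equal(length(setdiff(unique(lab), 0L)), 3L)
  truth <- rep(1:3, each = 50)
  expect_equal(adjusted_rand_index(lab[lab > 0], truth[lab > 0]), 1)

  # a 10-member block can never become a standalone module
  d4 <- blocks(c(50, 50, 10))
  lab4 <- dynamic_hybrid_cut(cluster_dendrogram(d4), d4)
  small <- lab4[101:110]
  big_modules <- table(lab4[lab4 > 0])
  expect_true(all(big_modules >= 20))

  # structureless input never yields more than one module
  de <- matrix(0.5, 40, 40); diag(de) <- 0
  labe <- dynamic_hybrid_cut(cluster_dendrogram(de), de)
  expect_lte(length(setdiff(unique(labe), 0L)), 1L)
})

test_that("eigenproteins explain variance as the factor structure dictates", {
  set.seed(44)
  n <- 30
  prof <- rnorm(n)
  m_same <- matrix(rep(prof, each = 6), 6, n,
                   dimnames = list(paste0("P", 1:6), paste0("s", 1:n)))
  m_same <- m_same * runif(6, 0.5, 2) + rnorm(6)   # scaled/shifted copies
  e <- module_eigenproteins(m_same, rep("M1", 6))
  expect_equal(unname(e$pve["M1"]), 1.0, tolerance = 1e-12)
  expect_equal(abs(cor(e$eigenproteins["M1", ], prof)), 1, tolerance = 1e-12)

  # mutually orthogonal member profiles: pve ~ 1/n_members
  q <- qr.Q(qr(matrix(rnorm(n * 5), n, 5)))
  m_orth <- t(q)
  dimnames(m_orth) <- list(paste0("P", 1:5), paste0("s", 1:n))
  e2 <- module_eigenproteins(m_orth, rep("M1", 5))
  expect_lt(abs(unname(e2$pve["M1"]) - 1 / 5), 0.03)

  # sign convention: mean member correlation positive on random data
  m_rand <- matrix(rnorm(40 * n), 40, n,
                   dimnames = list(paste0("P", 1:40), paste0("s", 1:n)))
  lab <- rep(c("M1", "M2"), each = 20)
  e3 <- module_eigenproteins(m_rand, lab)
  for (mod in c("M1", "M2")) {
    mc <- mean(cor(t(m_rand[lab == mod, ]), e3$eigenproteins[mod, ]))
    expect_gt(mc, 0)
  }
})

test_that("modules merge below the cut height and not above it", {
  set.seed(45)
  n <- 60
  f1 <- rnorm(n)
  f_close <- 0.97 * f1 + sqrt(1 - 0.97^2) * rnorm(n)   # eig diss ~ 0.03 < 0.07
  f_apart <- 0.90 * f1 + sqrt(1 - 0.90^2) * rnorm(n)   # eig diss ~ 0.10 > 0.07
  f_indep <- rnorm(n)
  make_mod <- function(base, k, noise = 0.2) {
    t(sapply(seq_len(k), function(i) base + rnorm(n, 0, noise)))
  }
  m <- rbind(make_mod(f1, 20), make_mod(f_close, 20),
             make_mod(f_apart, 20), make_mod(f_indep, 20))
  dimnames(m) <- list(sprintf("P%02d", 1:80), paste0("s", 1:n))
  lab <- rep(c("M1", "M2", "M3", "M4"), each = 20)
  merged <- merge_close_modules(m, lab, merge_cut_height = 0.07)
  expect_equal(length(unique(merged)), 3L)
  expect_equal(length(unique(merged[1:40])), 1L)   # the 0.97 pair fused
  expect_equal(length(unique(merged[c(1, 41)])), 2L)  # the 0.90 pair did not
})

test_that("kME table has the right shape and recovers membership", {
  pair <- small_pair()
  x <- pair$vascular
  lab <- pair$truth$modules[rownames(x)]
  eig <- module_eigenproteins(x, lab)$eigenproteins
  kme <- suppressWarnings(kme_table(x, eig))
  expect_equal(dim(kme), c(nrow(x), nrow(eig)))
  expect_true(all(abs(kme) <= 1, na.rm = TRUE))
  # module members have their top kME at their own module far more often
  # than anywhere else
  assigned <- lab != "M0"
  top <- colnames(kme)[max.col(replace(kme, is.na(kme), -2))]
  expect_gt(mean(top[assigned] == lab[assigned]), 0.9)
  # pure-noise proteins have uniformly weak kME
  noise <- lab == "M0" &
    !names(lab) %in% c(pair$truth$unique_vascular, pair$truth$unique_bulk)
  expect_gt(mean(abs(kme[noise, ]) < 0.3, na.rm = TRUE), 0.95)
})

test_that("iterative reassignment applies the three kME rules", {
  set.seed(46)
  n <- 80
  fa <- rnorm(n); fb <- rnorm(n)
  mk <- function(f, k) t(sapply(seq_len(k), function(i) f + rnorm(n, 0, 0.35)))
  m <- rbind(mk(fa, 25), mk(fb, 25),
             weak   = 0.15 * fa + rnorm(n),          # all kME < 0.30
             mover  = 0.40 * fa + 0.80 * fb + rnorm(n, 0, 0.2),  # gap > 0.10
             stayer = 0.69 * fa + 0.71 * fb + rnorm(n, 0, 0.1))  # gap <= 0.10
  rownames(m) <- c(sprintf("A%02d", 1:25), sprintf("B%02d", 1:25),
                   "weak", "mover", "stayer")
  colnames(m) <- paste0("s", 1:n)
  lab <- setNames(c(rep("M1", 25), rep("M2", 25), "M1", "M1", "M1"),
                  rownames(m))
  part <- iterative_reassignment(m, lab)
  relab <- part$labels
  expect_identical(unname(relab["weak"]), "M0")
  expect_identical(unname(relab["mover"]), unname(relab["B01"]))
  expect_identical(unname(relab["stayer"]), unname(relab["A01"]))
  expect_true(part$converged)
})

test_that("full network build recovers planted modules from the cohort", {
  co <- test_cohort()
  reg <- test_corrected()
  part <- build_network(reg)
  truth <- co$truth$modules[names(part$labels)]
  assigned <- part$labels != "M0"
  expect_gte(adjusted_rand_index(part$labels[assigned], truth[assigned]), 0.8)
  expect_lte(part$n_iterations, 30L)
  expect_true(part$converged)
  # naming invariant: sizes non-increasing in rank order
  sz <- module_sizes(part)
  expect_true(all(diff(as.integer(sz)) <= 0))
  # eigenprotein sign invariant holds for every module
  for (mod in names(sz)) {
    mc <- mean(part$kme[part$labels == mod, mod], na.rm = TRUE)
    expect_gt(mc, 0)
  }
})

test_that("a permuted-sample matrix yields essentially no modules", {
  reg <- test_corrected()
  set.seed(47)
  scr <- t(apply(reg, 1, sample))
  dimnames(scr) <- dimnames(reg)
  part <- build_network(scr)
  sizes <- module_sizes(part)
  biggest <- if (length(sizes)) max(sizes) else 0L
  in_null_or_one <- sum(part$labels == "M0") + biggest
  expect_gte(in_null_or_one / length(part$labels), 0.8)
})

test_that("raising the kME assignment threshold never assigns more proteins", {
  pair <- small_pair()
  x <- pair$vascular
  lab0 <- pair$truth$modules[rownames(x)]
  n_assigned <- sapply(c(0.2, 0.3, 0.45, 0.6), function(th) {
    p <- iterative_reassignment(x, lab0, network_params(kme_assign_min = th))
    sum(p$labels != "M0")
  })
  expect_true(all(diff(n_assigned) <= 0))
})
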
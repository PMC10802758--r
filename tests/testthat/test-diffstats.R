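test_that("ANOVA and Tukey p-values match the textbook oracles", {
  set.seed(61)
  grp <- rep(c("CTL", "AD", "PSP"), times = c(8, 7, 9))
  m <- matrix(rnorm(20 * 24, 10), 20, 24,
              dimnames = list(sprintf("P%02d|U%02d", 1:20, 1:20),
                              sprintf("s%02d", 1:24)))
  m[3, grp == "AD"] <- m[3, grp == "AD"] + 1.5
  res <- anova_tukey(m, grp)
  for (i in c(1, 3, 12)) {
    df <- data.frame(y = m[i, ], g = factor(grp))
    fit <- aov(y ~ g, df)
    expect_equal(res$anova_p[i], summary(fit)[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-10)
    tk <- TukeyHSD(fit)$g
    # match comparisons irrespective of level ordering
    for (cmp in rownames(tk)) {
      lv <- strsplit(cmp, "-")[[1]]
      col <- paste0("p_", lv[1], "_vs_", lv[2])
      if (!col %in% names(res)) col <- paste0("p_", lv[2], "_vs_", lv[1])
      expect_equal(res[[col]][i], tk[cmp, "p adj"], tolerance = 1e-8)
    }
  }
})

test_that("the Bonferroni fallback fires only below 1e-8.5 and caps at 1", {
  set.seed(62)
  grp <- rep(c("CTL", "AD", "PSP"), each = 15)
  m <- matrix(rnorm(3 * 45, 10, 0.3), 3, 45,
              dimnames = list(c("null|P1", "huge|P2", "mid|P3"),
                              sprintf("s%02d", 1:45)))
  m["huge|P2", grp == "AD"] <- m["huge|P2", grp == "AD"] + 8   # astronomically significant
  m["mid|P3", grp == "AD"] <- m["mid|P3", grp == "AD"] + 0.4   # significant, above threshold
  res <- anova_tukey(m, grp)
  fb_cols <- grep("^fallback_", names(res), value = TRUE)
  expect_false(any(unlist(res[res$protein == "null|P1", fb_cols])))
  expect_false(any(unlist(res[res$protein == "mid|P3", fb_cols])))
  hit <- unlist(res[res$protein == "huge|P2", fb_cols])
  expect_true(any(hit))
  # the substituted p equals 3 x the Welch t-test p for that pair
  i <- which(res$protein == "huge|P2")
  cmp <- sub("fallback_", "", names(hit)[hit][1])
  lv <- strsplit(cmp, "_vs_")[[1]]
  tt <- t.test(m["huge|P2", grp == lv[1]], m["huge|P2", grp == lv[2]])
  expect_equal(res[[paste0("p_", cmp)]][i], min(1, 3 * tt$p.value),
               tolerance = 1e-10)
  expect_true(all(unlist(res[, grep("^p_", names(res))]) <= 1, na.rm = TRUE))
})

test_that("degenerate proteins are skipped, not reported as p = 0", {
  grp <- rep(c("CTL", "AD", "PSP"), each = 4)
  m <- rbind("const|P1" = rep(5, 12),
             "sparse|P2" = c(1, NA, NA, NA, 2, 3, 4, 5, 6, 7, 8, 9))
  colnames(m) <- sprintf("s%02d", 1:12)
  res <- anova_tukey(m, grp)
  expect_true(all(res$skipped))
  expect_true(all(is.na(res$anova_p)))
  expect_error(anova_tukey(m[, 1:4, drop = FALSE], rep("CTL", 4)), "2 diagnosis")
})

test_that("ANOVA type-I error is calibrated on null data", {
  set.seed(63)
  m <- matrix(rnorm(2000 * 60), 2000, 60,
              dimnames = list(sprintf("P%04d|U%04d", 1:2000, 1:2000),
                              sprintf("s%02d", 1:60)))
  grp <- rep(c("CTL", "AD", "PSP"), each = 20)
  res <- anova_tukey(m, grp)
  rate <- mean(res$anova_p < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("module-trait correlations behave at the extremes and under recoding", {
  set.seed(64)
  n <- 40
  tr <- data.frame(sample = sprintf("s%02d", 1:n),
                   cont = rnorm(n),
                   diagnosis = rep(c("CTL", "AD"), each = n / 2),
                   flat = 1)
  eig <- rbind(M1 = tr$cont, M2 = rnorm(n))
  colnames(eig) <- tr$sample
  expect_warning(res <- module_trait_correlation(eig, tr), "constant trait")
  r1 <- res[res$module == "M1" & res$trait == "cont", ]
  expect_equal(r1$bicor, 1, tolerance = 1e-9)
  expect_lt(r1$p, 1e-20)
  # binary recoding changes at most the sign, never the magnitude or p
  tr2 <- tr
  tr2$bin <- as.numeric(tr$diagnosis == "AD")
  tr3 <- tr2
  tr3$bin <- 1 - tr2$bin
  res2 <- suppressWarnings(module_trait_correlation(eig, tr2))
  res3 <- suppressWarnings(module_trait_correlation(eig, tr3))
  a <- res2[res2$trait == "bin", "bicor"]
  b <- res3[res3$trait == "bin", "bicor"]
  expect_equal(a, -b, tolerance = 1e-12)
  expect_equal(res2[res2$trait == "bin", "p"],
               res3[res3$trait == "bin", "p"], tolerance = 1e-12)
  # character-coded diagnosis agrees with explicit 0/1 coding up to sign
  d <- res[res$trait == "diagnosis", "bicor"]
  expect_equal(abs(d), abs(a), tolerance = 1e-12)
})

test_that("trait-correlation p-values are uniform under the null", {
  set.seed(65)
  n <- 62
  ps <- replicate(400, {
    e <- rnorm(n); tr <- rnorm(n)
    r <- suppressWarnings(bicor(e, tr))
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tval), n - 2, lower.tail = FALSE)
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("vascular/bulk enrichment recovers planted ratios and uniqueness", {
  v <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("A|P1", "B|P2"), c("s1", "s2")))
  b <- v
  expect_equal(log2_enrichment(v, b)$proteins$mean_log2_ratio, c(0, 0))
  b2 <- v; v2 <- v; v2["A|P1", ] <- v2["A|P1", ] + 2
  expect_equal(log2_enrichment(v2, b2)$proteins$mean_log2_ratio[1], 2.0)
  expect_error(log2_enrichment(v[, 1, drop = FALSE], b[, 2, drop = FALSE]),
               "no paired samples")

  co <- test_cohort()
  bio <- co$design$sample[!co$design$is_gis]
  en <- log2_enrichment(co$vascular[, bio], co$bulk[, bio],
                        labels = co$truth$modules)
  shared <- en$proteins[en$proteins$uniqueness == "shared", ]
  planted <- co$truth$vascular_enrichment[shared$protein]
  resid_sd <- co$config$residual_sd
  se <- sqrt(2 * resid_sd^2 / length(bio))
  covered <- abs(shared$mean_log2_ratio - planted) < 3 * (se + 0.02)
  expect_gt(mean(covered), 0.95)
  expect_setequal(en$proteins$protein[en$proteins$uniqueness == "vascular"],
                  co$truth$unique_vascular)
  expect_setequal(en$proteins$protein[en$proteins$uniqueness == "bulk"],
                  co$truth$unique_bulk)
})

test_that("classifier protein selection equals the brute-force filter", {
  diff <- data.frame(protein = paste0("P", 1:6),
                     p_AD_vs_CTL = c(0.01, 0.01, 0.20, 0.01, 0.04, 0.001),
                     p_PSP_vs_CTL = c(0.02, 0.01, 0.01, 0.01, 0.06, 0.002),
                     p_PSP_vs_AD = c(0.03, 0.01, 0.01, 0.01, 0.01, 0.003))
  enr <- data.frame(protein = paste0("P", 1:6),
                    mean_log2_ratio = c(log2(3), log2(2.9), 5, NA, 4, 1),
                    uniqueness = c("shared", "shared", "shared", "vascular",
                                   "shared", "bulk"))
  got <- select_classifier_proteins(diff, enr, min_fold = 3, alpha = 0.05)
  oracle <- sapply(1:6, function(i) {
    sig <- all(c(diff$p_AD_vs_CTL[i], diff$p_PSP_vs_CTL[i],
                 diff$p_PSP_vs_AD[i]) < 0.05)
    elig <- identical(enr$uniqueness[i], "vascular") ||
      (!is.na(enr$mean_log2_ratio[i]) && enr$mean_log2_ratio[i] >= log2(3))
    sig && elig
  })
  expect_setequal(got, paste0("P", 1:6)[oracle])
  expect_true("P1" %in% got)    # exactly 3-fold, all p significant
  expect_false("P2" %in% got)   # 2.9-fold, not unique
})

test_that("reporter-channel scaling conserves the maximum column sum", {
  x <- matrix(c(10, 90, 40, 160), 2, 2,
              dimnames = list(c("pepA", "pepB"), c("c1", "c2")))
  xs <- normalize_reporter_channels(x)
  expect_equal(unname(colSums(xs)), c(200, 200))
  expect_equal(xs[, "c1"] / x[, "c1"], c(pepA = 2, pepB = 2))
  set.seed(66)
  for (i in 1:5) {
    r <- matrix(rexp(60, 1 / 100), 10, 6)
    colnames(r) <- paste0("c", 1:6)
    rs <- normalize_reporter_channels(r)
    expect_equal(unname(colSums(rs)), rep(max(colSums(r)), 6), tolerance = 1e-9)
  }
  one <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("p", 1:4), "c1"))
  expect_equal(normalize_reporter_channels(one), one)
  bad <- cbind(one, c2 = rep(0, 4))
  expect_error(normalize_reporter_channels(bad), "c2")
})

test_that("amyloid-beta ratios are extracted by exact peptide sequence", {
  pep <- c("GAIIGLMVGGVV", "GAIIGLMVGGVVIA", "OTHERPEPTIDE")
  v <- matrix(c(3, 1, 5,   4, 2, 5), 3, 2,
              dimnames = list(pep, c("s1", "s2")))
  b <- matrix(c(1, 1, 5,   2, 2, 5), 3, 2,
              dimnames = list(pep, c("s1", "s2")))
  ab <- abeta_ratios(v, b)
  expect_equal(unname(ab$ab40_ab42$vascular), c(2, 2))   # log2(8/2) = 2
  expect_equal(unname(ab$ab40_ab42$bulk), c(0, 0))
  expect_equal(unname(ab$vascular_over_bulk["Abeta40", ]), c(2, 2))
  expect_error(abeta_ratios(v[-1, ], b), "GAIIGLMVGGVV")
})
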
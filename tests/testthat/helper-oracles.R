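# Independent brute-force oracles used to validate the implementations.
# These are deliberately naive (loops, direct formulas) and share no code
# with the package internals.

# direct-formula biweight midcorrelation on a complete pair
oracle_bicor <- function(x, y) {
  tr <- function(v) {
    m <- median(v)
    mad <- median(abs(v - m))
    u <- (v - m) / (9 * mad)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - m) * w
  }
  a <- tr(x); b <- tr(y)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# triple-loop mean-denominator TOM
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / ((k[i] + k[j]) / 2 + 1 - a[i, j])
  }
  out
}

# hand-rolled UPGMA returning sorted merge heights
oracle_average_linkage_heights <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dm <- d
  heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- c(1L, 2L); bd <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (dm[i, j] < bd) { bd <- dm[i, j]; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    i <- best[1L]; j <- best[2L]
    ni <- length(active[[i]]); nj <- length(active[[j]])
    newrow <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)
    dm <- dm[-j, -j, drop = FALSE]
    newrow <- newrow[-j]
    dm[i, ] <- newrow; dm[, i] <- newrow; dm[i, i] <- 0
    active[[i]] <- c(active[[i]], active[[j]])
    active[[j]] <- NULL
  }
  sort(heights)
}

# exact hypergeometric upper-tail by direct summation of choose() terms
oracle_hyper_tail <- function(overlap, module_size, category_size, background) {
  hi <- min(module_size, category_size)
  if (overlap > hi) return(0)
  sum(vapply(overlap:hi, function(k)
    exp(lchoose(category_size, k) +
          lchoose(background - category_size, module_size - k) -
          lchoose(background, module_size)), numeric(1)))
}
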
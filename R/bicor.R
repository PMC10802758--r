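#' Biweight midcorrelation
#'
#' Outlier-robust correlation based on median/MAD Tukey-biweight
#' downweighting: with `m` the median and `MAD` the median absolute
#' deviation, `u_i = (x_i - m_x) / (9 MAD_x)`, weight
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (0 otherwise), transformed value
#' `x~_i = (x_i - m_x) w_i`, and
#' `bicor = sum(x~ y~) / sqrt(sum(x~^2) sum(y~^2))`.
#'
#' Only pairwise-complete observations are used; the medians and MADs are
#' computed on that complete subset.  If either vector has zero MAD the
#' pair falls back to Pearson correlation (with a warning), matching the
#' usual robust-correlation convention for tied data.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_obs Minimum paired non-missing observations (default 4);
#'   below it `NA` is returned with a warning.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
bicor <- function(x, y, min_obs = 4L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_obs) {
    warning(sprintf("only %d paired observations (< %d); returning NA",
                    sum(ok), min_obs))
    return(NA_real_)
  }
  x <- x[ok]; y <- y[ok]
  tx <- .bicor_transform(x)
  ty <- .bicor_transform(y)
  den <- sqrt(sum(tx$v^2)) * sqrt(sum(ty$v^2))
  if (den == 0) return(NA_real_)
  if (tx$pearson || ty$pearson)
    warning("zero MAD: falling back to Pearson weighting for this pair")
  sum(tx$v * ty$v) / den
}

# Tukey-biweight transform of one vector; zero-MAD vectors degrade to
# plain centering, which turns the correlation into Pearson for that side.
.bicor_transform <- function(x) {
  m <- stats::median(x)
  mad <- stats::median(abs(x - m))
  if (mad == 0) return(list(v = x - mean(x), pearson = TRUE))
  u <- (x - m) / (9 * mad)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  list(v = (x - m) * w, pearson = FALSE)
}

#' Biweight midcorrelation between the rows of two matrices
#'
#' Vectorized bicor of every row of `x` against every row of `y`
#' (`y = x` by default).  Each row is robust-transformed using the
#' median/MAD of its own non-missing values; missing entries contribute
#' zero and the normalization for each pair is restricted to the mutually
#' observed positions, giving a fast pairwise-complete estimate.  Rows
#' with zero MAD fall back to Pearson weighting.  Pairs with fewer than
#' `min_obs` shared observations are set to `fallback` (0 by default, a
#' neutral value for downstream signed adjacencies) with a warning.
#'
#' @param x Numeric matrix (variables in rows).
#' @param y Optional second matrix over the same columns.
#' @param min_obs Minimum shared observations per pair.
#' @param fallback Value assigned to under-observed pairs.
#' @return `nrow(x)` x `nrow(y)` correlation matrix.
#' @export
bicor_matrix <- function(x, y = NULL, min_obs = 4L, fallback = 0) {
  sym <- is.null(y)
  if (sym) y <- x
  stopifnot(ncol(x) == ncol(y))
  tx <- .bicor_transform_rows(x)
  ty <- if (sym) tx else .bicor_transform_rows(y)
  num <- tcrossprod(tx$v, ty$v)
  sx2 <- tcrossprod(tx$v^2, ty$obs)   # sum of x~^2 over positions observed in y
  sy2 <- tcrossprod(tx$obs, ty$v^2)
  den <- sqrt(sx2 * sy2)
  r <- num / den
  r[den == 0] <- NA_real_
  nobs <- tcrossprod(tx$obs, ty$obs)
  if (any(nobs < min_obs)) {
    warning(sum(nobs < min_obs), " pair(s) with < ", min_obs,
            " shared observations set to ", fallback)
    r[nobs < min_obs] <- fallback
  }
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(rownames(x), rownames(y))
  r
}

.bicor_transform_rows <- function(x) {
  obs <- is.finite(x)
  v <- x
  v[!obs] <- NA_real_
  m <- apply(v, 1L, stats::median, na.rm = TRUE)
  d <- v - m
  mad <- apply(abs(d), 1L, stats::median, na.rm = TRUE)
  out <- matrix(0, nrow(x), ncol(x))
  deg <- !is.finite(mad) | mad == 0
  if (any(!deg)) {
    u <- d[!deg, , drop = FALSE] / (9 * mad[!deg])
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    out[!deg, ] <- d[!deg, , drop = FALSE] * w
  }
  if (any(deg)) {
    # zero-MAD rows: plain centering (Pearson weighting)
    mu <- rowMeans(v[deg, , drop = FALSE], na.rm = TRUE)
    out[deg, ] <- v[deg, , drop = FALSE] - mu
  }
  out[!obs] <- 0
  list(v = out, obs = obs * 1)
}
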
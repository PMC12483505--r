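# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian smoothing of a regularly sampled vector
#'
#' Smooths with a discrete Gaussian kernel truncated at +/- 4 sigma and
#' renormalized at the edges (the kernel mass falling outside the vector is
#' redistributed, so constants are preserved everywhere).
#'
#' @param x numeric vector.
#' @param sigma_bins kernel standard deviation in bins (> 0).
#' @return smoothed numeric vector, same length as `x`.
#' @export
gauss_smooth <- function(x, sigma_bins = 2) {
  if (!is.numeric(sigma_bins) || length(sigma_bins) != 1L || sigma_bins <= 0)
    stop("gauss_smooth: 'sigma_bins' must be a single positive number")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- ceiling(4 * sigma_bins)
  k <- stats::dnorm(-half:half, sd = sigma_bins)
  k <- k / sum(k)
  pad <- rep(0, half)
  num <- stats::filter(c(pad, x, pad), k, sides = 2)
  den <- stats::filter(c(pad, rep(1, n), pad), k, sides = 2)
  idx <- (half + 1L):(half + n)
  as.numeric(num[idx] / den[idx])
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sample t-test on rate vectors
#'
#' Minimal equal-variance (Student) or Welch two-sample t-test used by the
#' selectivity classifier and its permutation nulls, where the overhead of
#' `stats::t.test` matters (it is cross-checked against `stats::t.test` in the
#' test suite).
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param var_equal pooled-variance Student test if TRUE (default), Welch
#'   otherwise.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
student_t2 <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (!is.finite(se) || se == 0)
    return(list(t = NA_real_, df = df, p = NA_real_))
  tt <- (mx - my) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' One-sided normal-tail p-value for a shuffle Z statistic
#'
#' Converts a Z score (observed statistic z-scored against its shuffle null)
#' into a p-value from the normal tail. `alternative = "greater"` gives the
#' upper tail, `"less"` the lower, `"two.sided"` doubles the smaller tail.
#'
#' @param z numeric Z score(s).
#' @param alternative tail convention.
#' @return p-value(s).
#' @export
z_to_p <- function(z, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  switch(alternative,
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z, lower.tail = TRUE),
    two.sided = 2 * stats::pnorm(-abs(z)))
}

# Deterministic CSV writer: fixed column order as given, no row names,
# no quoting (fields are simple tokens/numbers). Numbers are written with
# format() defaults, which are deterministic for identical doubles.
write_table_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pearson r of y against permuted 1..n indices for many shuffles at once.
# Returns a vector of shuffle r values. y must be non-constant.
perm_index_cors <- function(y, n_shuffles) {
  n <- length(y)
  zy <- (y - mean(y)) / stats::sd(y)
  idx <- seq_len(n)
  zx <- (idx - mean(idx)) / stats::sd(idx)
  out <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    out[s] <- sum(zx[sample.int(n)] * zy) / (n - 1)
  }
  out
}
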
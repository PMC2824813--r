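#' Kendall's tau-b with tie-corrected normal p-value
#'
#' Computes the tie-corrected rank correlation
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' where \eqn{C} and \eqn{D} are the concordant and discordant pair counts,
#' \eqn{n_0 = n(n-1)/2}, and \eqn{n_1}, \eqn{n_2} are the numbers of tied
#' pairs in `x` and `y`. Significance uses the normal approximation of
#' \eqn{C - D} with the standard tie-corrected variance; with country-tied
#' environmental variables ties are heavy and this correction matters. The
#' normal approximation is adequate for n above about 10, the size filter
#' applied by [scan_snps()].
#'
#' @param x,y Numeric vectors of equal length. Pairs with a missing value
#'   in either vector are dropped.
#' @return List with `tau`, `p_value` (two-sided), `statistic` (the normal
#'   z score) and `n_used`.
#' @examples
#' kendall_tau_b(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2L) stop("need at least two complete observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant input")

  rx <- rank(x); ry <- rank(y)
  # concordance via pairwise sign products
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
  num <- sum(s)                         # C - D

  tx <- tabulate(match(rx, unique(rx)))
  ty <- tabulate(match(ry, unique(ry)))
  kt <- kendall_var(n, tx, ty)
  tau <- num / sqrt((kt$n0 - kt$n1) * (kt$n0 - kt$n2))
  z <- num / sqrt(kt$v)
  list(tau = tau, p_value = 2 * stats::pnorm(-abs(z)), statistic = z, n_used = n)
}

# tie-corrected variance of C - D plus tie-pair counts; tx/ty are tie-group
# sizes of x and y
kendall_var <- function(n, tx, ty) {
  n0 <- n * (n - 1) / 2
  t1x <- sum(tx * (tx - 1)); t1y <- sum(ty * (ty - 1))
  t2x <- sum(tx * (tx - 1) * (tx - 2)); t2y <- sum(ty * (ty - 1) * (ty - 2))
  vtx <- sum(tx * (tx - 1) * (2 * tx + 5)); vty <- sum(ty * (ty - 1) * (2 * ty + 5))
  v <- (n * (n - 1) * (2 * n + 5) - vtx - vty) / 18 +
    t2x * t2y / (9 * n * (n - 1) * (n - 2)) +
    t1x * t1y / (2 * n * (n - 1))
  list(n0 = n0, n1 = t1x / 2, n2 = t1y / 2, v = v)
}

#' Partial Kendall rank correlation
#'
#' Correlation between `x` and `y` after removing the rank association of
#' both with `z`, through the closed form
#' \deqn{\tau_{xy\cdot z} = (\tau_{xy} - \tau_{xz}\tau_{yz}) /
#'   \sqrt{(1-\tau_{xz}^2)(1-\tau_{yz}^2)}.}
#' Significance is assessed by plugging the partial coefficient into the
#' same tie-corrected normal approximation used for the plain coefficient;
#' this is a documented approximation, not an exact null distribution.
#'
#' @param x,y,z Numeric vectors of equal length (complete cases used).
#' @return List with `tau` (the partial coefficient), `p_value`,
#'   `statistic` and `n_used`.
#' @export
partial_kendall <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("'x', 'y' and 'z' must have equal length")
  ok <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  txy <- kendall_tau_b(x, y)
  txz <- kendall_tau_b(x, z)
  tyz <- kendall_tau_b(y, z)
  if (abs(txz$tau) >= 1 || abs(tyz$tau) >= 1)
    stop("degenerate covariate: |tau| with the conditioning variable is 1")
  tp <- (txy$tau - txz$tau * tyz$tau) /
    sqrt((1 - txz$tau^2) * (1 - tyz$tau^2))
  # reuse the scale of the plain coefficient: z = tau_p / sd(tau_xy)
  se <- if (txy$tau != 0 && is.finite(txy$statistic) && txy$statistic != 0)
    abs(txy$tau / txy$statistic) else tau_se_no_ties(length(x))
  zstat <- tp / se
  list(tau = tp, p_value = 2 * stats::pnorm(-abs(zstat)),
       statistic = zstat, n_used = length(x))
}

tau_se_no_ties <- function(n) sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))

# Vectorised tau-b of every row of X against a fixed y with no missing
# cells. Returns tau, p, z, plus a logical vector of rows where the
# correlation is undefined (constant row).
kendall_rows <- function(X, y) {
  n <- ncol(X)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  sy <- sign(y[i] - y[j])
  ry <- rank(y)
  ty <- tabulate(match(ry, unique(ry)))

  nsnp <- nrow(X)
  tau <- p <- z <- rep(NA_real_, nsnp)
  undefined <- logical(nsnp)
  chunk <- max(1L, floor(2e6 / length(i)))
  for (start in seq(1L, nsnp, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nsnp)
    sx <- sign(X[idx, i, drop = FALSE] - X[idx, j, drop = FALSE])
    num <- as.vector(sx %*% sy)
    xtie_pairs <- as.vector(rowSums(sx == 0))
    n0 <- n * (n - 1) / 2

    # rows without ties in x take the closed form directly
    plain <- xtie_pairs == 0
    kt0 <- kendall_var(n, rep(1L, n), ty)
    if (any(plain)) {
      k <- idx[plain]
      tau[k] <- num[plain] / sqrt(n0 * (n0 - kt0$n2))
      z[k] <- num[plain] / sqrt(kt0$v)
    }
    if (any(!plain)) {
      for (r in which(!plain)) {
        k <- idx[r]
        xr <- X[k, ]
        if (length(unique(xr)) < 2L) { undefined[k] <- TRUE; next }
        tx <- tabulate(match(xr, unique(xr)))
        kt <- kendall_var(n, tx, ty)
        tau[k] <- num[r] / sqrt((kt$n0 - kt$n1) * (kt$n0 - kt$n2))
        z[k] <- num[r] / sqrt(kt$v)
      }
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  list(tau = tau, p_value = p, statistic = z, undefined = undefined)
}
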
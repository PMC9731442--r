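#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its empirical
#' distribution function and any unimodal distribution function. It is computed
#' here by the iterative greatest-convex-minorant / least-concave-majorant
#' algorithm: the candidate modal interval is shrunk until the maximal gap
#' between the two hulls no longer exceeds the deviations accumulated in the
#' tails. Ties are handled by working on the unique values with the ECDF's
#' lower and upper step values as the two hull targets.
#'
#' @param x numeric vector (at least 2 finite values for a nonzero result).
#' @return the dip statistic, a scalar in `[0, 0.25]`.
#' @export
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(0)
  ux <- unique(x)
  cnt <- tabulate(match(x, ux))
  cum <- cumsum(cnt)
  m <- length(ux)
  ylo <- (cum - cnt) / n
  yhi <- cum / n
  interp <- function(ii, ys, at) {
    if (length(ii) == 1) return(rep(ys[ii], length(at)))
    approx(ux[ii], ys[ii], xout = at, rule = 2, ties = "ordered")$y
  }
  low <- 1L; high <- m; D <- 0; d <- 0
  repeat {
    idx <- low:high
    g <- idx[.lower_hull(ux[idx], ylo[idx])]
    l <- idx[.upper_hull(ux[idx], yhi[idx])]
    cand <- sort(unique(c(g, l)))
    gap <- interp(l, yhi, ux[cand]) - interp(g, ylo, ux[cand])
    d <- max(gap)
    im <- cand[which.max(gap)]
    if (d <= D) break
    ig <- max(g[g <= im]); ih <- min(l[l >= im])
    dl <- if (ig > low) max(yhi[low:ig] - interp(g, ylo, ux[low:ig])) else 0
    du <- if (ih < high) max(interp(l, yhi, ux[ih:high]) - ylo[ih:high]) else 0
    D <- max(D, dl, du)
    if (ig == low && ih == high) { D <- max(D, d); break }
    low <- ig; high <- ih
  }
  max(D, d) / 2
}

# greatest convex minorant / least concave majorant touch points
# (monotone-chain hulls; cross products avoid divisions so tied slopes are safe)
.lower_hull <- function(xs, ys) {
  h <- integer(0)
  for (i in seq_along(xs)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1]; b <- h[length(h)]
      if ((ys[b] - ys[a]) * (xs[i] - xs[b]) >=
          (ys[i] - ys[b]) * (xs[b] - xs[a])) h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  h
}

.upper_hull <- function(xs, ys) {
  h <- integer(0)
  for (i in seq_along(xs)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1]; b <- h[length(h)]
      if ((ys[b] - ys[a]) * (xs[i] - xs[b]) <=
          (ys[i] - ys[b]) * (xs[b] - xs[a])) h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  h
}

#' Bootstrap dip test of unimodality
#'
#' Compares the sample's dip with the dip distribution of uniform samples of
#' the same size (the standard calibration: among unimodal laws the uniform
#' maximises the dip's null distribution). Integer-valued data (e.g. read
#' depths) are jittered by `U(-0.5, 0.5)` so the continuous reference applies.
#'
#' @param x numeric vector.
#' @param n_boot number of uniform reference samples.
#' @param seed integer seed controlling jitter and resampling.
#' @param max_n dips are computed on at most this many values (random
#'   subsample) to bound cost on long depth vectors.
#' @return list with elements `statistic`, `p_value`, `n_boot`, `n_used`.
#' @export
dip_test <- function(x, n_boot = 200, seed = 1L, max_n = 5000L) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values")
  res <- local_seed(seed, {
    if (length(x) > max_n) x <- sample(x, max_n)
    if (anyDuplicated(x)) {
      # lattice/tied data: break ties at half the smallest positive gap so
      # the continuous uniform reference distribution applies
      g <- min(diff(sort(unique(x))))
      x <- x + runif(length(x), -g / 2, g / 2)
    }
    d <- dip_statistic(x)
    ref <- vapply(seq_len(n_boot),
                  function(i) dip_statistic(runif(length(x))), 0)
    list(statistic = d, p_value = (1 + sum(ref >= d)) / (n_boot + 1),
         n_used = length(x))
  })
  res$n_boot <- n_boot
  res
}

# evaluate an expression under a temporary RNG state
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
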
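#' Gower-centred kernel from a distance matrix
#'
#' Double-centres \eqn{-\tfrac12 D^2} (the classical transform turning a
#' squared-distance matrix into an inner-product matrix) and scales the
#' result to trace `n`, the trace of the identity residual, so estimated
#' variance components are directly comparable across kernels.
#'
#' @param D symmetric distance matrix.
#' @return symmetric positive semi-definite kernel matrix (negative
#'   eigenvalues, which arise when `D` is not Euclidean, are clipped with a
#'   warning).
#' @export
gower_kernel <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - 1 / n
  K <- -0.5 * J %*% (D^2) %*% J
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    warning("non-PSD kernel after centring; negative eigenvalues clipped")
    K <- ev$vectors %*% diag(pmax(ev$values, 0)) %*% t(ev$vectors)
  }
  tr <- sum(diag(K))
  if (tr <= 0) stop("degenerate (zero-trace) kernel")
  K * (n / tr)
}

# rank-1 kernel over pair observations: Gower centring of the squared
# differences of the pairwise-distance vector collapses to the centred outer
# product of that vector
.pair_kernel <- function(D) {
  v <- D[lower.tri(D)]
  u <- v - mean(v)
  K <- outer(u, u)
  tr <- sum(diag(K))
  if (tr <= 0) stop("degenerate pair kernel (constant distances)")
  K * (length(v) / tr)
}

#' Variance components by EM-REML over kernel matrices
#'
#' Fits \eqn{y \sim N(1\mu, \sum_k \sigma^2_k K_k + \sigma^2_e I)} by
#' restricted maximum likelihood using the expectation-maximisation update
#' with nonnegativity clipping, and returns each component's share of the
#' total random variance. With fewer than `min_em` observations a
#' Haseman-Elston-style method-of-moments fit (least squares of the outer
#' product of centred `y` on the kernels) is used instead, as EM-REML is
#' unstable on a handful of points.
#'
#' @param y numeric response vector.
#' @param kernels named list of symmetric kernel matrices (trace-normalised,
#'   e.g. from [gower_kernel()]).
#' @param max_iter,tol EM controls.
#' @param min_em observation threshold below which the method-of-moments
#'   fallback is used.
#' @return list `proportions` (named, includes `residual`; sums to 1),
#'   `sigma2` (variance components), `fixed_share` (share of the total mean
#'   square attributable to the fitted intercept), `converged`,
#'   `iterations`, `method`.
#' @export
fit_variance_components <- function(y, kernels, max_iter = 5000,
                                    tol = 1e-6, min_em = 6) {
  m <- length(y)
  if (is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_along(kernels))
  for (K in kernels)
    if (!all(dim(K) == m)) stop("kernel not conformable with response")
  Ks <- c(kernels, list(residual = diag(m)))
  k <- length(Ks)
  if (m < min_em || k >= m) {
    # tiny designs, or at least as many components as observations: REML is
    # unidentifiable there, so use the moment fit
    s2 <- .mom_components(y, Ks)
    meth <- "method-of-moments"; conv <- TRUE; it <- 0L
  } else {
    ranks <- vapply(Ks, function(K)
      sum(eigen(K, symmetric = TRUE, only.values = TRUE)$values >
            1e-8 * m), 0)
    X <- matrix(1, m, 1)
    s2 <- rep(max(var(y), 1e-8) / k, k)
    conv <- FALSE; it <- 0L
    floor_s2 <- 1e-10
    ll_old <- -Inf
    while (it < max_iter) {
      it <- it + 1L
      V <- Reduce(`+`, Map(`*`, Ks, s2))
      ch <- tryCatch(chol(V), error = function(e)
        stop("variance-component fit failed: singular covariance at ",
             "iteration ", it))
      Vi <- chol2inv(ch)
      XtViX <- crossprod(X, Vi %*% X)
      P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
      Py <- P %*% y
      # restricted log-likelihood, used as the convergence criterion: a
      # component crawling toward the zero boundary changes it negligibly
      ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
                      sum(y * Py))
      new <- s2
      for (j in seq_len(k)) {
        new[j] <- s2[j] + s2[j]^2 *
          (sum(Py * (Ks[[j]] %*% Py)) - sum(P * Ks[[j]])) / ranks[j]
      }
      # pin vanishing components so the rest can settle
      new[new < 1e-6 * sum(new)] <- floor_s2
      s2 <- new
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) { conv <- TRUE; break }
      ll_old <- ll
    }
    if (!conv)
      stop("EM-REML did not converge after ", max_iter, " iterations; ",
           "last components: ", paste(signif(s2, 4), collapse = ", "))
    meth <- "EM-REML"
  }
  names(s2) <- names(Ks)
  contrib <- s2 * vapply(Ks, function(K) sum(diag(K)), 0)
  if (sum(contrib) <= 0) {
    props <- stats::setNames(c(rep(0, k - 1), 1), names(Ks))
  } else {
    props <- contrib / sum(contrib)
  }
  mu <- mean(y)
  fixed_share <- (m * mu^2) / (m * mu^2 + sum((y - mu)^2))
  list(proportions = props, sigma2 = s2, fixed_share = fixed_share,
       converged = conv, iterations = it, method = meth)
}

# least-squares fit of vech(y_c y_c') on vech of the kernels
.mom_components <- function(y, Ks) {
  yc <- y - mean(y)
  S <- outer(yc, yc)
  lt <- lower.tri(S, diag = TRUE)
  Xm <- vapply(Ks, function(K) K[lt], numeric(sum(lt)))
  fit <- stats::lm.fit(Xm, S[lt])
  co <- fit$coefficients
  co[is.na(co)] <- 0          # unidentifiable under rank deficiency
  pmax(co, 0)
}

#' Partition genomic variance over environmental and geographic distances
#'
#' The response is the vectorised upper triangle of the median pairwise-FST
#' matrix; each named distance matrix contributes a covariance kernel over
#' the pair observations (Gower centring of the squared pairwise-distance
#' differences, which collapses to the centred outer product of the distance
#' vector), plus an identity residual. Components are estimated by
#' [fit_variance_components()] and each variable's share of the genomic
#' variance is reported, with an independent one-sided [mantel_test()] per
#' variable as verification.
#'
#' @param fst_matrix symmetric median pairwise-FST matrix (samples x
#'   samples), e.g. `pairwise_fst(...)$median_matrix`.
#' @param distances named list of symmetric distance matrices over the same
#'   samples (environmental variables, geographic distance).
#' @param n_perm,seed Mantel-test controls.
#' @param residual_warn warn when the residual share exceeds this fraction
#'   (weakly identified model).
#' @return an object of class `variance_partition`: list `proportions`
#'   (per variable + `residual`), `sigma2`, `fixed_share`, `mantel`
#'   (data.frame `variable`, `r`, `p`), `method`, `n_pairs`.
#' @export
variance_partition <- function(fst_matrix, distances, n_perm = 999,
                               seed = 1L, residual_warn = 0.3) {
  m <- as.matrix(fst_matrix)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples (3 pairs)")
  if (is.null(names(distances)) || any(!nzchar(names(distances))))
    stop("'distances' must be a named list")
  for (D in distances)
    if (!all(dim(as.matrix(D)) == n))
      stop("distance matrix not conformable with the FST matrix")
  diag(m) <- 0
  y <- m[lower.tri(m)]
  kernels <- lapply(distances, function(D) .pair_kernel(as.matrix(D)))
  fit <- fit_variance_components(y, kernels)
  mantel <- do.call(rbind, lapply(names(distances), function(v) {
    mt <- mantel_test(m, as.matrix(distances[[v]]), n_perm = n_perm,
                      seed = seed)
    data.frame(variable = v, r = mt$r, p = mt$p)
  }))
  if (fit$proportions[["residual"]] > residual_warn)
    warning(sprintf(
      "residual share %.0f%% exceeds %.0f%%: the model is weakly identified at this sample size",
      100 * fit$proportions[["residual"]], 100 * residual_warn))
  structure(list(proportions = fit$proportions, sigma2 = fit$sigma2,
                 fixed_share = fit$fixed_share, mantel = mantel,
                 method = fit$method, n_pairs = length(y)),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> %d pairs, %s\n", x$n_pairs, x$method))
  print(round(x$proportions, 3))
  invisible(x)
}
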
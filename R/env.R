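#' Preprocess an environmental metadata table
#'
#' Applies the standard cleaning for isolation-by-environment analyses of
#' oceanographic station data: ammonium is dropped (redundant with the other
#' nitrogen species), nitrate and nitrite are summed into a single
#' `nitrate_nitrite` variable, and every retained variable is z-scored.
#' Collinearity is *reported*, not acted on: pairwise Spearman correlations
#' (flagged at `p < 0.01`) and variance inflation factors (flagged at
#' `>= 10`); flagged variables are retained.
#'
#' @param env data.frame of samples x variables; recognised variable columns
#'   are `temperature`, `salinity`, `oxygen`, `ammonium`, `iron`, `nitrate`,
#'   `nitrite`, `phosphate`, `silicate` (others are passed through
#'   untouched if numeric, z-scored as well).
#' @param drop list of variables to drop (default `ammonium`).
#' @return list with `env` (z-scored data.frame), `correlations` (list of
#'   `rho`, `p`, `flagged`), `vif` (named vector with attribute `flagged`),
#'   `dropped` (variables removed because constant).
#' @export
preprocess_env <- function(env, drop = "ammonium") {
  if (nrow(env) < 3) stop("need at least 3 samples")
  num <- vapply(env, is.numeric, TRUE)
  vars <- env[num]
  vars <- vars[!names(vars) %in% drop]
  if (all(c("nitrate", "nitrite") %in% names(vars))) {
    vars$nitrate_nitrite <- vars$nitrate + vars$nitrite
    vars$nitrate <- vars$nitrite <- NULL
  }
  const <- vapply(vars, function(v) stats::sd(v) == 0, TRUE)
  if (any(const)) {
    warning("constant variable(s) dropped (z-score undefined): ",
            paste(names(vars)[const], collapse = ", "))
    vars <- vars[!const]
  }
  # population-sd z-scores: mean 0, root-mean-square deviation 1
  z <- as.data.frame(lapply(vars, function(v) {
    c <- v - mean(v)
    c / sqrt(mean(c^2))
  }))
  rownames(z) <- rownames(env)
  k <- ncol(z)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(names(z), names(z)))
  diag(rho) <- 1; diag(p) <- 0
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ct <- suppressWarnings(cor.test(z[[i]], z[[j]], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  vif <- vapply(seq_len(k), function(i) {
    if (k == 1) return(1)
    fit <- stats::lm(z[[i]] ~ ., data = z[-i])
    r2 <- summary(fit)$r.squared
    if (is.na(r2) || r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- names(z)
  attr(vif, "flagged") <- names(vif)[vif >= 10]
  list(env = z,
       correlations = list(rho = rho, p = p,
                           flagged = which(p < 0.01 & upper.tri(p),
                                           arr.ind = TRUE)),
       vif = vif,
       dropped = names(const)[const])
}

#' Euclidean distance matrix between samples
#'
#' @param x numeric vector, matrix or data.frame (samples in rows).
#' @return symmetric matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(x) {
  m <- as.matrix(x)
  if (anyNA(m)) {
    bad <- rownames(m)[rowSums(is.na(m)) > 0]
    if (is.null(bad)) bad <- which(rowSums(is.na(m)) > 0)
    stop("missing value(s) for sample(s): ", paste(bad, collapse = ", "))
  }
  as.matrix(dist(m))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles with a one-sided permutation
#' p-value: rows and columns of `B` are permuted together and
#' `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`, the standard test for
#' isolation by distance / environment.
#'
#' @param A,B symmetric distance matrices over the same samples.
#' @param n_perm number of permutations.
#' @param seed RNG seed (the p-value is bit-reproducible given `seed` and
#'   `n_perm`).
#' @return list `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 9999, seed = 1L) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("matrices must have identical dimensions")
  n <- nrow(A)
  lt <- lower.tri(A)
  a <- A[lt]
  if (stats::sd(a) == 0 || stats::sd(B[lt]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- cor(a, B[lt])
  count <- local_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      rp <- cor(a, B[pm, pm][lt])
      if (rp >= r_obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(r = r_obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm)
}
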
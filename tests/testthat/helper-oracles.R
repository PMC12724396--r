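# Independent oracles and simulation helpers shared across test files.
# These deliberately use naive/brute-force computations (explicit loops,
# dense matrices, grid searches) so they exercise a different code path
# than the package implementation.

# brute-force cross-basis response: f(t) = sum_l sum_jk c_jk B_j(x[t-l]) L_k(l)
bf_crossbasis_response <- function(x, coef, var_spec, lag_spec) {
  bvar <- bspline_basis(x, var_spec)
  blag <- natural_cubic_basis(0:lag_spec$max_lag, knots = lag_spec$knots,
                              boundary = lag_spec$boundary,
                              intercept = TRUE)
  nv <- ncol(bvar); nl <- ncol(blag)
  out <- rep(NA_real_, length(x))
  for (t in seq_along(x)) {
    if (t <= lag_spec$max_lag) next
    acc <- 0
    for (l in 0:lag_spec$max_lag) {
      for (j in seq_len(nv)) {
        for (k in seq_len(nl)) {
          acc <- acc + coef[(j - 1L) * nl + k] * bvar[t - l, j] *
            blag[l + 1L, k]
        }
      }
    }
    out[t] <- acc
  }
  out
}

# brute-force overall cumulative log-RR at a constant exposure x:
# all lags held at x, summed over the lag dimension
bf_overall_logrr <- function(x, coef, var_spec, lag_spec) {
  bvar <- bspline_basis(x, var_spec)
  blag <- natural_cubic_basis(0:lag_spec$max_lag, knots = lag_spec$knots,
                              boundary = lag_spec$boundary,
                              intercept = TRUE)
  nv <- ncol(bvar); nl <- ncol(blag)
  vapply(seq_along(x), function(i) {
    acc <- 0
    for (l in 0:lag_spec$max_lag) {
      for (j in seq_len(nv)) {
        for (k in seq_len(nl)) {
          acc <- acc + coef[(j - 1L) * nl + k] * bvar[i, j] *
            blag[l + 1L, k]
        }
      }
    }
    acc
  }, 0)
}

# dense multivariate-normal log-density of the whole meta dataset:
# one big block-diagonal covariance, generic determinant/solve path
dense_meta_loglik <- function(beta, psi, dataset, formula) {
  p <- dataset$p
  mm <- model.matrix(formula, dataset$covs)
  n <- nrow(dataset$covs)
  cities <- dataset$covs$city
  y <- as.numeric(t(dataset$theta))
  X <- kronecker(mm, diag(p))
  V <- matrix(0, n * p, n * p)
  for (i in seq_len(n)) {
    ri <- ((i - 1L) * p + 1L):(i * p)
    V[ri, ri] <- dataset$S[[i]]
    for (j in seq_len(n)) {
      if (cities[i] != cities[j]) next
      rj <- ((j - 1L) * p + 1L):(j * p)
      zi <- cbind(1, dataset$covs$time[i])
      zj <- cbind(1, dataset$covs$time[j])
      # Z_i D Z_j' with D = diag(psi) acting blockwise on coordinates
      blk <- diag(psi[1:p], p) * drop(zi[1] * zj[1]) +
        diag(psi[(p + 1):(2 * p)], p) * drop(zi[2] * zj[2])
      V[ri, rj] <- V[ri, rj] + blk
    }
  }
  r <- y - drop(X %*% beta)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + sum(r * solve(V, r)))
}

# 1-D random-effects meta-analysis ML oracle: intercept-only model,
# profile log-likelihood over tau^2 maximised by a two-pass grid search
grid_re_ml <- function(theta, s2, tau2_max = NULL) {
  prof <- function(tau2) {
    w <- 1 / (s2 + tau2)
    mu <- sum(w * theta) / sum(w)
    sum(stats::dnorm(theta, mu, sqrt(s2 + tau2), log = TRUE))
  }
  if (is.null(tau2_max)) tau2_max <- 5 * stats::var(theta)
  g1 <- seq(0, tau2_max, length.out = 2001L)
  v1 <- vapply(g1, prof, 0)
  t1 <- g1[which.max(v1)]
  lo <- max(0, t1 - 2 * diff(g1[1:2]))
  g2 <- seq(lo, t1 + 2 * diff(g1[1:2]), length.out = 4001L)
  v2 <- vapply(g2, prof, 0)
  list(tau2 = g2[which.max(v2)], loglik = max(v2), mu = {
    w <- 1 / (s2 + g2[which.max(v2)])
    sum(w * theta) / sum(w)
  })
}

# simulate a meta-level dataset from the Model-3 structure
sim_meta_data <- function(n_cities = 30L, n_sub = 8L, p = 4L,
                          beta_hpp = rep(0, 4L), psi_int = 0.02,
                          psi_time = 5e-4, s_scale = 0.05, seed = 1L) {
  set.seed(seed)
  regions <- c("Northern", "Eastern", "Western", "Southern")
  reg <- factor(rep(regions, length.out = n_cities), levels = regions)
  covs <- data.frame(
    city = rep(sprintf("c%02d", seq_len(n_cities)), each = n_sub),
    region = rep(reg, each = n_sub),
    subperiod = rep(seq_len(n_sub), n_cities),
    time = rep(seq(-10.5, 10.5, length.out = n_sub), n_cities),
    hpp = as.numeric(rep(seq_len(n_sub), n_cities) >
                       rep(sample(seq_len(n_sub - 1L), n_cities, TRUE),
                           each = n_sub)),
    stringsAsFactors = FALSE)
  mm0 <- stats::model.matrix(~ region * time, covs)
  bmat <- matrix(stats::rnorm(ncol(mm0) * p, 0, 0.2), ncol = p)
  n <- nrow(covs)
  S <- replicate(n, {
    a <- matrix(stats::rnorm(p * p, 0, s_scale), p)
    crossprod(a) + diag(s_scale^2, p)
  }, simplify = FALSE)
  theta <- mm0 %*% bmat + outer(covs$hpp, beta_hpp)
  for (ci in unique(covs$city)) {
    idx <- which(covs$city == ci)
    bi <- stats::rnorm(p, 0, sqrt(psi_int))
    bt <- stats::rnorm(p, 0, sqrt(psi_time))
    for (i in idx) {
      theta[i, ] <- theta[i, ] + bi + covs$time[i] * bt +
        MASS::mvrnorm(1L, rep(0, p), S[[i]])
    }
  }
  list(dataset = meta_dataset(theta, S, covs),
       beta_region = bmat, beta_hpp = beta_hpp,
       psi = c(rep(psi_int, p), rep(psi_time, p)))
}

# tiny synthetic cohort used by several test files
small_cohort <- function(n_cities = 6L, years = c(2004L, 2015L),
                         hpp_effect = 0.7, seed = 99L, ...) {
  build_cohort(truth_params(n_cities = n_cities, years = years,
                            hpp_effect = hpp_effect, seed = seed, ...))
}
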
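#' Assemble the second-stage meta-regression dataset
#'
#' Combines the reduced first-stage coefficients (one 4-vector outcome
#' plus its 4x4 within-unit covariance per city-subperiod) with the
#' unit-level covariates: the subperiod HPP indicator (from the
#' catalogue's implementation years), region, HPP class, and `Time` (the
#' subperiod midpoint year centered at the grand mean).
#'
#' @param stage1 a `"stage1_fits"` object from [first_stage()].
#' @param catalogue HPP catalogue (see [validate_catalogue()]).
#'
#' @return Object of class `"meta_dataset"`: list with `theta` (n x p
#'   outcome matrix), `S` (list of within-unit covariances), `covs`
#'   (unit covariates), `time_center`, plus the percentile tables and
#'   basis specs carried through for stage 3.
#' @export
assemble_meta_dataset <- function(stage1, catalogue) {
  stopifnot(inherits(stage1, "stage1_fits"))
  catalogue <- validate_catalogue(catalogue)
  fits <- stage1$fits
  if (!length(fits)) stop("no converged first-stage fits")
  ctries <- unique(vapply(fits, `[[`, "", "country"))
  missing <- setdiff(ctries, catalogue$country)
  if (length(missing))
    stop("country missing from catalogue: ",
         paste(missing, collapse = ", "))
  p <- length(fits[[1L]]$coef)
  theta <- t(vapply(fits, `[[`, numeric(p), "coef"))
  S <- lapply(fits, `[[`, "vcov")
  for (i in seq_along(S)) {
    if (!is_psd(S[[i]], tol = 1e-8 * max(1, max(abs(S[[i]])))))
      stop("within-unit covariance not PSD for unit ", i)
  }
  ci <- match(vapply(fits, `[[`, "", "country"), catalogue$country)
  start_year <- vapply(fits, `[[`, 0, "start_year")
  end_year <- vapply(fits, `[[`, 0, "end_year")
  hpp_year <- catalogue$hpp_year[ci]
  rule <- stage1$config$indicator_rule
  hpp <- mapply(function(iy, sy, ey) hpp_indicator(iy, sy, ey,
                                                   rule = rule),
                hpp_year, start_year, end_year)
  mid <- vapply(fits, `[[`, 0, "mid_time")
  tc <- mean(mid)
  covs <- data.frame(
    city = vapply(fits, `[[`, "", "city_id"),
    country = vapply(fits, `[[`, "", "country"),
    region = factor(vapply(fits, `[[`, "", "region")),
    hppclass = factor(catalogue$hpp_class[ci], levels = 1:3),
    subperiod = vapply(fits, `[[`, 0L, "subperiod"),
    start_year = start_year, end_year = end_year,
    mid_time = mid, time = mid - tc, hpp = as.numeric(hpp),
    population = vapply(fits, `[[`, 0, "population"),
    mmt_pct = vapply(fits, `[[`, 0, "mmt_pct"),
    n_years = vapply(fits, `[[`, 0, "n_years"),
    stringsAsFactors = FALSE)
  structure(list(theta = theta, S = S, covs = covs, p = p,
                 time_center = tc, city_tables = stage1$city_tables,
                 var_spec = stage1$var_spec, config = stage1$config),
            class = "meta_dataset")
}

#' Construct a meta-dataset directly from components
#'
#' Mostly used for simulation studies at the meta level (and by the
#' test-suite oracles): supply outcomes, within-unit covariances and
#' covariates without running stage 1.
#'
#' @param theta n x p outcome matrix.
#' @param S list of n within-unit covariance matrices (p x p, PSD).
#' @param covs data.frame with at least `city` and `time`.
#' @param var_spec optional exposure basis spec (needed for stage 3).
#' @param city_tables optional percentile tables (needed for stage 3).
#' @param config optional [run_config()].
#' @return A `"meta_dataset"`.
#' @export
meta_dataset <- function(theta, S, covs, var_spec = NULL,
                         city_tables = NULL, config = run_config()) {
  theta <- as.matrix(theta)
  if (length(S) != nrow(theta)) stop("'S' must have one entry per unit")
  for (i in seq_along(S)) {
    S[[i]] <- as.matrix(S[[i]])
    if (!is_psd(S[[i]], tol = 1e-8 * max(1, max(abs(S[[i]])))))
      stop("within-unit covariance not PSD for unit ", i)
  }
  if (is.null(covs$time)) stop("'covs' must contain 'time'")
  if (is.null(covs$city)) stop("'covs' must contain 'city'")
  if (anyNA(covs)) stop("covariates must be complete")
  structure(list(theta = theta, S = S, covs = covs, p = ncol(theta),
                 time_center = 0, city_tables = city_tables,
                 var_spec = var_spec, config = config),
            class = "meta_dataset")
}

# model registry: fixed-effect formulas on the unit covariates
meta_formula <- function(model) {
  if (inherits(model, "formula")) return(model)
  switch(model,
         model3 = ~ hpp + region * time,
         model3_nohpp = ~ region * time,
         model4 = ~ hpp + hpp:region + region * time,
         model5 = ~ hpp:hppclass + region * time,
         stop("unknown model id: ", model))
}

# per-city precomputed structures for the marginal likelihood
meta_parts <- function(dataset, formula) {
  p <- dataset$p
  mf <- stats::model.frame(formula, dataset$covs)
  trms <- attr(mf, "terms")
  mm <- stats::model.matrix(trms, mf)
  xlev <- stats::.getXlevels(trms, mf)
  cities <- unique(dataset$covs$city)
  parts <- vector("list", length(cities))
  names(parts) <- cities
  for (ic in seq_along(cities)) {
    idx <- which(dataset$covs$city == cities[ic])
    nc <- length(idx)
    y <- as.numeric(t(dataset$theta[idx, , drop = FALSE]))
    X <- kronecker(mm[idx, , drop = FALSE], diag(p))
    Z <- kronecker(cbind(1, dataset$covs$time[idx]), diag(p))
    S <- matrix(0, nc * p, nc * p)
    for (i in seq_len(nc)) {
      r <- ((i - 1L) * p + 1L):(i * p)
      S[r, r] <- dataset$S[[idx[i]]]
    }
    parts[[ic]] <- list(y = y, X = X, Z = Z, S = S, idx = idx)
  }
  list(parts = parts, mm = mm, terms = trms, xlev = xlev, p = p,
       q = ncol(mm), n_units = nrow(dataset$covs),
       cities = cities)
}

# core evaluation: marginal log-likelihood pieces for a given psi;
# returns either the profiled-GLS solution or the loglik at fixed beta.
# With grad = TRUE also returns d loglik / d psi at the (profiled) beta
# via the envelope identity
#   d ll / d psi_k = 0.5 * sum_c [ (z_k' V^-1 r)^2 - z_k' V^-1 z_k ]
# where z_k is the k-th random-effect design column.
meta_ll_core <- function(parts, psi, beta = NULL, grad = FALSE) {
  qp <- ncol(parts$parts[[1L]]$X)
  nre <- ncol(parts$parts[[1L]]$Z)
  xtvx <- matrix(0, qp, qp)
  xtvy <- numeric(qp)
  yty <- 0; logdet <- 0; ntot <- 0L
  ncities <- length(parts$parts)
  if (grad) { axs <- vector("list", ncities); ays <- axs; azs <- axs }
  for (ic in seq_len(ncities)) {
    pc <- parts$parts[[ic]]
    V <- pc$S + pc$Z %*% (psi * t(pc$Z))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch))
      stop("singular marginal covariance for city ", pc$idx[1L])
    A <- backsolve(ch, cbind(pc$X, pc$y, pc$Z), transpose = TRUE)
    Lx <- A[, seq_len(qp), drop = FALSE]
    Ly <- A[, qp + 1L]
    xtvx <- xtvx + crossprod(Lx)
    xtvy <- xtvy + crossprod(Lx, Ly)
    yty <- yty + sum(Ly^2)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    ntot <- ntot + length(pc$y)
    if (grad) {
      axs[[ic]] <- Lx; ays[[ic]] <- Ly
      azs[[ic]] <- A[, (qp + 2L):(qp + 1L + nre), drop = FALSE]
    }
  }
  if (is.null(beta)) {
    beta <- tryCatch(solve(xtvx, xtvy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
  }
  quad <- yty - 2 * sum(beta * xtvy) + sum(beta * (xtvx %*% beta))
  ll <- -0.5 * (ntot * log(2 * pi) + logdet + quad)
  out <- list(ll = ll, beta = drop(beta), xtvx = xtvx)
  if (grad) {
    g <- numeric(nre)
    for (ic in seq_len(ncities)) {
      lr <- ays[[ic]] - drop(axs[[ic]] %*% beta)
      g <- g + drop(crossprod(azs[[ic]], lr))^2 -
        colSums(azs[[ic]]^2)
    }
    out$grad_psi <- 0.5 * g
  }
  out
}

#' Marginal log-likelihood of the multilevel meta-regression
#'
#' For each city the subperiod outcomes are stacked; the marginal
#' covariance is `blockdiag(S_i) + Z Psi Z'`, where `Z` holds the
#' city-level random intercept and random `time` slope acting on each
#' outcome coordinate, and `Psi` is diagonal (`2 * p` variances).  The
#' log-likelihood is the sum of the Gaussian log-densities over cities.
#'
#' @param beta fixed-effect vector (length `p * q`, coordinate index
#'   fastest).
#' @param psi nonnegative vector of `2 * p` random-effect variances
#'   (intercept block first, then time block).
#' @param dataset a `"meta_dataset"`.
#' @param model model id or formula (defines the fixed-effect design).
#'
#' @return The log-likelihood (scalar).
#' @export
marginal_loglik <- function(beta, psi, dataset, model = "model3") {
  if (any(psi < 0)) stop("'psi' must be nonnegative")
  parts <- meta_parts(dataset, meta_formula(model))
  if (length(psi) != 2L * parts$p)
    stop("'psi' must have length 2 * p")
  if (length(beta) != parts$p * parts$q)
    stop("'beta' must have length p * q")
  meta_ll_core(parts, psi, beta = beta)$ll
}

#' Fit the multivariate mixed-effect meta-regression
#'
#' Maximum likelihood with the fixed effects profiled out: for each
#' candidate diagonal random-effect covariance `Psi` the fixed effects
#' are the GLS solution, and the `2 * p` log-variances are optimised by
#' quasi-Newton (L-BFGS-B) from several starting values, keeping the
#' best converged solution.
#'
#' @param dataset a `"meta_dataset"`.
#' @param model model id (`"model3"`, `"model3_nohpp"`, `"model4"`,
#'   `"model5"`) or a one-sided formula on the unit covariates.
#' @param starts number of starting values (>= 1; default 3).
#'
#' @return Object of class `"meta_model"`: `beta`, `beta_mat` (p x q),
#'   `vcov_beta`, `psi`, `loglik`, `converged`, `model`, `formula`,
#'   `terms`/`xlev` (for scenario prediction), `n_units`, `n_cities`,
#'   `unit_keys`.
#' @export
fit_meta <- function(dataset, model = "model3", starts = 3L) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (length(unique(dataset$covs$city)) < 2L)
    stop("need at least 2 cities")
  formula <- meta_formula(model)
  parts <- meta_parts(dataset, formula)
  p <- parts$p
  vscale <- mean(apply(dataset$theta, 2L, stats::var))
  if (!is.finite(vscale) || vscale <= 0) vscale <- 1
  tsc <- stats::sd(dataset$covs$time)
  if (!is.finite(tsc) || tsc == 0) tsc <- 1
  scale0 <- rep(c(vscale, vscale / tsc^2), each = p)
  lower <- log(scale0) - 28
  upper <- log(scale0) + 8

  # objective and analytic gradient share one evaluation via a cache
  cache <- new.env(parent = emptyenv())
  evalfn <- function(u) {
    if (!is.null(cache$u) && identical(u, cache$u)) return(cache$res)
    res <- tryCatch(meta_ll_core(parts, exp(u), grad = TRUE),
                    error = function(e) NULL)
    cache$u <- u
    cache$res <- res
    res
  }
  nll <- function(u) {
    res <- evalfn(u)
    if (is.null(res) || !is.finite(res$ll)) return(1e10)
    -res$ll
  }
  gnll <- function(u) {
    res <- evalfn(u)
    if (is.null(res) || !is.finite(res$ll)) return(rep(0, length(u)))
    -res$grad_psi * exp(u) # chain rule for the log-variance scale
  }
  start_frac <- c(0.3, 0.02, 1e-4, 1, 1e-6)[
    seq_len(min(max(1L, starts), 5L))]
  best <- NULL
  for (f in start_frac) {
    u0 <- log(scale0 * f)
    opt <- tryCatch(
      stats::optim(u0, nll, gnll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e4, maxit = 200L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-9 ||
        (abs(opt$value - best$value) <= 1e-9 &&
         sum(exp(opt$par)) < sum(exp(best$par))))
      best <- opt
  }
  if (is.null(best)) stop("meta-regression failed in all starts")
  psi <- exp(best$par)
  psi[psi < 1e-12 * vscale] <- 0
  res <- meta_ll_core(parts, psi)
  if (is.null(res)) stop("singular fixed-effect design")
  vcov_beta <- solve(res$xtvx)
  vcov_beta <- (vcov_beta + t(vcov_beta)) / 2
  structure(list(
    beta = res$beta, beta_mat = matrix(res$beta, nrow = p),
    vcov_beta = vcov_beta, psi = psi, loglik = res$ll,
    converged = best$convergence == 0,
    model = if (inherits(model, "formula")) "formula" else model,
    formula = formula, terms = parts$terms, xlev = parts$xlev,
    p = p, q = parts$q, coef_names = colnames(parts$mm),
    n_units = parts$n_units, n_cities = length(parts$cities),
    unit_keys = paste(dataset$covs$city, dataset$covs$subperiod,
                      sep = ":")),
    class = "meta_model")
}

#' Likelihood ratio test between nested meta-regression models
#'
#' @param full,reduced two `"meta_model"` fits on identical units, the
#'   reduced model nested in the full one.
#' @return List with `statistic`, `df` (difference in fixed-effect
#'   parameter count) and `p` (chi-square upper tail).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "meta_model"), inherits(reduced, "meta_model"))
  if (!identical(sort(full$unit_keys), sort(reduced$unit_keys)))
    stop("models were not fitted on identical units")
  df <- length(full$beta) - length(reduced$beta)
  if (df < 0) stop("'reduced' has more parameters than 'full'")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

# fixed-effect design rows for (possibly modified) covariates
meta_design_rows <- function(model, covs) {
  mm <- stats::model.matrix(stats::delete.response(model$terms), covs,
                            xlev = model$xlev)
  if (ncol(mm) != model$q) stop("design mismatch in prediction")
  mm
}

#' Fixed-effect prediction of a pooled curve
#'
#' @param model a `"meta_model"`.
#' @param covariates single-row data.frame (or list) with the model's
#'   covariates (e.g. `region`, `time`, `hpp`).
#'
#' @return List with `coef` (p-vector `X beta`) and `vcov`
#'   (delta-method covariance `X V X'`).
#' @export
predict_fixed <- function(model, covariates) {
  covs <- as.data.frame(covariates)
  mm <- meta_design_rows(model, covs)
  p <- model$p
  xk <- kronecker(mm, diag(p))
  co <- drop(xk %*% model$beta)
  vc <- xk %*% model$vcov_beta %*% t(xk)
  list(coef = co, vcov = (vc + t(vc)) / 2)
}

#' Best linear unbiased predictions of unit curves
#'
#' Empirical-Bayes city effects `b = Psi Z' V^{-1} (y - X beta)` are
#' computed from the observed covariates; scenario predictions then
#' combine the fixed part under (possibly modified) covariates with the
#' same `b`, so toggling the HPP indicator changes only the fixed-effect
#' term.
#'
#' @param model a `"meta_model"`.
#' @param dataset the `"meta_dataset"` the model was fitted on.
#' @param newcovs optional modified covariates (same rows as
#'   `dataset$covs`); default: observed.
#' @param beta optional fixed-effect vector overriding the estimate
#'   (used by the Monte-Carlo sampler; the random effects stay at their
#'   estimated values).
#'
#' @return n x p matrix of unit-level coefficient predictions, with the
#'   city random effects in attribute `"b"`.
#' @export
blup <- function(model, dataset, newcovs = NULL, beta = NULL) {
  stopifnot(inherits(model, "meta_model"),
            inherits(dataset, "meta_dataset"))
  parts <- meta_parts(dataset, model$formula)
  if (!identical(paste(dataset$covs$city, dataset$covs$subperiod,
                       sep = ":"), model$unit_keys) &&
      !setequal(paste(dataset$covs$city, dataset$covs$subperiod,
                      sep = ":"), model$unit_keys))
    stop("dataset units do not match the fitted model")
  p <- model$p
  bhat <- blup_raneff(model, parts)
  covs <- if (is.null(newcovs)) dataset$covs else newcovs
  mm <- meta_design_rows(model, covs)
  bm <- if (is.null(beta)) model$beta_mat else matrix(beta, nrow = p)
  fixed <- mm %*% t(bm)
  out <- fixed
  for (ic in seq_along(parts$parts)) {
    pc <- parts$parts[[ic]]
    b <- bhat[[ic]]
    for (i in seq_along(pc$idx)) {
      u <- pc$idx[i]
      out[u, ] <- out[u, ] + b[1:p] + covs$time[u] * b[(p + 1):(2 * p)]
    }
  }
  structure(out, b = bhat)
}

# per-city random-effect estimates at the model's (beta, psi)
blup_raneff <- function(model, parts) {
  p <- model$p
  lapply(parts$parts, function(pc) {
    r <- pc$y - drop(pc$X %*% model$beta)
    V <- pc$S + pc$Z %*% (model$psi * t(pc$Z))
    drop(model$psi * (t(pc$Z) %*% solve(V, r)))
  })
}
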
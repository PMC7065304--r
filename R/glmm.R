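#' @importFrom stats plogis dnorm qnorm rnorm runif rbinom rpois setNames
NULL

# ---- internal: data preparation --------------------------------------

# Assemble response, fixed-effect design matrix (intercept, covariates,
# log-dose last) and patient index for likelihood work.
prep_glmm_data <- function(cohort, covariates, include_dose,
                           severity_center) {
  y <- cohort[["response"]]
  if (is.null(y)) stop("visit table lacks a 'response' column")
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("'response' must be binary 0/1 with no missing values")
  y <- as.numeric(y)
  pid_raw <- cohort[["patient_id"]]
  if (is.null(pid_raw)) stop("visit table lacks a 'patient_id' column")
  upid <- unique(pid_raw)
  pid <- match(pid_raw, upid)

  X <- cbind(`(Intercept)` = 1,
             resolve_covariates(cohort, covariates, severity_center))
  if (include_dose) {
    dose <- cohort[["dose_mg_per_kg"]]
    if (is.null(dose)) stop("visit table lacks a 'dose_mg_per_kg' column")
    if (any(!is.finite(dose) | dose <= 0))
      stop("all doses must be positive and finite")
    X <- cbind(X, log_dose = log(dose))
  }
  list(y = y, X = X, pid = pid, m = length(upid), upid = upid)
}

# ---- internal: posterior modes of the random intercepts --------------

# Vectorized safeguarded Newton for the per-patient conditional mode of
# b given the data, at fixed sigma^2. Returns the modes and the negative
# second derivative (curvature) of the penalized log-likelihood there.
posterior_modes <- function(eta0, y, pid, m, sigma2,
                            tol = 1e-11, maxit = 50L) {
  b <- numeric(m)
  pen_ll <- function(bv) {
    eta <- eta0 + bv[pid]
    rowsum(y * eta - log1pexp(eta), pid, reorder = FALSE)[, 1L] -
      bv^2 / (2 * sigma2)
  }
  f <- pen_ll(b)
  for (it in seq_len(maxit)) {
    eta <- eta0 + b[pid]
    p <- plogis(eta)
    g <- rowsum(y - p, pid, reorder = FALSE)[, 1L] - b / sigma2
    h <- rowsum(p * (1 - p), pid, reorder = FALSE)[, 1L] + 1 / sigma2
    step <- g / h
    if (any(!is.finite(step))) break
    if (max(abs(step)) < tol) break
    lam <- rep(1, m)
    for (k in 1:30) {
      bn <- b + lam * step
      fn <- pen_ll(bn)
      bad <- fn < f - 1e-12
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    b <- bn
    f <- fn
  }
  p <- plogis(eta0 + b[pid])
  h <- rowsum(p * (1 - p), pid, reorder = FALSE)[, 1L] + 1 / sigma2
  list(mode = b, curvature = h)
}

# ---- marginal likelihood ---------------------------------------------

# Core adaptive Gauss-Hermite marginal log-likelihood given a prepared
# data list, fixed-effect vector and sigma; returns the scalar loglik.
agh_loglik <- function(dat, beta_all, sigma2, gh) {
  eta0 <- drop(dat$X %*% beta_all)
  if (sigma2 < 1e-12) {
    return(sum(dat$y * eta0 - log1pexp(eta0)))
  }
  mm <- posterior_modes(eta0, dat$y, dat$pid, dat$m, sigma2)
  s <- 1 / sqrt(mm$curvature)
  Q <- length(gh$x)
  L <- matrix(0, dat$m, Q)
  sigma <- sqrt(sigma2)
  for (q in seq_len(Q)) {
    bq <- mm$mode + sqrt(2) * s * gh$x[q]
    etaq <- eta0 + bq[dat$pid]
    llq <- rowsum(dat$y * etaq - log1pexp(etaq), dat$pid,
                  reorder = FALSE)[, 1L] +
      dnorm(bq, 0, sigma, log = TRUE)
    L[, q] <- log(gh$w[q]) + gh$x[q]^2 + llq
  }
  mx <- apply(L, 1L, max)
  sum(log(sqrt(2) * s) + mx + log(rowSums(exp(L - mx))))
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Integrates the patient-level random intercept out of the Bernoulli
#' likelihood,
#' \deqn{\ell = \sum_i \ln \int \prod_j p_{ij}(b)^{y_{ij}}
#'   (1-p_{ij}(b))^{1-y_{ij}} \, \phi(b; 0, \sigma^2)\, db,}
#' with each one-dimensional integral evaluated by Gauss-Hermite
#' quadrature whose nodes are recentered at the patient's posterior mode
#' and rescaled by the posterior curvature there. With `sigma2 = 0` the
#' value collapses exactly to the plain logistic log-likelihood.
#'
#' @param params [model_params()]; covariate names in `params$beta` must
#'   resolve in `cohort` (see [linear_predictor()] for the severity
#'   convention).
#' @param cohort Visit table with `patient_id`, `response`,
#'   `dose_mg_per_kg` and any covariate columns.
#' @param n_nodes Number of quadrature nodes (>= 1); 15 is ample for
#'   binary data at these cluster sizes.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(params, cohort, n_nodes = 15L) {
  stopifnot(inherits(params, "mph_params"), n_nodes >= 1)
  dat <- prep_glmm_data(cohort, names(params$beta), include_dose = TRUE,
                        severity_center = params$severity_center)
  beta_all <- c(params$beta0, params$beta, params$d)
  gh <- pracma::gaussHermite(as.integer(n_nodes))
  agh_loglik(dat, beta_all, params$sigma2, gh)
}

# ---- maximum likelihood fit ------------------------------------------

# Central-difference gradient of fn at x.
num_grad <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    hk <- h * (1 + abs(x[k]))
    xp <- x; xp[k] <- xp[k] + hk
    xm <- x; xm[k] <- xm[k] - hk
    (fn(xp) - fn(xm)) / (2 * hk)
  }, numeric(1))
}

#' Fit the random-intercept logistic dose-response model
#'
#' Maximum-likelihood estimation of
#' \eqn{\mathrm{logit}\,P(Y_{ij}=1)=\beta_0+X_{ij}\beta+b_i+d\ln D_{ij}},
#' \eqn{b_i \sim N(0,\sigma^2)}, by BFGS on the adaptive Gauss-Hermite
#' marginal log-likelihood. The variance is optimized on the
#' \eqn{\ln\sigma} scale for unconstrained positivity; its confidence
#' interval is Wald on the \eqn{\ln\sigma^2} scale, back-transformed.
#' Standard errors come from the inverse numerical Hessian; coefficient
#' p-values are Wald z tests, and odds ratios are the exponentiated
#' coefficients and interval endpoints.
#'
#' @param cohort Visit table (see [marginal_loglik()]).
#' @param covariates Character vector of fixed-effect covariate names;
#'   `"severity"` denotes centered baseline severity.
#' @param n_nodes Gauss-Hermite nodes (default 15).
#' @param include_dose Include the `log(dose)` term (default `TRUE`).
#' @param severity_center Centering constant for `"severity"`; default
#'   `NULL` uses the mean per-patient baseline severity in `cohort`.
#' @param start Optional named start values (fixed effects then
#'   `ln_sigma`).
#' @return An object of class `mph_fit`: estimated [model_params()] in
#'   `$params`, plus coefficient table components (`coefficients`, `se`,
#'   `ci95`, `odds_ratios`, `p_values`), `sigma2` with `sigma2_ci95`,
#'   `loglik`, counts, `converged` and `n_quad_nodes`.
#' @export
fit_glmm <- function(cohort, covariates = c("time_months", "severity"),
                     n_nodes = 15L, include_dose = TRUE,
                     severity_center = NULL, start = NULL) {
  if (length(unique(cohort$patient_id)) < 2L)
    stop("need at least 2 patients to estimate a random intercept")
  if ("severity" %in% covariates && is.null(severity_center)) {
    bs <- if (!is.null(cohort[["baseline_severity"]]))
      cohort[["baseline_severity"]] else cohort[["severity_score"]]
    severity_center <- mean(tapply(bs, cohort$patient_id, function(v) v[1L]))
  }
  if (is.null(severity_center)) severity_center <- 0
  dat <- prep_glmm_data(cohort, covariates, include_dose, severity_center)
  gh <- pracma::gaussHermite(as.integer(n_nodes))
  p_fix <- ncol(dat$X)

  negll <- function(theta) {
    # wild trial points (finite-difference line searches) get a finite
    # penalty instead of NaN so the optimizer can back off
    if (any(!is.finite(theta)) || max(abs(theta)) > 50) return(1e10)
    v <- -agh_loglik(dat, theta[seq_len(p_fix)],
                     exp(2 * theta[p_fix + 1L]), gh)
    if (!is.finite(v)) 1e10 else v
  }

  if (is.null(start)) {
    g0 <- stats::glm.fit(dat$X, dat$y, family = stats::binomial())
    start <- c(g0$coefficients, 0)   # ln sigma = 0
  }
  theta <- start
  opt <- stats::optim(theta, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  theta <- opt$par
  fval <- opt$value
  grad <- num_grad(negll, theta)
  # Newton polish with numerical Hessian: BFGS alone rarely drives the
  # gradient below the 1e-5 tolerance on this likelihood surface
  H <- stats::optimHess(theta, negll)
  for (it in 1:10) {
    if (max(abs(grad)) < 1e-5) break
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- theta - lam * step
      fc <- negll(cand)
      if (fc <= fval + 1e-10 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (fc > fval + 1e-10) break
    theta <- cand
    fval <- fc
    grad <- num_grad(negll, theta)
    H <- stats::optimHess(theta, negll)
  }
  converged <- (opt$convergence == 0) && max(abs(grad)) < 1e-5
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  k <- p_fix + 1L
  if (is.null(vcov) || any(!is.finite(diag(vcov))) ||
      any(diag(vcov) < 0)) {
    se <- rep(NA_real_, k)
    converged <- FALSE
  } else se <- sqrt(diag(vcov))

  nm <- c(colnames(dat$X), "ln_sigma")
  coefs <- setNames(theta, nm)
  se <- setNames(se, nm)
  z <- qnorm(0.975)
  ci95 <- cbind(lower = coefs - z * se, upper = coefs + z * se)
  fixed <- setdiff(nm, c("(Intercept)", "ln_sigma"))
  or <- cbind(OR = exp(coefs[fixed]), lower = exp(ci95[fixed, "lower"]),
              upper = exp(ci95[fixed, "upper"]))
  pv <- setNames(2 * stats::pnorm(-abs(coefs / se)), nm)

  sigma2 <- exp(2 * coefs["ln_sigma"])
  se_ls2 <- 2 * se["ln_sigma"]       # delta method: ln sigma^2 = 2 ln sigma
  sigma2_ci <- exp(log(sigma2) + c(-1, 1) * z * se_ls2)

  beta_nm <- setdiff(colnames(dat$X), c("(Intercept)", "log_dose"))
  params <- model_params(
    beta0 = unname(coefs["(Intercept)"]),
    beta = coefs[beta_nm],
    d = if (include_dose) unname(coefs["log_dose"]) else 0,
    sigma2 = unname(sigma2),
    severity_center = severity_center
  )
  structure(
    list(params = params, coefficients = coefs, se = se, ci95 = ci95,
         odds_ratios = or, p_values = pv, sigma2 = unname(sigma2),
         sigma2_ci95 = sigma2_ci, loglik = -fval,
         n_patients = dat$m, n_obs = length(dat$y),
         converged = converged, n_quad_nodes = as.integer(n_nodes),
         severity_center = severity_center,
         gradient_norm = max(abs(grad))),
    class = "mph_fit"
  )
}

#' @export
print.mph_fit <- function(x, ...) {
  cat("Random-intercept logistic dose-response fit",
      sprintf("(adaptive GH, %d nodes)\n", x$n_quad_nodes))
  cat(sprintf("  %d patients, %d visits; log-likelihood %.4f%s\n",
              x$n_patients, x$n_obs, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  fixed <- setdiff(names(x$coefficients), "ln_sigma")
  tab <- data.frame(
    estimate = round(x$coefficients[fixed], 4),
    se = round(x$se[fixed], 4),
    ci_lower = round(x$ci95[fixed, "lower"], 4),
    ci_upper = round(x$ci95[fixed, "upper"], 4),
    p = signif(x$p_values[fixed], 3)
  )
  print(tab)
  cat(sprintf("  random-intercept variance: %.4f (%.4f, %.4f)\n",
              x$sigma2, x$sigma2_ci95[1], x$sigma2_ci95[2]))
  invisible(x)
}

#' @export
coef.mph_fit <- function(object, ...) object$coefficients

#' @export
logLik.mph_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' Serialize a fit to JSON
#'
#' Writes coefficients, standard errors, confidence intervals, odds
#' ratios, p-values, the variance estimate, log-likelihood, counts and
#' the severity centering constant.
#'
#' @param fit An `mph_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mph_fit"))
  out <- list(
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se),
    ci95 = list(lower = as.list(setNames(fit$ci95[, "lower"],
                                         rownames(fit$ci95))),
                upper = as.list(setNames(fit$ci95[, "upper"],
                                         rownames(fit$ci95)))),
    odds_ratios = as.data.frame(fit$odds_ratios),
    p_values = as.list(fit$p_values),
    sigma2 = fit$sigma2, sigma2_ci95 = fit$sigma2_ci95,
    loglik = fit$loglik, n_patients = fit$n_patients, n_obs = fit$n_obs,
    converged = fit$converged, n_quad_nodes = fit$n_quad_nodes,
    severity_center = fit$severity_center
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- covariate screening ---------------------------------------------

#' Univariable screening followed by a multivariable fit
#'
#' Mirrors the two-column modelling strategy used for observational
#' dose-response cohorts: each candidate covariate is first fit alone in
#' a random-intercept logistic model; candidates with a Wald p-value
#' below `alpha` are then carried jointly into the multivariable model.
#' The candidate name `"log_dose"` denotes the `log(dose)` term.
#'
#' @param cohort Visit table.
#' @param candidates Character vector of candidate covariate names
#'   (may include `"log_dose"` and `"severity"`).
#' @param alpha Selection threshold on the univariable p-value.
#' @param n_nodes Gauss-Hermite nodes for every fit.
#' @return A list: `table` (one row per candidate with OR, 95% CI and
#'   p-value from the univariable fits), `selected` (character vector),
#'   and `multivariable` (an `mph_fit` on the selected set, or `NULL`
#'   when nothing is selected).
#' @export
univariable_screen <- function(cohort, candidates, alpha = 0.05,
                               n_nodes = 15L) {
  stopifnot(length(candidates) >= 1, alpha > 0, alpha <= 1)
  rows <- lapply(candidates, function(cand) {
    if (cand == "log_dose") {
      f <- fit_glmm(cohort, covariates = character(0), n_nodes = n_nodes,
                    include_dose = TRUE)
      key <- "log_dose"
    } else {
      f <- fit_glmm(cohort, covariates = cand, n_nodes = n_nodes,
                    include_dose = FALSE)
      key <- cand
    }
    data.frame(candidate = cand,
               OR = unname(f$odds_ratios[key, "OR"]),
               ci_lower = unname(f$odds_ratios[key, "lower"]),
               ci_upper = unname(f$odds_ratios[key, "upper"]),
               p_value = unname(f$p_values[key]),
               converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  selected <- tab$candidate[tab$p_value < alpha | alpha >= 1]
  multi <- NULL
  if (length(selected)) {
    multi <- fit_glmm(
      cohort,
      covariates = setdiff(selected, "log_dose"),
      include_dose = "log_dose" %in% selected,
      n_nodes = n_nodes
    )
  }
  list(table = tab, selected = selected, multivariable = multi)
}
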
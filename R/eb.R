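#' Empirical-Bayes prediction of a patient's random intercept
#'
#' Given fixed population parameters and a patient's accumulated visit
#' history, predicts the random intercept \eqn{\hat b} either as the
#' conditional (posterior) mode — the argmax over \eqn{b} of the
#' penalized log-likelihood
#' \eqn{\sum_j \ln \mathrm{Bern}(y_j \mid \mathrm{expit}(\eta_j(b))) +
#' \ln\phi(b;0,\sigma^2)} — found by safeguarded Newton, or as the
#' posterior mean computed by adaptive Gauss-Hermite quadrature centered
#' at that mode. A patient with no history gets \eqn{\hat b = 0} exactly:
#' a new patient starts at the population prior.
#'
#' @param params [model_params()] (population fit; `sigma2 > 0` for a
#'   nontrivial prediction).
#' @param history Data frame of the patient's prior visits with columns
#'   `time_months`, `dose_mg_per_kg`, `response`, plus any covariate
#'   columns the model needs (for `"severity"`, a `baseline_severity` or
#'   `severity_score` column). May be `NULL` or empty.
#' @param method `"mode"` (default, the conditional mode) or `"gh_mean"`
#'   (adaptive Gauss-Hermite posterior mean).
#' @param n_nodes Quadrature nodes for `"gh_mean"`.
#' @return A list with `b_hat` and `curvature` (negative second
#'   derivative of the penalized log-likelihood at the optimum; the
#'   prior precision `1/sigma2` for an empty history).
#' @export
#' @examples
#' p <- mph_reference_params()
#' predict_b(p, NULL)$b_hat  # 0: no history yet
predict_b <- function(params, history,
                      method = c("mode", "gh_mean"), n_nodes = 15L) {
  method <- match.arg(method)
  stopifnot(inherits(params, "mph_params"))
  if (is.null(history) || nrow(history) == 0L) {
    return(list(b_hat = 0,
                curvature = if (params$sigma2 > 0) 1 / params$sigma2
                            else Inf))
  }
  tm <- history[["time_months"]]
  if (!is.null(tm) && nrow(history) > 1L && any(diff(tm) <= 0))
    stop("history visit times must be strictly increasing")
  if (any(history[["dose_mg_per_kg"]] <= 0))
    stop("history doses must be positive")
  if (params$sigma2 <= 0)
    return(list(b_hat = 0, curvature = Inf))

  y <- as.numeric(history[["response"]])
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("history responses must be binary 0/1")
  eta0 <- fixed_eta(params, history)
  sigma2 <- params$sigma2

  pen_ll <- function(b) sum(y * (eta0 + b) - log1pexp(eta0 + b)) -
    b^2 / (2 * sigma2)
  b <- 0
  f <- pen_ll(b)
  conv <- FALSE
  for (it in 1:100) {
    p <- plogis(eta0 + b)
    g <- sum(y - p) - b / sigma2
    if (abs(g) < 1e-10) { conv <- TRUE; break }
    h <- sum(p * (1 - p)) + 1 / sigma2
    step <- g / h
    lam <- 1
    repeat {
      bn <- b + lam * step
      fn <- pen_ll(bn)
      if (fn >= f - 1e-14 || lam < 1e-8) break
      lam <- lam / 2
    }
    b <- bn
    f <- fn
  }
  if (!conv && abs(sum(y - plogis(eta0 + b)) - b / sigma2) >= 1e-8)
    stop("random-effect prediction did not converge; last iterate b = ",
         format(b))
  p <- plogis(eta0 + b)
  curv <- sum(p * (1 - p)) + 1 / sigma2

  if (method == "mode") return(list(b_hat = b, curvature = curv))

  gh <- pracma::gaussHermite(as.integer(n_nodes))
  s <- 1 / sqrt(curv)
  bq <- b + sqrt(2) * s * gh$x
  lq <- vapply(bq, pen_ll, numeric(1)) + log(gh$w) + gh$x^2
  wq <- exp(lq - max(lq))
  list(b_hat = sum(wq * bq) / sum(wq), curvature = curv)
}

#' Shrinkage profile of the random-intercept update
#'
#' Diagnostic for the sequential empirical-Bayes update: the predicted
#' \eqn{\hat b} after 1, 2, ..., k identical non-improved visits at fixed
#' covariates and dose. Accumulating consistent failures pulls the
#' estimate monotonically downward, bounded by the prior variance.
#'
#' @param params [model_params()].
#' @param k_consistent_failures Number of repeated failure visits
#'   (>= 1).
#' @param covariates Named covariate values held fixed across the visits
#'   (with `"severity"` given as the raw score).
#' @param dose Administered dose in mg/kg.
#' @return Numeric vector of length `k`: \eqn{\hat b} after each visit.
#' @export
shrinkage_profile <- function(params, k_consistent_failures,
                              covariates = numeric(0), dose = 1) {
  k <- k_consistent_failures
  stopifnot(k >= 1)
  t0 <- if ("time_months" %in% names(covariates))
    as.numeric(covariates[["time_months"]]) else 0
  one <- data.frame(time_months = t0, dose_mg_per_kg = dose, response = 0)
  # carry covariates as columns so fixed_eta resolves them
  for (nm in setdiff(names(covariates), "time_months")) {
    cn <- if (nm == "severity") "baseline_severity" else nm
    one[[cn]] <- covariates[[nm]]
  }
  vapply(seq_len(k), function(j) {
    h <- one[rep(1L, j), , drop = FALSE]
    # visits are identical in all covariates; nudge times by a negligible
    # epsilon so the strictly-increasing ordering invariant holds
    h$time_months <- t0 + (seq_len(j) - 1) * 1e-9
    predict_b(params, h)$b_hat
  }, numeric(1))
}
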
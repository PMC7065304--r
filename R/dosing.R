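#' Target improvement probability for dose inversion
#'
#' Container for the probability \eqn{p_0} that dose recommendations aim
#' to attain. Construct it explicitly, or derive it from a fitted cohort
#' with [compute_target_p0()].
#'
#' @param p0 Target probability in `(0, 1)`; exactly one of `p0` and
#'   `logit_p0` may be omitted.
#' @param logit_p0 The target on the log-odds scale.
#' @param source `"explicit"` or `"percentile_from_fit"`.
#' @return An object of class `dose_target` with fields `p0`, `logit_p0`
#'   and `source`.
#' @export
#' @examples
#' dose_target(p0 = 0.9866)$logit_p0  # 4.2990
dose_target <- function(p0 = NULL, logit_p0 = NULL, source = "explicit") {
  if (is.null(p0) && is.null(logit_p0))
    stop("supply p0 or logit_p0")
  if (!is.null(p0) && (!is.finite(p0) || p0 <= 0 || p0 >= 1))
    stop("p0 must lie strictly inside (0, 1)")
  if (is.null(logit_p0)) logit_p0 <- stats::qlogis(p0)
  if (is.null(p0)) p0 <- stats::plogis(logit_p0)
  if (abs(logit_p0 - stats::qlogis(p0)) > 1e-8)
    stop("p0 and logit_p0 are inconsistent")
  structure(list(p0 = p0, logit_p0 = logit_p0, source = source),
            class = "dose_target")
}

#' Derive the dosing target from a fitted cohort
#'
#' Evaluates the fitted improvement probability at each patient's last
#' visit — using that patient's empirical-Bayes \eqn{\hat b} predicted
#' from their full history — and takes the stated percentile of those
#' probabilities (linear interpolation between order statistics). The
#' 90th percentile is the conventional choice: the target is set where
#' the best-responding tenth of the cohort already sits.
#'
#' @param fit An `mph_fit` (or [model_params()]).
#' @param cohort Visit table the probabilities are evaluated on.
#' @param percentile Percentile in `(0, 100)`; default 90.
#' @param n_nodes Quadrature nodes for the random-effect prediction.
#' @return A [dose_target()] with `source = "percentile_from_fit"`.
#' @export
compute_target_p0 <- function(fit, cohort, percentile = 90,
                              n_nodes = 15L) {
  params <- if (inherits(fit, "mph_fit")) fit$params else fit
  stopifnot(inherits(params, "mph_params"))
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly inside (0, 100)")
  if (nrow(cohort) == 0L) stop("cohort is empty")
  ids <- unique(cohort$patient_id)
  probs <- vapply(ids, function(id) {
    h <- cohort[cohort$patient_id == id, , drop = FALSE]
    ord <- order(h$time_months)
    h <- h[ord, , drop = FALSE]
    bh <- predict_b(params, h, n_nodes = n_nodes)$b_hat
    last <- h[nrow(h), , drop = FALSE]
    inv_logit(fixed_eta(params, last) + bh)
  }, numeric(1))
  p0 <- unname(stats::quantile(probs, percentile / 100, type = 7))
  tg <- dose_target(p0 = p0, source = "percentile_from_fit")
  attr(tg, "probs") <- unname(probs)  # last-visit fitted probabilities
  tg
}

# Shared inversion: solve logit P = logit_p0 for the dose.
invert_dose <- function(params, eta_without_dose, logit_p0,
                        clip = c(0.01, 2)) {
  if (params$d == 0)
    stop("log-dose coefficient is 0: the dose equation cannot be inverted")
  dose <- exp((logit_p0 - eta_without_dose) / params$d)
  clipped <- FALSE
  dose_clipped <- dose
  if (!is.null(clip)) {
    dose_clipped <- min(max(dose, clip[1]), clip[2])
    clipped <- dose_clipped != dose
  }
  list(dose = dose_clipped, dose_unclipped = dose, clipped = clipped)
}

new_dose_rec <- function(inv, b_hat, target, severity, severity_mode,
                         time_months) {
  structure(
    list(dose_mg_per_kg = inv$dose,
         dose_unclipped_mg_per_kg = inv$dose_unclipped,
         clipped = inv$clipped, b_hat_used = b_hat,
         p0_used = target$p0, logit_p0_used = target$logit_p0,
         severity_used = severity, severity_mode = severity_mode,
         time_months = time_months),
    class = "dose_recommendation"
  )
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "Recommended dose: %.4f mg/kg%s  (target p0 = %.4f, b_hat = %.4f, severity %s = %g, t = %g mo)\n",
    x$dose_mg_per_kg, if (x$clipped) " [clipped]" else "",
    x$p0_used, x$b_hat_used, x$severity_mode, x$severity_used,
    x$time_months))
  invisible(x)
}

#' Initial dose for a new patient
#'
#' Inverts the fitted model at treatment start: with no history the
#' random intercept is set to \eqn{\hat b_{k,0} = 0} and the dose solves
#' \deqn{D_{k1} = \exp\{(\mathrm{logit}\,p_0 - \beta_0 - X\beta)/d\}}
#' at time 0, with severity entered as the centered baseline score.
#'
#' @param params [model_params()] (or an `mph_fit`'s `$params`).
#' @param baseline_severity CPRS-R:S total at baseline, in `[0, 81]`.
#' @param target A [dose_target()].
#' @param other_covariates Named values for any further covariates in the
#'   model.
#' @param clip Length-2 dose bounds in mg/kg (default `c(0.01, 2)`); the
#'   unclipped value is retained in the result. `NULL` disables clipping.
#' @return A `dose_recommendation`.
#' @export
#' @examples
#' rec <- initial_dose(mph_reference_params(), baseline_severity = 55,
#'                     target = dose_target(logit_p0 = 0.6221))
#' rec$dose_mg_per_kg
initial_dose <- function(params, baseline_severity, target,
                         other_covariates = numeric(0),
                         clip = c(0.01, 2)) {
  stopifnot(inherits(target, "dose_target"))
  if (baseline_severity < 0 || baseline_severity > 81)
    stop("baseline_severity must lie in [0, 81]")
  covs <- c(severity = baseline_severity, time_months = 0,
            other_covariates)
  covs <- covs[!duplicated(names(covs))]
  eta0 <- linear_predictor(params, covs, dose = 1, b = 0)  # ln 1 = 0
  inv <- invert_dose(params, eta0, target$logit_p0, clip)
  new_dose_rec(inv, b_hat = 0, target, baseline_severity, "baseline", 0)
}

#' Follow-up dose given the current empirical-Bayes estimate
#'
#' Inverts the fitted model at a follow-up visit:
#' \deqn{D_{kn} = \exp\{(\mathrm{logit}\,p_0 - \beta_0 - X\beta -
#'   \hat b_{k,n-1})/d\},}
#' where \eqn{X\beta} includes the months-on-treatment term and the
#' centered severity score selected by `severity_mode`.
#'
#' @inheritParams initial_dose
#' @param severity CPRS-R:S score entering the severity term.
#' @param time_months Months since treatment start (>= 0).
#' @param b_hat The patient's predicted random intercept (see
#'   [predict_b()]).
#' @param severity_mode `"current"` (the score observed at the most
#'   recent visit, the default) or `"baseline"`; recorded in the result.
#' @return A `dose_recommendation`.
#' @export
followup_dose <- function(params, severity, time_months, b_hat, target,
                          severity_mode = c("current", "baseline"),
                          other_covariates = numeric(0),
                          clip = c(0.01, 2)) {
  severity_mode <- match.arg(severity_mode)
  stopifnot(inherits(target, "dose_target"), time_months >= 0)
  covs <- c(severity = severity, time_months = time_months,
            other_covariates)
  covs <- covs[!duplicated(names(covs))]
  eta0 <- linear_predictor(params, covs, dose = 1, b = b_hat)
  inv <- invert_dose(params, eta0, target$logit_p0, clip)
  new_dose_rec(inv, b_hat, target, severity, severity_mode, time_months)
}

#' Sequential dose recommendations along a patient's visit stream
#'
#' Implements the two-step procedure: the first visit uses
#' \eqn{\hat b = 0}; every later visit re-predicts
#' \eqn{\hat b_{k,n-1}} from all prior visits (responses at the
#' administered dose, taken to be the previously recommended dose unless
#' the stream provides one) and inverts the model for the next dose.
#'
#' @param params [model_params()].
#' @param target [dose_target()].
#' @param visits Data frame ordered in time with columns `time_months`,
#'   `severity_score`, `response`, optionally `baseline_severity`,
#'   `dose_mg_per_kg` (administered dose overriding the fed-back
#'   recommendation) and further covariates.
#' @param severity_mode `"current"` uses each visit's own score in the
#'   severity term; `"baseline"` uses `baseline_severity` throughout.
#' @param b_hat_override Optional numeric vector (length `nrow(visits)`)
#'   of externally supplied \eqn{\hat b} values, e.g. when replaying
#'   published worked examples whose inputs are only partially known.
#' @param clip Dose bounds as in [initial_dose()].
#' @param n_nodes Quadrature nodes for the random-effect updates.
#' @return A data frame audit trail with one row per visit: `visit`,
#'   `time_months`, `severity_used`, `b_hat`, `dose_mg_per_kg`,
#'   `dose_unclipped_mg_per_kg`, `clipped`, `administered_mg_per_kg`.
#' @export
recommend_trajectory <- function(params, target, visits,
                                 severity_mode = c("current", "baseline"),
                                 b_hat_override = NULL,
                                 clip = c(0.01, 2), n_nodes = 15L) {
  severity_mode <- match.arg(severity_mode)
  stopifnot(inherits(target, "dose_target"), nrow(visits) >= 1)
  if (is.unsorted(visits$time_months, strictly = FALSE))
    stop("visit stream must be ordered in time")
  if (!is.null(b_hat_override) &&
      length(b_hat_override) != nrow(visits))
    stop("b_hat_override must have one value per visit")
  n <- nrow(visits)
  out <- vector("list", n)
  administered <- numeric(n)
  for (k in seq_len(n)) {
    sev <- if (severity_mode == "current") visits$severity_score[k]
           else visits$baseline_severity[k]
    bh <- if (!is.null(b_hat_override)) b_hat_override[k]
    else if (k == 1L) 0
    else {
      hist <- visits[seq_len(k - 1L), , drop = FALSE]
      hist$dose_mg_per_kg <- administered[seq_len(k - 1L)]
      predict_b(params, hist, n_nodes = n_nodes)$b_hat
    }
    other <- setdiff(names(params$beta), c("severity", "time_months"))
    oc <- if (length(other))
      stats::setNames(as.numeric(visits[k, other]), other)
    else numeric(0)
    rec <- followup_dose(params, sev, visits$time_months[k], bh, target,
                         severity_mode, other_covariates = oc,
                         clip = clip)
    administered[k] <- if (!is.null(visits[["dose_mg_per_kg"]]) &&
                           !is.na(visits$dose_mg_per_kg[k]))
      visits$dose_mg_per_kg[k] else rec$dose_mg_per_kg
    out[[k]] <- data.frame(
      visit = k, time_months = visits$time_months[k],
      severity_used = sev, b_hat = bh,
      dose_mg_per_kg = rec$dose_mg_per_kg,
      dose_unclipped_mg_per_kg = rec$dose_unclipped_mg_per_kg,
      clipped = rec$clipped, administered_mg_per_kg = administered[k]
    )
  }
  res <- do.call(rbind, out)
  attr(res, "target") <- target
  attr(res, "severity_mode") <- severity_mode
  res
}

#' Dose-response recommendation surface
#'
#' Population-level (\eqn{\hat b = 0}) recommended dose over a grid of
#' severity scores and months on treatment, for plotting the
#' recommendation curves. Doses increase with severity and decrease with
#' time on treatment (given the fitted signs).
#'
#' @param params [model_params()].
#' @param target [dose_target()].
#' @param severity_grid Numeric vector of CPRS-R:S scores.
#' @param time_grid Numeric vector of months on treatment.
#' @param clip Dose bounds; `NULL` (default) leaves the curve unclipped.
#' @return Data frame with columns `severity`, `time_months`,
#'   `dose_mg_per_kg`.
#' @export
dose_response_curves <- function(params, target, severity_grid,
                                 time_grid, clip = NULL) {
  stopifnot(length(severity_grid) >= 1, length(time_grid) >= 1)
  grid <- expand.grid(severity = severity_grid, time_months = time_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$dose_mg_per_kg <- vapply(seq_len(nrow(grid)), function(r) {
    followup_dose(params, grid$severity[r], grid$time_months[r],
                  b_hat = 0, target = target, clip = clip
                  )$dose_mg_per_kg
  }, numeric(1))
  grid
}

#' Serialize a recommendation trajectory to JSON
#'
#' @param trajectory Result of [recommend_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(trajectory, path) {
  tg <- attr(trajectory, "target")
  out <- list(
    target = list(p0 = tg$p0, logit_p0 = tg$logit_p0, source = tg$source),
    severity_mode = attr(trajectory, "severity_mode"),
    visits = trajectory
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
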
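#' Parameters of the random-intercept logistic dose-response model
#'
#' Container for the fixed and random-effect parameters of the model
#' \deqn{\mathrm{logit}\,P(Y_{ij}=1) = \beta_0 + X_{ij}\beta + b_i +
#'   d\,\ln D_{ij}, \qquad b_i \sim N(0, \sigma^2),}
#' where \eqn{Y_{ij}} is the binary improvement indicator for patient
#' \eqn{i} at visit \eqn{j} (CPRS-R:S total \eqn{\le 40}), \eqn{D_{ij}} is
#' the methylphenidate dose in mg/kg, and \eqn{X_{ij}} collects covariates.
#' The severity covariate always enters centered: a coefficient named
#' `"severity"` multiplies `score - severity_center`.
#'
#' @param beta0 Fixed intercept (log-odds scale).
#' @param beta Named numeric vector of covariate coefficients. The name
#'   `"severity"` denotes baseline ADHD severity (CPRS-R:S total), applied
#'   to the centered score; `"time_months"` denotes months since treatment
#'   start. Other names must match covariate columns in the data they are
#'   applied to.
#' @param d Coefficient of `log(dose)` (log-odds per unit `ln` mg/kg).
#' @param sigma2 Variance of the patient-level random intercept; must be
#'   `>= 0`.
#' @param severity_center Centering constant for the severity covariate
#'   (a CPRS-R:S score, typically the cohort mean baseline severity).
#' @return An object of class `mph_params`.
#' @seealso [mph_reference_params()] for the published reference estimates,
#'   [linear_predictor()], [fit_glmm()].
#' @export
#' @examples
#' p <- model_params(beta0 = -0.5, beta = c(time_months = 0.1), d = 1,
#'                   sigma2 = 1)
#' linear_predictor(p, c(time_months = 6), dose = 0.3, b = 0)
model_params <- function(beta0, beta = numeric(0), d = 0, sigma2 = 0,
                         severity_center = 0) {
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0))
  beta <- stats::setNames(as.numeric(beta), names(beta))
  if (length(beta) > 0 && (is.null(names(beta)) || any(!nzchar(names(beta)))))
    stop("every element of 'beta' must be named")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) ||
      sigma2 < 0)
    stop("'sigma2' must be a single non-negative number")
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d))
  structure(
    list(beta0 = beta0, beta = beta, d = d, sigma2 = sigma2,
         severity_center = severity_center),
    class = "mph_params"
  )
}

#' Reference parameter estimates for MPH response in ADHD
#'
#' The multivariable random-intercept model estimated on a historical
#' cohort of 221 children with ADHD treated with methylphenidate:
#' intercept 1.9377, time on treatment 0.0800 per month, centered baseline
#' severity -0.0512 per CPRS-R:S point (centered at 51.3817), log-dose
#' 0.8610, and random-intercept variance 1.452. These values serve as the
#' ground truth of the synthetic-cohort generator and as the fixed
#' population model behind the worked dosing examples.
#'
#' @return An `mph_params` object.
#' @export
mph_reference_params <- function() {
  model_params(
    beta0 = 1.9377,
    beta = c(time_months = 0.0800, severity = -0.0512),
    d = 0.8610,
    sigma2 = 1.452,
    severity_center = 51.3817
  )
}

#' @export
print.mph_params <- function(x, ...) {
  cat("Random-intercept logistic dose-response parameters\n")
  cat("  intercept (beta0):", format(x$beta0), "\n")
  if (length(x$beta))
    cat("  covariates:", paste(sprintf("%s=%g", names(x$beta), x$beta),
                               collapse = ", "), "\n")
  cat("  log-dose (d):", format(x$d), "\n")
  cat("  random-intercept variance (sigma^2):", format(x$sigma2), "\n")
  cat("  severity centered at:", format(x$severity_center), "\n")
  invisible(x)
}

#' Inverse logit (expit)
#'
#' Numerically stable inverse of the logit link,
#' \eqn{1/(1+e^{-\eta})}.
#'
#' @param eta Numeric vector of log-odds.
#' @return Probabilities in `[0, 1]`.
#' @export
#' @examples
#' inv_logit(0)       # 0.5
#' inv_logit(4.2990)  # ~0.9866, a typical dosing target
inv_logit <- function(eta) stats::plogis(eta)

# log(1 + exp(x)) without overflow; exact to double precision.
log1pexp <- function(x) {
  out <- x
  lo <- x < 33.3
  out[lo] <- log1p(exp(x[lo]))
  out
}

#' Linear predictor of the dose-response model
#'
#' Evaluates \eqn{\eta = \beta_0 + X\beta + b + d \ln D} for one visit.
#' A covariate named `"severity"` is supplied as the raw CPRS-R:S score
#' and centered internally at `params$severity_center`.
#'
#' @param params An [model_params()] object.
#' @param covariates Named numeric vector supplying a value for every name
#'   in `params$beta`.
#' @param dose Dose in mg/kg; must be positive.
#' @param b Patient random intercept (0 for a population-average patient).
#' @return The linear predictor (log-odds scale).
#' @export
#' @examples
#' # an average patient at dose 1 mg/kg has eta = beta0
#' p <- mph_reference_params()
#' linear_predictor(p, c(time_months = 0, severity = 51.3817), dose = 1,
#'                  b = 0)  # 1.9377
linear_predictor <- function(params, covariates = numeric(0), dose, b = 0) {
  stopifnot(inherits(params, "mph_params"))
  if (!is.numeric(dose) || any(dose <= 0))
    stop("'dose' must be positive (mg/kg)")
  xb <- 0
  if (length(params$beta)) {
    nm <- names(params$beta)
    missing_nm <- setdiff(nm, names(covariates))
    if (length(missing_nm))
      stop("covariate(s) named in the model but not supplied: ",
           paste(missing_nm, collapse = ", "))
    x <- as.numeric(covariates[nm])
    if ("severity" %in% nm)
      x[nm == "severity"] <- x[nm == "severity"] - params$severity_center
    xb <- sum(params$beta * x)
  }
  params$beta0 + xb + b + params$d * log(dose)
}

# Resolve the fixed-effect design matrix for a visit table.
# Column semantics: "severity" -> baseline_severity (fallback:
# severity_score) centered at `center`; any other name -> the column of
# that name, verbatim.
resolve_covariates <- function(data, names, center) {
  if (!length(names)) return(matrix(0, nrow(data), 0))
  cols <- lapply(names, function(nm) {
    if (nm == "severity") {
      src <- if (!is.null(data[["baseline_severity"]])) "baseline_severity"
             else "severity_score"
      if (is.null(data[[src]]))
        stop("covariate 'severity' needs a 'baseline_severity' or ",
             "'severity_score' column")
      as.numeric(data[[src]]) - center
    } else {
      if (is.null(data[[nm]]))
        stop("covariate column not found in data: ", nm)
      as.numeric(data[[nm]])
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names
  m
}

# Fixed part of the linear predictor (everything except b) for each row
# of a visit table.
fixed_eta <- function(params, data) {
  X <- resolve_covariates(data, names(params$beta), params$severity_center)
  dose <- data[["dose_mg_per_kg"]]
  if (is.null(dose)) stop("visit table lacks a 'dose_mg_per_kg' column")
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("all doses must be positive and finite")
  drop(params$beta0 + (if (ncol(X)) X %*% params$beta else 0) +
         params$d * log(dose))
}
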
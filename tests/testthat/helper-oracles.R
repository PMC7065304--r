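# Independent oracles and in-code fixtures shared across the test files.
# Every oracle below re-derives the quantity from first principles and
# never calls the package code path it is used to check.

# Fixed part of the linear predictor, re-derived from the model
# definition (not via mphdose internals).
oracle_fixed_eta <- function(params, visits) {
  eta <- rep(params$beta0, nrow(visits)) +
    params$d * log(visits$dose_mg_per_kg)
  for (nm in names(params$beta)) {
    x <- if (nm == "severity") {
      src <- if (!is.null(visits[["baseline_severity"]]))
        visits[["baseline_severity"]] else visits[["severity_score"]]
      src - params$severity_center
    } else visits[[nm]]
    eta <- eta + params$beta[[nm]] * x
  }
  eta
}

# Brute-force marginal log-likelihood: dense trapezoid quadrature over
# b in [-width*sigma, width*sigma] per patient.
oracle_marginal_loglik <- function(params, visits, npts = 20000,
                                   width = 10) {
  sig <- sqrt(params$sigma2)
  total <- 0
  for (id in unique(visits$patient_id)) {
    h <- visits[visits$patient_id == id, , drop = FALSE]
    e0 <- oracle_fixed_eta(params, h)
    y <- h$response
    bs <- seq(-width * sig, width * sig, length.out = npts)
    integrand <- vapply(bs, function(b) {
      eta <- e0 + b
      exp(sum(y * eta - log1p(exp(eta)))) * dnorm(b, 0, sig)
    }, numeric(1))
    total <- total + log(pracma::trapz(bs, integrand))
  }
  total
}

# Dense-grid + golden-section search for the posterior mode of b.
oracle_posterior_mode <- function(params, history, width = 8) {
  sig <- sqrt(params$sigma2)
  e0 <- oracle_fixed_eta(params, history)
  y <- history$response
  pen_ll <- function(b) {
    eta <- e0 + b
    sum(y * eta - log(1 + exp(eta))) - b^2 / (2 * params$sigma2)
  }
  grid <- seq(-width * sig, width * sig, length.out = 16001)
  vals <- vapply(grid, pen_ll, numeric(1))
  k <- which.max(vals)
  step <- grid[2] - grid[1]
  # fine grid around the coarse winner, then a parabolic vertex through
  # the three best ordinates (pure enumeration, no iterative solver)
  fine <- seq(grid[k] - 2 * step, grid[k] + 2 * step,
              length.out = 2001)
  fv <- vapply(fine, pen_ll, numeric(1))
  j <- which.max(fv)
  j <- min(max(j, 2L), length(fine) - 1L)
  d <- fine[2] - fine[1]
  fine[j] + 0.5 * d * (fv[j - 1] - fv[j + 1]) /
    (fv[j - 1] - 2 * fv[j] + fv[j + 1])
}

# Small deterministic 3-patient toy cohort with mixed outcomes.
toy_cohort <- function() {
  data.frame(
    patient_id = rep(1:3, each = 2),
    visit_index = rep(0:1, times = 3),
    time_months = c(0, 4, 0, 6, 0, 3),
    severity_score = c(55, 38, 62, 45, 48, 33),
    baseline_severity = rep(c(55, 62, 48), each = 2),
    dose_mg_per_kg = c(0.3, 0.3, 0.8, 0.8, 0.15, 0.15),
    response = c(0L, 1L, 0L, 0L, 1L, 1L)
  )
}

# Visit streams of the two hypothetical worked-example patients, with
# their externally supplied random-intercept estimates. All values are
# synthetic illustration inputs, not measured data.
hypothetical_patient_1 <- function() {
  data.frame(time_months = c(1, 2, 4),
             severity_score = c(45, 42, 39),
             response = c(0L, 0L, 1L),
             b_hat = c(-0.1647, -0.1651, -0.1690),
             dose_printed = c(0.1638, 0.1247, 0.0871))
}

hypothetical_patient_2 <- function() {
  data.frame(time_months = c(1, 2, 5, 6),
             severity_score = c(67, 65, 39, 30),
             response = c(0L, 0L, 1L, 1L),
             b_hat = c(-0.1497, -0.1449, -0.1456, -0.1439),
             dose_printed = c(0.6023, 0.4781, 0.0773, 0.0412))
}
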
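#' Dichotomize a CPRS-R:S severity score into improvement
#'
#' A visit counts as improved when the Conners' Parent Rating Scale
#' (revised short form) total no longer meets the ADHD criterion:
#' improvement = 1 iff score <= 40, 0 iff score > 40.
#'
#' @param severity_score Integer vector of CPRS-R:S totals in `[0, 81]`.
#' @return Integer vector of 0/1 improvement indicators.
#' @export
#' @examples
#' dichotomize(c(40, 41))  # 1 0
dichotomize <- function(severity_score) {
  s <- severity_score
  bad <- which(!is.finite(s) | s < 0 | s > 81)
  if (length(bad))
    stop("severity_score out of range [0, 81] at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  as.integer(s <= 40)
}

#' Cohort simulation settings
#'
#' Configuration of the synthetic longitudinal-cohort generator. Defaults
#' reproduce the demographic profile of the historical cohort the model
#' was estimated on: 221 children, baseline CPRS-R:S severity
#' 51.38 +/- 10.82 (truncated to scores above the ADHD criterion of 40),
#' 4.94 visits on average over a mean 22.42 months of treatment.
#'
#' @param n_patients Number of patients (>= 1).
#' @param true_params [model_params()] generating the binary responses.
#' @param baseline_severity_mean,baseline_severity_sd Normal parameters of
#'   baseline severity before truncation to `(40, 81]`.
#' @param followups_mean Mean number of visits per patient (the count is
#'   `1 + Poisson(followups_mean - 1)` follow-ups after baseline).
#' @param period_months_mean Mean total months under observation.
#' @param dose_policy How doses are assigned: `"constant"` (one log-uniform
#'   draw per patient, the default), `"random-walk"` (per-visit lognormal
#'   multiplicative drift), or `"adaptive"` (dose raised 25% after a
#'   non-improved visit, lowered 20% after an improved one).
#' @param dose_range_mg_per_kg Length-2 positive range for doses; the
#'   default 0.1--1.5 mg/kg brackets clinically used MPH doses.
#' @param seed Integer root seed; the same seed reproduces the cohort
#'   bit-for-bit. Per-patient substreams are derived from it by counter,
#'   so draws do not depend on patient order.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 221,
                          true_params = mph_reference_params(),
                          baseline_severity_mean = 51.38,
                          baseline_severity_sd = 10.82,
                          followups_mean = 4.94,
                          period_months_mean = 22.42,
                          dose_policy = c("constant", "random-walk",
                                          "adaptive"),
                          dose_range_mg_per_kg = c(0.1, 1.5),
                          seed = 1L) {
  dose_policy <- match.arg(dose_policy)
  stopifnot(n_patients >= 1, inherits(true_params, "mph_params"),
            followups_mean >= 1, period_months_mean > 0,
            length(dose_range_mg_per_kg) == 2L)
  if (any(dose_range_mg_per_kg <= 0) ||
      diff(dose_range_mg_per_kg) < 0)
    stop("dose range must be strictly positive and ordered")
  structure(
    list(n_patients = as.integer(n_patients), true_params = true_params,
         baseline_severity_mean = baseline_severity_mean,
         baseline_severity_sd = baseline_severity_sd,
         followups_mean = followups_mean,
         period_months_mean = period_months_mean,
         dose_policy = dose_policy,
         dose_range_mg_per_kg = as.numeric(dose_range_mg_per_kg),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Derived per-patient seed: injective in i for i < 1e6, independent of
# patient order, always below 2^31 - 1.
patient_seed <- function(root, i) {
  as.integer((as.numeric(root) + as.numeric(i) * 1000003) %% 2147483647)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lo && x <= hi) return(x)
  }
}

#' Generate a synthetic longitudinal ADHD/MPH cohort
#'
#' Simulates visit records whose binary improvement outcomes follow the
#' random-intercept logistic dose-response model of `config$true_params`:
#' per patient, a random intercept `b ~ N(0, sigma^2)`, a truncated-normal
#' baseline severity (> 40, i.e. meeting the ADHD criterion), a
#' `1 + Poisson` number of follow-ups with uniformly drawn inter-visit
#' gaps, doses per `dose_policy`, and
#' `Y ~ Bernoulli(inv_logit(beta0 + X beta + b + d ln D))` with severity
#' entering as centered baseline severity. A displayed per-visit CPRS-R:S
#' score consistent with the binary outcome is synthesized (uniform on
#' 20--40 when improved, 41--70 otherwise).
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements `visits` (one row per patient-visit) and
#'   `baselines` (one row per patient), both data frames.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' table(coh$visits$response)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$true_params
  if (p$sigma2 < 0) stop("sigma2 must be non-negative")
  rng <- config$dose_range_mg_per_kg
  gap_hi <- max(1, 2 * config$period_months_mean / config$followups_mean)

  visits <- vector("list", config$n_patients)
  baselines <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(patient_seed(config$seed, i))
    b_i <- if (p$sigma2 > 0) stats::rnorm(1L, 0, sqrt(p$sigma2)) else 0
    sev0 <- round(rtruncnorm1(config$baseline_severity_mean,
                              config$baseline_severity_sd, 40.5, 81.49))
    sex <- stats::rbinom(1L, 1L, 0.765)           # 1 = male
    age_months <- round(rtruncnorm1(82.5, 26.5, 36, 156))
    birth_weight_kg <- round(rtruncnorm1(3.09, 0.56, 1.0, 5.5), 2)
    weight0 <- round(rtruncnorm1(28, 7, 12, 60), 1)
    risperidone <- stats::rbinom(1L, 1L, 0.30)
    fluoxetine <- stats::rbinom(1L, 1L, 0.12)
    odd <- stats::rbinom(1L, 1L, 0.25)
    mood_disorder <- stats::rbinom(1L, 1L, 0.05)
    anxiety_disorder <- stats::rbinom(1L, 1L, 0.08)
    other_comorbidity <- stats::rbinom(1L, 1L, 0.15)

    n_fu <- 1L + stats::rpois(1L, max(config$followups_mean - 1, 0))
    gaps <- stats::runif(n_fu, 1, gap_hi)
    times <- c(0, cumsum(gaps))
    nv <- n_fu + 1L

    doses <- switch(
      config$dose_policy,
      "constant" = rep(exp(stats::runif(1L, log(rng[1]), log(rng[2]))), nv),
      "random-walk" = {
        d <- numeric(nv)
        d[1] <- exp(stats::runif(1L, log(rng[1]), log(rng[2])))
        if (nv > 1)
          for (j in 2:nv)
            d[j] <- min(max(d[j - 1] * exp(stats::rnorm(1L, 0, 0.15)),
                            rng[1]), rng[2])
        d
      },
      "adaptive" = rep(sqrt(rng[1] * rng[2]), nv)  # filled in below
    )

    row_cov <- data.frame(
      time_months = times, baseline_severity = sev0, sex = sex,
      age_months = age_months, birth_weight_kg = birth_weight_kg,
      weight_kg = round(weight0 + 0.2 * times +
                          stats::rnorm(nv, 0, 0.5), 1),
      risperidone = risperidone, fluoxetine = fluoxetine, odd = odd,
      mood_disorder = mood_disorder, anxiety_disorder = anxiety_disorder,
      other_comorbidity = other_comorbidity
    )

    y <- integer(nv)
    u <- stats::runif(nv)           # one uniform per visit, drawn up front
    for (j in seq_len(nv)) {
      if (config$dose_policy == "adaptive" && j > 1)
        doses[j] <- min(max(doses[j - 1] *
                              (if (y[j - 1] == 1) 0.8 else 1.25),
                            rng[1]), rng[2])
      eta <- linear_predictor(
        p, c(structure(as.numeric(row_cov[j, names(p$beta)[
               names(p$beta) != "severity"], drop = FALSE]),
             names = names(p$beta)[names(p$beta) != "severity"]),
             if ("severity" %in% names(p$beta)) c(severity = sev0)),
        dose = doses[j], b = b_i)
      y[j] <- as.integer(u[j] < inv_logit(eta))
    }
    sev_lo <- stats::runif(nv)      # displayed score given the outcome
    severity_score <- ifelse(y == 1L, 20L + floor(sev_lo * 21),
                             41L + floor(sev_lo * 30))

    visits[[i]] <- cbind(
      data.frame(patient_id = i, visit_index = seq_len(nv) - 1L,
                 time_months = times,
                 severity_score = as.integer(severity_score),
                 dose_mg_per_kg = doses, response = y),
      row_cov[, setdiff(names(row_cov), "time_months"), drop = FALSE]
    )
    baselines[[i]] <- data.frame(
      patient_id = i, baseline_severity = sev0, age_months = age_months,
      sex = sex, birth_weight_kg = birth_weight_kg
    )
  }
  list(visits = do.call(rbind, visits),
       baselines = do.call(rbind, baselines))
}

#' Apply the cohort eligibility criteria
#'
#' Retains patients who meet the ADHD criterion at baseline
#' (CPRS-R:S > 40), are aged 3--13 years (36--156 months), and have at
#' least one follow-up visit after baseline. Patients violating several
#' rules are counted once, under the first violated rule in that order.
#'
#' @param visits Visit table (as produced by [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param baselines Baseline table with columns `patient_id`,
#'   `baseline_severity`, `age_months`.
#' @return A list with the filtered `visits` and `baselines` tables and an
#'   `exclusions` named integer vector of counts by reason
#'   (`baseline_severity`, `age`, `no_followup`).
#' @export
apply_eligibility <- function(visits, baselines) {
  stopifnot(all(c("patient_id") %in% names(visits)),
            all(c("patient_id", "baseline_severity", "age_months") %in%
                  names(baselines)))
  nvis <- table(visits$patient_id)
  n_visits <- as.integer(nvis[as.character(baselines$patient_id)])
  n_visits[is.na(n_visits)] <- 0L

  reason <- rep(NA_character_, nrow(baselines))
  reason[is.na(reason) & !(baselines$baseline_severity > 40)] <-
    "baseline_severity"
  reason[is.na(reason) & (baselines$age_months < 36 |
                            baselines$age_months > 156)] <- "age"
  reason[is.na(reason) & n_visits < 2L] <- "no_followup"

  keep_ids <- baselines$patient_id[is.na(reason)]
  excl <- c(baseline_severity = sum(reason == "baseline_severity",
                                    na.rm = TRUE),
            age = sum(reason == "age", na.rm = TRUE),
            no_followup = sum(reason == "no_followup", na.rm = TRUE))
  list(visits = visits[visits$patient_id %in% keep_ids, , drop = FALSE],
       baselines = baselines[is.na(reason), , drop = FALSE],
       exclusions = excl)
}

#' Write an eligibility exclusion report as JSON
#'
#' @param exclusions Named counts as returned by [apply_eligibility()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(exclusions, path) {
  jsonlite::write_json(as.list(exclusions), path, auto_unbox = TRUE)
  invisible(path)
}

cohort_mandatory_cols <- c("patient_id", "visit_index", "time_months",
                           "severity_score", "dose_mg_per_kg", "response")

#' Read or write a longitudinal visit table as CSV
#'
#' The CSV schema has one row per patient-visit with mandatory columns
#' `patient_id, visit_index, time_months, severity_score, dose_mg_per_kg,
#' response`; any further columns are carried as covariates. Rows are
#' returned sorted by `(patient_id, visit_index)`. Writing then reading a
#' table reproduces numeric values to at least 12 significant digits.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv`: the visit table as a data frame.
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_mandatory_cols, names(x))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (nm in setdiff(names(x), "patient_id")) {
    if (is.character(x[[nm]])) {
      conv <- suppressWarnings(as.numeric(x[[nm]]))
      bad <- which(is.na(conv) & !is.na(x[[nm]]) & nzchar(x[[nm]]))
      if (length(bad))
        stop("non-numeric value in column '", nm, "' at data row ",
             bad[1L])
      x[[nm]] <- conv
    } else {
      x[[nm]] <- as.numeric(x[[nm]])   # uniform double storage
    }
  }
  x <- x[order(x$patient_id, x$visit_index), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' @rdname read_cohort_csv
#' @param visits Visit table to write.
#' @return `write_cohort_csv`: `path`, invisibly.
#' @export
write_cohort_csv <- function(visits, path) {
  miss <- setdiff(cohort_mandatory_cols, names(visits))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  ord <- c(cohort_mandatory_cols,
           setdiff(names(visits), cohort_mandatory_cols))
  utils::write.csv(visits[, ord, drop = FALSE], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
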
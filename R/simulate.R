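#' Configure the synthetic cohort simulator
#'
#' The simulator emulates the structure of a IB-IIA NSCLC surgical cohort:
#' nine covariates (two continuous, seven categorical), roughly 30% observed
#' events, survival times truncated at 215 months of follow-up, and heavy
#' per-entry missingness (default 0.19 per entry, i.e. about 85% of rows
#' carry at least one missing value). Event times follow a Weibull
#' proportional-hazards model with true linear log-hazard `eta = X beta`
#' (plus optional nonlinear terms), so the ground-truth risk of every subject
#' is known and closed-form survival is available for calibration tests.
#' Censoring is exponential with its rate solved by bisection so the realized
#' censoring fraction approaches `censor_rate_target` in expectation.
#'
#' @param n cohort size.
#' @param p_continuous,p_categorical covariate counts (defaults 2 and 7).
#' @param categorical_levels level count per categorical covariate (recycled).
#' @param beta true linear log-hazard coefficients, length
#'   `p_continuous + p_categorical`.
#' @param nonlinear_terms optional list of interaction specs, each a list
#'   with `j` (one index: squared term) or `j`, `k` (pairwise product) and
#'   `coef`.
#' @param weibull_shape,weibull_scale baseline event-time distribution
#'   (scale in months).
#' @param censor_rate_target desired fraction of censored subjects in [0, 1).
#' @param missing_rate per-entry MCAR masking probability in [0, 1).
#' @param admin_cap administrative end of follow-up in months (`Inf` to
#'   disable).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n = 1137,
                              p_continuous = 2,
                              p_categorical = 7,
                              categorical_levels = c(2, 5, 2, 2, 2, 2, 2),
                              beta = NULL,
                              nonlinear_terms = NULL,
                              weibull_shape = 1.3,
                              weibull_scale = 140,
                              censor_rate_target = 0.7,
                              missing_rate = 0.19,
                              admin_cap = 215,
                              seed = 1L) {
  p <- p_continuous + p_categorical
  if (is.null(beta)) {
    # Modest mixed effects: continuous covariates dominate, categorical
    # codes (magnitude up to ~2) contribute smaller per-unit effects.
    beta <- c(rep(c(0.5, -0.35), length.out = p_continuous),
              rep(c(0.25, -0.2, 0.15), length.out = p_categorical))
  }
  cfg <- list(n = as.integer(n), p_continuous = as.integer(p_continuous),
              p_categorical = as.integer(p_categorical),
              categorical_levels = rep(as.integer(categorical_levels),
                                       length.out = p_categorical),
              beta = as.numeric(beta), nonlinear_terms = nonlinear_terms,
              weibull_shape = weibull_shape, weibull_scale = weibull_scale,
              censor_rate_target = censor_rate_target,
              missing_rate = missing_rate, admin_cap = admin_cap,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n < 2) stop_survnet("n must be at least 2")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_survnet("missing_rate must lie in [0, 1)")
  }
  if (cfg$censor_rate_target < 0 || cfg$censor_rate_target >= 1) {
    stop_survnet("censor_rate_target must lie in [0, 1)")
  }
  if (cfg$weibull_shape <= 0 || cfg$weibull_scale <= 0) {
    stop_survnet("Weibull shape and scale must be positive")
  }
  if (length(cfg$beta) != cfg$p_continuous + cfg$p_categorical) {
    stop_survnet("beta must have length p_continuous + p_categorical")
  }
  invisible(cfg)
}

# Schema implied by a simulation config: continuous x1..x<pc>, categorical
# c1..c<pk> with L<k> levels coded symmetrically around zero.
sim_schema <- function(cfg) {
  covs <- list()
  for (j in seq_len(cfg$p_continuous)) {
    covs[[length(covs) + 1]] <- list(name = paste0("x", j), kind = "continuous")
  }
  for (j in seq_len(cfg$p_categorical)) {
    k <- cfg$categorical_levels[j]
    labels <- paste0("L", seq_len(k))
    covs[[length(covs) + 1]] <- list(name = paste0("c", j), kind = "categorical",
                                     codes = symmetric_codes(labels))
  }
  cohort_schema(covs)
}

# Exponential censoring rate hit by bisection: choose lambda so that the
# expected observed-event fraction E[1{e < cap} exp(-lambda e)] equals
# 1 - target, given the realized event times e.
calibrate_censor_rate <- function(event_times, target, admin_cap) {
  if (target <= 0) return(0)
  uncapped <- pmin(event_times, admin_cap)
  event_frac <- function(lambda) mean((event_times < admin_cap) * exp(-lambda * uncapped))
  want <- 1 - target
  if (event_frac(0) <= want) return(0)  # cap alone censors more than requested
  lo <- 0; hi <- 1
  while (event_frac(hi) > want) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (event_frac(mid) > want) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a right-censored cohort with known ground-truth risk
#'
#' Draws covariates (continuous: standard normal; categorical: uniform over
#' the schema codes), computes the true log-hazard, samples
#' proportional-hazards Weibull event times by inverse transform, applies
#' calibrated exponential censoring and an administrative follow-up cap, and
#' finally masks each covariate entry missing independently with probability
#' `missing_rate` (MCAR).
#'
#' @param config a [simulation_config()].
#' @return list with `records` (data.frame as consumed by [encode_cohort()]),
#'   `truth` (per-subject true log-hazard), `schema`, and `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  schema <- sim_schema(cfg)
  p <- cfg$p_continuous + cfg$p_categorical
  with_seed(cfg$seed, {
    n <- cfg$n
    Z <- matrix(0, n, p)
    for (j in seq_len(cfg$p_continuous)) Z[, j] <- stats::rnorm(n)
    for (j in seq_len(cfg$p_categorical)) {
      codes <- schema$covariates[[cfg$p_continuous + j]]$codes
      Z[, cfg$p_continuous + j] <- sample(unname(codes), n, replace = TRUE)
    }
    eta <- drop(Z %*% cfg$beta)
    for (term in cfg$nonlinear_terms %||% list()) {
      if (is.null(term$k)) {
        eta <- eta + term$coef * Z[, term$j]^2
      } else {
        eta <- eta + term$coef * Z[, term$j] * Z[, term$k]
      }
    }
    # S(t | eta) = exp(-(t / scale)^shape * exp(eta)) inverted at U ~ U(0,1).
    u <- stats::runif(n)
    e_time <- cfg$weibull_scale * (-log(u) * exp(-eta))^(1 / cfg$weibull_shape)
    lambda <- calibrate_censor_rate(e_time, cfg$censor_rate_target, cfg$admin_cap)
    c_time <- if (lambda > 0) stats::rexp(n, rate = lambda) else rep(Inf, n)
    c_time <- pmin(c_time, cfg$admin_cap)
    time <- pmin(e_time, c_time)
    event <- as.numeric(e_time <= c_time & is.finite(time))
    # survival times live on (0, cap]; keep them strictly positive
    time <- pmax(time, .Machine$double.eps)

    records <- data.frame(id = sprintf("S%05d", seq_len(n)), stringsAsFactors = FALSE)
    for (j in seq_len(p)) {
      cv <- schema$covariates[[j]]
      if (cv$kind == "continuous") {
        records[[cv$name]] <- Z[, j]
      } else {
        records[[cv$name]] <- names(cv$codes)[match(Z[, j], cv$codes)]
      }
    }
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
      for (j in seq_len(p)) {
        records[[schema$covariates[[j]]$name]][mask[, j]] <- NA
      }
    }
    records$time <- time
    records$event <- event
    list(records = records, truth = eta, schema = schema, config = cfg)
  })
}

#' Concordance of the true log-hazard against simulated outcomes
#'
#' The ceiling any fitted model can approach on a simulated cohort: Harrell's
#' C-index of the ground-truth risk.
#'
#' @param truth per-subject true log-hazard from [simulate_cohort()].
#' @param t,s observed times and event indicators.
#' @return number in [0, 1].
#' @export
oracle_cindex <- function(truth, t, s) concordance_index(truth, t, s)
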
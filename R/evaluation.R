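#' Harrell's concordance index for right-censored data
#'
#' Comparable pairs are anchored at events: ordered pairs `(i, j)` with
#' `s_i = 1` and `t_i < t_j`. A pair is concordant when the earlier event
#' carries the higher risk score (`risk_i > risk_j`, credit 1); tied risks
#' earn credit 0.5. Pairs with tied times are not comparable. The index is
#' total credit over the number of comparable pairs: 0.5 is random ranking,
#' 1 is perfect. Invariant under strictly increasing transforms of the risk.
#'
#' @param risk per-subject risk scores (higher = worse prognosis).
#' @param t observed times.
#' @param s event indicators (1 = death observed).
#' @return number in [0, 1].
#' @export
concordance_index <- function(risk, t, s) {
  risk <- as.numeric(risk)
  stopifnot(length(risk) == length(t), length(t) == length(s))
  ev <- which(s == 1)
  if (length(ev) == 0) stop_survnet("concordance_index: no events, no comparable pairs")
  # anchor rows at events; columns over all subjects with strictly later times
  comparable <- outer(t[ev], t, "<")
  n_pairs <- sum(comparable)
  if (n_pairs == 0) stop_survnet("concordance_index: no comparable pairs")
  conc <- outer(risk[ev], risk, ">")
  tied <- outer(risk[ev], risk, "==")
  (sum(comparable & conc) + 0.5 * sum(comparable & tied)) / n_pairs
}

#' Dichotomize subjects into high- and low-risk groups
#'
#' The threshold PI is the median of the reference scores (by default the
#' scores themselves, i.e. the test-set median). A subject is high-risk
#' when its score is strictly greater than PI; scores equal to PI fall to
#' the low-risk group.
#'
#' @param risk scores to dichotomize.
#' @param reference scores whose median defines the threshold.
#' @return a `risk_groups` list: `threshold`, and `group` (factor with
#'   levels `low`, `high`).
#' @export
dichotomize <- function(risk, reference = risk) {
  stopifnot(length(risk) >= 1, length(reference) >= 1)
  pi_thr <- stats::median(as.numeric(reference))
  grp <- factor(ifelse(as.numeric(risk) > pi_thr, "high", "low"),
                levels = c("low", "high"))
  structure(list(threshold = pi_thr, group = grp), class = "risk_groups")
}

#' Kaplan-Meier product-limit estimator
#'
#' Step-function estimate of the survival function under right censoring,
#' with per-event-time at-risk and death counts and a Greenwood 95%
#' confidence band on the complementary log-log scale. Censored times tied
#' with an event time count as at risk at that time (events first).
#'
#' @param t observed times (positive).
#' @param s event indicators.
#' @param conf_level confidence level for the band.
#' @return a `survival_curve`: `time` (event times), `survival`, `at_risk`,
#'   `deaths`, `lower`, `upper`.
#' @export
kaplan_meier <- function(t, s, conf_level = 0.95) {
  stopifnot(length(t) == length(s), length(t) >= 1)
  if (any(t <= 0)) stop_survnet("times must be positive")
  ev_times <- sort(unique(t[s == 1]))
  if (length(ev_times) == 0) {
    return(structure(list(time = numeric(0), survival = numeric(0),
                          at_risk = integer(0), deaths = integer(0),
                          lower = numeric(0), upper = numeric(0)),
                     class = "survival_curve"))
  }
  at_risk <- vapply(ev_times, function(tk) sum(t >= tk), numeric(1))
  deaths <- vapply(ev_times, function(tk) sum(t == tk & s == 1), numeric(1))
  surv <- cumprod(1 - deaths / at_risk)
  # Greenwood variance on the cloglog scale
  gw <- cumsum(deaths / (at_risk * (at_risk - deaths)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(surv))
  pos <- surv > 0 & surv < 1
  se_cll <- sqrt(gw[pos]) / abs(log(surv[pos]))
  lower[pos] <- surv[pos]^exp(z * se_cll)
  upper[pos] <- surv[pos]^exp(-z * se_cll)
  lower[surv == 0] <- 0; upper[surv == 0] <- 0
  structure(list(time = ev_times, survival = surv,
                 at_risk = as.integer(at_risk), deaths = as.integer(deaths),
                 lower = lower, upper = upper),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Kaplan-Meier curve over", length(x$time), "event times\n")
  if (length(x$time)) {
    print(utils::head(data.frame(time = x$time, at_risk = x$at_risk,
                                 deaths = x$deaths, survival = x$survival), 10))
    if (length(x$time) > 10) cat("...\n")
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Compares the hazard of two groups over time: at each event time the
#' observed number of group-1 events is compared with its expectation under
#' the shared-hazard null, with hypergeometric variance. The statistic
#' `(O - E)^2 / V` is referred to a chi-square distribution on 1 df.
#'
#' @param groups a `risk_groups` from [dichotomize()], or any two-level
#'   factor/vector aligned with `t`.
#' @param t observed times.
#' @param s event indicators.
#' @return list with `statistic`, `p_value`, `observed`, `expected` (both
#'   for the first group level).
#' @export
logrank_test <- function(groups, t, s) {
  g <- if (inherits(groups, "risk_groups")) groups$group else factor(groups)
  stopifnot(length(g) == length(t), length(t) == length(s))
  lev <- levels(droplevels(g))
  if (length(lev) != 2) stop_survnet("logrank_test needs exactly two nonempty groups")
  if (sum(s == 1) == 0) stop_survnet("logrank_test needs at least one event")
  in1 <- g == lev[1]
  ev_times <- sort(unique(t[s == 1]))
  O <- E <- V <- 0
  for (tk in ev_times) {
    at <- t >= tk
    n_tot <- sum(at); n1 <- sum(at & in1)
    d_tot <- sum(t == tk & s == 1); d1 <- sum(t == tk & s == 1 & in1)
    O <- O + d1
    E <- E + d_tot * n1 / n_tot
    if (n_tot > 1) {
      V <- V + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d_tot) / (n_tot - 1)
    }
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Robustness of a trained model to artificially missing inputs
#'
#' Repeats the published input-dropout experiment on a frozen model: each
#' covariate entry of the test matrix is independently set missing (value
#' zeroed and its indicator cleared, indistinguishable from a genuinely
#' missing entry under the zero-fill convention) with probability `dp`, the
#' perturbed cohort is scored in inference mode, and the C-index recorded.
#'
#' @param model trained `survnet_model`.
#' @param test_cohort an `encoded_cohort`.
#' @param dp_grid drop probabilities in [0, 1).
#' @param repeats perturbation repeats per grid point (default 100).
#' @param seed integer; the whole experiment is deterministic given it.
#' @return data.frame in long format: `dp`, `run`, `cindex`.
#' @export
robustness_experiment <- function(model, test_cohort, dp_grid = c(0, 0.2, 0.4),
                                  repeats = 100L, seed = 1L) {
  stopifnot(inherits(model, "survnet_model"), inherits(test_cohort, "encoded_cohort"))
  if (any(dp_grid < 0 | dp_grid >= 1)) stop_survnet("drop probabilities must lie in [0, 1)")
  if (repeats < 1) stop_survnet("repeats must be >= 1")
  X <- test_cohort$X
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    rows <- vector("list", length(dp_grid) * repeats)
    k <- 0
    for (dp in dp_grid) {
      for (run in seq_len(repeats)) {
        if (dp > 0) {
          drop_mask <- matrix(stats::runif(n * p) < dp, n, p)
          Xp <- X; Xp[drop_mask] <- 0
        } else {
          Xp <- X
        }
        out <- survnet_forward(model, Xp, training = FALSE)
        ci <- concordance_index(out$p_x, test_cohort$time, test_cohort$event)
        k <- k + 1
        rows[[k]] <- data.frame(dp = dp, run = run, cindex = ci)
      }
    }
    do.call(rbind, rows)
  })
}
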
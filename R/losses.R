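#' Loss weights for the multi-task objective
#'
#' The total training objective is
#' `J = alpha * J_cox + beta * J_class + gamma * J_rec`, all three terms
#' expressed as losses to minimize (negative log-likelihoods for the Cox and
#' classification terms). Defaults follow the published configuration:
#' alpha = 0.2, beta = 1, gamma = 3, classification horizon T = 36 months.
#'
#' @param alpha Cox partial-likelihood weight.
#' @param beta classification weight.
#' @param gamma reconstruction weight.
#' @param horizon_T classification horizon in months.
#' @export
loss_weights <- function(alpha = 0.2, beta = 1, gamma = 3, horizon_T = 36) {
  if (alpha < 0 || beta < 0 || gamma < 0) stop_survnet("loss weights must be nonnegative")
  if (horizon_T <= 0) stop_survnet("horizon_T must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, horizon_T = horizon_T),
            class = "loss_weights")
}

#' Incomplete-aware reconstruction loss
#'
#' Half mean squared reconstruction error restricted to observed entries:
#' `(1/2n) * sum_i || r_i * (x*_i - x_i) ||^2`. Masked (missing) entries
#' contribute nothing and receive exactly zero gradient, so the decoder is
#' never trained to reproduce the zero-fill placeholder.
#'
#' @param X input matrix (zero-filled).
#' @param X_star reconstruction, same shape.
#' @param R binary missingness-indicator matrix (0 = missing).
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(X, X_star, R) {
  if (!all(dim(X) == dim(X_star)) || !all(dim(X) == dim(R))) {
    stop_survnet("X, X_star and R must share dimensions")
  }
  sum((R * (X_star - X))^2) / (2 * nrow(X))
}

#' Censoring-masked classification targets at a fixed horizon
#'
#' Label `d = 1` for subjects observed beyond the horizon (`t > T`; `t == T`
#' counts as having survived to the horizon), `d = 0` for subjects who died
#' at or before it. Subjects censored before the horizon carry no label:
#' their validity mask `delta` is 0 and they are ignored by the
#' classification loss.
#'
#' @param t observed times.
#' @param s event indicators (1 = death).
#' @param horizon_T horizon in months.
#' @return list with binary vectors `d` and `delta`.
#' @export
classification_targets <- function(t, s, horizon_T) {
  stopifnot(length(t) == length(s))
  if (any(t <= 0)) stop_survnet("times must be positive")
  delta <- as.numeric(!(t < horizon_T & s == 0))
  d <- as.numeric(t > horizon_T | (t == horizon_T))
  d[delta == 0] <- 0  # defined only where delta == 1; zero keeps arithmetic safe
  list(d = d, delta = delta)
}

#' Masked binary cross-entropy for survival classification
#'
#' `-(1/N) * sum_i delta_i * [d_i log a_c + (1 - d_i) log(1 - a_c)]` with
#' `N = sum(delta)`. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before
#' the logs. Rows with `delta = 0` have exactly zero gradient. A batch with
#' no valid rows returns 0 with a warning.
#'
#' @param a_c predicted survival probabilities in (0, 1).
#' @param targets output of [classification_targets()].
#' @return nonnegative scalar.
#' @export
classification_loss <- function(a_c, targets) {
  d <- targets$d; delta <- targets$delta
  stopifnot(length(a_c) == length(d))
  nv <- sum(delta)
  if (nv == 0) {
    warning("classification_loss: no valid rows in batch (all censored before the horizon)")
    return(0)
  }
  p <- clamp(as.numeric(a_c), 1e-7, 1 - 1e-7)
  -sum(delta * (d * log(p) + (1 - d) * log(1 - p))) / nv
}

# Risk-set log-sum-exp for each row: lse[i] = log sum_{j: t[j] >= t[i]} exp(p[j]).
# Sorted cumulative implementation; tied times share one risk set (Breslow).
risk_set_lse <- function(p_x, t) {
  n <- length(t)
  ord <- order(t, decreasing = TRUE)
  ps <- p_x[ord]; ts <- t[ord]
  m <- max(ps)
  cum <- cumsum(exp(ps - m))
  # position of the last element of each tie group in sorted order
  grp_end <- cumsum(rle(ts)$lengths)
  grp_id <- rep(seq_along(grp_end), rle(ts)$lengths)
  lse_sorted <- m + log(cum[grp_end][grp_id])
  lse <- numeric(n)
  lse[ord] <- lse_sorted
  lse
}

#' Negative mean Cox log partial likelihood
#'
#' `-(1/D) * sum_{i: s_i = 1} [p_i - log sum_{j: t_j >= t_i} exp(p_j)]`,
#' with `D` the number of events. Risk sets include the index subject and
#' all ties (Breslow convention); the inner sum uses a numerically stable
#' log-sum-exp. Invariant under adding a constant to all scores and under
#' permutation of subjects.
#'
#' @param p_x prognosis index (log-hazard scale).
#' @param t observed times.
#' @param s event indicators.
#' @param normalize divide by the event count (default) or return the raw
#'   negative sum.
#' @return scalar.
#' @export
cox_loss <- function(p_x, t, s, normalize = TRUE) {
  p_x <- as.numeric(p_x)
  stopifnot(length(p_x) == length(t), length(t) == length(s))
  D <- sum(s == 1)
  if (D == 0) {
    stop_survnet("cox_loss: no events in batch; use larger batches or ",
                 "event-stratified batching")
  }
  lse <- risk_set_lse(p_x, t)
  ll <- sum((p_x - lse)[s == 1])
  if (normalize) -ll / D else -ll
}

# Gradient of cox_loss w.r.t. p_x (normalized form).
cox_loss_grad <- function(p_x, t, s) {
  n <- length(t); D <- sum(s == 1)
  lse <- risk_set_lse(p_x, t)
  ord <- order(t, decreasing = TRUE)
  ts <- t[ord]
  grp_end <- cumsum(rle(ts)$lengths)
  grp_id <- rep(seq_along(grp_end), rle(ts)$lengths)
  # For event i (sorted position q), risk set = sorted positions 1..grp_end[grp_id[q]].
  # grad_k = -(1/D) [ s_k - exp(p_k) * sum_{events i: k in R_i} exp(-lse_i) ].
  c_contrib <- numeric(n)  # event contributions placed at their risk-set end position
  s_sorted <- s[ord]; lse_sorted <- lse[ord]
  ev <- which(s_sorted == 1)
  for (q in ev) {
    e <- grp_end[grp_id[q]]
    c_contrib[e] <- c_contrib[e] + exp(-lse_sorted[q])
  }
  S_sorted <- rev(cumsum(rev(c_contrib)))
  S <- numeric(n); S[ord] <- S_sorted
  -(s - exp(p_x) * S) / D
}

#' Weighted multi-task objective
#'
#' `alpha * cox + beta * classification + gamma * reconstruction`; a term
#' whose module is disabled in the architecture contributes exactly zero
#' regardless of its weight.
#'
#' @param cox,classification,reconstruction the three component losses.
#' @param weights a [loss_weights()].
#' @param arch a [survnet_arch()] (module toggles).
#' @return scalar.
#' @export
total_loss <- function(cox, classification, reconstruction, weights,
                       arch = survnet_arch()) {
  cls <- if (arch$use_classification) weights$beta * classification else 0
  rec <- if (arch$use_reconstruction) weights$gamma * reconstruction else 0
  weights$alpha * cox + cls + rec
}
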
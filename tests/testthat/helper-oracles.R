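# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Harrell's C by explicit double loop over ordered pairs.
brute_cindex <- function(risk, t, s) {
  n <- length(t)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (s[i] != 1) next
    for (j in seq_len(n)) {
      if (t[i] < t[j]) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Negative mean Cox log partial likelihood by explicit loops (Breslow ties,
# risk set t_j >= t_i).
brute_cox_loss <- function(p, t, s) {
  ev <- which(s == 1)
  ll <- 0
  for (i in ev) {
    rs <- which(t >= t[i])
    ll <- ll + p[i] - log(sum(exp(p[rs])))
  }
  -ll / length(ev)
}

# A minimal standalone Cox-Net forward pass (tanh encoder, inference-mode
# batch norm on running stats, tanh hidden, linear head) for the ablation
# identity check.
coxnet_forward <- function(params, bn, eps, X) {
  a2 <- tanh(sweep(X %*% params$We, 2, params$be, "+"))
  xhat <- sweep(sweep(a2, 2, bn$running_mean), 2, 1 / sqrt(bn$running_var + eps), "*")
  a3 <- sweep(sweep(xhat, 2, params$bn_gamma, "*"), 2, params$bn_beta, "+")
  a4 <- tanh(sweep(a3 %*% params$W3, 2, params$b3, "+"))
  drop(sweep(a4 %*% params$wp, 2, params$bp, "+"))
}

schema_names_for_test <- function(schema) {
  vapply(schema$covariates, `[[`, character(1), "name")
}

# Small deterministic censored fixture cohort (records form).
tiny_records <- function() {
  data.frame(
    id = c("p1", "p2", "p3", "p4"),
    age = c(40, 60, 50, NA),
    tumor_size = c(2, NA, 3.5, 1),
    sex = c("Male", "Female", NA, "Male"),
    tumor_location = c("LeftUpper", "RightLower", "RightMiddle", "LeftLower"),
    differentiation = c("Lower", NA, "MiddleOrHigh", "Lower"),
    cancer_type = c("Adenocarcinoma", "Squamous", "Adenocarcinoma", "Squamous"),
    lymph_node = c("Dissection", "Dissection", "BiopsyOrNone", NA),
    pleura_invasion = c("No", "Yes", "No", "Yes"),
    operation = c("Lobectomy", "Lobectomy", "SubLobectomy", "Lobectomy"),
    time = c(12, 40, 7, 90),
    event = c(1, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

# Quick random censored instance generator for property tests.
random_instance <- function(n, tie_times = TRUE, tie_risk = TRUE) {
  t <- if (tie_times) sample(1:8, n, replace = TRUE) else sort(runif(n, 1, 100))
  s <- rbinom(n, 1, 0.6)
  risk <- if (tie_risk) sample(seq(-1, 1, by = 0.5), n, replace = TRUE) else rnorm(n)
  if (sum(s) == 0) s[sample.int(n, 1)] <- 1
  list(risk = risk, t = t, s = s)
}
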
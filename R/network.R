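#' Architecture configuration
#'
#' The default architecture matches the published network settings: a
#' 9-unit input layer, a 64-unit tanh encoder, batch normalization, a 32-unit
#' tanh hidden layer, and three heads: a linear reconstruction decoder
#' (64 -> input), a logistic survival-classification head (32 -> 1), and a
#' linear Cox head (32 -> 1) whose raw log-hazard is gated elementwise by the
#' classification probability (`p_x = a_p * a_c`).
#'
#' @param input_dim number of covariates (default 9).
#' @param encoder_units width of the tanh encoder layer (default 64).
#' @param hidden_units width of the tanh hidden layer (default 32).
#' @param use_batchnorm apply batch normalization to the encoder activation.
#' @param dropout_rate dropout on the hidden activation feeding the Cox head
#'   only; in [0, 1), default 0.
#' @param use_reconstruction,use_classification,use_gating module toggles for
#'   ablations. Gating requires the classification head. With all three off
#'   the model reduces exactly to the Cox-Net baseline.
#' @param bias_terms include bias vectors (default `TRUE`; the strict
#'   equation form omits them).
#' @param batchnorm_epsilon variance floor inside batch normalization.
#' @return a `survnet_arch` list.
#' @export
survnet_arch <- function(input_dim = 9L,
                         encoder_units = 64L,
                         hidden_units = 32L,
                         use_batchnorm = TRUE,
                         dropout_rate = 0,
                         use_reconstruction = TRUE,
                         use_classification = TRUE,
                         use_gating = TRUE,
                         bias_terms = TRUE,
                         batchnorm_epsilon = 1e-5) {
  if (input_dim < 1 || encoder_units < 1 || hidden_units < 1) {
    stop_survnet("all unit counts must be positive")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop_survnet("dropout_rate must lie in [0, 1)")
  if (use_gating && !use_classification) {
    stop_survnet("context gating requires the classification head")
  }
  structure(list(input_dim = as.integer(input_dim),
                 encoder_units = as.integer(encoder_units),
                 hidden_units = as.integer(hidden_units),
                 use_batchnorm = isTRUE(use_batchnorm),
                 dropout_rate = dropout_rate,
                 use_reconstruction = isTRUE(use_reconstruction),
                 use_classification = isTRUE(use_classification),
                 use_gating = isTRUE(use_gating),
                 bias_terms = isTRUE(bias_terms),
                 batchnorm_epsilon = batchnorm_epsilon),
            class = "survnet_arch")
}

# Uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)), for
# both weights and biases (the convention of torch's Linear layers).
init_linear <- function(fan_in, fan_out, bias) {
  b <- 1 / sqrt(fan_in)
  W <- matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
  bv <- if (bias) stats::runif(fan_out, -b, b) else rep(0, fan_out)
  list(W = W, b = bv)
}

#' Initialize a SurvNet model
#'
#' Parameters are drawn with uniform fan-in scaling, deterministically from
#' the seed. Heads disabled in the architecture allocate no parameters.
#'
#' @param arch a [survnet_arch()].
#' @param seed integer.
#' @return a `survnet_model`: parameter list, batch-norm running state, the
#'   architecture, and (once trained) the standardization stats of its
#'   training cohort.
#' @export
init_model <- function(arch = survnet_arch(), seed = 1L) {
  stopifnot(inherits(arch, "survnet_arch"))
  with_seed(seed, {
    p <- arch$input_dim; e <- arch$encoder_units; h <- arch$hidden_units
    bias <- arch$bias_terms
    params <- list()
    enc <- init_linear(p, e, bias); params$We <- enc$W; params$be <- enc$b
    if (arch$use_reconstruction) {
      dec <- init_linear(e, p, bias); params$Wd <- dec$W; params$bd <- dec$b
    }
    if (arch$use_batchnorm) {
      params$bn_gamma <- rep(1, e)
      params$bn_beta <- rep(0, e)
    }
    hid <- init_linear(e, h, bias); params$W3 <- hid$W; params$b3 <- hid$b
    if (arch$use_classification) {
      cls <- init_linear(h, 1, bias); params$wc <- cls$W; params$bc <- cls$b
    }
    cox <- init_linear(h, 1, bias); params$wp <- cox$W; params$bp <- cox$b
    structure(list(params = params,
                   bn = list(running_mean = rep(0, e), running_var = rep(1, e),
                             momentum = 0.1),
                   arch = arch, stats = NULL),
              class = "survnet_model")
  })
}

#' Number of trainable parameters
#' @param model a `survnet_model`.
#' @export
n_parameters <- function(model) {
  free <- model$params
  if (!model$arch$bias_terms) free <- free[!names(free) %in% c("be", "bd", "b3", "bc", "bp")]
  sum(vapply(free, length, integer(1)))
}

#' @export
print.survnet_model <- function(x, ...) {
  a <- x$arch
  cat("survnet_model: ", a$input_dim, " -> ", a$encoder_units, " (tanh)",
      if (a$use_batchnorm) " -> batchnorm", " -> ", a$hidden_units, " (tanh)\n", sep = "")
  cat("  heads: cox",
      if (a$use_classification) "+ classification",
      if (a$use_reconstruction) "+ reconstruction",
      if (a$use_gating) "+ gating", "\n")
  cat("  trainable parameters:", n_parameters(x), "\n")
  invisible(x)
}

add_bias <- function(Z, b) sweep(Z, 2, b, "+")

#' Forward pass
#'
#' Computes every layer activation and the model outputs for a batch:
#' `a2` (encoder tanh activation), `x_star` (linear reconstruction),
#' `a3` (batch-normalized `a2`), `a4` (hidden tanh activation), `a_c`
#' (survival probability at the horizon, logistic head on `a4`), `a_p`
#' (raw log-hazard, linear head on the dropped-out `a4`), and `p_x`
#' (gated prognosis index, `a_p * a_c` when gating is enabled, else `a_p`).
#'
#' In training mode batch normalization uses batch statistics (biased
#' variance) and updates the running moments; dropout is active. In
#' inference mode running statistics are used and dropout is disabled, so
#' the pass is deterministic and batch-size invariant.
#'
#' @param model a `survnet_model`.
#' @param X numeric matrix, one row per subject, `input_dim` columns.
#' @param training logical; batch statistics + dropout when `TRUE`.
#' @return a `survnet_outputs` list; in training mode the element `model`
#'   carries the updated running statistics.
#' @export
survnet_forward <- function(model, X, training = FALSE) {
  stopifnot(inherits(model, "survnet_model"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  arch <- model$arch
  if (ncol(X) != arch$input_dim) {
    stop_survnet("input has ", ncol(X), " columns; architecture expects ", arch$input_dim)
  }
  n <- nrow(X)
  if (training && arch$use_batchnorm && n < 2) {
    stop_survnet("batch normalization needs batch size >= 2 in training mode")
  }
  pp <- model$params
  z2 <- add_bias(X %*% pp$We, pp$be)
  a2 <- tanh(z2)

  x_star <- NULL
  if (arch$use_reconstruction) x_star <- add_bias(a2 %*% pp$Wd, pp$bd)

  bn_cache <- NULL
  if (arch$use_batchnorm) {
    eps <- arch$batchnorm_epsilon
    if (training) {
      mu <- colMeans(a2)
      v <- colMeans(sweep(a2, 2, mu)^2)  # biased batch variance
      inv_std <- 1 / sqrt(v + eps)
      xhat <- sweep(sweep(a2, 2, mu), 2, inv_std, "*")
      m <- model$bn$momentum
      model$bn$running_mean <- (1 - m) * model$bn$running_mean + m * mu
      model$bn$running_var <- (1 - m) * model$bn$running_var + m * v * n / (n - 1)
      bn_cache <- list(xhat = xhat, inv_std = inv_std)
    } else {
      inv_std <- 1 / sqrt(model$bn$running_var + eps)
      xhat <- sweep(sweep(a2, 2, model$bn$running_mean), 2, inv_std, "*")
    }
    a3 <- add_bias(sweep(xhat, 2, pp$bn_gamma, "*"), pp$bn_beta)
  } else {
    a3 <- a2
  }

  z4 <- add_bias(a3 %*% pp$W3, pp$b3)
  a4 <- tanh(z4)

  drop_mask <- NULL
  if (training && arch$dropout_rate > 0) {
    keep <- 1 - arch$dropout_rate
    drop_mask <- matrix(stats::runif(length(a4)) < keep, nrow(a4), ncol(a4)) / keep
    aL <- a4 * drop_mask
  } else {
    aL <- a4
  }

  a_c <- NULL
  if (arch$use_classification) {
    a_c <- 1 / (1 + exp(-add_bias(a4 %*% pp$wc, pp$bc)))
  }
  a_p <- add_bias(aL %*% pp$wp, pp$bp)
  p_x <- if (arch$use_gating) a_p * a_c else a_p

  structure(list(a2 = a2, a3 = a3, a4 = a4, aL = aL,
                 x_star = x_star, a_c = drop(a_c), a_p = drop(a_p), p_x = drop(p_x),
                 bn_cache = bn_cache, drop_mask = drop_mask,
                 model = model),
            class = "survnet_outputs")
}

#' Score a cohort with a trained model
#'
#' Inference-mode forward on an encoded cohort; returns per-patient scores.
#'
#' @param model a `survnet_model`.
#' @param cohort an `encoded_cohort`.
#' @return data.frame with `id`, `p_x`, `a_p`, and (when the head exists)
#'   `a_c`.
#' @export
predict_risk <- function(model, cohort) {
  out <- survnet_forward(model, cohort$X, training = FALSE)
  res <- data.frame(id = cohort$ids, p_x = out$p_x, a_p = out$a_p,
                    stringsAsFactors = FALSE)
  if (!is.null(out$a_c)) res$a_c <- out$a_c
  res
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing JSON (full double precision): parameters,
#' architecture, batch-norm running state, and the training cohort's
#' standardization statistics. Loading restores identical inference outputs.
#'
#' @param model a `survnet_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    format = "survnet-checkpoint-1",
    arch = unclass(model$arch),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p)) else list(data = as.numeric(p))
    }),
    bn = model$bn,
    stats = model$stats
  )
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "survnet-checkpoint-1")) {
    stop_survnet("not a survnet checkpoint: ", path)
  }
  arch <- do.call(survnet_arch, obj$arch[names(formals(survnet_arch))[
    names(formals(survnet_arch)) %in% names(obj$arch)]])
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  })
  stats <- NULL
  if (!is.null(obj$stats) && length(obj$stats)) {
    stats <- lapply(obj$stats, function(s) list(center = s$center, scale = s$scale))
  }
  structure(list(params = params,
                 bn = list(running_mean = as.numeric(obj$bn$running_mean),
                           running_var = as.numeric(obj$bn$running_var),
                           momentum = obj$bn$momentum),
                 arch = arch, stats = stats),
            class = "survnet_model")
}
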
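#' Multi-task loss and analytic parameter gradients for one batch
#'
#' Runs a training-mode forward pass, evaluates the three task losses and
#' their weighted total, and backpropagates analytic gradients with respect
#' to every trainable parameter (verified against central finite differences
#' in the test suite; any change here must keep that test green). The Cox
#' term is skipped, with `cox_skipped = TRUE`, when the batch contains no
#' events; the other task losses still contribute.
#'
#' @param model a `survnet_model`.
#' @param X,R batch covariate and missingness-indicator matrices.
#' @param t,s batch times and event indicators.
#' @param weights a [loss_weights()].
#' @return list with `losses` (the three components), `total`, `grads`
#'   (named list congruent with `model$params`), `model` (running batch-norm
#'   statistics updated), and `cox_skipped`.
#' @export
survnet_loss_grads <- function(model, X, R, t, s, weights) {
  arch <- model$arch
  n <- nrow(X)
  out <- survnet_forward(model, X, training = TRUE)
  model <- out$model  # running batch-norm stats updated
  pp <- model$params

  grads <- lapply(pp, function(p) array(0, dim = dim(p) %||% length(p)))
  grads <- lapply(grads, function(g) if (is.matrix(g)) g else as.numeric(g))

  # ---- task losses -------------------------------------------------------
  J_re <- 0
  if (arch$use_reconstruction) J_re <- reconstruction_loss(X, out$x_star, R)

  tg <- NULL; J_c <- 0; nv <- 0
  if (arch$use_classification) {
    tg <- classification_targets(t, s, weights$horizon_T)
    nv <- sum(tg$delta)
    if (nv > 0) {
      p <- clamp(out$a_c, 1e-7, 1 - 1e-7)
      J_c <- -sum(tg$delta * (tg$d * log(p) + (1 - tg$d) * log(1 - p))) / nv
    }
  }

  cox_skipped <- sum(s == 1) == 0
  J_cox <- 0
  if (!cox_skipped) J_cox <- cox_loss(out$p_x, t, s)

  total <- total_loss(J_cox, J_c, J_re, weights, arch)

  # ---- backward ----------------------------------------------------------
  da4 <- matrix(0, n, arch$hidden_units)
  da2 <- matrix(0, n, arch$encoder_units)

  # Cox head (+ gating path into the classification probability)
  da_c <- numeric(n)
  if (!cox_skipped && weights$alpha > 0) {
    dpx <- weights$alpha * cox_loss_grad(out$p_x, t, s)
    if (arch$use_gating) {
      da_p <- dpx * out$a_c
      da_c <- da_c + dpx * out$a_p
    } else {
      da_p <- dpx
    }
    da_p <- as_column(da_p)
    grads$wp <- grads$wp + t(out$aL) %*% da_p
    grads$bp <- grads$bp + sum(da_p)
    daL <- da_p %*% t(pp$wp)
    if (!is.null(out$drop_mask)) daL <- daL * out$drop_mask
    da4 <- da4 + daL
  }

  # Classification head (reads a4 directly, not the dropped-out activation)
  if (arch$use_classification) {
    dz_c <- da_c * out$a_c * (1 - out$a_c)
    if (nv > 0 && weights$beta > 0) {
      dz_c <- dz_c + weights$beta * tg$delta * (out$a_c - tg$d) / nv
    }
    if (any(dz_c != 0)) {
      dz_c <- as_column(dz_c)
      grads$wc <- grads$wc + t(out$a4) %*% dz_c
      grads$bc <- grads$bc + sum(dz_c)
      da4 <- da4 + dz_c %*% t(pp$wc)
    }
  }

  # Reconstruction decoder
  if (arch$use_reconstruction && weights$gamma > 0) {
    dxs <- weights$gamma * R * (out$x_star - X) / n
    grads$Wd <- grads$Wd + t(out$a2) %*% dxs
    grads$bd <- grads$bd + colSums(dxs)
    da2 <- da2 + dxs %*% t(pp$Wd)
  }

  # Hidden layer
  dz4 <- da4 * (1 - out$a4^2)
  grads$W3 <- grads$W3 + t(out$a3) %*% dz4
  grads$b3 <- grads$b3 + colSums(dz4)
  da3 <- dz4 %*% t(pp$W3)

  # Batch normalization (training statistics)
  if (arch$use_batchnorm) {
    xhat <- out$bn_cache$xhat
    inv_std <- out$bn_cache$inv_std
    grads$bn_gamma <- grads$bn_gamma + colSums(da3 * xhat)
    grads$bn_beta <- grads$bn_beta + colSums(da3)
    dxhat <- sweep(da3, 2, pp$bn_gamma, "*")
    sum_dxhat <- colSums(dxhat)
    sum_dxhat_xhat <- colSums(dxhat * xhat)
    da2 <- da2 + sweep(
      n * dxhat - matrix(sum_dxhat, n, length(sum_dxhat), byrow = TRUE) -
        xhat * matrix(sum_dxhat_xhat, n, length(sum_dxhat_xhat), byrow = TRUE),
      2, inv_std / n, "*")
  } else {
    da2 <- da2 + da3
  }

  # Encoder
  dz2 <- da2 * (1 - out$a2^2)
  grads$We <- grads$We + t(X) %*% dz2
  grads$be <- grads$be + colSums(dz2)

  if (!arch$bias_terms) {
    for (nm in intersect(c("be", "bd", "b3", "bc", "bp"), names(grads))) {
      grads[[nm]] <- grads[[nm]] * 0
    }
  }

  list(losses = list(cox = J_cox, classification = J_c, reconstruction = J_re),
       total = total, grads = grads, model = model, cox_skipped = cox_skipped)
}
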
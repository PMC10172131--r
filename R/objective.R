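#' Similarity and temperature configuration
#'
#' Two similarity measures are supported: the dot product between
#' normalized feature vectors (`"cosine"`, embeddings on the unit
#' hypersphere) and the negative mean squared error (`"negative_mse"`,
#' embeddings in Euclidean space). Both are scaled by the inverse of a
#' temperature `tau` that is either fixed or learned jointly with the
#' encoder. In learnable mode the log inverse temperature
#' `alpha = -log(tau)` is stored as a parameter of the loss and the scaling
#' applied to similarities is `min(exp(alpha), 1/tau_min)`, so the inverse
#' temperature always lies in `(0, 1/tau_min]`.
#'
#' @param kind `"cosine"` or `"negative_mse"`.
#' @param temperature_mode `"fixed"` or `"learnable"`.
#' @param tau initial (or fixed) temperature, positive.
#' @param tau_min lower temperature bound for learnable mode, positive.
#' @return an object of class `similarity_config` (carries the learnable
#'   state `alpha = -log(tau)`).
#' @export
similarity_config <- function(kind = c("cosine", "negative_mse"),
                              temperature_mode = c("fixed", "learnable"),
                              tau = 1, tau_min = 0.1) {
  kind <- match.arg(kind)
  temperature_mode <- match.arg(temperature_mode)
  if (!(is.numeric(tau) && tau > 0)) stop("tau must be positive")
  if (!(is.numeric(tau_min) && tau_min > 0)) stop("tau_min must be positive")
  structure(list(kind = kind, temperature_mode = temperature_mode,
                 tau = tau, tau_min = tau_min, alpha = -log(tau)),
            class = "similarity_config")
}

#' Effective inverse temperature
#'
#' `min(exp(alpha), 1/tau_min)`: the scaling applied to all similarities in
#' learnable-temperature mode. `alpha` is trainable; the clamp guarantees
#' the temperature never drops below `tau_min`.
#'
#' @param alpha log inverse temperature.
#' @param tau_min positive lower temperature bound.
#' @return positive scalar in `(0, 1/tau_min]`.
#' @export
effective_inverse_temperature <- function(alpha, tau_min) {
  if (!(is.numeric(tau_min) && tau_min > 0)) stop("tau_min must be positive")
  min(exp(alpha), 1 / tau_min)
}

as_row <- function(z) if (is.null(dim(z))) matrix(z, nrow = 1L) else z

config_beta <- function(config) {
  if (config$temperature_mode == "learnable")
    effective_inverse_temperature(config$alpha, config$tau_min)
  else 1 / config$tau
}

#' Pairwise similarity scores
#'
#' @param z,z_prime embedding matrices with matching shapes (rows are
#'   compared pairwise).
#' @param config a [similarity_config()].
#' @param check with the cosine kind, verify that inputs are unit-norm.
#' @return numeric vector of temperature-scaled similarity scores; bounded
#'   above by `1/tau` for cosine and by 0 for negative MSE.
#' @export
similarity <- function(z, z_prime, config, check = TRUE) {
  z <- as_row(z); z_prime <- as_row(z_prime)
  beta <- config_beta(config)
  if (config$kind == "cosine") {
    if (check) {
      nrms <- c(rowSums(z^2), rowSums(z_prime^2))
      if (any(abs(nrms - 1) > 1e-4))
        stop("cosine similarity requires unit-norm embeddings (encoder normalize_output = TRUE)")
    }
    rowSums(z * z_prime) * beta
  } else {
    -rowSums((z - z_prime)^2) * beta
  }
}

#' InfoNCE loss over a contrastive batch of embeddings
#'
#' Computes `mean_i [ -psi(x_i, y+_i) + log sum_j exp(psi(x_i, y_j)) ]`
#' where `psi` is the temperature-scaled similarity. The implementation
#' subtracts each row's maximum negative similarity from both terms before
#' exponentiation; the shift cancels analytically, so the value equals the
#' naive formula in exact arithmetic while staying numerically stable. The
#' shift is treated as a constant in differentiation.
#'
#' @param ref_emb,pos_emb `[n x E]` reference and positive embeddings
#'   (row-paired).
#' @param neg_emb `[n x E]` negative embeddings, shared by every reference.
#' @param config a [similarity_config()].
#' @param grad if `TRUE`, also return gradients with respect to the three
#'   embedding matrices and (learnable mode) `alpha`.
#' @return an object of class `loss_result`: `total`, `alignment_term`
#'   (minus the mean positive similarity), `uniformity_term` (mean
#'   log-sum-exp of negative similarities), `n`, `beta`, and `grads` when
#'   requested. `total = alignment_term + uniformity_term`.
#' @export
infonce <- function(ref_emb, pos_emb, neg_emb, config, grad = FALSE) {
  ref_emb <- as_row(ref_emb); pos_emb <- as_row(pos_emb); neg_emb <- as_row(neg_emb)
  n <- nrow(ref_emb)
  if (nrow(pos_emb) != n)
    stop(sprintf("reference and positive batches differ in size (%d vs %d)", n, nrow(pos_emb)))
  m <- nrow(neg_emb)
  if (m < 1L) stop("at least one negative sample is required")
  beta <- config_beta(config)

  if (config$kind == "cosine") {
    pos_raw <- rowSums(ref_emb * pos_emb)           # unscaled similarities
    neg_raw <- ref_emb %*% t(neg_emb)
  } else {
    pos_raw <- -rowSums((ref_emb - pos_emb)^2)
    rsq <- rowSums(ref_emb^2); nsq <- rowSums(neg_emb^2)
    neg_raw <- -(outer(rsq, rep(1, m)) + outer(rep(1, n), nsq) - 2 * ref_emb %*% t(neg_emb))
  }
  pos_sim <- pos_raw * beta
  neg_sim <- neg_raw * beta

  shift <- cpp_row_max(neg_sim)
  expd <- exp(neg_sim - shift)
  rs <- rowSums(expd)
  total <- mean(-(pos_sim - shift) + log(rs))
  alignment <- -mean(pos_sim)
  uniformity <- mean(shift + log(rs))

  res <- structure(list(total = total, alignment_term = alignment,
                        uniformity_term = uniformity, n = n, beta = beta),
                   class = "loss_result")
  if (!grad) return(res)

  S <- expd / rs                                    # softmax over negatives
  if (config$kind == "cosine") {
    d_ref <- beta / n * (-pos_emb + S %*% neg_emb)
    d_pos <- -beta / n * ref_emb
    d_neg <- beta / n * crossprod(S, ref_emb)
  } else {
    d_ref <- 2 * beta / n * ((ref_emb - pos_emb) - (ref_emb - S %*% neg_emb))
    d_pos <- 2 * beta / n * (pos_emb - ref_emb)
    d_neg <- -2 * beta / n * (neg_emb * colSums(S) - crossprod(S, ref_emb))
  }
  d_alpha <- 0
  if (config$temperature_mode == "learnable" && exp(config$alpha) < 1 / config$tau_min) {
    d_alpha <- beta * mean(-pos_raw + rowSums(S * neg_raw))
  }
  res$grads <- list(ref = d_ref, pos = d_pos, neg = d_neg, alpha = d_alpha)
  res
}

#' @export
print.loss_result <- function(x, ...) {
  cat(sprintf("<loss_result> total=%.6f (alignment=%.6f, uniformity=%.6f), n=%d\n",
              x$total, x$alignment_term, x$uniformity_term, x$n))
  invisible(x)
}

#' Goodness of fit of a contrastive model
#'
#' The batch-size-independent transform `L_n - log(n)` of the InfoNCE loss:
#' 0 for an uninformative embedding (e.g. trained on shuffled labels, or any
#' constant similarity) and bounded below by `-D_KL(p || q)`, the divergence
#' between the positive and negative conditionals. Lower is better.
#'
#' @param loss_total InfoNCE loss value (or a `loss_result`).
#' @param n batch size the loss was computed with (taken from the
#'   `loss_result` if one is given).
#' @return `loss_total - log(n)`.
#' @export
goodness_of_fit <- function(loss_total, n = NULL) {
  if (inherits(loss_total, "loss_result")) {
    n <- loss_total$n
    loss_total <- loss_total$total
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("goodness of fit requires the batch size n >= 2")
  loss_total - log(n)
}
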
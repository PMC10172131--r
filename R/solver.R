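#' Training configuration
#'
#' @param max_iterations number of optimizer steps; every step draws a fresh
#'   contrastive batch from the full dataset.
#' @param batch_size number of reference samples per step, or `"full"` for
#'   batch gradient descent over every valid window.
#' @param learning_rate positive step size.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed integer seed; fixes sampling, initialization and therefore
#'   the whole loss trace.
#' @param hybrid_split optional integer pair `(behaviour_dims, time_dims)`
#'   summing to the embedding dimension, used by [fit_hybrid()].
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(max_iterations = 1000L, batch_size = 512L,
                       learning_rate = 3e-4, optimizer = c("adam", "sgd"),
                       seed = 1L, hybrid_split = NULL) {
  optimizer <- match.arg(optimizer)
  if (!identical(batch_size, "full")) {
    batch_size <- as.integer(batch_size)
    if (batch_size < 1L) stop("batch_size must be positive or 'full'")
  }
  if (!(is.numeric(learning_rate) && learning_rate > 0))
    stop("learning_rate must be positive")
  if (!is.null(hybrid_split)) {
    hybrid_split <- as.integer(hybrid_split)
    if (length(hybrid_split) != 2L || any(hybrid_split < 0L))
      stop("hybrid_split must be two non-negative integers")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 batch_size = batch_size, learning_rate = learning_rate,
                 optimizer = optimizer, seed = as.integer(seed),
                 hybrid_split = hybrid_split),
            class = "fit_config")
}

check_fit_consistency <- function(spec, similarity) {
  if (spec$normalize_output && similarity$kind != "cosine")
    stop("normalized encoder output requires the cosine similarity")
  if (!spec$normalize_output && similarity$kind == "cosine")
    stop("cosine similarity requires normalize_output = TRUE")
  invisible(TRUE)
}

## Adam / SGD over the structured parameter lists -----------------------------

make_optimizer_state <- function(encoder) {
  lapply(encoder$layers, function(l) {
    if (l$type %in% c("dense", "conv", "meanconcat"))
      list(mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    else NULL
  })
}

optimizer_step <- function(encoder, grads, opt_state, config, step,
                           trainable = NULL) {
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (li in seq_along(encoder$layers)) {
    if (is.null(grads[[li]])) next
    if (!is.null(trainable) && !(li %in% trainable)) next
    g <- grads[[li]]
    if (config$optimizer == "sgd") {
      encoder$layers[[li]]$W <- encoder$layers[[li]]$W - lr * g$dW
      encoder$layers[[li]]$b <- encoder$layers[[li]]$b - lr * g$db
    } else {
      st <- opt_state[[li]]
      st$mW <- b1 * st$mW + (1 - b1) * g$dW
      st$vW <- b2 * st$vW + (1 - b2) * g$dW^2
      st$mb <- b1 * st$mb + (1 - b1) * g$db
      st$vb <- b2 * st$vb + (1 - b2) * g$db^2
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      encoder$layers[[li]]$W <- encoder$layers[[li]]$W -
        lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
      encoder$layers[[li]]$b <- encoder$layers[[li]]$b -
        lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
      opt_state[[li]] <- st
    }
  }
  list(encoder = encoder, opt_state = opt_state)
}

new_history <- function(n) {
  list(step = integer(n), total = numeric(n), alignment = numeric(n),
       uniformity = numeric(n), temperature = numeric(n), gof = numeric(n))
}

record_history <- function(h, i, loss) {
  h$step[i] <- i
  h$total[i] <- loss$total
  h$alignment[i] <- loss$alignment_term
  h$uniformity[i] <- loss$uniformity_term
  h$temperature[i] <- 1 / loss$beta
  h$gof[i] <- loss$total - log(loss$n)
  h
}

finish_history <- function(h) as.data.frame(h)

#' Fit a contrastive embedding model on one session
#'
#' Runs `max_iterations` optimizer steps; each step draws a fresh batch of
#' reference/positive/negative windows from the full dataset according to
#' the sampling configuration, evaluates the InfoNCE loss and takes one
#' Adam (or SGD) step on the encoder (and on the log inverse temperature in
#' learnable mode). Deterministic given the seed.
#'
#' @param session a `session_data`.
#' @param spec an [encoder_spec()]; its receptive field and normalization
#'   flag must agree with `sampling` and `similarity`.
#' @param sampling a [sampling_config()].
#' @param similarity a [similarity_config()].
#' @param config a [fit_config()].
#' @param verbose print progress every 200 steps.
#' @return an object of class `trained_model` with the encoder(s), configs,
#'   final temperature state, and a per-step loss history
#'   (`total`, `alignment`, `uniformity`, `temperature`, `gof`).
#' @export
fit_contrastive <- function(session, spec, sampling, similarity,
                            config = fit_config(), verbose = FALSE) {
  check_fit_consistency(spec, similarity)
  if (sampling$receptive_field != spec$receptive_field)
    stop("sampling and encoder receptive fields differ")
  set.seed(config$seed)
  encoder <- build_encoder(spec)
  state <- make_sampler_state(session, sampling)
  opt_state <- make_optimizer_state(encoder)
  alpha_state <- c(m = 0, v = 0)
  history <- new_history(config$max_iterations)

  for (it in seq_len(config$max_iterations)) {
    batch <- sample_batch_state(state, config$batch_size)
    res <- contrastive_step(encoder, session, batch, similarity)
    upd <- optimizer_step(encoder, res$grads, opt_state, config, it)
    encoder <- upd$encoder; opt_state <- upd$opt_state
    if (similarity$temperature_mode == "learnable") {
      au <- alpha_step(similarity$alpha, res$loss$grads$alpha, alpha_state, config, it)
      similarity$alpha <- au$alpha; alpha_state <- au$state
    }
    history <- record_history(history, it, res$loss)
    if (verbose && it %% 200L == 0L)
      message(sprintf("step %d: loss %.4f (gof %.4f)", it, res$loss$total, history$gof[it]))
  }

  structure(list(encoders = list(encoder), spec = spec, sampling = sampling,
                 similarity = similarity, fit = config,
                 session_ids = session$session_id,
                 history = finish_history(history)),
            class = "trained_model")
}

# One batch: forward ref/pos/neg in a single pass, loss + gradient, and the
# parameter gradients accumulated over the three roles.
contrastive_step <- function(encoder, session, batch, similarity) {
  rf <- batch$receptive_field
  nr <- length(batch$reference)
  np <- length(batch$positive)
  W <- extract_window_batch(session,
                            c(batch$reference, batch$positive, batch$negative), rf)
  fw <- encoder_forward(encoder, W, keep_cache = TRUE)
  emb <- fw$out
  i_ref <- seq_len(nr)
  i_pos <- nr + seq_len(np)
  i_neg <- (nr + np + 1L):nrow(emb)
  loss <- infonce(emb[i_ref, , drop = FALSE], emb[i_pos, , drop = FALSE],
                  emb[i_neg, , drop = FALSE], similarity, grad = TRUE)
  dEmb <- matrix(0, nrow(emb), ncol(emb))
  dEmb[i_ref, ] <- loss$grads$ref
  dEmb[i_pos, ] <- dEmb[i_pos, , drop = FALSE] + loss$grads$pos
  dEmb[i_neg, ] <- dEmb[i_neg, , drop = FALSE] + loss$grads$neg
  bw <- encoder_backward(encoder, fw$cache, dEmb)
  list(loss = loss, grads = bw$grads)
}

alpha_step <- function(alpha, d_alpha, state, config, step) {
  if (config$optimizer == "sgd") {
    return(list(alpha = alpha - config$learning_rate * d_alpha, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state["m"] <- b1 * state["m"] + (1 - b1) * d_alpha
  state["v"] <- b2 * state["v"] + (1 - b2) * d_alpha^2
  alpha <- alpha - config$learning_rate *
    (state["m"] / (1 - b1^step)) / (sqrt(state["v"] / (1 - b2^step)) + eps)
  list(alpha = unname(alpha), state = state)
}

#' Fit a hybrid (behaviour + time) model
#'
#' A single shared encoder is trained with two InfoNCE terms per step: the
#' behaviour-conditioned loss on the first `hybrid_split[1]` embedding
#' coordinates and the time-conditioned loss on the remaining
#' `hybrid_split[2]` coordinates; the total loss is their unweighted sum.
#' The encoder is built without output normalization; with the cosine
#' similarity each coordinate block is renormalized inside the loss.
#'
#' @param session a `session_data`.
#' @param spec an [encoder_spec()] with `normalize_output = FALSE`.
#' @param behaviour_sampling a behaviour-conditioned [sampling_config()].
#' @param time_sampling a time-conditioned [sampling_config()].
#' @param similarity a [similarity_config()].
#' @param config a [fit_config()] with `hybrid_split` set (summing to the
#'   embedding dimension).
#' @return a `trained_model` (the transform yields the full embedding; the
#'   split is recorded in the model).
#' @export
fit_hybrid <- function(session, spec, behaviour_sampling, time_sampling,
                       similarity, config) {
  if (is.null(config$hybrid_split))
    stop("fit_hybrid requires hybrid_split in the fit configuration")
  split <- config$hybrid_split
  if (sum(split) != spec$output_dimension)
    stop(sprintf("hybrid_split (%d + %d) must sum to the output dimension %d",
                 split[1L], split[2L], spec$output_dimension))
  if (spec$normalize_output)
    stop("fit_hybrid uses per-block normalization; build the encoder with normalize_output = FALSE")
  set.seed(config$seed)
  encoder <- build_encoder(spec)
  st_b <- make_sampler_state(session, behaviour_sampling)
  st_t <- if (split[2L] > 0L) make_sampler_state(session, time_sampling) else NULL
  opt_state <- make_optimizer_state(encoder)
  history <- new_history(config$max_iterations)
  cols_b <- seq_len(split[1L])
  cols_t <- if (split[2L] > 0L) split[1L] + seq_len(split[2L]) else integer(0)

  for (it in seq_len(config$max_iterations)) {
    grads_total <- zero_grads_like(encoder)
    batch_b <- sample_batch_state(st_b, config$batch_size)
    res_b <- hybrid_block_step(encoder, session, batch_b, similarity, cols_b)
    grads_total <- accumulate_grads(grads_total, res_b$grads)
    total <- res_b$loss$total
    align <- res_b$loss$alignment_term
    unif <- res_b$loss$uniformity_term
    if (length(cols_t)) {
      batch_t <- sample_batch_state(st_t, config$batch_size)
      res_t <- hybrid_block_step(encoder, session, batch_t, similarity, cols_t)
      grads_total <- accumulate_grads(grads_total, res_t$grads)
      total <- total + res_t$loss$total
      align <- align + res_t$loss$alignment_term
      unif <- unif + res_t$loss$uniformity_term
    }
    upd <- optimizer_step(encoder, grads_total, opt_state, config, it)
    encoder <- upd$encoder; opt_state <- upd$opt_state
    loss_rec <- list(total = total, alignment_term = align, uniformity_term = unif,
                     beta = res_b$loss$beta, n = res_b$loss$n)
    history <- record_history(history, it, loss_rec)
  }

  structure(list(encoders = list(encoder), spec = spec,
                 sampling = behaviour_sampling, time_sampling = time_sampling,
                 similarity = similarity, fit = config,
                 session_ids = session$session_id,
                 history = finish_history(history)),
            class = "trained_model")
}

hybrid_block_step <- function(encoder, session, batch, similarity, cols) {
  rf <- batch$receptive_field
  nr <- length(batch$reference)
  W <- extract_window_batch(session,
                            c(batch$reference, batch$positive, batch$negative), rf)
  fw <- encoder_forward(encoder, W, keep_cache = TRUE)
  block <- fw$out[, cols, drop = FALSE]
  if (similarity$kind == "cosine") {
    nr_res <- normalize_rows(block)
    z <- nr_res$out
  } else z <- block
  i_ref <- seq_len(nr); i_pos <- nr + seq_len(nr); i_neg <- (2L * nr + 1L):nrow(z)
  loss <- infonce(z[i_ref, , drop = FALSE], z[i_pos, , drop = FALSE],
                  z[i_neg, , drop = FALSE], similarity, grad = TRUE)
  dZ <- matrix(0, nrow(z), ncol(z))
  dZ[i_ref, ] <- loss$grads$ref
  dZ[i_pos, ] <- dZ[i_pos, , drop = FALSE] + loss$grads$pos
  dZ[i_neg, ] <- dZ[i_neg, , drop = FALSE] + loss$grads$neg
  dBlock <- if (similarity$kind == "cosine")
    normalize_rows_backward(z, nr_res$nrm, dZ) else dZ
  dEmb <- matrix(0, nrow(fw$out), ncol(fw$out))
  dEmb[, cols] <- dBlock
  bw <- encoder_backward(encoder, fw$cache, dEmb)
  list(loss = loss, grads = bw$grads)
}

#' Fit a shared embedding across multiple sessions
#'
#' One encoder per session (input dimensionality may differ) is trained
#' jointly into a common embedding space. Every step draws an equal quota of
#' references from each session, matches positives across sessions via the
#' shared continuous context, pools the negatives from all sessions, and
#' applies one InfoNCE over the pooled batch.
#'
#' @param dataset a `multisession_data` with shared context dimensionality.
#' @param spec an [encoder_spec()] template; its `num_input` is replaced
#'   per session.
#' @param sampling a [sampling_config()] with mode `"continuous"` or
#'   `"delta"`.
#' @param similarity a [similarity_config()].
#' @param config a [fit_config()] (`batch_size` is the total reference
#'   count, rounded up to a multiple of the number of sessions).
#' @return a `trained_model` holding one encoder per session.
#' @export
fit_multisession <- function(dataset, spec, sampling, similarity,
                             config = fit_config()) {
  stopifnot(inherits(dataset, "multisession_data"))
  check_fit_consistency(spec, similarity)
  if (identical(config$batch_size, "full"))
    stop("multi-session training uses a fixed per-session quota; give a numeric batch_size")
  N <- dataset$n_sessions
  set.seed(config$seed)
  encoders <- lapply(dataset$sessions, function(s) {
    sp <- spec; sp$num_input <- s$n_signal
    build_encoder(sp)
  })
  states <- lapply(dataset$sessions, make_sampler_state, config = sampling)
  opt_states <- lapply(encoders, make_optimizer_state)
  alpha_state <- c(m = 0, v = 0)
  history <- new_history(config$max_iterations)

  for (it in seq_len(config$max_iterations)) {
    batch <- sample_multisession_batch_state(states, config$batch_size)
    step <- multisession_step(encoders, dataset, batch, similarity)
    for (s in seq_len(N)) {
      upd <- optimizer_step(encoders[[s]], step$grads[[s]], opt_states[[s]], config, it)
      encoders[[s]] <- upd$encoder; opt_states[[s]] <- upd$opt_state
    }
    if (similarity$temperature_mode == "learnable") {
      au <- alpha_step(similarity$alpha, step$loss$grads$alpha, alpha_state, config, it)
      similarity$alpha <- au$alpha; alpha_state <- au$state
    }
    history <- record_history(history, it, step$loss)
  }

  structure(list(encoders = encoders, spec = spec, sampling = sampling,
                 similarity = similarity, fit = config,
                 session_ids = vapply(dataset$sessions, function(s) s$session_id, character(1)),
                 history = finish_history(history)),
            class = "trained_model")
}

# Forward all windows belonging to each session through that session's
# encoder in one pass, assemble the pooled ref/pos/neg embeddings, and route
# the loss gradients back per encoder.
multisession_step <- function(encoders, dataset, batch, similarity) {
  N <- length(encoders)
  rf <- batch$receptive_field
  pos_tab <- batch$positive
  n_ref_per <- lengths(batch$reference)
  ref_offset <- c(0L, cumsum(n_ref_per))
  total_ref <- sum(n_ref_per)
  E <- encoders[[1L]]$spec$output_dimension

  fw <- vector("list", N)
  idx <- vector("list", N)   # per-session row bookkeeping
  ref_emb <- NULL; pos_emb <- NULL; neg_emb <- NULL
  ref_rows <- matrix(0L, total_ref, 2L)  # (session, local row) of each pooled ref
  # global positive order follows pos_tab rows (session-major quota order)
  for (s in seq_len(N)) {
    sess <- dataset$sessions[[s]]
    pos_here <- which(pos_tab$pos_session == s)
    ts <- c(batch$reference[[s]], pos_tab$pos_t[pos_here], batch$negative[[s]])
    W <- extract_window_batch(sess, ts, rf)
    fw[[s]] <- encoder_forward(encoders[[s]], W, keep_cache = TRUE)
    nr <- n_ref_per[s]; np <- length(pos_here); nn <- length(batch$negative[[s]])
    idx[[s]] <- list(ref = seq_len(nr), pos = nr + seq_len(np),
                     neg = nr + np + seq_len(nn), pos_global = pos_here)
  }
  ref_emb <- do.call(rbind, lapply(seq_len(N), function(s)
    fw[[s]]$out[idx[[s]]$ref, , drop = FALSE]))
  pos_emb <- matrix(0, total_ref, E)
  for (s in seq_len(N))
    pos_emb[idx[[s]]$pos_global, ] <- fw[[s]]$out[idx[[s]]$pos, , drop = FALSE]
  neg_emb <- do.call(rbind, lapply(seq_len(N), function(s)
    fw[[s]]$out[idx[[s]]$neg, , drop = FALSE]))

  loss <- infonce(ref_emb, pos_emb, neg_emb, similarity, grad = TRUE)

  grads <- vector("list", N)
  neg_offset <- c(0L, cumsum(lengths(batch$negative)))
  for (s in seq_len(N)) {
    dOut <- matrix(0, nrow(fw[[s]]$out), E)
    dOut[idx[[s]]$ref, ] <- loss$grads$ref[(ref_offset[s] + 1L):ref_offset[s + 1L], , drop = FALSE]
    dOut[idx[[s]]$pos, ] <- dOut[idx[[s]]$pos, , drop = FALSE] +
      loss$grads$pos[idx[[s]]$pos_global, , drop = FALSE]
    dOut[idx[[s]]$neg, ] <- dOut[idx[[s]]$neg, , drop = FALSE] +
      loss$grads$neg[(neg_offset[s] + 1L):neg_offset[s + 1L], , drop = FALSE]
    grads[[s]] <- encoder_backward(encoders[[s]], fw[[s]]$cache, dOut)$grads
  }
  list(loss = loss, grads = grads)
}

#' Embed a session with a trained model
#'
#' Requires no context labels: the transform depends on the signal alone.
#'
#' @param model a `trained_model`.
#' @param session a `session_data` whose signal dimensionality matches the
#'   selected encoder.
#' @param session_index which encoder to use (multi-session models hold one
#'   per training session).
#' @return `[T - rf + 1, E]` embedding matrix with a `time_index` attribute.
#' @export
transform_session <- function(model, session, session_index = 1L) {
  stopifnot(inherits(model, "trained_model"))
  encoder <- model$encoders[[session_index]]
  encode_session(encoder, session)
}

#' Adapt a trained model to an unseen session
#'
#' Re-initializes the input layer to match the new session's signal
#' dimensionality and trains it for `adapt_steps` while all downstream
#' layers stay frozen (set `full_finetune = TRUE` to update everything).
#' With `adapt_steps = 0` and matching dimensionality the model is returned
#' with its pretrained weights intact.
#'
#' @param model a single-session `trained_model`.
#' @param new_session the session to adapt to.
#' @param config a [fit_config()] for the adaptation steps.
#' @param adapt_steps number of optimizer steps.
#' @param full_finetune unfreeze all layers.
#' @return a `trained_model` for the new session (its `history` covers the
#'   adaptation steps).
#' @export
adapt_model <- function(model, new_session, config = fit_config(max_iterations = 1L),
                        adapt_steps = config$max_iterations, full_finetune = FALSE) {
  stopifnot(inherits(model, "trained_model"))
  encoder <- model$encoders[[1L]]
  spec <- encoder$spec
  set.seed(config$seed)
  param_layers <- encoder_param_layers(encoder)
  first <- param_layers[1L]
  if (new_session$n_signal != spec$num_input) {
    if (spec$receptive_field == 40L)
      stop("the receptive-field-40 front end couples the input width to two layers; adapt requires matching dimensionality here")
    old <- encoder$layers[[first]]
    encoder$layers[[first]] <- if (old$type == "dense")
      layer_dense(new_session$n_signal, ncol(old$W))
    else layer_conv(old$kernel, new_session$n_signal, old$n_out,
                    stride = old$stride, skip = old$skip)
    spec$num_input <- new_session$n_signal
    encoder$spec <- spec
  } else {
    # fresh input layer even at equal width, unless no training is requested
    if (adapt_steps > 0L) {
      old <- encoder$layers[[first]]
      encoder$layers[[first]] <- if (old$type == "dense")
        layer_dense(nrow(old$W), ncol(old$W))
      else if (old$type == "conv")
        layer_conv(old$kernel, old$n_in, old$n_out, stride = old$stride, skip = old$skip)
      else layer_meanconcat(old$kernel, old$n_in, old$n_out, stride = old$stride)
    }
  }
  trainable <- if (full_finetune) param_layers else first
  state <- make_sampler_state(new_session, model$sampling)
  opt_state <- make_optimizer_state(encoder)
  similarity <- model$similarity
  history <- new_history(adapt_steps)
  if (adapt_steps > 0L) {
    for (it in seq_len(adapt_steps)) {
      batch <- sample_batch_state(state, config$batch_size)
      res <- contrastive_step(encoder, new_session, batch, similarity)
      upd <- optimizer_step(encoder, res$grads, opt_state, config, it,
                            trainable = trainable)
      encoder <- upd$encoder; opt_state <- upd$opt_state
      history <- record_history(history, it, res$loss)
    }
  }
  structure(list(encoders = list(encoder), spec = spec,
                 sampling = model$sampling, similarity = similarity,
                 fit = config, session_ids = new_session$session_id,
                 history = finish_history(history)),
            class = "trained_model")
}

#' Evaluate the InfoNCE loss of a model on a session
#'
#' Draws one contrastive batch (freshly, from the model's sampling
#' configuration) and evaluates the loss without updating any parameters.
#'
#' @param model a `trained_model`.
#' @param session a `session_data`.
#' @param n batch size or `"full"`.
#' @param session_index which encoder to use.
#' @return a `loss_result`.
#' @export
evaluate_loss <- function(model, session, n = "full", session_index = 1L) {
  state <- make_sampler_state(session, model$sampling)
  batch <- sample_batch_state(state, n)
  encoder <- model$encoders[[session_index]]
  rf <- batch$receptive_field
  nr <- length(batch$reference)
  W <- extract_window_batch(session, c(batch$reference, batch$positive, batch$negative), rf)
  emb <- encoder_forward(encoder, W)$out
  i_ref <- seq_len(nr); i_pos <- nr + seq_len(nr); i_neg <- (2L * nr + 1L):nrow(emb)
  infonce(emb[i_ref, , drop = FALSE], emb[i_pos, , drop = FALSE],
          emb[i_neg, , drop = FALSE], model$similarity)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d encoder(s), E=%d, %d steps, final loss %.4f (gof %.4f)\n",
              length(x$encoders), x$spec$output_dimension,
              nrow(x$history), utils::tail(x$history$total, 1L),
              utils::tail(x$history$gof, 1L)))
  invisible(x)
}
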
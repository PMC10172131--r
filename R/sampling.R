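#' Sampling configuration for contrastive pairs
#'
#' The geometry of the learned embedding is shaped entirely by how
#' reference, positive and negative samples are drawn. Five conditionals are
#' supported for the positive distribution `p(y|x)`:
#' \describe{
#'   \item{time}{positive at a time offset drawn uniformly from `time_offsets`.}
#'   \item{discrete}{positive drawn uniformly among samples sharing the
#'     reference's categorical label.}
#'   \item{continuous}{an empirical difference `d = c[t+tau] - c[t]` is drawn
#'     uniformly over all `(t, tau in time_offsets)`, and the positive is the
#'     sample whose context is nearest (Euclidean) to `c_ref + d`.}
#'   \item{delta}{a target context is drawn from `Normal(c_ref, delta^2 I)`
#'     and the positive is the nearest sample in context space.}
#'   \item{mixed}{the continuous conditional restricted to candidates that
#'     share the reference's categorical label.}
#' }
#' References and negatives are drawn from the empirical distribution over
#' valid windows; with `"uniform_over_category"` the marginal over the
#' categorical label is flattened (sampling a category uniformly via the
#' cumulative label histogram, then a member uniformly), which makes the
#' embedding invariant to that label when applied to both positives and
#' negatives.
#'
#' @param mode one of `"time"`, `"discrete"`, `"continuous"`, `"mixed"`,
#'   `"delta"`.
#' @param time_offsets positive integer offsets (required for time /
#'   continuous / mixed modes).
#' @param delta positive standard deviation of the Gaussian positive
#'   conditional (mode `"delta"`).
#' @param negative_mode,reference_mode `"empirical"` or
#'   `"uniform_over_category"`.
#' @param receptive_field encoder window length; sampling is restricted to
#'   time indices whose full window fits in the session.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(mode = c("time", "discrete", "continuous", "mixed", "delta"),
                            time_offsets = NULL, delta = NULL,
                            negative_mode = c("empirical", "uniform_over_category"),
                            reference_mode = c("empirical", "uniform_over_category"),
                            receptive_field = 1L) {
  mode <- match.arg(mode)
  negative_mode <- match.arg(negative_mode)
  reference_mode <- match.arg(reference_mode)
  if (mode %in% c("time", "continuous", "mixed")) {
    if (is.null(time_offsets) || length(time_offsets) == 0L)
      stop(sprintf("mode '%s' requires a non-empty set of time_offsets", mode))
    time_offsets <- sort(unique(as.integer(time_offsets)))
    if (any(time_offsets < 1L)) stop("time_offsets must be positive integers")
  }
  if (mode == "delta") {
    if (is.null(delta) || !(is.numeric(delta) && delta > 0))
      stop("mode 'delta' requires a positive delta")
  }
  structure(list(mode = mode, time_offsets = time_offsets, delta = delta,
                 negative_mode = negative_mode, reference_mode = reference_mode,
                 receptive_field = as.integer(receptive_field)),
            class = "sampling_config")
}

check_sampling_config <- function(session, config) {
  if (config$mode == "discrete" && session$n_categories == 0L)
    stop("mode 'discrete' requires a discrete context")
  if (config$mode %in% c("continuous", "delta") && session$n_context == 0L)
    stop(sprintf("mode '%s' requires a continuous context", config$mode))
  if (config$mode == "mixed" &&
      (session$n_context == 0L || session$n_categories == 0L))
    stop("mode 'mixed' requires both continuous and discrete contexts")
  if (config$reference_mode == "uniform_over_category" && session$n_categories == 0L)
    stop("uniform_over_category reference sampling requires a discrete context")
  if (config$negative_mode == "uniform_over_category" && session$n_categories == 0L)
    stop("uniform_over_category negative sampling requires a discrete context")
  invisible(TRUE)
}

## Precomputed per-(session, config) sampling structures: the valid window
## set, per-category member lists, the empirical difference multiset D and a
## sorted 1D context view for fast nearest-neighbour lookups.
make_sampler_state <- function(session, config) {
  check_sampling_config(session, config)
  valid <- valid_window_indices(session, config$receptive_field)
  state <- list(session = session, config = config, valid = valid,
                n_valid = length(valid))
  if (session$n_context > 0L) {
    state$ctx <- session$continuous_context[valid + 1L, , drop = FALSE]
    state$ctx_nn <- make_nn_index(state$ctx)
  }
  if (session$n_categories > 0L) {
    kv <- session$discrete_context[valid + 1L]
    state$k_valid <- kv
    state$cat_members <- split(seq_along(valid), factor(kv, levels = 0:(session$n_categories - 1L)))
    if (session$n_context > 0L) {
      state$cat_nn <- lapply(state$cat_members, function(idx) {
        if (length(idx) == 0L) return(NULL)
        make_nn_index(state$ctx[idx, , drop = FALSE])
      })
    }
  }
  if (config$mode %in% c("continuous", "mixed")) {
    state$diff_set <- empirical_difference_set(session, config$time_offsets)
  }
  if (config$mode == "time") {
    # restrict the reference marginal to indices with at least one valid
    # forward offset (the valid window set is contiguous)
    usable <- valid + min(config$time_offsets) <= valid[length(valid)]
    if (!any(usable)) stop("no reference admits a valid time offset")
    state$ref_positions <- which(usable)
  }
  state
}

# All context differences c[t+tau] - c[t] over valid (t, t+tau) pairs.
empirical_difference_set <- function(session, time_offsets) {
  cc <- session$continuous_context
  T_len <- session$n_time
  parts <- lapply(time_offsets, function(tau) {
    if (tau >= T_len) return(NULL)
    cc[(tau + 1L):T_len, , drop = FALSE] - cc[1:(T_len - tau), , drop = FALSE]
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L)
    stop("empirical difference set is empty: all time offsets exceed the session length")
  do.call(rbind, parts)
}

## Nearest-neighbour index over candidate context rows. 1D contexts use a
## sorted vector + findInterval (O(log n) per query); higher dimensions fall
## back to a blocked brute-force distance computation. Ties break to the
## smallest candidate (hence smallest time) index.
make_nn_index <- function(ctx) {
  if (ncol(ctx) == 1L) {
    ord <- order(ctx[, 1L])  # stable: equal values keep index order
    list(kind = "sorted1d", values = ctx[ord, 1L], order = ord, n = nrow(ctx))
  } else {
    list(kind = "brute", ctx = ctx, sq = rowSums(ctx^2), n = nrow(ctx))
  }
}

nn_lookup <- function(index, queries) {
  if (index$kind == "sorted1d") {
    q <- queries[, 1L]
    v <- index$values
    n <- index$n
    pos <- findInterval(q, v, all.inside = FALSE)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, n)
    # first occurrence of each candidate value: stable sort order puts the
    # smallest original index first among duplicates
    f_lo <- findInterval(v[lo], v, left.open = TRUE) + 1L
    f_hi <- findInterval(v[hi], v, left.open = TRUE) + 1L
    d_lo <- abs(q - v[lo])
    d_hi <- abs(v[hi] - q)
    pick_hi <- d_hi < d_lo | (d_hi == d_lo & index$order[f_hi] < index$order[f_lo])
    index$order[ifelse(pick_hi, f_hi, f_lo)]
  } else {
    # argmin over candidates of ||q - c||^2 = argmax of 2 q.c - ||c||^2
    cpp_argmax_rows(queries %*% t(index$ctx), index$sq)
  }
}

draw_from_members <- function(members, n) {
  if (length(members) == 1L) rep.int(members, n) else sample(members, n, replace = TRUE)
}

sample_marginal <- function(state, n, mode, reference = FALSE) {
  if (n <= 0L) stop("n must be positive")
  if (reference && !is.null(state$ref_positions)) {
    pos <- draw_from_members(state$ref_positions, n)
  } else if (mode == "empirical" || state$session$n_categories == 0L) {
    pos <- draw_from_members(seq_len(state$n_valid), n)
  } else {
    sizes <- lengths(state$cat_members)
    cats <- which(sizes > 0L)
    if (length(cats) == 0L) stop("no category has a valid member")
    drawn <- draw_from_members(cats, n)
    pos <- integer(n)
    for (k in cats) {
      sel <- which(drawn == k)
      if (length(sel)) pos[sel] <- draw_from_members(state$cat_members[[k]], length(sel))
    }
  }
  pos  # positions into state$valid
}

#' Draw reference samples
#'
#' @param session a `session_data`.
#' @param n number of samples.
#' @param config a [sampling_config()].
#' @return 0-based time indices of length `n`. Uses R's global RNG; seed with
#'   [set.seed()] for reproducibility.
#' @export
sample_reference <- function(session, n, config) {
  state <- make_sampler_state(session, config)
  state$valid[sample_marginal(state, n, config$reference_mode, reference = TRUE)]
}

#' Draw negative samples
#'
#' @inheritParams sample_reference
#' @export
sample_negative <- function(session, n, config) {
  state <- make_sampler_state(session, config)
  state$valid[sample_marginal(state, n, config$negative_mode)]
}

positive_discrete_state <- function(state, ref_pos) {
  k <- state$k_valid[ref_pos]
  out <- integer(length(ref_pos))
  for (kk in unique(k)) {
    members <- state$cat_members[[kk + 1L]]
    if (length(members) == 0L)
      stop(sprintf("category %d has no valid member", kk))
    sel <- which(k == kk)
    out[sel] <- draw_from_members(members, length(sel))
  }
  out
}

positive_continuous_state <- function(state, ref_pos) {
  D <- state$diff_set
  d_idx <- draw_from_members(seq_len(nrow(D)), length(ref_pos))
  target <- state$ctx[ref_pos, , drop = FALSE] + D[d_idx, , drop = FALSE]
  nn_lookup(state$ctx_nn, target)
}

positive_delta_state <- function(state, ref_pos) {
  m <- ncol(state$ctx)
  noise <- matrix(stats::rnorm(length(ref_pos) * m, sd = state$config$delta), ncol = m)
  target <- state$ctx[ref_pos, , drop = FALSE] + noise
  nn_lookup(state$ctx_nn, target)
}

positive_time_state <- function(state, ref_pos) {
  offs <- state$config$time_offsets
  ref_t <- state$valid[ref_pos]
  vmax <- state$valid[state$n_valid]
  valid_set <- logical(vmax + 1L)
  valid_set[state$valid + 1L] <- TRUE
  out <- integer(length(ref_pos))
  for (i in seq_along(ref_pos)) {
    cand <- ref_t[i] + offs
    cand <- cand[cand <= vmax & valid_set[cand + 1L]]
    if (length(cand) == 0L)
      stop(sprintf("no valid time offset for reference index %d", ref_t[i]))
    out[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  match(out, state$valid)
}

positive_mixed_state <- function(state, ref_pos) {
  D <- state$diff_set
  d_idx <- draw_from_members(seq_len(nrow(D)), length(ref_pos))
  target <- state$ctx[ref_pos, , drop = FALSE] + D[d_idx, , drop = FALSE]
  k <- state$k_valid[ref_pos]
  out <- integer(length(ref_pos))
  for (kk in unique(k)) {
    sel <- which(k == kk)
    members <- state$cat_members[[kk + 1L]]
    if (length(members) == 0L)
      stop(sprintf("no candidate shares category %d", kk))
    local <- nn_lookup(state$cat_nn[[kk + 1L]], target[sel, , drop = FALSE])
    out[sel] <- members[local]
  }
  out
}

positive_state <- function(state, ref_pos) {
  switch(state$config$mode,
         time = positive_time_state(state, ref_pos),
         discrete = positive_discrete_state(state, ref_pos),
         continuous = positive_continuous_state(state, ref_pos),
         delta = positive_delta_state(state, ref_pos),
         mixed = positive_mixed_state(state, ref_pos))
}

#' Draw one positive sample per reference index
#'
#' Exposed per conditional for testing; [sample_batch()] is the training
#' entry point.
#'
#' @param session a `session_data`.
#' @param ref_t 0-based reference time indices (must be valid windows).
#' @param config a [sampling_config()] whose mode selects the conditional.
#' @return 0-based positive time indices, one per reference.
#' @export
sample_positive <- function(session, ref_t, config) {
  state <- make_sampler_state(session, config)
  ref_pos <- match(as.integer(ref_t), state$valid)
  if (anyNA(ref_pos)) stop("some reference indices are not valid windows")
  state$valid[positive_state(state, ref_pos)]
}

#' Draw a full contrastive batch
#'
#' Draws `n` references from the configured marginal, one positive per
#' reference from the configured conditional, and `n` negatives shared by
#' all references. All draws are taken from the full dataset, not from a
#' pre-drawn minibatch.
#'
#' @param session a `session_data`.
#' @param n batch size, or `"full"` to use every valid window as a reference
#'   (and as the negative pool).
#' @param config a [sampling_config()].
#' @return an object of class `contrastive_batch`: list with 0-based integer
#'   vectors `reference`, `positive`, `negative` of equal length and the
#'   `receptive_field`.
#' @export
sample_batch <- function(session, n, config) {
  state <- make_sampler_state(session, config)
  sample_batch_state(state, n)
}

sample_batch_state <- function(state, n) {
  full <- identical(n, "full")
  if (full) {
    ref_pos <- state$ref_positions %||% seq_len(state$n_valid)
    neg_pos <- seq_len(state$n_valid)
  } else {
    n <- as.integer(n)
    ref_pos <- sample_marginal(state, n, state$config$reference_mode, reference = TRUE)
    neg_pos <- sample_marginal(state, n, state$config$negative_mode)
  }
  pos_pos <- positive_state(state, ref_pos)
  structure(list(reference = state$valid[ref_pos],
                 positive = state$valid[pos_pos],
                 negative = state$valid[neg_pos],
                 receptive_field = state$config$receptive_field),
            class = "contrastive_batch")
}

#' Draw a multi-session contrastive batch
#'
#' References are allocated in equal quotas of `ceiling(n / N)` per session
#' irrespective of session length; for every reference a positive session is
#' drawn uniformly and the positive found there by continuous-context
#' matching against the reference's context; negatives are drawn uniformly
#' across sessions (an equal quota from each session's empirical
#' distribution).
#'
#' @param dataset a `multisession_data` whose sessions share continuous
#'   context dimensionality.
#' @param n total number of references (rounded up to a multiple of the
#'   number of sessions).
#' @param config a [sampling_config()] with mode `"continuous"` or `"delta"`.
#' @return an object of class `multisession_batch`: list with per-session
#'   `reference` and `negative` index vectors, and a `positive` data frame
#'   with columns `ref_session`, `ref_t`, `pos_session`, `pos_t`.
#' @export
sample_multisession_batch <- function(dataset, n, config) {
  states <- lapply(dataset$sessions, make_sampler_state, config = config)
  sample_multisession_batch_state(states, n)
}

sample_multisession_batch_state <- function(states, n) {
  N <- length(states)
  if (N == 1L) {
    # single session: reduces to ordinary batching under its own conditional
    b <- sample_batch_state(states[[1L]], n)
    return(structure(list(reference = list(b$reference),
                          negative = list(b$negative),
                          positive = data.frame(ref_session = 1L, ref_t = b$reference,
                                                pos_session = 1L, pos_t = b$positive),
                          receptive_field = b$receptive_field),
                     class = "multisession_batch"))
  }
  if (N >= 2L) {
    m <- unique(vapply(states, function(s) ncol(s$ctx %||% matrix(0, 0, 0)), integer(1)))
    if (length(m) != 1L)
      stop("multi-session sampling requires a shared continuous context dimensionality")
    if (!states[[1L]]$config$mode %in% c("continuous", "delta"))
      stop("multi-session sampling supports the continuous and delta conditionals")
  }
  quota <- as.integer(ceiling(n / N))
  reference <- vector("list", N)
  negative <- vector("list", N)
  pos_rows <- vector("list", N)
  for (i in seq_len(N)) {
    st <- states[[i]]
    ref_pos <- sample_marginal(st, quota, st$config$reference_mode, reference = TRUE)
    reference[[i]] <- st$valid[ref_pos]
    negative[[i]] <- st$valid[sample_marginal(st, quota, st$config$negative_mode)]
    pos_session <- draw_from_members(seq_len(N), quota)
    ref_ctx <- st$ctx[ref_pos, , drop = FALSE]
    pos_t <- integer(quota)
    for (j in unique(pos_session)) {
      sel <- which(pos_session == j)
      stj <- states[[j]]
      if (st$config$mode == "delta") {
        noise <- matrix(stats::rnorm(length(sel) * ncol(ref_ctx), sd = st$config$delta),
                        ncol = ncol(ref_ctx))
        target <- ref_ctx[sel, , drop = FALSE] + noise
      } else {
        D <- stj$diff_set
        d_idx <- draw_from_members(seq_len(nrow(D)), length(sel))
        target <- ref_ctx[sel, , drop = FALSE] + D[d_idx, , drop = FALSE]
      }
      pos_t[sel] <- stj$valid[nn_lookup(stj$ctx_nn, target)]
    }
    pos_rows[[i]] <- data.frame(ref_session = i, ref_t = reference[[i]],
                                pos_session = pos_session, pos_t = pos_t)
  }
  structure(list(reference = reference, negative = negative,
                 positive = do.call(rbind, pos_rows),
                 receptive_field = states[[1L]]$config$receptive_field),
            class = "multisession_batch")
}
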
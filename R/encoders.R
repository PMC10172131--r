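#' Encoder architecture specification
#'
#' Three feature-extractor families are provided, selected by the receptive
#' field (the number of consecutive time samples consumed per embedding
#' vector):
#' \describe{
#'   \item{1}{a four-layer MLP: `D -> H`, `H -> H`, `H -> H/2` (bottleneck),
#'     `H/2 -> E`.}
#'   \item{10}{five time-convolution layers with kernel sizes 2,3,3,3,3; the
#'     three middle layers carry additive skip connections; the final layer
#'     maps `H -> E`.}
#'   \item{40}{a front end concatenating a fixed 2x average-pool downsample
#'     of the input with a learned downsample (kernel 4, stride 2), directly
#'     followed (no activation between) by a kernel-3 stride-2 convolution —
#'     a net 4x subsampling — then three kernel-3 skip layers and a final
#'     kernel-3 layer to `E`.}
#' }
#' GELU activations follow every layer except the last. All convolutions are
#' valid (no padding), so each family consumes exactly `receptive_field`
#' samples per output. When `normalize_output` is `TRUE` the output is
#' L2-normalized onto the unit hypersphere; this must be paired with the
#' cosine similarity (and must be `FALSE` for the negative-MSE similarity).
#'
#' @param receptive_field 1, 10 or 40.
#' @param num_input signal dimensionality `D`.
#' @param num_hidden hidden width `H` (must be at least 2 so the MLP
#'   bottleneck `H/2` is at least 1).
#' @param output_dimension embedding dimensionality `E`.
#' @param normalize_output logical.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(receptive_field, num_input, num_hidden = 32L,
                         output_dimension = 8L, normalize_output = TRUE) {
  receptive_field <- as.integer(receptive_field)
  if (!receptive_field %in% c(1L, 10L, 40L))
    stop("receptive_field must be 1, 10 or 40")
  if (num_hidden %/% 2L < 1L) stop("num_hidden / 2 must be at least 1")
  structure(list(receptive_field = receptive_field,
                 num_input = as.integer(num_input),
                 num_hidden = as.integer(num_hidden),
                 output_dimension = as.integer(output_dimension),
                 normalize_output = isTRUE(normalize_output)),
            class = "encoder_spec")
}

## Layer constructors. Weights use fan-in-scaled uniform initialization
## (U(-1/sqrt(fan_in), 1/sqrt(fan_in))), drawn from R's global RNG.

init_mat <- function(nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

layer_dense <- function(n_in, n_out) {
  list(type = "dense", W = init_mat(n_in, n_out, n_in),
       b = stats::runif(n_out, -1 / sqrt(n_in), 1 / sqrt(n_in)))
}

layer_conv <- function(kernel, n_in, n_out, stride = 1L, skip = FALSE) {
  fan_in <- kernel * n_in
  list(type = "conv", kernel = as.integer(kernel), stride = as.integer(stride),
       skip = isTRUE(skip), n_in = n_in, n_out = n_out,
       W = init_mat(fan_in, n_out, fan_in),
       b = stats::runif(n_out, -1 / sqrt(fan_in), 1 / sqrt(fan_in)))
}

layer_meanconcat <- function(kernel, n_in, n_out, stride = 2L) {
  fan_in <- kernel * n_in
  list(type = "meanconcat", kernel = as.integer(kernel), stride = as.integer(stride),
       n_in = n_in, n_out = n_out,
       W = init_mat(fan_in, n_out, fan_in),
       b = stats::runif(n_out, -1 / sqrt(fan_in), 1 / sqrt(fan_in)))
}

layer_simple <- function(type) list(type = type)

#' Build an encoder with freshly initialized parameters
#'
#' @param spec an [encoder_spec()].
#' @return an object of class `contrast_encoder` (spec + parameter layers).
#'   Initialization draws from R's global RNG; seed with [set.seed()].
#' @export
build_encoder <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  D <- spec$num_input; H <- spec$num_hidden; E <- spec$output_dimension
  layers <- switch(as.character(spec$receptive_field),
    "1" = list(layer_simple("flatten"),
               layer_dense(D, H), layer_simple("gelu"),
               layer_dense(H, H), layer_simple("gelu"),
               layer_dense(H, H %/% 2L), layer_simple("gelu"),
               layer_dense(H %/% 2L, E)),
    "10" = list(layer_conv(2L, D, H), layer_simple("gelu"),
                layer_conv(3L, H, H, skip = TRUE), layer_simple("gelu"),
                layer_conv(3L, H, H, skip = TRUE), layer_simple("gelu"),
                layer_conv(3L, H, H, skip = TRUE), layer_simple("gelu"),
                layer_conv(3L, H, E), layer_simple("flatten")),
    "40" = list(layer_meanconcat(4L, D, H),
                layer_conv(3L, D + H, H, stride = 2L), layer_simple("gelu"),
                layer_conv(3L, H, H, skip = TRUE), layer_simple("gelu"),
                layer_conv(3L, H, H, skip = TRUE), layer_simple("gelu"),
                layer_conv(3L, H, H, skip = TRUE), layer_simple("gelu"),
                layer_conv(3L, H, E), layer_simple("flatten")))
  if (spec$normalize_output) layers <- c(layers, list(layer_simple("normalize")))
  structure(list(spec = spec, layers = layers), class = "contrast_encoder")
}

#' @export
print.contrast_encoder <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<contrast_encoder> RF=%d, D=%d, H=%d, E=%d, normalized=%s, %d layers\n",
              s$receptive_field, s$num_input, s$num_hidden, s$output_dimension,
              s$normalize_output, length(x$layers)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Forward / backward passes. Activations flow as [n, L, C] arrays until a
## flatten squeezes the (length-1) time axis; gradients retrace the same
## path.

# GELU, tanh formulation (matches the erf form to ~1e-3 absolute); the
# gradient is the exact derivative of that expression. Both are elementwise
# C++ kernels that preserve the input's shape.
gelu <- function(x) cpp_gelu(x)
gelu_grad <- function(x) cpp_gelu_grad(x)

conv_out_len <- function(L, kernel, stride) (L - kernel) %/% stride + 1L

slab <- function(X, idx) {
  # [n, |idx|, C] slice flattened to [n, |idx| * C]
  n <- dim(X)[1L]; C <- dim(X)[3L]
  Y <- X[, idx, , drop = FALSE]
  dim(Y) <- c(n, length(idx) * C)
  Y
}

conv_forward <- function(layer, X) {
  n <- dim(X)[1L]; L <- dim(X)[2L]
  k <- layer$kernel; s <- layer$stride
  Lo <- conv_out_len(L, k, s)
  if (Lo < 1L) stop("input shorter than convolution kernel")
  out <- array(0, dim = c(n, Lo, layer$n_out))
  for (j in seq_len(Lo)) {
    idx <- ((j - 1L) * s + 1L):((j - 1L) * s + k)
    out[, j, ] <- slab(X, idx) %*% layer$W +
      matrix(layer$b, n, layer$n_out, byrow = TRUE)
  }
  if (layer$skip) {
    crop <- (k - 1L) %/% 2L
    out <- out + X[, (crop + 1L):(L - crop), , drop = FALSE]
  }
  out
}

conv_backward <- function(layer, X, dOut) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; C <- dim(X)[3L]
  k <- layer$kernel; s <- layer$stride
  Lo <- dim(dOut)[2L]
  dX <- array(0, dim = dim(X))
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  db <- numeric(length(layer$b))
  for (j in seq_len(Lo)) {
    idx <- ((j - 1L) * s + 1L):((j - 1L) * s + k)
    g <- matrix(dOut[, j, ], n, layer$n_out)
    dW <- dW + crossprod(slab(X, idx), g)
    db <- db + colSums(g)
    dSeg <- g %*% t(layer$W)
    dim(dSeg) <- c(n, k, C)
    dX[, idx, ] <- dX[, idx, , drop = FALSE] + dSeg
  }
  if (layer$skip) {
    crop <- (k - 1L) %/% 2L
    dX[, (crop + 1L):(L - crop), ] <-
      dX[, (crop + 1L):(L - crop), , drop = FALSE] + dOut
  }
  list(dX = dX, dW = dW, db = db)
}

# Fixed 2x average-pool of the input, cropped to the learned-branch length,
# concatenated channel-wise with the learned kernel-4 stride-2 convolution.
meanconcat_forward <- function(layer, X) {
  n <- dim(X)[1L]; L <- dim(X)[2L]; C <- dim(X)[3L]
  conv_part <- conv_forward(list(type = "conv", kernel = layer$kernel,
                                 stride = layer$stride, skip = FALSE,
                                 n_in = layer$n_in, n_out = layer$n_out,
                                 W = layer$W, b = layer$b), X)
  Lo <- dim(conv_part)[2L]
  pooled <- (X[, seq(1L, by = 2L, length.out = Lo), , drop = FALSE] +
             X[, seq(2L, by = 2L, length.out = Lo), , drop = FALSE]) / 2
  out <- array(0, dim = c(n, Lo, C + layer$n_out))
  out[, , seq_len(C)] <- pooled
  out[, , C + seq_len(layer$n_out)] <- conv_part
  out
}

meanconcat_backward <- function(layer, X, dOut) {
  n <- dim(X)[1L]; C <- dim(X)[3L]
  Lo <- dim(dOut)[2L]
  dPooled <- dOut[, , seq_len(C), drop = FALSE]
  dConv <- dOut[, , C + seq_len(layer$n_out), drop = FALSE]
  res <- conv_backward(list(type = "conv", kernel = layer$kernel,
                            stride = layer$stride, skip = FALSE,
                            n_in = layer$n_in, n_out = layer$n_out,
                            W = layer$W, b = layer$b), X, dConv)
  odd <- seq(1L, by = 2L, length.out = Lo)
  res$dX[, odd, ] <- res$dX[, odd, , drop = FALSE] + dPooled / 2
  res$dX[, odd + 1L, ] <- res$dX[, odd + 1L, , drop = FALSE] + dPooled / 2
  res
}

normalize_rows <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  nrm <- pmax(nrm, 1e-12)
  list(out = Z / nrm, nrm = nrm)
}

normalize_rows_backward <- function(Zn, nrm, dOut) {
  (dOut - Zn * rowSums(Zn * dOut)) / nrm
}

encoder_forward <- function(encoder, X, keep_cache = FALSE) {
  if (is.matrix(X)) X <- array(X, dim = c(nrow(X), 1L, ncol(X)))
  cache <- if (keep_cache) vector("list", length(encoder$layers)) else NULL
  cur <- X
  for (li in seq_along(encoder$layers)) {
    layer <- encoder$layers[[li]]
    if (keep_cache) cache[[li]] <- list(input = cur)
    cur <- switch(layer$type,
      flatten = {
        if (length(dim(cur)) == 3L) {
          stopifnot(dim(cur)[2L] == 1L)
          matrix(cur, dim(cur)[1L], dim(cur)[3L])
        } else cur
      },
      dense = cur %*% layer$W + matrix(layer$b, nrow(cur), length(layer$b), byrow = TRUE),
      gelu = gelu(cur),
      conv = conv_forward(layer, cur),
      meanconcat = meanconcat_forward(layer, cur),
      normalize = {
        res <- normalize_rows(cur)
        if (keep_cache) cache[[li]]$nrm <- res$nrm
        res$out
      },
      stop("unknown layer type"))
    if (keep_cache) cache[[li]]$output <- cur
  }
  list(out = cur, cache = cache)
}

# Returns parameter gradients (list parallel to layers, NULL for
# parameter-free layers) and the gradient w.r.t. the input.
encoder_backward <- function(encoder, cache, dOut) {
  grads <- vector("list", length(encoder$layers))
  cur <- dOut
  for (li in rev(seq_along(encoder$layers))) {
    layer <- encoder$layers[[li]]
    inp <- cache[[li]]$input
    cur <- switch(layer$type,
      flatten = {
        if (length(dim(inp)) == 3L) array(cur, dim = dim(inp)) else cur
      },
      dense = {
        grads[[li]] <- list(dW = crossprod(inp, cur), db = colSums(cur))
        cur %*% t(layer$W)
      },
      gelu = {
        g <- gelu_grad(inp)
        cur * g
      },
      conv = {
        res <- conv_backward(layer, inp, cur)
        grads[[li]] <- list(dW = res$dW, db = res$db)
        res$dX
      },
      meanconcat = {
        res <- meanconcat_backward(layer, inp, cur)
        grads[[li]] <- list(dW = res$dW, db = res$db)
        res$dX
      },
      normalize = normalize_rows_backward(cache[[li]]$output, cache[[li]]$nrm, cur))
  }
  list(grads = grads, dX = cur)
}

#' Encode a batch of signal windows
#'
#' @param encoder a `contrast_encoder`.
#' @param windows `[n, receptive_field, D]` array, or an `[n, D]` matrix for
#'   receptive field 1.
#' @return `[n, E]` embedding matrix (unit rows when the encoder
#'   normalizes its output).
#' @export
encode <- function(encoder, windows) {
  rf <- encoder$spec$receptive_field
  if (is.matrix(windows)) {
    if (rf != 1L) stop("matrix input is only valid for receptive field 1")
  } else if (dim(windows)[2L] != rf) {
    stop(sprintf("windows have length %d but the encoder's receptive field is %d",
                 dim(windows)[2L], rf))
  }
  encoder_forward(encoder, windows)$out
}

#' Encode a whole session as a sliding-window time series
#'
#' Applies the encoder to every valid window; row `i` of the result is the
#' embedding of the window centred at the `i`-th valid time index. A session
#' of length `T` yields `T - receptive_field + 1` rows (no padding).
#'
#' @param encoder a `contrast_encoder`.
#' @param session a `session_data` with matching signal dimensionality.
#' @param chunk_size number of windows encoded per block (memory control).
#' @return `[T - rf + 1, E]` matrix with attribute `time_index` (the 0-based
#'   centre indices).
#' @export
encode_session <- function(encoder, session, chunk_size = 4096L) {
  if (session$n_signal != encoder$spec$num_input)
    stop(sprintf("session has %d signal dimensions but the encoder expects %d; use adapt_model() for new sessions",
                 session$n_signal, encoder$spec$num_input))
  rf <- encoder$spec$receptive_field
  valid <- valid_window_indices(session, rf)
  E <- encoder$spec$output_dimension
  out <- matrix(0, length(valid), E)
  for (start in seq(1L, length(valid), by = chunk_size)) {
    sel <- start:min(start + chunk_size - 1L, length(valid))
    W <- extract_window_batch(session, valid[sel], rf)
    out[sel, ] <- encoder_forward(encoder, W)$out
  }
  attr(out, "time_index") <- valid
  out
}

## Parameter bookkeeping used by the solver -----------------------------------

encoder_param_layers <- function(encoder) {
  which(vapply(encoder$layers, function(l)
    l$type %in% c("dense", "conv", "meanconcat"), logical(1)))
}

zero_grads_like <- function(encoder) {
  lapply(encoder$layers, function(l) {
    if (l$type %in% c("dense", "conv", "meanconcat"))
      list(dW = matrix(0, nrow(l$W), ncol(l$W)), db = numeric(length(l$b)))
    else NULL
  })
}

accumulate_grads <- function(total, grads) {
  for (li in seq_along(grads)) {
    if (!is.null(grads[[li]])) {
      total[[li]]$dW <- total[[li]]$dW + grads[[li]]$dW
      total[[li]]$db <- total[[li]]$db + grads[[li]]$db
    }
  }
  total
}
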
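#' Session data for contrastive embedding
#'
#' A session bundles a time-aligned multidimensional signal (e.g. binned
#' neural activity, one row per time bin) with optional continuous context
#' (behavioural variables such as position or kinematics) and optional
#' discrete context (categorical labels such as trial type or direction).
#' All arrays share the same number of rows `T`; the signal must be finite
#' everywhere.
#'
#' @param signal numeric matrix `[T x D]`, one row per time step.
#' @param continuous_context optional numeric matrix `[T x m]` (a vector is
#'   treated as a single column).
#' @param discrete_context optional vector of length `T` with values from a
#'   finite label set; labels are re-encoded internally to `0..K-1` and the
#'   original labels kept for reporting.
#' @param sample_rate_hz positive number, metadata only.
#' @param session_id identifier string, metadata only.
#' @return an object of class `session_data` with elements `signal`,
#'   `continuous_context`, `discrete_context` (integer codes, 0-based),
#'   `discrete_levels`, `n_time`, `n_signal`, `n_context`, `n_categories`,
#'   `sample_rate_hz`, `session_id`.
#' @export
make_session <- function(signal, continuous_context = NULL,
                         discrete_context = NULL,
                         sample_rate_hz = 1, session_id = "session") {
  signal <- as_numeric_matrix(signal, "signal")
  if (!all(is.finite(signal)))
    stop("signal contains missing or non-finite values")
  T_len <- nrow(signal)
  if (T_len < 1L) stop("signal must contain at least one time step")

  cc <- NULL
  if (!is.null(continuous_context)) {
    cc <- as_numeric_matrix(continuous_context, "continuous_context")
    if (nrow(cc) != T_len)
      stop(sprintf("continuous_context has %d rows but signal has %d (arrays must be time-aligned)",
                   nrow(cc), T_len))
    if (!all(is.finite(cc)))
      stop("continuous_context contains non-finite values")
  }

  dk <- NULL
  levels_k <- NULL
  if (!is.null(discrete_context)) {
    if (length(discrete_context) != T_len)
      stop(sprintf("discrete_context has length %d but signal has %d rows (arrays must be time-aligned)",
                   length(discrete_context), T_len))
    if (anyNA(discrete_context))
      stop("discrete_context contains missing values")
    f <- factor(discrete_context)
    levels_k <- levels(f)
    dk <- as.integer(f) - 1L
  }

  structure(list(
    signal = signal,
    continuous_context = cc,
    discrete_context = dk,
    discrete_levels = levels_k,
    n_time = T_len,
    n_signal = ncol(signal),
    n_context = if (is.null(cc)) 0L else ncol(cc),
    n_categories = if (is.null(dk)) 0L else length(levels_k),
    sample_rate_hz = sample_rate_hz,
    session_id = as.character(session_id)
  ), class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data '%s'> T=%d, D=%d", x$session_id, x$n_time, x$n_signal))
  if (x$n_context > 0L) cat(sprintf(", continuous context m=%d", x$n_context))
  if (x$n_categories > 0L) cat(sprintf(", discrete context K=%d", x$n_categories))
  cat("\n")
  invisible(x)
}

as_numeric_matrix <- function(x, what) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what))
  x
}

#' Multi-session dataset
#'
#' Orders several sessions into a dataset for joint training. Signal
#' dimensionality may differ per session, but all sessions that carry a
#' continuous context must share its dimensionality `m` so that samples can
#' be related across sessions.
#'
#' @param sessions list of `session_data` objects.
#' @return an object of class `multisession_data`.
#' @export
make_multisession <- function(sessions) {
  if (!is.list(sessions) || length(sessions) < 1L)
    stop("sessions must be a non-empty list")
  ok <- vapply(sessions, inherits, logical(1), what = "session_data")
  if (!all(ok)) stop("all elements must be session_data objects")
  ms <- vapply(sessions, function(s) s$n_context, integer(1))
  ms <- unique(ms[ms > 0L])
  if (length(ms) > 1L)
    stop("sessions with continuous context must share context dimensionality m")
  structure(list(sessions = sessions,
                 n_sessions = length(sessions),
                 n_context = if (length(ms)) ms else 0L),
            class = "multisession_data")
}

window_offsets <- function(receptive_field) {
  rf <- as.integer(receptive_field)
  if (rf < 1L) stop("receptive_field must be >= 1")
  left <- rf %/% 2L
  c(left = left, right = rf - 1L - left)
}

#' Valid window indices for a receptive field
#'
#' Time indices `t` (0-based) for which the full centred window of
#' `receptive_field` consecutive samples lies inside `[0, T)`. A window of
#' even length `r` covers rows `t - r/2 .. t + r/2 - 1`; odd lengths are
#' symmetric around `t`. There are exactly `T - r + 1` valid indices.
#'
#' @param session a `session_data` object.
#' @param receptive_field window length in samples (1, 10 and 40 are the
#'   encoder defaults, any positive length is accepted).
#' @return integer vector of 0-based time indices.
#' @export
valid_window_indices <- function(session, receptive_field) {
  rf <- as.integer(receptive_field)
  T_len <- session$n_time
  if (rf > T_len)
    stop(sprintf("receptive field %d exceeds session length %d (empty dataset)", rf, T_len))
  off <- window_offsets(rf)
  seq.int(off[["left"]], T_len - 1L - off[["right"]])
}

#' Extract one signal window
#'
#' @param session a `session_data` object.
#' @param t 0-based time index; must belong to the valid window set.
#' @param receptive_field window length in samples.
#' @return numeric matrix `[receptive_field x D]`.
#' @export
extract_window <- function(session, t, receptive_field) {
  rf <- as.integer(receptive_field)
  off <- window_offsets(rf)
  t <- as.integer(t)
  lo <- t - off[["left"]]
  hi <- t + off[["right"]]
  if (lo < 0L || hi >= session$n_time)
    stop(sprintf("window [%d, %d] for t=%d falls outside [0, %d)", lo, hi, t, session$n_time))
  session$signal[(lo + 1L):(hi + 1L), , drop = FALSE]
}

# Stack windows for a batch of 0-based centre indices into an
# [n, rf, D] array (rf = 1 collapses to plain row indexing).
extract_window_batch <- function(session, ts, receptive_field) {
  rf <- as.integer(receptive_field)
  off <- window_offsets(rf)
  n <- length(ts)
  D <- session$n_signal
  if (rf == 1L) {
    return(array(session$signal[ts + 1L, , drop = FALSE], dim = c(n, 1L, D)))
  }
  out <- array(0, dim = c(n, rf, D))
  starts <- as.integer(ts) - off[["left"]]
  for (j in seq_len(rf)) {
    out[, j, ] <- session$signal[starts + j, , drop = FALSE]
  }
  out
}

## ---------------------------------------------------------------------------
## File I/O: plain-text directory container
##
## A dataset is stored as a directory with a JSON manifest and one CSV file
## per array ("signal", optional "continuous", optional "discrete" per
## session). Doubles are written with 17 significant digits, which round-trips
## IEEE-754 values exactly.

format_double_rows <- function(mat) {
  apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
}

write_array_csv <- function(mat, path, colnames_prefix = "v") {
  header <- paste(paste0(colnames_prefix, seq_len(ncol(mat))), collapse = ",")
  writeLines(c(header, format_double_rows(mat)), path)
}

read_array_csv <- function(path) {
  dat <- utils::read.csv(path, header = TRUE, colClasses = "numeric")
  m <- as.matrix(dat)
  dimnames(m) <- NULL
  m
}

#' Write a dataset to a plain-text directory container
#'
#' Each session becomes a subdirectory `session_<i>/` holding `signal.csv`
#' and, when present, `continuous.csv` and `discrete.csv`; `manifest.json`
#' records shapes, label alphabets and metadata. The round trip
#' `read_dataset(write_dataset(x))` reproduces all arrays exactly.
#'
#' @param dataset a `session_data` or `multisession_data` object.
#' @param path directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (inherits(dataset, "session_data")) dataset <- make_multisession(list(dataset))
  if (!inherits(dataset, "multisession_data")) stop("dataset must be session_data or multisession_data")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  manifest <- list(container = "contrastembed-dataset", version = 1L,
                   n_sessions = dataset$n_sessions, sessions = list())
  for (i in seq_len(dataset$n_sessions)) {
    s <- dataset$sessions[[i]]
    sdir <- file.path(path, sprintf("session_%d", i))
    dir.create(sdir)
    write_array_csv(s$signal, file.path(sdir, "signal.csv"))
    entry <- list(session_id = s$session_id, n_time = s$n_time,
                  n_signal = s$n_signal, sample_rate_hz = s$sample_rate_hz)
    if (!is.null(s$continuous_context)) {
      write_array_csv(s$continuous_context, file.path(sdir, "continuous.csv"))
      entry$n_context <- s$n_context
    }
    if (!is.null(s$discrete_context)) {
      writeLines(c("k", as.character(s$discrete_context)), file.path(sdir, "discrete.csv"))
      entry$discrete_levels <- as.list(s$discrete_levels)
    }
    manifest$sessions[[i]] <- entry
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset from a directory container
#'
#' @param path directory written by [write_dataset()] (or assembled by hand
#'   in the same layout).
#' @return a `multisession_data` object.
#' @export
read_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop(sprintf("no manifest.json under '%s': not a dataset container", path))
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (is.null(manifest$container) || manifest$container != "contrastembed-dataset")
    stop("manifest does not describe a contrastembed dataset container")
  n <- manifest$n_sessions
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    entry <- manifest$sessions[[i]]
    sdir <- file.path(path, sprintf("session_%d", i))
    sig_path <- file.path(sdir, "signal.csv")
    if (!file.exists(sig_path)) stop(sprintf("missing signal array for session %d", i))
    signal <- read_array_csv(sig_path)
    if (!is.null(entry$n_signal) && ncol(signal) != entry$n_signal)
      stop(sprintf("session %d: signal has %d columns, manifest says %d",
                   i, ncol(signal), entry$n_signal))
    cc <- NULL
    cpath <- file.path(sdir, "continuous.csv")
    if (file.exists(cpath)) cc <- read_array_csv(cpath)
    dk <- NULL
    dpath <- file.path(sdir, "discrete.csv")
    if (file.exists(dpath)) {
      codes <- utils::read.csv(dpath, header = TRUE)[[1L]]
      lv <- unlist(entry$discrete_levels)
      dk <- lv[codes + 1L]
    }
    sessions[[i]] <- make_session(signal, cc, dk,
                                  sample_rate_hz = entry$sample_rate_hz %||% 1,
                                  session_id = entry$session_id %||% sprintf("session_%d", i))
  }
  make_multisession(sessions)
}

#' Write an embedding time series with metadata
#'
#' @param path directory to create.
#' @param embedding numeric matrix `[T' x E]`.
#' @param time_index 0-based time indices the rows correspond to.
#' @param session_id identifier recorded in the metadata.
#' @param metadata optional named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(path, embedding, time_index = seq_len(nrow(embedding)) - 1L,
                            session_id = "session", metadata = list()) {
  embedding <- as_numeric_matrix(embedding, "embedding")
  if (length(time_index) != nrow(embedding))
    stop("time_index length must match embedding rows")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  write_array_csv(embedding, file.path(path, "embedding.csv"), colnames_prefix = "e")
  writeLines(c("t", sprintf("%d", as.integer(time_index))), file.path(path, "time_index.csv"))
  meta <- c(list(container = "contrastembed-embedding", version = 1L,
                 session_id = session_id,
                 n_time = nrow(embedding), n_dim = ncol(embedding)), metadata)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path embedding container directory.
#' @return list with `embedding`, `time_index`, `metadata`.
#' @export
read_embedding <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"), simplifyVector = TRUE)
  emb <- read_array_csv(file.path(path, "embedding.csv"))
  ti <- utils::read.csv(file.path(path, "time_index.csv"))[[1L]]
  list(embedding = emb, time_index = as.integer(ti), metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
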
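#' Linear consistency between two embeddings
#'
#' The R-squared of a least-squares linear regression (with intercept)
#' mapping the source embedding onto the target, averaged uniformly over
#' target dimensions. Invariant to any invertible affine transformation of
#' the source; identical embeddings (or rotated/shifted copies) score 1.
#'
#' @param source_emb,target_emb row-aligned embedding matrices.
#' @param fit_idx,eval_idx optional row subsets: fit the map on `fit_idx`
#'   and score on `eval_idx` (both default to all rows, i.e. the in-sample
#'   alignment score).
#' @return R-squared.
#' @export
linear_consistency <- function(source_emb, target_emb,
                               fit_idx = NULL, eval_idx = NULL) {
  source_emb <- as_numeric_matrix(source_emb, "source_emb")
  target_emb <- as_numeric_matrix(target_emb, "target_emb")
  if (nrow(source_emb) != nrow(target_emb))
    stop("source and target embeddings must have the same number of rows")
  linear_r2(source_emb, target_emb, fit_idx, eval_idx)
}

#' Pairwise consistency across runs
#'
#' Evaluates [linear_consistency()] for every ordered pair of embeddings
#' computed on identical data (R runs give `R * (R - 1)` comparisons; ten
#' runs give 90).
#'
#' @param embeddings list of at least two row-aligned embedding matrices.
#' @return an object of class `consistency_report`: `r2_matrix` (off-
#'   diagonal entries defined), `comparisons`, `mean`, `sd`.
#' @export
run_consistency <- function(embeddings) {
  R <- length(embeddings)
  if (R < 2L) stop("at least two embeddings are required")
  nr <- vapply(embeddings, nrow, integer(1))
  if (length(unique(nr)) != 1L) stop("embeddings must be row-aligned")
  m <- matrix(NA_real_, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j) m[i, j] <- linear_consistency(embeddings[[i]], embeddings[[j]])
  }
  vals <- m[!is.na(m)]
  structure(list(r2_matrix = m, comparisons = length(vals),
                 mean = mean(vals), sd = stats::sd(vals)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d comparisons, mean R^2 = %.4f (sd %.4f)\n",
              x$comparisons, x$mean, x$sd))
  invisible(x)
}

#' Behaviour-binned embedding features
#'
#' Averages unit-norm embedding vectors within position bins, separately
#' per direction, and renormalizes each average back onto the hypersphere.
#' This makes embeddings of subjects with different neurons comparable
#' through their shared behaviour. Empty bins are imputed by pooling the
#' member embeddings of the two adjacent bins (same direction) before
#' averaging.
#'
#' @param embedding `[N x E]` unit-norm embedding rows.
#' @param position numeric vector of length N.
#' @param direction vector of length N with (typically two) discrete values.
#' @param n_bins number of equal-width position bins per direction.
#' @return `[n_directions * n_bins x E]` matrix, direction-major then
#'   bin-minor, every row unit-norm.
#' @export
behaviour_bin_average <- function(embedding, position, direction, n_bins = 100L) {
  embedding <- as_numeric_matrix(embedding, "embedding")
  N <- nrow(embedding)
  if (length(position) != N || length(direction) != N)
    stop("position and direction must align with embedding rows")
  breaks <- seq(min(position), max(position), length.out = n_bins + 1L)
  bin <- findInterval(position, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  dirs <- sort(unique(direction))
  out <- matrix(NA_real_, length(dirs) * n_bins, ncol(embedding))
  row_i <- 0L
  for (d in dirs) {
    members <- lapply(seq_len(n_bins), function(b) which(direction == d & bin == b))
    for (b in seq_len(n_bins)) {
      row_i <- row_i + 1L
      idx <- members[[b]]
      if (length(idx) == 0L) {
        idx <- c(if (b > 1L) members[[b - 1L]],
                 if (b < n_bins) members[[b + 1L]])
        if (length(idx) == 0L)
          stop(sprintf("bin %d (direction %s) and both neighbours are empty", b, d))
      }
      v <- colMeans(embedding[idx, , drop = FALSE])
      nrm <- sqrt(sum(v^2))
      if (nrm < 1e-12) stop("bin average has zero norm; cannot renormalize")
      out[row_i, ] <- v / nrm
    }
  }
  out
}

#' Behaviour-aligned consistency between two subjects
#'
#' Bins both subjects' embeddings by their own position/direction labels
#' (which must share semantics: same position range, same direction coding)
#' and returns the linear consistency between the two bin-feature matrices.
#'
#' @param embedding_a,embedding_b unit-norm embeddings of the two subjects.
#' @param position_a,position_b,direction_a,direction_b per-subject labels.
#' @param n_bins position bins per direction.
#' @return R-squared between bin-feature matrices.
#' @export
subject_consistency <- function(embedding_a, position_a, direction_a,
                                embedding_b, position_b, direction_b,
                                n_bins = 100L) {
  fa <- behaviour_bin_average(embedding_a, position_a, direction_a, n_bins)
  fb <- behaviour_bin_average(embedding_b, position_b, direction_b, n_bins)
  linear_consistency(fa, fb)
}

## k-nearest-neighbour decoding ----------------------------------------------

knn_predict <- function(train_emb, train_labels, query_emb, k, metric, task,
                        chunk = 512L) {
  nq <- nrow(query_emb)
  if (metric == "cosine") {
    tn <- train_emb / pmax(sqrt(rowSums(train_emb^2)), 1e-12)
    qn <- query_emb / pmax(sqrt(rowSums(query_emb^2)), 1e-12)
  }
  labels_mat <- if (task == "regression") as_numeric_matrix(train_labels, "labels") else NULL
  pred <- if (task == "regression") matrix(0, nq, ncol(labels_mat)) else character(nq)
  for (start in seq(1L, nq, by = chunk)) {
    sel <- start:min(start + chunk - 1L, nq)
    d <- if (metric == "cosine") {
      1 - qn[sel, , drop = FALSE] %*% t(tn)
    } else {
      q <- query_emb[sel, , drop = FALSE]
      outer(rowSums(q^2), rep(1, nrow(train_emb))) +
        outer(rep(1, length(sel)), rowSums(train_emb^2)) - 2 * q %*% t(train_emb)
    }
    for (ii in seq_along(sel)) {
      nb <- order(d[ii, ])[seq_len(k)]
      if (task == "regression") {
        pred[sel[ii], ] <- colMeans(labels_mat[nb, , drop = FALSE])
      } else {
        tab <- table(train_labels[nb])
        pred[sel[ii]] <- names(tab)[which.max(tab)]
      }
    }
  }
  pred
}

#' Decode labels from an embedding with a kNN decoder
#'
#' `k` is selected on a validation split only (by R-squared for regression,
#' accuracy for classification) and the evaluation metrics are computed
#' once on the evaluation set. For positional regression the median
#' absolute error is reported alongside R-squared.
#'
#' @param train_emb,train_labels decoder training rows. Labels are a numeric
#'   vector/matrix for regression or a discrete vector for classification.
#' @param eval_emb,eval_labels held-out rows scored once.
#' @param task `"regression"` or `"classification"`.
#' @param k_grid candidate neighbour counts (clipped with a warning if they
#'   exceed the training size).
#' @param metric `"cosine"` (for sphere-normalized embeddings) or
#'   `"euclidean"`.
#' @param val_emb,val_labels optional explicit validation split; when
#'   omitted the last 20 percent of the training rows are held out for the
#'   `k` search.
#' @return an object of class `decoding_report`: `task`, `k`, `metric
#'   values` (`r2` and `median_abs_err`, or `accuracy`), `k_scores`.
#' @export
knn_decode <- function(train_emb, train_labels, eval_emb, eval_labels,
                       task = c("regression", "classification"),
                       k_grid = c(1L, 4L, 9L, 16L, 25L),
                       metric = c("cosine", "euclidean"),
                       val_emb = NULL, val_labels = NULL) {
  task <- match.arg(task)
  metric <- match.arg(metric)
  train_emb <- as_numeric_matrix(train_emb, "train_emb")
  eval_emb <- as_numeric_matrix(eval_emb, "eval_emb")
  if (length(k_grid) == 0L) stop("k_grid must be non-empty")

  if (is.null(val_emb)) {
    n <- nrow(train_emb)
    n_val <- max(1L, floor(0.2 * n))
    val_rows <- (n - n_val + 1L):n
    fit_rows <- seq_len(n - n_val)
    val_emb <- train_emb[val_rows, , drop = FALSE]
    val_labels <- subset_labels(train_labels, val_rows)
    train_emb <- train_emb[fit_rows, , drop = FALSE]
    train_labels <- subset_labels(train_labels, fit_rows)
  }
  k_grid <- unique(as.integer(k_grid))
  if (any(k_grid > nrow(train_emb))) {
    warning("k exceeds the decoder training size; clipped")
    k_grid <- unique(pmin(k_grid, nrow(train_emb)))
  }

  score_k <- function(k) {
    pred <- knn_predict(train_emb, train_labels, val_emb, k, metric, task)
    if (task == "regression") {
      lv <- as_numeric_matrix(val_labels, "val_labels")
      1 - sum((lv - pred)^2) / sum(sweep(lv, 2L, colMeans(lv))^2)
    } else mean(pred == as.character(val_labels))
  }
  k_scores <- vapply(k_grid, score_k, numeric(1))
  k_best <- k_grid[which.max(k_scores)]

  pred <- knn_predict(train_emb, train_labels, eval_emb, k_best, metric, task)
  metrics <- if (task == "regression") {
    le <- as_numeric_matrix(eval_labels, "eval_labels")
    list(r2 = 1 - sum((le - pred)^2) / sum(sweep(le, 2L, colMeans(le))^2),
         median_abs_err = stats::median(abs(le - pred)))
  } else {
    list(accuracy = mean(pred == as.character(eval_labels)))
  }
  structure(list(task = task, k = k_best, metric = metric,
                 metrics = metrics, predictions = pred,
                 k_scores = stats::setNames(k_scores, k_grid)),
            class = "decoding_report")
}

subset_labels <- function(labels, rows) {
  if (is.matrix(labels)) labels[rows, , drop = FALSE] else labels[rows]
}

#' @export
print.decoding_report <- function(x, ...) {
  vals <- paste(sprintf("%s=%.4f", names(x$metrics), unlist(x$metrics)), collapse = ", ")
  cat(sprintf("<decoding_report> %s (k=%d, %s): %s\n", x$task, x$k, x$metric, vals))
  invisible(x)
}

## Topology -------------------------------------------------------------------

#' Persistent cohomology summary of an embedding point cloud
#'
#' Vietoris-Rips persistence (Z/2) on a uniform random subsample of the
#' embedding rows, dimensions 0..`maxdim`. By default the filtration is
#' capped at the enclosing radius, which leaves the diagram unchanged (the
#' complex is a cone beyond it) while keeping the simplex count tractable;
#' this is equivalent to an infinite filtration ceiling.
#'
#' @param embedding `[N x E]` matrix.
#' @param n_points number of rows subsampled (clipped with a warning when it
#'   exceeds N). The cost of dimension-2 persistence grows as
#'   `choose(n_points, 4)`; around 100 points is a practical ceiling.
#' @param maxdim largest homology dimension (0..2).
#' @return an object of class `persistence_summary`: per-dimension matrices
#'   of `(birth, death)` (death `Inf` for essential classes), plus the
#'   `lifespans` per dimension and the subsample row indices.
#' @export
persistence_summary <- function(embedding, n_points = 100L, maxdim = 2L) {
  embedding <- as_numeric_matrix(embedding, "embedding")
  N <- nrow(embedding)
  if (n_points > N) {
    warning(sprintf("n_points (%d) exceeds available rows (%d); clipped", n_points, N))
    n_points <- N
  }
  rows <- if (n_points < N) sort(sample.int(N, n_points)) else seq_len(N)
  pts <- embedding[rows, , drop = FALSE]
  D <- as.matrix(stats::dist(pts))
  enclosing <- min(apply(D, 1L, max))
  diagrams <- cpp_rips_persistence(D, as.integer(maxdim), enclosing)
  names(diagrams) <- paste0("dim", 0:maxdim)
  lifespans <- lapply(diagrams, function(m) {
    if (nrow(m) == 0L) numeric(0) else m[, 2L] - m[, 1L]
  })
  structure(list(diagrams = diagrams, lifespans = lifespans,
                 maxdim = as.integer(maxdim), n_points = n_points,
                 rows = rows),
            class = "persistence_summary")
}

#' @export
print.persistence_summary <- function(x, ...) {
  cat(sprintf("<persistence_summary> %d points, dims 0..%d\n", x$n_points, x$maxdim))
  for (d in 0:x$maxdim) {
    ls <- x$lifespans[[d + 1L]]
    fin <- ls[is.finite(ls)]
    cat(sprintf("  dim %d: %d classes (%d essential), max finite lifespan %.4f\n",
                d, length(ls), sum(is.infinite(ls)),
                if (length(fin)) max(fin) else 0))
  }
  invisible(x)
}

max_finite_lifespans <- function(summary) {
  vapply(summary$lifespans, function(ls) {
    fin <- ls[is.finite(ls)]
    if (length(fin)) max(fin) else 0
  }, numeric(1))
}

#' Shuffled-label null thresholds for Betti numbers
#'
#' Repeatedly permutes the session's context labels (whole rows, seeded),
#' refits the embedding with the supplied recipe, computes its persistence
#' summary, and records the maximum finite lifespan per dimension; the
#' threshold for each dimension is the maximum over shuffles. The original
#' procedure uses 500 shuffles; a reduced count is a scaled-down surrogate.
#'
#' @param session a `session_data`.
#' @param fit_recipe function `session -> embedding matrix` encapsulating
#'   the model fit and transform; it may optionally accept a second
#'   argument, the shuffle index, e.g. to derive a per-shuffle fit seed.
#' @param n_shuffles number of label permutations.
#' @param n_points,maxdim forwarded to [persistence_summary()].
#' @return numeric vector of per-dimension lifespan thresholds
#'   (length `maxdim + 1`).
#' @export
shuffled_null_threshold <- function(session, fit_recipe, n_shuffles = 20L,
                                    n_points = 100L, maxdim = 2L) {
  if (n_shuffles < 1L) stop("n_shuffles must be at least 1")
  # draw all permutations and subsample seeds up front: recipes that seed
  # their own RNG internally must not collapse the null's diversity
  perms <- lapply(seq_len(n_shuffles), function(i) sample.int(session$n_time))
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_shuffles)
  pass_index <- length(formals(fit_recipe)) >= 2L
  thresholds <- matrix(0, n_shuffles, maxdim + 1L)
  for (s in seq_len(n_shuffles)) {
    shuffled <- permute_context(session, perms[[s]])
    emb <- if (pass_index) fit_recipe(shuffled, s) else fit_recipe(shuffled)
    set.seed(sub_seeds[s])
    ps <- persistence_summary(emb, n_points = n_points, maxdim = maxdim)
    thresholds[s, ] <- max_finite_lifespans(ps)
  }
  apply(thresholds, 2L, max)
}

#' Permute a session's context labels
#'
#' Applies one permutation to both continuous and discrete context rows
#' (the signal is untouched), preserving the label marginals while breaking
#' the signal-label relationship.
#'
#' @param session a `session_data`.
#' @param perm a permutation of `1..T`.
#' @return a new `session_data`.
#' @export
permute_context <- function(session, perm) {
  cc <- session$continuous_context
  if (!is.null(cc)) cc <- cc[perm, , drop = FALSE]
  dk <- session$discrete_context
  if (!is.null(dk)) dk <- session$discrete_levels[dk[perm] + 1L]
  make_session(session$signal, cc, dk,
               sample_rate_hz = session$sample_rate_hz,
               session_id = paste0(session$session_id, "-shuffled"))
}

#' Coordinate-shuffle null thresholds for a raw point cloud
#'
#' For point clouds without labels (e.g. checking a reference shape),
#' permuting each coordinate column independently destroys the joint
#' structure while preserving marginals; the max finite lifespan per
#' dimension over shuffles serves as the significance threshold.
#'
#' @param points `[N x E]` matrix.
#' @param n_shuffles number of coordinate permutations.
#' @param n_points,maxdim forwarded to [persistence_summary()].
#' @return per-dimension lifespan thresholds.
#' @export
pointcloud_null_threshold <- function(points, n_shuffles = 20L,
                                      n_points = 100L, maxdim = 2L) {
  points <- as_numeric_matrix(points, "points")
  thresholds <- matrix(0, n_shuffles, maxdim + 1L)
  for (s in seq_len(n_shuffles)) {
    shuffled <- apply(points, 2L, sample)
    ps <- persistence_summary(shuffled, n_points = n_points, maxdim = maxdim)
    thresholds[s, ] <- max_finite_lifespans(ps)
  }
  apply(thresholds, 2L, max)
}

#' Betti numbers from a persistence summary
#'
#' Counts, per dimension, the classes whose lifespan strictly exceeds the
#' dimension's threshold; essential (infinite-lifespan) classes are always
#' counted. A ring-structured embedding gives `(1, 1, 0)`; a uniform sample
#' of the two-sphere gives `(1, 0, 1)`.
#'
#' @param summary a [persistence_summary()].
#' @param thresholds per-dimension lifespan thresholds, recycled if scalar.
#' @return integer vector `(b0, b1, ..., b_maxdim)`.
#' @export
betti_numbers <- function(summary, thresholds) {
  stopifnot(inherits(summary, "persistence_summary"))
  nd <- summary$maxdim + 1L
  thresholds <- rep_len(thresholds, nd)
  vapply(seq_len(nd), function(d) {
    ls <- summary$lifespans[[d]]
    sum(is.infinite(ls) | ls > thresholds[d])
  }, integer(1))
}
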
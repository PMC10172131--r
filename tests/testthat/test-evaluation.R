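test_that("linear consistency is invariant to invertible affine maps", {
  set.seed(1)
  z <- matrix(rnorm(400), 100, 4)
  expect_equal(linear_consistency(z, z), 1)
  A <- matrix(rnorm(16), 4, 4)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4, 4)
  expect_equal(linear_consistency(z %*% A + 2, z), 1, tolerance = 1e-8)
  # independent pair, out of sample, explains nothing
  w <- matrix(rnorm(400), 100, 4)
  r2 <- linear_consistency(w, z, fit_idx = 1:50, eval_idx = 51:100)
  expect_lt(abs(r2), 0.4)
  expect_error(linear_consistency(z[1:10, ], z), "same number of rows")
})

test_that("run consistency enumerates ordered pairs", {
  set.seed(2)
  base <- matrix(rnorm(300), 100, 3)
  embs <- lapply(1:3, function(i) base %*% matrix(rnorm(9), 3, 3))
  rep3 <- run_consistency(embs)
  expect_equal(rep3$comparisons, 6L)
  expect_equal(rep3$mean, 1, tolerance = 1e-6)
  rep2 <- run_consistency(embs[1:2])
  expect_equal(rep2$comparisons, 2L)
  expect_error(run_consistency(embs[1]), "at least two")
  # ten runs give 90 comparisons
  embs10 <- lapply(1:10, function(i) base + matrix(rnorm(300, sd = 0.01), 100, 3))
  expect_equal(run_consistency(embs10)$comparisons, 90L)
})

test_that("behaviour binning averages, renormalizes and imputes empty bins", {
  n_bins <- 10L
  set.seed(3)
  pos <- runif(200)
  pos <- pos[pos < 0.4 | pos > 0.5]         # bin 5 of 10 left empty
  dir <- rep(c("L", "R"), length.out = length(pos))
  z <- random_unit_rows(length(pos), 3, seed = 3)
  feats <- behaviour_bin_average(z, pos, dir, n_bins)
  expect_equal(dim(feats), c(2L * n_bins, 3L))
  expect_equal(rowSums(feats^2), rep(1, 2 * n_bins), tolerance = 1e-12)
  # the empty bin is imputed from its two neighbours' pooled members
  bin_of <- findInterval(pos, seq(min(pos), max(pos), length.out = n_bins + 1L),
                         rightmost.closed = TRUE, all.inside = TRUE)
  nb <- which(dir == "L" & bin_of %in% c(4L, 6L))
  v <- colMeans(z[nb, , drop = FALSE]); v <- v / sqrt(sum(v^2))
  expect_equal(feats[5, ], v)

  # a bin whose members are identical reproduces that vector
  z2 <- matrix(rep(c(1, 0, 0), 4), 4, 3, byrow = TRUE)
  f2 <- behaviour_bin_average(z2, c(0.1, 0.1, 0.9, 0.9), rep("a", 4), 2L)
  expect_equal(f2[1, ], c(1, 0, 0))

  # both neighbours empty is an imputation error
  expect_error(behaviour_bin_average(z2, c(0, 0, 1, 1), rep("a", 4), 7L),
               "neighbours are empty")
})

test_that("subject consistency matches linearly mixed embeddings across subjects", {
  set.seed(4)
  n <- 400
  pos <- runif(n); dir <- sample(c(0, 1), n, TRUE)
  base <- cbind(cos(2 * pi * pos), sin(2 * pi * pos), dir - 0.5) +
    matrix(rnorm(3 * n, sd = 0.05), n, 3)
  za <- base / sqrt(rowSums(base^2))
  mix <- matrix(rnorm(9), 3, 3); while (abs(det(mix)) < 0.1) mix <- matrix(rnorm(9), 3, 3)
  zb <- base %*% mix
  zb <- zb / sqrt(rowSums(zb^2))
  expect_equal(subject_consistency(za, pos, dir, za, pos, dir, 20L), 1)
  r_mix <- subject_consistency(za, pos, dir, zb, pos, dir, 20L)
  # shared latent structure, different "neurons": far above the shuffled null
  set.seed(5)
  nulls <- replicate(20, {
    p <- sample(n)
    subject_consistency(za, pos, dir, zb, pos[p], dir[p], 20L)
  })
  expect_gt(r_mix, max(nulls))
})

test_that("kNN decoding recovers labels and is rotation-invariant under cosine", {
  z <- random_unit_rows(300, 4, seed = 6)
  labels <- z[, 1] + 2
  # evaluating on the training rows with k = 1 is exact
  rep1 <- knn_decode(z, labels, z, labels, task = "regression",
                     k_grid = 1L, metric = "cosine",
                     val_emb = z[1:50, ], val_labels = labels[1:50])
  expect_equal(rep1$metrics$median_abs_err, 0)
  expect_equal(rep1$metrics$r2, 1)

  # constant labels classify perfectly
  repc <- knn_decode(z, rep("x", 300), z[1:50, ], rep("x", 50),
                     task = "classification", k_grid = c(1L, 4L), metric = "cosine")
  expect_equal(repc$metrics$accuracy, 1)

  # rotation of both train and eval leaves cosine decoding unchanged
  set.seed(7)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  tr <- 1:200; te <- 201:300
  r_a <- knn_decode(z[tr, ], labels[tr], z[te, ], labels[te],
                    task = "regression", metric = "cosine")
  r_b <- knn_decode(z[tr, ] %*% Q, labels[tr], z[te, ] %*% Q, labels[te],
                    task = "regression", metric = "cosine")
  expect_equal(r_a$metrics$r2, r_b$metrics$r2, tolerance = 1e-8)
  expect_equal(r_a$k, r_b$k)

  # oversized k is clipped with a warning
  expect_warning(knn_decode(z[1:20, ], labels[1:20], z[te, ], labels[te],
                            task = "regression", k_grid = c(4L, 100L),
                            metric = "cosine"), "clipped")
})

test_that("persistence recovers known shapes and tolerates duplicates", {
  circ <- noisy_circle_points(200, seed = 8)
  set.seed(8)
  ps <- persistence_summary(circ, n_points = 80, maxdim = 1)
  ls1 <- sort(ps$lifespans[[2]], decreasing = TRUE)
  expect_gt(ls1[1], 1)                      # one long-lived loop
  if (length(ls1) > 1) expect_lt(ls1[2], 0.3)

  # duplicated points leave the dominant classes unchanged
  set.seed(8)
  ps_dup <- persistence_summary(rbind(circ, circ[1:30, ]), n_points = 80, maxdim = 1)
  expect_equal(max(ps_dup$lifespans[[2]]), ls1[1], tolerance = 0.35)

  # cohomology and homology reductions agree exactly on small clouds
  for (seed in 1:3) {
    pts <- rbind(unit_sphere_points(18, seed = seed))
    D <- as.matrix(stats::dist(pts))
    thr <- min(apply(D, 1, max))
    a <- contrastembed:::cpp_rips_persistence(D, 2L, thr, "cohomology")
    b <- contrastembed:::cpp_rips_persistence(D, 2L, thr, "homology")
    for (d in 1:3) {
      sa <- a[[d]][order(a[[d]][, 1], a[[d]][, 2]), , drop = FALSE]
      sb <- b[[d]][order(b[[d]][, 1], b[[d]][, 2]), , drop = FALSE]
      expect_equal(sa, sb)
    }
  }
})

test_that("Betti counting respects thresholds and essential classes", {
  set.seed(9)
  blob <- matrix(rnorm(200 * 3), 200, 3)
  ps <- persistence_summary(blob, n_points = 60, maxdim = 2)
  # thresholds above every finite lifespan leave only the essential class
  expect_equal(betti_numbers(ps, c(Inf, Inf, Inf)), c(1L, 0L, 0L))

  # null thresholds grow monotonically with the number of shuffles (the
  # first permutation is shared; persistence runs on all rows)
  s <- toy_session(150, 4, seed = 10)
  recipe <- function(sess) cbind(sess$continuous_context, sess$signal[, 1:2])
  set.seed(11)
  t1 <- shuffled_null_threshold(s, recipe, n_shuffles = 1, n_points = 150, maxdim = 1)
  set.seed(11)
  t5 <- shuffled_null_threshold(s, recipe, n_shuffles = 5, n_points = 150, maxdim = 1)
  expect_true(all(t5 >= t1))

  # label permutation preserves marginals and breaks alignment only
  perm <- sample(s$n_time)
  sp <- permute_context(s, perm)
  expect_identical(sp$signal, s$signal)
  expect_equal(sort(sp$continuous_context[, 1]), sort(s$continuous_context[, 1]))
})
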
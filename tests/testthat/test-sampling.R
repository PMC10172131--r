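test_that("samplers are reproducible under a fixed seed", {
  s <- toy_session(300, 4, seed = 2, discrete = TRUE)
  cfg <- sampling_config("mixed", time_offsets = 1:5)
  set.seed(7); b1 <- sample_batch(s, 64, cfg)
  set.seed(7); b2 <- sample_batch(s, 64, cfg)
  expect_identical(b1, b2)
})

test_that("empirical reference sampling is uniform over valid windows", {
  s <- toy_session(50, 3, seed = 4)
  cfg <- sampling_config("delta", delta = 0.1)
  set.seed(1)
  draws <- sample_reference(s, 10000, cfg)
  tab <- tabulate(draws + 1L, nbins = 50)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("uniform-over-category sampling flattens a 9:1 imbalance", {
  set.seed(5)
  k <- c(rep("big", 900), rep("small", 100))[sample.int(1000)]
  s <- make_session(matrix(rnorm(1000 * 3), 1000, 3), discrete_context = k)
  cfg <- sampling_config("discrete", reference_mode = "uniform_over_category",
                         negative_mode = "uniform_over_category")
  set.seed(6)
  refs <- sample_reference(s, 10000, cfg)
  negs <- sample_negative(s, 10000, cfg)
  for (draws in list(refs, negs)) {
    counts <- table(k[draws + 1L])
    expect_gt(stats::chisq.test(counts, p = c(0.5, 0.5))$p.value, 0.01)
  }
})

test_that("discrete positives always share the reference category", {
  s <- toy_session(400, 3, seed = 8, discrete = TRUE)
  cfg <- sampling_config("discrete")
  set.seed(9)
  refs <- sample_reference(s, 10000, cfg)
  pos <- sample_positive(s, refs, cfg)
  expect_identical(s$discrete_context[pos + 1L], s$discrete_context[refs + 1L])
  # within-category selection is uniform
  k0 <- which(s$discrete_context == 0L) - 1L
  sel <- pos[s$discrete_context[refs + 1L] == 0L]
  tab <- table(factor(sel, levels = k0))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  # a single-member category returns the reference itself
  s1 <- make_session(matrix(rnorm(9), 3, 3), discrete_context = c("a", "a", "b"))
  expect_equal(sample_positive(s1, 2L, sampling_config("discrete")), 2L)
})

test_that("mixed positives share the category and reduce to continuous for K=1", {
  s <- toy_session(400, 3, seed = 10, discrete = TRUE)
  cfg <- sampling_config("mixed", time_offsets = 1:3)
  set.seed(11)
  refs <- sample_reference(s, 10000, cfg)
  pos <- sample_positive(s, refs, cfg)
  expect_identical(s$discrete_context[pos + 1L], s$discrete_context[refs + 1L])

  sK1 <- make_session(s$signal, s$continuous_context,
                      rep("only", s$n_time))
  cfgm <- sampling_config("mixed", time_offsets = 1:3)
  cfgc <- sampling_config("continuous", time_offsets = 1:3)
  refs2 <- 10:19
  set.seed(12); p1 <- sample_positive(sK1, refs2, cfgm)
  set.seed(12); p2 <- sample_positive(s, refs2, cfgc)
  expect_identical(p1, p2)
})

test_that("continuous conditional follows the empirical difference set", {
  # ramp context: differences with offset 1 are exactly +1, so the positive
  # is the reference's successor
  s <- make_session(matrix(rnorm(100 * 2), 100, 2),
                    continuous_context = as.numeric(0:99))
  cfg <- sampling_config("continuous", time_offsets = 1L)
  refs <- 0:98
  set.seed(13)
  pos <- sample_positive(s, refs, cfg)
  expect_identical(pos, refs + 1L)

  # realized offsets match the difference-set distribution (KS); a smooth
  # random-walk context keeps targets inside the observed range
  set.seed(14)
  cw <- cumsum(rnorm(2000, sd = 0.05))
  st <- make_session(matrix(rnorm(2000 * 2), 2000, 2), continuous_context = cw)
  cfg2 <- sampling_config("continuous", time_offsets = c(1L, 5L))
  D <- contrastembed:::empirical_difference_set(st, c(1L, 5L))[, 1L]
  set.seed(15)
  refs <- sample_reference(st, 5000, cfg2)
  pos <- sample_positive(st, refs, cfg2)
  realized <- st$continuous_context[pos + 1L, 1L] - st$continuous_context[refs + 1L, 1L]
  expect_gt(suppressWarnings(stats::ks.test(realized, D)$p.value), 0.01)
})

test_that("delta conditional matches a folded-normal offset law on a dense ramp", {
  T_len <- 20000L
  s <- make_session(matrix(0, T_len, 1),
                    continuous_context = seq(0, 1, length.out = T_len))
  delta <- 0.01
  cfg <- sampling_config("delta", delta = delta)
  set.seed(16)
  refs <- sample_reference(s, 5000, cfg)
  refs <- refs[refs > 2000 & refs < 18000]  # keep clear of the boundary
  pos <- sample_positive(s, refs, cfg)
  realized <- abs(s$continuous_context[pos + 1L] - s$continuous_context[refs + 1L])
  oracle <- abs(stats::rnorm(5000, sd = delta))
  expect_gt(suppressWarnings(stats::ks.test(realized, oracle)$p.value), 0.01)

  # zero-noise limit returns the reference itself when contexts are unique
  cfg0 <- sampling_config("delta", delta = 1e-12)
  set.seed(17)
  expect_identical(sample_positive(s, 5000:5009, cfg0), 5000:5009)
})

test_that("time conditional draws offsets uniformly and errors at the boundary", {
  s <- toy_session(300, 2, seed = 18)
  cfg <- sampling_config("time", time_offsets = 10L)
  set.seed(19)
  expect_identical(sample_positive(s, 0:9, cfg), 10:19)
  expect_error(sample_positive(s, 299L, cfg), "offset")

  cfgU <- sampling_config("time", time_offsets = 1:10)
  set.seed(20)
  refs <- rep(100L, 10000L)
  pos <- sample_positive(s, refs, cfgU)
  tab <- table(factor(pos - 100L, levels = 1:10))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("batches have matched sizes and full-batch mode covers all windows", {
  s <- toy_session(200, 3, seed = 21)
  cfg <- sampling_config("delta", delta = 0.1, receptive_field = 10L)
  set.seed(22)
  b <- sample_batch(s, 32, cfg)
  expect_length(b$reference, 32L)
  expect_length(b$positive, 32L)
  expect_length(b$negative, 32L)
  valid <- valid_window_indices(s, 10L)
  expect_true(all(c(b$reference, b$positive, b$negative) %in% valid))

  set.seed(23)
  bf <- sample_batch(s, "full", cfg)
  expect_identical(bf$reference, valid)
  expect_identical(bf$negative, valid)

  set.seed(24)
  b1 <- sample_batch(s, 1, cfg)
  expect_length(b1$reference, 1L)
})

test_that("multi-session batches use equal quotas and uniform positive sessions", {
  set.seed(25)
  long <- make_session(matrix(rnorm(1000 * 3), 1000, 3), runif(1000), session_id = "long")
  short <- make_session(matrix(rnorm(100 * 5), 100, 5), runif(100), session_id = "short")
  md <- make_multisession(list(long, short))
  cfg <- sampling_config("delta", delta = 0.05)
  set.seed(26)
  b <- sample_multisession_batch(md, 200, cfg)
  expect_length(b$reference[[1]], 100L)
  expect_length(b$reference[[2]], 100L)
  expect_length(b$negative[[1]], 100L)

  # positive sessions uniform over N across many draws
  set.seed(27)
  counts <- c(0L, 0L)
  for (i in 1:20) {
    bb <- sample_multisession_batch(md, 200, cfg)
    counts <- counts + tabulate(bb$positive$pos_session, 2L)
  }
  expect_gt(stats::chisq.test(counts, p = c(0.5, 0.5))$p.value, 0.01)

  # sessions without shared context dimensionality are rejected
  bad <- make_session(matrix(0, 50, 2), matrix(0, 50, 2))
  expect_error(make_multisession(list(long, bad)), "dimensionality")

  # a single session reduces to ordinary batching
  set.seed(28); b1 <- sample_multisession_batch(make_multisession(list(long)), 50, cfg)
  set.seed(28); b2 <- sample_batch(long, 50, cfg)
  expect_identical(b1$reference[[1]], b2$reference)
  expect_identical(b1$positive$pos_t, b2$positive)
  expect_identical(b1$negative[[1]], b2$negative)
})
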
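test_that("training is deterministic given the seed and learns above chance", {
  s <- toy_session(400, 6, seed = 1)
  spec <- encoder_spec(1, 6, num_hidden = 16, output_dimension = 3,
                       normalize_output = FALSE)
  samp <- sampling_config("delta", delta = 0.1)
  sim <- similarity_config("negative_mse", tau = 1)
  cfg <- fit_config(max_iterations = 120, batch_size = 64,
                    learning_rate = 1e-3, seed = 42)
  m1 <- fit_contrastive(s, spec, samp, sim, cfg)
  m2 <- fit_contrastive(s, spec, samp, sim, cfg)
  expect_identical(m1$history$total, m2$history$total)
  expect_identical(m1$encoders[[1]]$layers, m2$encoders[[1]]$layers)
  # the loss ends strictly below the uninformative value log n
  expect_lt(utils::tail(m1$history$total, 1), log(64))
  expect_equal(m1$history$gof, m1$history$total - log(64))
})

test_that("configuration inconsistencies are rejected before training", {
  s <- toy_session(100, 4, seed = 2)
  samp <- sampling_config("delta", delta = 0.1)
  cfg <- fit_config(max_iterations = 5, batch_size = 16, seed = 1)
  expect_error(fit_contrastive(s, encoder_spec(1, 4, normalize_output = TRUE),
                               samp, similarity_config("negative_mse"), cfg),
               "cosine")
  expect_error(fit_contrastive(s, encoder_spec(1, 4, normalize_output = FALSE),
                               samp, similarity_config("cosine"), cfg),
               "normalize_output")
  expect_error(fit_contrastive(s, encoder_spec(10, 4, normalize_output = FALSE),
                               samp, similarity_config("negative_mse"), cfg),
               "receptive fields differ")
})

test_that("full-batch training uses every valid window per step", {
  s <- toy_session(150, 4, seed = 3)
  spec <- encoder_spec(1, 4, num_hidden = 8, output_dimension = 2,
                       normalize_output = FALSE)
  m <- fit_contrastive(s, spec, sampling_config("delta", delta = 0.1),
                       similarity_config("negative_mse"),
                       fit_config(max_iterations = 3, batch_size = "full", seed = 4))
  expect_equal(m$history$gof, m$history$total - log(150))
})

test_that("transform is label-free, deterministic, and row-counted", {
  s <- toy_session(200, 5, seed = 5)
  spec <- encoder_spec(10, 5, num_hidden = 8, output_dimension = 3,
                       normalize_output = TRUE)
  m <- fit_contrastive(s, spec,
                       sampling_config("time", time_offsets = 1:5, receptive_field = 10),
                       similarity_config("cosine"),
                       fit_config(max_iterations = 30, batch_size = 32, seed = 6))
  e1 <- transform_session(m, s)
  expect_equal(nrow(e1), 200L - 10L + 1L)
  stripped <- make_session(s$signal, session_id = "no-labels")
  e2 <- transform_session(m, stripped)
  expect_identical(unname(e1), unname(e2))
  expect_identical(e1, transform_session(m, s))
  # mismatched dimensionality points at adaptation
  s_wide <- toy_session(50, 7, seed = 7)
  expect_error(transform_session(m, s_wide), "adapt")
})

test_that("hybrid training splits coordinate blocks and degenerates to a plain fit", {
  s <- toy_session(300, 6, seed = 8)
  sim <- similarity_config("negative_mse", tau = 1)
  sampB <- sampling_config("delta", delta = 0.1)
  sampT <- sampling_config("time", time_offsets = 1:5)

  spec5 <- encoder_spec(1, 6, num_hidden = 16, output_dimension = 5,
                        normalize_output = FALSE)
  mh <- fit_hybrid(s, spec5, sampB, sampT, sim,
                   fit_config(max_iterations = 40, batch_size = 64,
                              learning_rate = 1e-3, seed = 9, hybrid_split = c(3, 2)))
  expect_equal(ncol(transform_session(mh, s)), 5L)
  expect_error(fit_hybrid(s, spec5, sampB, sampT, sim,
                          fit_config(max_iterations = 2, batch_size = 8, seed = 1,
                                     hybrid_split = c(3, 3))),
               "sum to the output dimension")

  spec2 <- encoder_spec(1, 6, num_hidden = 16, output_dimension = 2,
                        normalize_output = FALSE)
  shared <- list(max_iterations = 25, batch_size = 32, learning_rate = 1e-3, seed = 10)
  mh0 <- fit_hybrid(s, spec2, sampB, sampT, sim,
                    do.call(fit_config, c(shared, list(hybrid_split = c(2, 0)))))
  mp <- fit_contrastive(s, spec2, sampB, sim, do.call(fit_config, shared))
  expect_equal(mh0$history$total, mp$history$total, tolerance = 1e-12)

  # both blocks receive gradient: coordinates in each block move from init
  set.seed(9)
  init <- build_encoder(spec5)
  final_W <- mh$encoders[[1]]$layers[[8]]$W   # last dense layer, H/2 x 5
  init_W <- init$layers[[8]]$W
  expect_gt(max(abs((final_W - init_W)[, 1:3])), 0)
  expect_gt(max(abs((final_W - init_W)[, 4:5])), 0)
})

test_that("multi-session training shares the embedding space across sessions", {
  set.seed(11)
  c_t <- runif(600, 0, 2 * pi)
  drive <- cbind(sin(c_t), cos(c_t), sin(2 * c_t))
  sA <- make_session(drive %*% matrix(rnorm(12), 3, 4) +
                       matrix(rnorm(2400, sd = 0.2), 600, 4),
                     c_t, session_id = "A")
  sB <- make_session(drive %*% matrix(rnorm(15), 3, 5) +
                       matrix(rnorm(3000, sd = 0.2), 600, 5),
                     c_t, session_id = "B")
  md <- make_multisession(list(sA, sB))
  spec <- encoder_spec(1, 4, num_hidden = 16, output_dimension = 2,
                       normalize_output = FALSE)
  m <- fit_multisession(md, spec, sampling_config("delta", delta = 0.1),
                        similarity_config("negative_mse"),
                        fit_config(max_iterations = 250, batch_size = 128,
                                   learning_rate = 1e-3, seed = 12))
  expect_length(m$encoders, 2L)
  expect_equal(m$encoders[[1]]$spec$num_input, 4L)
  expect_equal(m$encoders[[2]]$spec$num_input, 5L)
  ea <- transform_session(m, sA, 1)
  eb <- transform_session(m, sB, 2)
  # same underlying latent, different neurons: embeddings align linearly
  expect_gt(linear_consistency(ea, eb), 0.5)
  expect_lt(utils::tail(m$history$total, 1), m$history$total[1])
})

test_that("adaptation retrains only the input layer", {
  s <- toy_session(300, 6, seed = 13)
  spec <- encoder_spec(1, 6, num_hidden = 16, output_dimension = 3,
                       normalize_output = FALSE)
  samp <- sampling_config("delta", delta = 0.1)
  sim <- similarity_config("negative_mse")
  pre <- fit_contrastive(s, spec, samp, sim,
                         fit_config(max_iterations = 150, batch_size = 64,
                                    learning_rate = 1e-3, seed = 14))

  # zero adaptation steps with matching width keep the model intact
  m0 <- adapt_model(pre, s, fit_config(max_iterations = 0, batch_size = 32, seed = 15),
                    adapt_steps = 0)
  expect_identical(transform_session(m0, s), transform_session(pre, s))

  # new session with a different signal dimensionality
  s_new <- toy_session(300, 9, seed = 16)
  m1 <- adapt_model(pre, s_new,
                    fit_config(max_iterations = 5, batch_size = 64,
                               learning_rate = 1e-3, seed = 17),
                    adapt_steps = 5)
  expect_equal(m1$encoders[[1]]$spec$num_input, 9L)
  expect_equal(nrow(transform_session(m1, s_new)), 300L)
  # downstream layers are bit-identical to the pretrained ones
  for (li in setdiff(contrastembed:::encoder_param_layers(pre$encoders[[1]]),
                     2L)) {
    expect_identical(m1$encoders[[1]]$layers[[li]]$W,
                     pre$encoders[[1]]$layers[[li]]$W)
  }
})
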
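test_that("generated network hits the target connection statistics", {
  prof <- long_tail_profile(n_neurons = 4095, connection_probability = 0.015,
                            inhibitory_fraction = 0.28, seed = 42)
  net <- generate_longtailed_network(prof)
  expect_valid_network(net)
  s <- compute_summaries(net)
  n <- net$n_neurons
  se_p <- sqrt(0.015 * 0.985 / (n * (n - 1)))
  expect_lt(abs(s$connection_probability - 0.015), 3 * se_p)
  se_f <- sqrt(0.28 * 0.72 / n)
  expect_lt(abs(s$inhibitory_fraction - 0.28), 3 * se_f)
})

test_that("outgoing-weight magnitudes are long-tailed; shape follows the profile", {
  # oracle: closed-form skewness of the per-neuron log-normal scale
  sdl <- long_tail_profile()$out_scale_log_sd
  ln_skew <- (exp(sdl^2) + 2) * sqrt(exp(sdl^2) - 1)
  expect_gt(ln_skew, 1)
  prof <- long_tail_profile(n_neurons = 2000, seed = 7)
  net <- generate_longtailed_network(prof)
  s <- compute_summaries(net)
  so <- abs(s$s_out[!is.na(s$s_out)])
  expect_gt(sample_skewness(so), 1)
  # with many outgoing links per neuron, s_out concentrates near the scale
  # draw, so its skewness cannot exceed the scale distribution's by much
  expect_lt(sample_skewness(so), 3 * ln_skew)
  # zero-variance scale + zero CV degenerates |s_out| to a single atom
  prof0 <- long_tail_profile(n_neurons = 300, out_scale_log_sd = 0,
                             within_neuron_weight_cv = 0, seed = 8)
  net0 <- generate_longtailed_network(prof0)
  s0 <- compute_summaries(net0)
  so0 <- abs(s0$s_out[!is.na(s0$s_out)])
  expect_equal(max(so0) - min(so0), 0, tolerance = 1e-12)
  expect_equal(so0[1], exp(prof0$out_scale_log_mean), tolerance = 1e-12)
})

test_that("generation is deterministic under a fixed seed", {
  prof <- long_tail_profile(n_neurons = 300, seed = 99)
  a <- generate_longtailed_network(prof)
  b <- generate_longtailed_network(prof)
  expect_equal(as.matrix(a$weights), as.matrix(b$weights))
  expect_identical(a$neuron_type, b$neuron_type)
})

test_that("Gaussian surrogate matches reference moments but loses the tail", {
  prof <- long_tail_profile(seed = 13)   # full-size default profile
  ref <- generate_longtailed_network(prof)
  sur <- generate_gaussian_surrogate(ref, seed = 14)
  expect_valid_network(sur)
  # connection probability preserved
  s_ref <- compute_summaries(ref)
  s_sur <- compute_summaries(sur)
  expect_equal(s_sur$connection_probability, s_ref$connection_probability,
               tolerance = 0.03)
  # the Gaussian draw reproduces the reference's weight moments; the
  # subsequent same-sign adjustment leaves the SD essentially intact but
  # shifts the signed mean by a modest fraction of the weight SD
  expect_equal(sd(sur$weights@x), sd(ref$weights@x), tolerance = 0.05)
  expect_lt(abs(mean(sur$weights@x) - mean(ref$weights@x)),
            0.25 * sd(ref$weights@x))
  # |s_out| far less skewed than the long-tailed reference
  sk_ref <- sample_skewness(abs(s_ref$s_out[!is.na(s_ref$s_out)]))
  sk_sur <- sample_skewness(abs(s_sur$s_out[!is.na(s_sur$s_out)]))
  expect_gt(sk_ref, 1)
  expect_lt(sk_sur, 0.5)
  expect_lt(sk_sur, sk_ref)
  # determinism
  sur2 <- generate_gaussian_surrogate(ref, seed = 14)
  expect_equal(as.matrix(sur2$weights), as.matrix(sur$weights))
})

test_that("a constant-weight reference yields a constant-magnitude surrogate", {
  w <- Matrix::sparseMatrix(i = c(2, 3, 1), j = c(1, 2, 3), x = c(2, 2, 2),
                            dims = c(3, 3))
  ref <- synaptic_network(w)
  sur <- generate_gaussian_surrogate(ref, seed = 5)
  expect_true(all(abs(abs(sur$weights@x) - 2) < 1e-12))
})

test_that("column shuffle preserves each neuron's outgoing degree and weights exactly", {
  ref <- random_net(n = 80, seed = 11)
  for (seed in c(1, 2, 3)) {
    shuf <- shuffle_within_columns(ref, seed = seed)
    expect_valid_network(shuf)
    s_ref <- compute_summaries(ref)
    s_shuf <- compute_summaries(shuf)
    expect_identical(s_shuf$k_out, s_ref$k_out)
    expect_equal(s_shuf$s_out, s_ref$s_out)
    # full per-column weight multisets, not just the means
    for (j in seq_len(ref$n_neurons)) {
      expect_equal(sort(shuf$weights[, j, drop = FALSE]@x),
                   sort(ref$weights[, j, drop = FALSE]@x))
    }
    expect_identical(shuf$neuron_type, ref$neuron_type)
  }
})

test_that("a single-edge column moves its edge with the weight unchanged", {
  w <- Matrix::sparseMatrix(i = 2, j = 1, x = 0.7, dims = c(30, 30))
  ref <- synaptic_network(w)
  rows_seen <- integer(0)
  for (seed in 1:25) {
    shuf <- shuffle_within_columns(ref, seed = seed)
    expect_length(shuf$weights@x, 1L)
    expect_equal(shuf$weights@x, 0.7)
    expect_identical(diff(shuf$weights@p)[1], 1L)
    rows_seen <- c(rows_seen, shuf$weights@i + 1L)
  }
  expect_gt(length(unique(rows_seen)), 5)   # edge actually moves around
  expect_false(any(rows_seen == 1))         # never onto the diagonal
})

test_that("column shuffle destroys per-row weight correlations (s_in+ becomes lighter-tailed)", {
  ref <- rowscale_net()
  sk_ref <- sample_skewness(compute_summaries(ref)$s_in_plus)
  shuf <- shuffle_within_columns(ref, seed = 21)
  sk_shuf <- sample_skewness(compute_summaries(shuf)$s_in_plus)
  expect_gt(sk_ref, 1)
  expect_lt(sk_shuf, 0.5 * sk_ref)
})

test_that("row shuffle preserves per-row magnitude multisets and degrades the |s_out| tail", {
  ref <- random_net(n = 80, seed = 12)
  shuf <- shuffle_within_rows(ref, seed = 31)
  expect_valid_network(shuf)
  wr <- as.matrix(ref$weights)
  ws <- as.matrix(shuf$weights)
  for (i in seq_len(ref$n_neurons)) {
    expect_equal(sort(abs(wr[i, wr[i, ] != 0])), sort(abs(ws[i, ws[i, ] != 0])))
  }
  expect_identical(rowSums(wr != 0), rowSums(ws != 0))
  # long-tailed reference: |s_out| skewness collapses after row shuffling
  lt <- generate_longtailed_network(long_tail_profile(n_neurons = 2000, seed = 15))
  lt_shuf <- shuffle_within_rows(lt, seed = 16)
  sk_ref <- sample_skewness(abs(compute_summaries(lt)$s_out))
  sk_shuf <- sample_skewness(abs(compute_summaries(lt_shuf)$s_out))
  expect_gt(sk_ref, 1)
  expect_lt(sk_shuf, 0.5 * sk_ref)
})
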
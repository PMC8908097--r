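# A moderately dense small network used for integration-level checks.
sim_fixture_net <- function(n = 100, p = 0.1, seed = 4) {
  prof <- long_tail_profile(n_neurons = n, connection_probability = p,
                            inhibitory_fraction = 0.25,
                            out_scale_log_mean = log(0.3), seed = seed)
  generate_longtailed_network(prof)
}

test_that("initialization puts every neuron at rest values with zero conductances", {
  net <- sim_fixture_net(n = 20)
  cfg <- simulation_config()
  st <- initialize_state(net, cfg)
  expect_equal(st$v, rep(-65, 20))
  expect_equal(st$u, rep(-13, 20))   # b * v_init = 0.2 * -65
  expect_equal(st$g_exc, rep(0, 20))
  expect_equal(st$g_inh, rep(0, 20))
  # zero conductances mean zero synaptic current
  I <- st$g_exc * (cfg$V_E - st$v) + st$g_inh * (cfg$V_I - st$v)
  expect_equal(I, rep(0, 20))
})

test_that("the deterministic fixed point of the membrane equations is (-70, -14)", {
  # root of 0.04 v^2 + 5 v + 140 - b v = 0 on the stable branch (quadratic
  # formula gives v = -70 or v = -50; b v = u on the recovery nullcline)
  b <- 0.2
  v_star <- (-(5 - b) - sqrt((5 - b)^2 - 4 * 0.04 * 140)) / (2 * 0.04)
  expect_equal(v_star, -70)
  net <- sim_fixture_net(n = 5)
  cfg <- simulation_config(alpha = 0)
  st <- initialize_state(net, cfg)
  st$v <- rep(-70, 5)
  st$u <- rep(-14, 5)
  out <- izh_step(st, net, cfg)
  expect_equal(out$state$v, rep(-70, 5))
  expect_equal(out$state$u, rep(-14, 5))
})

test_that("one noise-free Euler step from initialization matches hand arithmetic", {
  net <- sim_fixture_net(n = 3)
  cfg <- simulation_config(alpha = 0)
  st <- initialize_state(net, cfg)
  out <- izh_step(st, net, cfg)
  # dv/dt = 0.04*65^2 - 5*65 + 140 + 13 = -3 -> v = -65 - 0.375
  expect_equal(out$state$v, rep(-65.375, 3))
  expect_equal(out$state$u, rep(-13, 3))
})

test_that("threshold crossing records a spike and applies the reset", {
  w <- Matrix::sparseMatrix(i = 2, j = 1, x = 0.5, dims = c(2, 2))
  net <- synaptic_network(w)   # neuron 1 excitatory, neuron 2 silent
  cfg <- simulation_config(alpha = 0)
  st <- initialize_state(net, cfg)
  st$v <- c(25, -65)
  st$u <- c(-20, -13)
  out <- izh_step(st, net, cfg)
  # dv/dt = 0.04*625 + 125 + 140 + 20 = 310 -> v = 25 + 38.75 >= 30
  expect_identical(out$spiked, 1L)
  expect_equal(out$state$v[1], -65)          # v -> c
  # u first takes its Euler update from the pre-reset state, then += d
  expect_equal(out$state$u[1], -20 + 0.125 * 0.02 * (0.2 * 25 + 20) + 8)
  # the spike increments its target's excitatory conductance by |w|
  expect_equal(out$state$g_exc[2], 0.5)
})

test_that("the compiled integrator agrees step-for-step with the R reference", {
  net <- sim_fixture_net(n = 30, p = 0.3, seed = 9)
  cfg <- simulation_config(alpha = 0, dt = 0.125, total_time = 50)
  # noise-free but active: start some neurons near threshold with strong drive
  init <- initialize_state(net, cfg)
  set.seed(31)
  init$v <- runif(30, -70, 29)
  init$g_exc <- runif(30, 0, 2)
  init$g_inh <- runif(30, 0, 1)
  got <- simulate_network(net, cfg, init = init)
  st <- init
  spikes_r <- list()
  n_steps <- round(cfg$total_time / cfg$dt)
  for (s in seq_len(n_steps)) {
    out <- izh_step(st, net, cfg, time_now = (s - 1) * cfg$dt)
    st <- out$state
    if (length(out$spiked))
      spikes_r[[length(spikes_r) + 1L]] <- data.frame(neuron = out$spiked,
                                                      time = out$spike_time)
  }
  ref <- do.call(rbind, spikes_r)
  ref <- ref[order(ref$time, ref$neuron), ]
  expect_equal(nrow(got), nrow(ref))
  expect_equal(got$neuron, ref$neuron)
  expect_equal(got$time, ref$time, tolerance = 1e-12)
  fin <- attr(got, "final_state")
  expect_equal(fin$v, st$v, tolerance = 1e-10)
  expect_equal(fin$u, st$u, tolerance = 1e-10)
  expect_equal(fin$g_exc, st$g_exc, tolerance = 1e-10)
  expect_equal(fin$g_inh, st$g_inh, tolerance = 1e-10)
})

test_that("closed-form conductance evaluates the decaying sum exactly", {
  expect_equal(conductance_closed_form(0, 2, tau = 5, t = 5), 2 * exp(-1))
  expect_equal(conductance_closed_form(10, 2, tau = 5, t = 5), 0)   # t < t0
  expect_equal(conductance_closed_form(c(0, 5), 1, tau = 5, t = 5), exp(-1) + 1)
  # superposition over presynaptic neurons with different weights
  expect_equal(conductance_closed_form(list(0, 2), c(1, 3), tau = 2, t = 4),
               exp(-2) + 3 * exp(-1))
})

test_that("simulated conductances match the closed form to floating-point accuracy", {
  net <- sim_fixture_net(n = 100, p = 0.1, seed = 17)
  cfg <- simulation_config(alpha = 3, total_time = 1000, seed = 18)
  sp <- simulate_network(net, cfg, record_conductances = TRUE)
  expect_gt(nrow(sp), 100)   # the check must exercise real spiking
  tr <- attr(sp, "conductances")
  w <- net$weights
  by_pre <- split(sp$time, factor(sp$neuron, levels = seq_len(net$n_neurons)))
  for (i in seq(1, 100, by = 7)) {
    wi <- w[i, ]
    pre_exc <- which(wi > 0)
    pre_inh <- which(wi < 0)
    ge_ref <- conductance_closed_form(by_pre[pre_exc], wi[pre_exc],
                                      cfg$tau_exc, tr$times)
    gi_ref <- conductance_closed_form(by_pre[pre_inh], abs(wi[pre_inh]),
                                      cfg$tau_inh, tr$times)
    rel <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-12)
    expect_lt(rel(tr$g_exc[i, ], ge_ref), 1e-10)
    expect_lt(rel(tr$g_inh[i, ], gi_ref), 1e-10)
  }
})

test_that("without noise the default initial condition stays silent", {
  net <- sim_fixture_net(n = 200, p = 0.05, seed = 23)
  cfg <- simulation_config(alpha = 0, total_time = 2000)
  sp <- simulate_network(net, cfg)
  expect_identical(nrow(sp), 0L)
})

test_that("seeded runs are bit-identical and firing grows with noise intensity", {
  net <- sim_fixture_net(n = 150, p = 0.05, seed = 25)
  cfg <- simulation_config(alpha = 3, total_time = 1000, seed = 26)
  a <- simulate_network(net, cfg)
  b <- simulate_network(net, cfg)
  expect_identical(a$neuron, b$neuron)
  expect_identical(a$time, b$time)
  cfg1 <- simulation_config(alpha = 1, total_time = 1000, seed = 26)
  expect_gt(firing_rates(a)$network_mean_rate,
            firing_rates(simulate_network(net, cfg1))$network_mean_rate)
})

test_that("conductances never go negative and v never starts a step above threshold", {
  net <- sim_fixture_net(n = 50, p = 0.1, seed = 27)
  cfg <- simulation_config(alpha = 3, total_time = 500, seed = 28)
  sp <- simulate_network(net, cfg, record_conductances = TRUE)
  tr <- attr(sp, "conductances")
  expect_gte(min(tr$g_exc), 0)
  expect_gte(min(tr$g_inh), 0)
  # consecutive spikes of one neuron are at least one step apart
  by_n <- split(sp$time, sp$neuron)
  gaps <- unlist(lapply(by_n, function(tt) if (length(tt) > 1) diff(tt) else numeric(0)))
  if (length(gaps)) expect_gte(min(gaps), cfg$dt - 1e-12)
})

test_that("a constantly driven neuron spikes tonically; stronger drive shortens the ISI", {
  w <- Matrix::sparseMatrix(i = 2, j = 1, x = 1e-9, dims = c(2, 2))
  net <- synaptic_network(w)
  cfg <- simulation_config(alpha = 0, total_time = 2000)
  steady_isi <- function(I) {
    sp <- simulate_network(net, cfg, I_ext = c(I, 0))
    tt <- sp$time[sp$neuron == 1]
    isis <- diff(tt)
    tail_isis <- tail(isis, 5)
    expect_lt(max(tail_isis) - min(tail_isis), 1e-9)   # periodic regime
    tail_isis[1]
  }
  isi10 <- steady_isi(10)
  isi20 <- steady_isi(20)
  expect_gt(isi10, 0)
  expect_lt(isi20, isi10)
})

test_that("halving the time step changes the network-average rate by less than 10%", {
  prof <- long_tail_profile(n_neurons = 500, seed = 33)
  net <- generate_longtailed_network(prof)
  r <- sapply(c(0.125, 0.0625), function(dt) {
    cfg <- simulation_config(dt = dt, total_time = 2000, seed = 34)
    firing_rates(simulate_network(net, cfg))$network_mean_rate
  })
  expect_gt(r[1], 0)
  expect_lt(abs(r[1] - r[2]) / r[1], 0.10)
})
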
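#' Simulation configuration
#'
#' All scalar parameters of the stochastic Izhikevich network model with
#' conductance-based synapses. Defaults are the study conditions: time step
#' 0.125 ms, total time 7500 ms, noise intensity `alpha = 3` (chosen so
#' that spontaneous network-average firing rates are comparable to
#' cortical-culture recordings), spike threshold 30 mV, initial membrane
#' potential -65 mV, conductance decay constants 5 ms (excitatory) and 6 ms
#' (inhibitory), reversal potentials 0 mV and -80 mV, regular-spiking
#' excitatory parameters `(a = 0.02, b = 0.2, c = -65, d = 8)` and
#' fast-spiking inhibitory parameters `(a = 0.1, b = 0.2, c = -65, d = 2)`.
#'
#' @param dt integration time step, ms.
#' @param total_time simulated duration, ms.
#' @param alpha intensity of the Gaussian white noise added to the membrane
#'   potential equation (Euler-Maruyama increment `alpha * sqrt(dt) * z`).
#' @param v_threshold spike threshold, mV.
#' @param v_init initial membrane potential, mV.
#' @param tau_exc,tau_inh conductance decay constants, ms.
#' @param V_E,V_I excitatory and inhibitory reversal potentials, mV.
#' @param excitatory_params,inhibitory_params named numeric vectors with
#'   elements `a`, `b`, `c`, `d`.
#' @param seed optional integer RNG seed for the noise stream.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dt = 0.125, total_time = 7500, alpha = 3,
                              v_threshold = 30, v_init = -65,
                              tau_exc = 5, tau_inh = 6,
                              V_E = 0, V_I = -80,
                              excitatory_params = c(a = 0.02, b = 0.2, c = -65, d = 8),
                              inhibitory_params = c(a = 0.1, b = 0.2, c = -65, d = 2),
                              seed = NULL) {
  if (dt <= 0) stopf("dt must be positive")
  if (total_time < dt) stopf("total_time must be at least dt")
  if (tau_exc <= 0 || tau_inh <= 0) stopf("decay constants must be positive")
  if (V_I >= V_E) stopf("V_I must be below V_E")
  for (p in list(excitatory_params, inhibitory_params))
    if (!all(c("a", "b", "c", "d") %in% names(p)))
      stopf("neuron parameter vectors need named elements a, b, c, d")
  structure(list(dt = dt, total_time = total_time, alpha = alpha,
                 v_threshold = v_threshold, v_init = v_init,
                 tau_exc = tau_exc, tau_inh = tau_inh, V_E = V_E, V_I = V_I,
                 excitatory_params = excitatory_params,
                 inhibitory_params = inhibitory_params,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

# Per-neuron a, b, c, d from the type labels. Silent neurons (no detected
# outgoing links) get regular-spiking parameters: their intrinsic class is
# unobservable from connectivity and the choice only affects their own
# spike trains, not the rest of the network.
neuron_params <- function(net, cfg) {
  inh <- net$neuron_type == "inhibitory"
  pe <- cfg$excitatory_params
  pi_ <- cfg$inhibitory_params
  list(a = ifelse(inh, pi_["a"], pe["a"]),
       b = ifelse(inh, pi_["b"], pe["b"]),
       c = ifelse(inh, pi_["c"], pe["c"]),
       d = ifelse(inh, pi_["d"], pe["d"]))
}

#' Initial network state
#'
#' All membrane potentials start at `v_init` (-65 mV by default), the
#' recovery variable on its nullcline `u = b * v` (so that the
#' noise-free network is quiescent), and both conductances at zero.
#'
#' @param net a [synaptic_network()].
#' @param cfg a [simulation_config()].
#' @return An object of class `neuron_state`: list with vectors `v`, `u`,
#'   `g_exc`, `g_inh`.
#' @export
initialize_state <- function(net, cfg) {
  n <- net$n_neurons
  par <- neuron_params(net, cfg)
  structure(list(v = rep(cfg$v_init, n),
                 u = as.numeric(par$b * cfg$v_init),
                 g_exc = numeric(n), g_inh = numeric(n)),
            class = "neuron_state")
}

#' Spike train set
#'
#' The full record of one simulation: `(neuron index, spike time)` pairs
#' sorted by time, plus the number of neurons and the recording window.
#'
#' @param neuron integer vector of 1-based neuron indices.
#' @param time_ms numeric vector of spike times in ms.
#' @param n_neurons number of neurons in the network.
#' @param total_time length of the recording window, ms.
#' @return A data frame of class `spike_train_set` with columns `neuron`
#'   and `time`, and attributes `n_neurons` and `total_time`.
#' @export
spike_train_set <- function(neuron, time_ms, n_neurons, total_time) {
  if (length(neuron) != length(time_ms)) stopf("neuron and time lengths differ")
  if (length(time_ms) && (min(time_ms) < 0 || max(time_ms) > total_time))
    stopf("spike times must lie in [0, total_time]")
  if (length(neuron) && (min(neuron) < 1 || max(neuron) > n_neurons))
    stopf("neuron indices out of range")
  ord <- order(time_ms, neuron)
  out <- data.frame(neuron = as.integer(neuron[ord]), time = as.numeric(time_ms[ord]))
  attr(out, "n_neurons") <- as.integer(n_neurons)
  attr(out, "total_time") <- as.numeric(total_time)
  class(out) <- c("spike_train_set", "data.frame")
  out
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d spikes, %d neurons, %.4g ms\n",
              nrow(x), attr(x, "n_neurons"), attr(x, "total_time")))
  invisible(x)
}

#' Simulate a network of stochastic Izhikevich neurons
#'
#' Integrates the coupled membrane/recovery equations with
#' conductance-based synaptic coupling by the Euler-Maruyama method and
#' records every spike. Conductances decay by the exact factor
#' `exp(-dt/tau)` between spikes; a spike detected at the end of a step is
#' delivered to its postsynaptic targets so that it first affects their
#' synaptic current at the following step. Spike times are the end times of
#' the steps in which the threshold was crossed. Runs are bit-reproducible
#' for a fixed seed.
#'
#' @param net a [synaptic_network()].
#' @param cfg a [simulation_config()]; `cfg$seed` (if set) seeds the noise
#'   stream locally without disturbing the caller's RNG.
#' @param record_conductances also return the full per-step conductance
#'   traces (memory: two `n_neurons x (n_steps + 1)` matrices); intended
#'   for small runs and oracle checks.
#' @param init optional `neuron_state` to start from (defaults to
#'   [initialize_state()]).
#' @param I_ext constant externally injected current, a scalar or one value
#'   per neuron (default 0; the spontaneous-activity experiments are purely
#'   noise-driven, but a constant drive is useful for single-neuron
#'   characterization).
#' @return A [spike_train_set()]. The final `neuron_state` is attached as
#'   attribute `"final_state"`; with `record_conductances = TRUE` the
#'   traces are attached as attribute `"conductances"` (list with matrices
#'   `g_exc`, `g_inh` and the vector `times` of sample instants).
#' @export
simulate_network <- function(net, cfg, record_conductances = FALSE, init = NULL,
                             I_ext = 0) {
  stopifnot(inherits(net, "synaptic_network"), inherits(cfg, "simulation_config"))
  if (is.null(init)) init <- initialize_state(net, cfg)
  n_steps <- as.integer(round(cfg$total_time / cfg$dt))
  par <- neuron_params(net, cfg)
  w <- net$weights
  res <- with_seed_if(cfg$seed,
    izh_run_cpp(w@p, w@i, abs(w@x), w@x > 0,
                par$a, par$b, par$c, par$d,
                init$v, init$u, init$g_exc, init$g_inh,
                rep_len(as.numeric(I_ext), net$n_neurons),
                cfg$dt, n_steps, cfg$alpha,
                cfg$v_threshold, cfg$V_E, cfg$V_I,
                cfg$tau_exc, cfg$tau_inh,
                record_conductances, 1e3))
  spikes <- spike_train_set(res$spike_neuron, res$spike_step * cfg$dt,
                            net$n_neurons, n_steps * cfg$dt)
  attr(spikes, "final_state") <- structure(
    list(v = res$v, u = res$u, g_exc = res$g_exc, g_inh = res$g_inh),
    class = "neuron_state")
  if (record_conductances)
    attr(spikes, "conductances") <- list(g_exc = res$ge_trace, g_inh = res$gi_trace,
                                         times = (0:n_steps) * cfg$dt)
  spikes
}

#' Single reference Euler-Maruyama step (pure R)
#'
#' One integration step of the network equations, written directly from
#' their definitions; the compiled integrator must agree with repeated
#' application of this function. Exposed for testing and for stepping tiny
#' systems interactively.
#'
#' @param state a `neuron_state`.
#' @param net a [synaptic_network()].
#' @param cfg a [simulation_config()].
#' @param noise vector of standard-Gaussian draws, one per neuron (use
#'   zeros for the deterministic skeleton).
#' @param time_now time at the start of the step, ms (only used to stamp
#'   the returned spike times).
#' @param I_ext constant externally injected current, scalar or per neuron.
#' @return List with the updated `state`, the integer vector `spiked` of
#'   neurons that fired, and `spike_time` (end of this step).
#' @export
izh_step <- function(state, net, cfg, noise = numeric(net$n_neurons), time_now = 0,
                     I_ext = 0) {
  par <- neuron_params(net, cfg)
  v <- state$v; u <- state$u; ge <- state$g_exc; gi <- state$g_inh
  I <- ge * (cfg$V_E - v) + gi * (cfg$V_I - v) + rep_len(as.numeric(I_ext), length(v))
  v_new <- v + cfg$dt * (0.04 * v^2 + 5 * v + 140 - u + I) +
    cfg$alpha * sqrt(cfg$dt) * noise
  u_new <- u + cfg$dt * par$a * (par$b * v - u)
  ge <- ge * exp(-cfg$dt / cfg$tau_exc)
  gi <- gi * exp(-cfg$dt / cfg$tau_inh)
  spiked <- which(v_new >= cfg$v_threshold)
  if (any(!is.finite(v_new)) || any(abs(v_new[setdiff(seq_along(v_new), spiked)]) > 1e3))
    stopf("membrane potential diverged at t = %g ms", time_now + cfg$dt)
  if (length(spiked)) {
    v_new[spiked] <- par$c[spiked]
    u_new[spiked] <- u_new[spiked] + par$d[spiked]
    w <- net$weights[, spiked, drop = FALSE]
    inc <- Matrix::rowSums(abs(w) * (w > 0))
    ge <- ge + as.numeric(inc)
    gi <- gi + as.numeric(Matrix::rowSums(abs(w) * (w < 0)))
  }
  list(state = structure(list(v = v_new, u = u_new, g_exc = ge, g_inh = gi),
                         class = "neuron_state"),
       spiked = spiked, spike_time = time_now + cfg$dt)
}

#' Closed-form synaptic conductance
#'
#' Exact evaluation of the conductance as a sum of exponentially decaying
#' contributions, `G(t) = sum_j w_j sum_k exp(-(t - t_jk)/tau)` over all
#' delivered spikes with `t_jk <= t` (a spike contributes its full weight
#' at its own delivery instant and nothing before it). This is the analytic
#' solution of the conductance dynamics between spikes and serves as the
#' independent oracle for the integrator's recursive decay.
#'
#' @param spike_times list of numeric vectors (one per presynaptic neuron),
#'   or a single numeric vector.
#' @param weights conductance increment per presynaptic neuron (recycled to
#'   the length of `spike_times`).
#' @param tau decay constant, ms.
#' @param t evaluation time(s), ms (vectorized).
#' @return Conductance value(s) at `t`.
#' @examples
#' conductance_closed_form(0, 2, tau = 5, t = 5)   # 2 * exp(-1)
#' @export
conductance_closed_form <- function(spike_times, weights, tau, t) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  weights <- rep_len(weights, length(spike_times))
  all_t <- unlist(spike_times, use.names = FALSE)
  all_w <- rep.int(weights, lengths(spike_times))
  if (!length(all_t)) return(numeric(length(t)) + 0 * t)
  vapply(t, function(tt) {
    keep <- all_t <= tt
    sum(all_w[keep] * exp(-(tt - all_t[keep]) / tau))
  }, numeric(1))
}
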
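#' Profile for the long-tailed synthetic network generator
#'
#' Parameter bundle describing a sparse random directed network whose
#' per-neuron average outgoing weight magnitudes follow a long-tailed
#' (log-normal) distribution, emulating the statistics of effective
#' networks reconstructed from cortical-culture multi-electrode-array
#' recordings. Defaults match the densest reconstructed culture:
#' 4095 neurons, 1.5\% connection probability, inhibitory fraction 0.28.
#'
#' Each neuron `j` draws an outgoing weight scale
#' `m_j ~ Lognormal(out_scale_log_mean, out_scale_log_sd)`; its individual
#' outgoing weight magnitudes are gamma-distributed with mean `m_j` and
#' coefficient of variation `within_neuron_weight_cv` (a CV of 0 makes all
#' of a neuron's weights equal to `m_j`). The log-normal across neurons is
#' what produces the heavy right tail of the `|s_out|` distribution; the
#' default `out_scale_log_sd = 0.8` gives a log-normal skewness of about
#' 3.7. `out_scale_log_mean` sets the overall synaptic strength; the
#' default (mean scale 0.0145) is calibrated so that at noise intensity
#' `alpha = 3` the network-average firing rate is of order 1-10 spikes/s
#' and the network typically bursts, while its Gaussian-weight and
#' row-shuffled surrogates typically do not (see the package vignette for
#' the calibration and its margins).
#'
#' @param n_neurons number of neurons (default 4095).
#' @param connection_probability probability that any ordered off-diagonal
#'   pair is connected (default 0.015).
#' @param inhibitory_fraction probability that a neuron is inhibitory
#'   (default 0.28).
#' @param out_scale_log_mean mean of `log(m_j)`.
#' @param out_scale_log_sd standard deviation of `log(m_j)` (default 0.8).
#' @param within_neuron_weight_cv coefficient of variation of a neuron's
#'   weight magnitudes around `m_j` (default 0.2).
#' @param seed optional integer RNG seed.
#' @return A `longtail_profile` list.
#' @export
long_tail_profile <- function(n_neurons = 4095,
                              connection_probability = 0.015,
                              inhibitory_fraction = 0.28,
                              out_scale_log_mean = log(0.0145) - 0.8^2 / 2,
                              out_scale_log_sd = 0.8,
                              within_neuron_weight_cv = 0.2,
                              seed = NULL) {
  if (n_neurons < 2) stopf("n_neurons must be at least 2")
  if (connection_probability <= 0 || connection_probability >= 1)
    stopf("connection_probability must be in (0, 1)")
  if (inhibitory_fraction <= 0 || inhibitory_fraction >= 1)
    stopf("inhibitory_fraction must be in (0, 1)")
  if (out_scale_log_sd < 0) stopf("out_scale_log_sd must be >= 0")
  if (within_neuron_weight_cv < 0) stopf("within_neuron_weight_cv must be >= 0")
  structure(list(n_neurons = as.integer(n_neurons),
                 connection_probability = connection_probability,
                 inhibitory_fraction = inhibitory_fraction,
                 out_scale_log_mean = out_scale_log_mean,
                 out_scale_log_sd = out_scale_log_sd,
                 within_neuron_weight_cv = within_neuron_weight_cv,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "longtail_profile")
}

# Sample M distinct off-diagonal ordered pairs (i, j), i != j, uniformly.
# Linear index idx in [0, n(n-1)): j = idx %/% (n-1), row slot shifted past
# the diagonal.
sample_offdiag_pairs <- function(n, m) {
  idx <- sample.int(n * (n - 1), m) - 1
  j <- idx %/% (n - 1)
  r <- idx %% (n - 1)
  i <- r + (r >= j)
  list(i = as.integer(i + 1), j = as.integer(j + 1))
}

#' Generate a synthetic network with long-tailed outgoing weights
#'
#' Draws a directed Erdos-Renyi graph at the profile's connection
#' probability, types each neuron inhibitory with the profile's inhibitory
#' fraction, and assigns weight magnitudes hierarchically: a log-normal
#' per-neuron outgoing scale, then gamma-distributed link magnitudes around
#' that scale. Signs follow neuron type (Dale's principle). Neurons that
#' happen to receive no outgoing links are labeled `"silent"`.
#'
#' @param profile a [long_tail_profile()].
#' @return A [synaptic_network()] whose `|s_out|` distribution is
#'   right-skewed/long-tailed for the default profile.
#' @export
generate_longtailed_network <- function(profile) {
  stopifnot(inherits(profile, "longtail_profile"))
  with_seed_if(profile$seed, {
    n <- profile$n_neurons
    npairs <- n * (n - 1)
    m <- stats::rbinom(1L, npairs, profile$connection_probability)
    pos <- sample_offdiag_pairs(n, m)
    is_inh <- stats::runif(n) < profile$inhibitory_fraction
    scale_j <- stats::rlnorm(n, profile$out_scale_log_mean, profile$out_scale_log_sd)
    cv <- profile$within_neuron_weight_cv
    mw <- scale_j[pos$j]
    mag <- if (cv > 0) {
      shape <- 1 / cv^2
      stats::rgamma(m, shape = shape, rate = shape / mw)
    } else mw
    x <- mag * ifelse(is_inh[pos$j], -1, 1)
    w <- Matrix::sparseMatrix(i = pos$i, j = pos$j, x = x, dims = c(n, n))
    types <- ifelse(is_inh, "inhibitory", "excitatory")
    types[tabulate(pos$j, nbins = n) == 0L] <- "silent"
    synaptic_network(w, types, validate = FALSE)
  })
}

#' Gaussian-weight random surrogate of a reference network
#'
#' Builds a random network with the reference's empirical connection
#' probability and synaptic weights drawn from a Gaussian with the mean and
#' standard deviation of the reference's nonzero signed weights, then
#' enforces the same-sign convention using the reference's neuron types
#' (magnitudes preserved, signs flipped where needed). The surrogate's
#' per-neuron average-weight distributions are approximately Gaussian, in
#' contrast to a long-tailed reference.
#'
#' @param ref a [synaptic_network()] with at least one edge.
#' @param seed optional integer RNG seed.
#' @return A [synaptic_network()].
#' @export
generate_gaussian_surrogate <- function(ref, seed = NULL) {
  stopifnot(inherits(ref, "synaptic_network"))
  xs <- ref$weights@x
  if (length(xs) == 0L) stopf("reference network has no edges")
  n <- ref$n_neurons
  p_emp <- length(xs) / (n * (n - 1))
  mu <- mean(xs)
  sdev <- if (length(xs) > 1L) stats::sd(xs) else 0
  with_seed_if(seed, {
    m <- stats::rbinom(1L, n * (n - 1), p_emp)
    pos <- sample_offdiag_pairs(n, m)
    x <- stats::rnorm(m, mu, sdev)
    x[x == 0] <- mu + 1e-12   # keep the edge: a drawn weight of exactly 0 is measure-zero
    w <- Matrix::sparseMatrix(i = pos$i, j = pos$j, x = x, dims = c(n, n))
    apply_sign_convention(w, ref$neuron_type)
  })
}

# Permute the entries of each column of `w` uniformly over off-diagonal
# positions (the full column including its zeros is permuted, which is
# equivalent to re-drawing the nonzero positions uniformly and carrying the
# weights along).
permute_within_columns <- function(w, n) {
  p <- w@p
  i_new <- integer(length(w@i))
  for (j in seq_len(n)) {
    lo <- p[j] + 1L
    hi <- p[j + 1L]
    if (hi < lo) next
    k <- hi - lo + 1L
    rows <- seq_len(n)[-j]
    i_new[lo:hi] <- if (length(rows) == 1L) rows else sample(rows, k)
  }
  j_all <- rep.int(seq_len(n), diff(p))
  Matrix::sparseMatrix(i = i_new, j = j_all, x = w@x, dims = c(n, n))
}

#' Column-shuffled surrogate (outgoing structure preserved)
#'
#' For each presynaptic neuron, randomly permutes the entries of its column
#' of the connectivity matrix over the off-diagonal positions and then
#' re-applies the same-sign convention. Each neuron keeps its outgoing
#' degree and its set of outgoing weights exactly, so the `|s_out|`
#' distribution is identical to the reference's, while the incoming-weight
#' distributions (`s_in+`, `|s_in-|`) are randomized toward Gaussian.
#'
#' @param ref a [synaptic_network()].
#' @param seed optional integer RNG seed.
#' @return A [synaptic_network()].
#' @export
shuffle_within_columns <- function(ref, seed = NULL) {
  stopifnot(inherits(ref, "synaptic_network"))
  with_seed_if(seed, {
    w <- permute_within_columns(ref$weights, ref$n_neurons)
    apply_sign_convention(w, ref$neuron_type)
  })
}

#' Row-shuffled surrogate (incoming structure approximately preserved)
#'
#' For each postsynaptic neuron, randomly permutes the entries of its row
#' of the connectivity matrix over the off-diagonal positions and then
#' re-applies the same-sign convention. Each row keeps its multiset of
#' weight magnitudes (the sign adjustment may flip signs to match the new
#' presynaptic neuron's type, so the incoming-average distributions are
#' close to, but not exactly, the reference's), while the outgoing-average
#' `|s_out|` distribution is randomized toward Gaussian.
#'
#' @param ref a [synaptic_network()].
#' @param seed optional integer RNG seed.
#' @return A [synaptic_network()].
#' @export
shuffle_within_rows <- function(ref, seed = NULL) {
  stopifnot(inherits(ref, "synaptic_network"))
  with_seed_if(seed, {
    wt <- permute_within_columns(Matrix::t(ref$weights), ref$n_neurons)
    apply_sign_convention(Matrix::t(wt), ref$neuron_type)
  })
}
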
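# Fixture builders used across the suite. Everything is generated in code;
# no stored data files.

# Tiny hand-specified network (columns = presynaptic neurons):
#   neuron 1: silent (no outgoing links), incoming weights {+1, +3, -2}
#   neuron 2: excitatory, outgoing {+1 -> 1, +2 -> 3}
#   neuron 3: excitatory, outgoing {+3 -> 1}
#   neuron 4: inhibitory, outgoing {-2 -> 1, -1 -> 2}
tiny_net <- function() {
  w <- Matrix::sparseMatrix(
    i = c(1, 1, 1, 2, 3),
    j = c(2, 3, 4, 4, 2),
    x = c(1, 3, -2, -1, 2),
    dims = c(4, 4))
  synaptic_network(w)
}

# Neuron 1 inhibitory with outgoing weights {-1, -3}; others excitatory.
out_inh_net <- function() {
  w <- Matrix::sparseMatrix(i = c(2, 3), j = c(1, 1), x = c(-1, -3),
                            dims = c(3, 3))
  synaptic_network(w)
}

# Three inhibitory edges {-1, -2, -3} (the sigma = sqrt(2/3) worked case)
# plus one excitatory edge that must never be touched by suppression.
sigma_case_net <- function() {
  w <- Matrix::sparseMatrix(i = c(2, 3, 4, 1), j = c(1, 1, 2, 3),
                            x = c(-1, -2, -3, 5), dims = c(4, 4))
  synaptic_network(w)
}

# Small random Dale-consistent network for property loops.
random_net <- function(n = 60, p = 0.1, f_inh = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n) < p, n, n)
    diag(m) <- FALSE
    inh <- stats::runif(n) < f_inh
    x <- matrix(stats::rlnorm(n * n, log(0.5), 0.6), n, n) * m
    x <- sweep(x, 2, ifelse(inh, -1, 1), "*")
    synaptic_network(Matrix::Matrix(x, sparse = TRUE))
  })
}

# Network whose incoming weights are correlated per postsynaptic neuron
# (long-tailed per-row scale), all excitatory: its s_in+ distribution is
# long-tailed, which column shuffling destroys.
rowscale_net <- function(n = 400, p = 0.05, seed = 5) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n) < p, n, n)
    diag(m) <- FALSE
    rscale <- stats::rlnorm(n, log(1), 1.2)
    x <- m * matrix(stats::rgamma(n * n, shape = 4, rate = 4), n, n) * rscale
    synaptic_network(Matrix::Matrix(x, sparse = TRUE))
  })
}

expect_valid_network <- function(net) {
  expect_s3_class(net, "synaptic_network")
  expect_silent(validate_network(net))
}
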
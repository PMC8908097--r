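#' Standard deviation of the inhibitory synaptic weights
#'
#' Population standard deviation (denominator `n`) of all nonzero negative
#' weights of the network. This is the unit in which uniform suppression or
#' enhancement levels `k` are expressed.
#'
#' @param net a [synaptic_network()].
#' @return A positive scalar.
#' @export
inhibitory_sigma <- function(net) {
  xs <- net$weights@x
  neg <- xs[xs < 0]
  if (length(neg) == 0L) stopf("network has no inhibitory edges")
  sqrt(mean((neg - mean(neg))^2))
}

#' Uniformly suppress (or enhance) inhibitory synaptic weights
#'
#' Suppression shifts every negative weight `w` to `min(w + k * sigma, 0)`,
#' where `sigma` is the population standard deviation of all inhibitory
#' weights of the unmodified network: inhibitory weights move toward zero
#' by a uniform amount `k * sigma`, and any weight that would cross zero is
#' clamped to zero (an inhibitory synapse is removed, never turned
#' excitatory). Enhancement shifts every negative weight to `w - k * sigma`
#' (no clamp is needed). Excitatory weights are never touched. An
#' inhibitory neuron whose outgoing links are all clamped away becomes
#' `"silent"`.
#'
#' @param net a [synaptic_network()] with at least one inhibitory edge.
#' @param k non-negative suppression level in units of `sigma` (the study
#'   grid is 0.25, 0.5, 1).
#' @param mode `"suppress"` (default) or `"enhance"`.
#' @param sigma optional override of the weight-SD scale; defaults to
#'   [inhibitory_sigma()] of `net`.
#' @return The modified [synaptic_network()].
#' @examples
#' w <- Matrix::sparseMatrix(i = c(2, 3, 1), j = c(1, 1, 2),
#'                           x = c(-1, -2, -3), dims = c(3, 3))
#' net <- synaptic_network(w)
#' suppress_inhibition(net, k = 1)$weights@x   # shifted by sigma = sqrt(2/3) * sd-unit
#' @export
suppress_inhibition <- function(net, k, mode = c("suppress", "enhance"),
                                sigma = NULL) {
  stopifnot(inherits(net, "synaptic_network"))
  mode <- match.arg(mode)
  if (k < 0) stopf("suppression level k must be non-negative")
  if (is.null(sigma)) sigma <- inhibitory_sigma(net)
  if (sigma <= 0) stopf("sigma must be positive")
  w <- net$weights
  neg <- w@x < 0
  if (!any(neg)) stopf("network has no inhibitory edges")
  w@x[neg] <- if (mode == "suppress") pmin(w@x[neg] + k * sigma, 0)
              else w@x[neg] - k * sigma
  w <- Matrix::drop0(w)
  types <- net$neuron_type
  types[diff(w@p) == 0L] <- "silent"
  synaptic_network(w, types, validate = FALSE)
}

#' Achieved suppression ratio of inhibitory weight magnitude
#'
#' The relative decrease in the average magnitude of the inhibitory
#' weights: `(mean|w_inh,orig| - mean|w_inh,mod|) / mean|w_inh,orig|`,
#' where both averages run over the *original* network's inhibitory edge
#' positions and an edge clamped to zero in the modified network
#' contributes zero. The ratio is in `[0, 1]` for suppression (1 = all
#' inhibition removed) and `<= 0` for enhancement.
#'
#' @param original the unmodified [synaptic_network()].
#' @param modified the network returned by [suppress_inhibition()].
#' @return A scalar ratio.
#' @export
suppression_ratio <- function(original, modified) {
  stopifnot(inherits(original, "synaptic_network"),
            inherits(modified, "synaptic_network"))
  w0 <- original$weights
  neg <- w0@x < 0
  if (!any(neg)) stopf("original network has no inhibitory edges")
  ii <- (w0@i + 1L)[neg]
  jj <- rep.int(seq_len(original$n_neurons), diff(w0@p))[neg]
  m0 <- mean(abs(w0@x[neg]))
  wmod_at <- modified$weights[cbind(ii, jj)]
  # positions clamped to zero contribute 0; enhancement gives larger magnitudes
  m1 <- mean(abs(pmin(wmod_at, 0)))
  (m0 - m1) / m0
}
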
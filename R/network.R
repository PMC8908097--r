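#' Weighted directed synaptic network
#'
#' Container for a signed, weighted, directed connectivity matrix together
#' with per-neuron type labels. Entry `w[i, j]` is the synaptic weight of
#' the link from presynaptic neuron `j` to postsynaptic neuron `i`;
#' positive weights are excitatory, negative inhibitory. All outgoing links
#' of a neuron share one sign (Dale consistency): a neuron is
#' `"excitatory"` if its column is positive, `"inhibitory"` if negative,
#' and `"silent"` if it has no outgoing links at all. Self-connections are
#' not allowed.
#'
#' @param weights a square matrix (dense or any [Matrix::sparseMatrix()]
#'   class) of signed synaptic weights, `weights[i, j]` = link j -> i.
#' @param neuron_type optional character vector of per-neuron labels in
#'   `c("excitatory", "inhibitory", "silent")`. When omitted, labels are
#'   inferred from the column signs.
#' @param validate check invariants (Dale consistency, zero diagonal,
#'   silent = empty column)? Default `TRUE`.
#' @return An object of class `synaptic_network`: a list with elements
#'   `weights` (a `dgCMatrix`), `neuron_type`, and `n_neurons`.
#' @examples
#' w <- Matrix::sparseMatrix(i = c(2, 3, 1), j = c(1, 1, 2),
#'                           x = c(0.5, 1.2, -0.7), dims = c(3, 3))
#' net <- synaptic_network(w)
#' net$neuron_type
#' @export
synaptic_network <- function(weights, neuron_type = NULL, validate = TRUE) {
  w <- methods::as(methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(w) != ncol(w)) stopf("weight matrix must be square")
  w <- Matrix::drop0(w)
  n <- nrow(w)
  if (is.null(neuron_type)) {
    neuron_type <- infer_types(w)
  } else {
    if (length(neuron_type) != n) stopf("need one neuron_type per neuron")
    bad <- setdiff(unique(neuron_type), c("excitatory", "inhibitory", "silent"))
    if (length(bad)) stopf("unknown neuron type '%s'", bad[1])
  }
  net <- structure(list(weights = w, neuron_type = neuron_type, n_neurons = n),
                   class = "synaptic_network")
  if (validate) validate_network(net)
  net
}

# Column signs -> type labels; mixed-sign columns are an error.
infer_types <- function(w) {
  n <- ncol(w)
  types <- rep("silent", n)
  p <- w@p
  for (j in seq_len(n)) {
    if (p[j + 1L] > p[j]) {
      xs <- w@x[(p[j] + 1L):p[j + 1L]]
      if (all(xs > 0)) types[j] <- "excitatory"
      else if (all(xs < 0)) types[j] <- "inhibitory"
      else stopf("column %d mixes excitatory and inhibitory weights", j)
    }
  }
  types
}

#' Validate a synaptic network's invariants
#'
#' Checks Dale consistency (each column's sign matches the neuron's type
#' label), zero diagonal, and that `"silent"` labels coincide exactly with
#' all-zero columns. Errors on the first violation.
#'
#' @param net a [synaptic_network()].
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  w <- net$weights
  n <- net$n_neurons
  if (length(net$neuron_type) != n) stopf("type label count != n_neurons")
  if (any(Matrix::diag(w) != 0)) stopf("self-connections are not allowed")
  p <- w@p
  for (j in seq_len(n)) {
    xs <- if (p[j + 1L] > p[j]) w@x[(p[j] + 1L):p[j + 1L]] else numeric(0)
    ty <- net$neuron_type[j]
    ok <- switch(ty,
      excitatory = length(xs) > 0 && all(xs > 0),
      inhibitory = length(xs) > 0 && all(xs < 0),
      silent     = length(xs) == 0L,
      stopf("unknown neuron type '%s'", ty))
    if (!ok) stopf("neuron %d violates Dale consistency for type '%s'", j, ty)
  }
  invisible(net)
}

#' @export
print.synaptic_network <- function(x, ...) {
  s <- compute_summaries(x)
  cat(sprintf("<synaptic_network> %d neurons, %d edges\n", x$n_neurons,
              length(x$weights@x)))
  cat(sprintf("  connection probability: %.4g%%\n", 100 * s$connection_probability))
  cat(sprintf("  types: %d excitatory, %d inhibitory, %d silent\n",
              sum(x$neuron_type == "excitatory"),
              sum(x$neuron_type == "inhibitory"),
              sum(x$neuron_type == "silent")))
  invisible(x)
}

#' Enforce the same-sign (Dale) convention on a weight matrix
#'
#' Forces every nonzero entry of column `j` to carry the sign dictated by
#' `types[j]`: positive for excitatory, negative for inhibitory; magnitudes
#' are unchanged. A column typed `"silent"` that nonetheless contains edges
#' is made positive and its neuron relabeled excitatory; a typed neuron
#' whose column is empty is relabeled silent. The diagonal is zeroed.
#'
#' @param weights square signed weight matrix (sparse or dense).
#' @param types character vector of per-neuron labels.
#' @return A valid [synaptic_network()].
#' @export
apply_sign_convention <- function(weights, types) {
  w <- methods::as(methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n <- ncol(w)
  if (length(types) != n) stopf("need one type per neuron")
  Matrix::diag(w) <- 0
  w <- Matrix::drop0(w)
  sgn <- ifelse(types == "inhibitory", -1, 1)
  colidx <- rep.int(seq_len(n), diff(w@p))
  w@x <- abs(w@x) * sgn[colidx]
  k_out <- diff(w@p)
  new_types <- ifelse(k_out == 0L, "silent",
                      ifelse(types == "inhibitory", "inhibitory", "excitatory"))
  synaptic_network(w, new_types, validate = FALSE)
}

#' Per-neuron degree and mean-weight summaries
#'
#' For each neuron computes the excitatory and inhibitory in-degrees
#' `k_in_plus`, `k_in_minus`, the out-degree `k_out`, and the mean synaptic
#' weights `s_in_plus` (over positive incoming links), `s_in_minus` (over
#' negative incoming links, a negative number) and `s_out` (over all
#' outgoing links). Means over an empty link set are `NA` ("undefined") and
#' are excluded from distribution summaries. Also reports the network's
#' connection probability (nonzero off-diagonal fraction) and the fraction
#' of neurons labeled inhibitory (denominator: all neurons, silent
#' included).
#'
#' @param net a [synaptic_network()].
#' @return An object of class `network_summaries`: a list with per-neuron
#'   vectors `k_in_plus`, `k_in_minus`, `k_out`, `s_in_plus`, `s_in_minus`,
#'   `s_out`, and scalars `connection_probability`, `inhibitory_fraction`,
#'   `n_edges`.
#' @export
compute_summaries <- function(net) {
  w <- net$weights
  n <- net$n_neurons
  wp <- w
  wp@x <- pmax(wp@x, 0)
  wp <- Matrix::drop0(wp)
  wm <- w
  wm@x <- pmin(wm@x, 0)
  wm <- Matrix::drop0(wm)

  k_in_plus <- count_row_nnz(wp, n)
  k_in_minus <- count_row_nnz(wm, n)
  k_out <- diff(w@p)
  s_in_plus <- ifelse(k_in_plus > 0, Matrix::rowSums(wp) / k_in_plus, NA_real_)
  s_in_minus <- ifelse(k_in_minus > 0, Matrix::rowSums(wm) / k_in_minus, NA_real_)
  s_out <- ifelse(k_out > 0, Matrix::colSums(w) / k_out, NA_real_)

  n_edges <- length(w@x)
  structure(list(
    k_in_plus = as.integer(k_in_plus),
    k_in_minus = as.integer(k_in_minus),
    k_out = as.integer(k_out),
    s_in_plus = as.numeric(s_in_plus),
    s_in_minus = as.numeric(s_in_minus),
    s_out = as.numeric(s_out),
    n_edges = n_edges,
    connection_probability = if (n > 1) n_edges / (n * (n - 1)) else NA_real_,
    inhibitory_fraction = if (n > 0) mean(net$neuron_type == "inhibitory") else NA_real_
  ), class = "network_summaries")
}

count_row_nnz <- function(w, n) {
  if (length(w@i) == 0L) return(integer(n))
  tabulate(w@i + 1L, nbins = n)
}

#' @export
print.network_summaries <- function(x, ...) {
  cat(sprintf("<network_summaries> %d edges, connection probability %.4g%%\n",
              x$n_edges, 100 * x$connection_probability))
  cat(sprintf("  inhibitory fraction %.3f\n", x$inhibitory_fraction))
  so <- abs(x$s_out[!is.na(x$s_out)])
  if (length(so) > 2)
    cat(sprintf("  |s_out|: mean %.4g, sd %.4g, skewness %.3g\n",
                mean(so), stats::sd(so), sample_skewness(so)))
  invisible(x)
}
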
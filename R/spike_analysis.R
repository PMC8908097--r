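#' Per-neuron firing rates
#'
#' The firing rate of a neuron is its total spike count over the recording
#' window divided by the window length, reported in spikes per second.
#' Neurons with no spikes are included with rate zero, so that
#' `sum(rate) * T` reproduces the total spike count exactly.
#'
#' @param spikes a [spike_train_set()].
#' @return An object of class `rate_report`: list with the per-neuron
#'   vector `rate`, `network_mean_rate`, `total_time` (ms), `n_neurons`,
#'   and a `summary` list (mean, median, sd, skewness over neurons).
#' @export
firing_rates <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  n <- attr(spikes, "n_neurons")
  T_ms <- attr(spikes, "total_time")
  if (is.null(T_ms) || T_ms <= 0) stopf("total_time must be positive")
  counts <- tabulate(spikes$neuron, nbins = n)
  rate <- counts / (T_ms / 1000)
  structure(list(rate = rate,
                 network_mean_rate = mean(rate),
                 total_time = T_ms, n_neurons = n,
                 summary = list(mean = mean(rate), median = stats::median(rate),
                                sd = stats::sd(rate), skewness = sample_skewness(rate))),
            class = "rate_report")
}

#' @importFrom stats median
#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("<rate_report> %d neurons over %.4g s: mean %.4g, median %.4g, sd %.4g spikes/s (skewness %.3g)\n",
              x$n_neurons, x$total_time / 1000, x$summary$mean, x$summary$median,
              x$summary$sd, x$summary$skewness))
  invisible(x)
}

#' Per-neuron firing-rate changes between two runs
#'
#' Computes `delta = modified - baseline` per neuron and classifies each
#' neuron as increased (`delta > epsilon`), decreased (`delta < -epsilon`)
#' or unchanged (`|delta| <= epsilon`). Also reports the relative change of
#' the network-average rate,
#' `(mean(modified) - mean(baseline)) / mean(baseline)`, and the skewness
#' of the delta distribution (a symmetric, zero-centered delta distribution
#' means no net change of the whole network's activity).
#'
#' @param baseline,modified [firing_rates()] reports over the same neurons
#'   and window.
#' @param epsilon tolerance in spikes/s below which a change counts as
#'   unchanged; defaults to one spike over the window, `1000 / total_time`,
#'   the smallest resolvable rate difference.
#' @return An object of class `response_report`: list with `delta`,
#'   `epsilon`, `counts` and `fractions` over the three classes,
#'   `network_rate_ratio`, and `delta_skewness`.
#' @export
rate_change <- function(baseline, modified, epsilon = NULL) {
  stopifnot(inherits(baseline, "rate_report"), inherits(modified, "rate_report"))
  if (baseline$n_neurons != modified$n_neurons)
    stopf("reports cover different neuron counts")
  if (is.null(epsilon)) epsilon <- 1000 / baseline$total_time
  delta <- modified$rate - baseline$rate
  cls <- ifelse(abs(delta) <= epsilon, "unchanged",
                ifelse(delta > 0, "increased", "decreased"))
  counts <- c(increased = sum(cls == "increased"),
              decreased = sum(cls == "decreased"),
              unchanged = sum(cls == "unchanged"))
  structure(list(delta = delta, epsilon = epsilon, class = cls,
                 counts = counts, fractions = counts / length(delta),
                 network_rate_ratio =
                   (modified$network_mean_rate - baseline$network_mean_rate) /
                   baseline$network_mean_rate,
                 delta_skewness = sample_skewness(delta)),
            class = "response_report")
}

#' @export
print.response_report <- function(x, ...) {
  cat(sprintf("<response_report> increased %d / decreased %d / unchanged %d (eps = %.3g spikes/s)\n",
              x$counts["increased"], x$counts["decreased"], x$counts["unchanged"],
              x$epsilon))
  cat(sprintf("  network rate ratio %.4g, delta skewness %.3g\n",
              x$network_rate_ratio, x$delta_skewness))
  invisible(x)
}

#' Pooled log inter-spike intervals
#'
#' Computes consecutive-spike intervals separately within each neuron's
#' spike train, pools them across neurons, and takes the natural logarithm.
#' Neurons with fewer than two spikes contribute no intervals. The pooled
#' ln(ISI) distribution is the network-level burst diagnostic: bursting
#' networks show one peak at intervals of order milliseconds (within-burst)
#' and another around a tenth of a second (between bursts).
#'
#' @param spikes a [spike_train_set()] in which at least one neuron has two
#'   or more spikes.
#' @param breaks histogram bin specification passed to [graphics::hist()]
#'   semantics via [base::cut()]-style equal-width bins; either a bin count
#'   (default 60) or a vector of bin edges over ln(ISI in ms).
#' @return An object of class `isi_report`: list with `log_isi` (pooled
#'   natural-log intervals, ms units inside the log), `n_isi`, and a
#'   `histogram` data frame with `bin_left`, `bin_right`, `count`.
#' @export
pooled_log_isi <- function(spikes, breaks = 60) {
  stopifnot(inherits(spikes, "spike_train_set"))
  isi <- unlist(lapply(split(spikes$time, spikes$neuron), function(tt) {
    if (length(tt) < 2) numeric(0) else diff(sort(tt))
  }), use.names = FALSE)
  if (!length(isi)) stopf("no neuron has two or more spikes; ISIs undefined")
  if (any(isi <= 0)) stopf("non-positive inter-spike interval encountered")
  log_isi <- log(isi)
  if (length(breaks) == 1L) {
    rng <- range(log_isi)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = breaks + 1L)
  } else edges <- sort(breaks)
  counts <- tabulate(findInterval(log_isi, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = length(edges) - 1L)
  structure(list(log_isi = log_isi, n_isi = length(log_isi),
                 histogram = data.frame(bin_left = edges[-length(edges)],
                                        bin_right = edges[-1], count = counts)),
            class = "isi_report")
}

# Relative prominence of each local maximum of a density curve y (on a
# uniform grid): height minus the highest saddle separating it from any
# higher maximum, divided by the global maximum.
peak_prominences <- function(y) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) is_max <- c(1L, is_max)
  if (y[n] > y[n - 1]) is_max <- c(is_max, n)
  if (!length(is_max)) is_max <- which.max(y)
  prom <- vapply(is_max, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    right <- if (p < n) y[(p + 1):n] else numeric(0)
    key <- -Inf
    higher_left <- which(left > h)
    if (length(higher_left)) key <- max(key, min(y[(max(higher_left) + 1):p]))
    higher_right <- which(right > h)
    if (length(higher_right)) key <- max(key, min(y[p:(p + min(higher_right) - 1)]))
    if (!is.finite(key)) h else h - key
  }, numeric(1))
  list(index = is_max, prominence = prom / max(y))
}

#' Classify the modality of a pooled ln(ISI) distribution
#'
#' Estimates the density of the pooled ln(ISI) sample with a Gaussian
#' kernel (Silverman's rule-of-thumb bandwidth by default), finds its local
#' maxima, and keeps those whose relative prominence (height above the
#' deepest separating valley, as a fraction of the global density maximum)
#' exceeds the threshold. Two or more surviving peaks classify the network
#' as `"bimodal"` (bursting); one peak as `"unimodal"`. Two generating
#' modes closer than about one bandwidth merge into a single peak and are
#' reported unimodal - a resolution limit of any kernel estimate.
#'
#' Spike times produced by a fixed-step integrator are quantized to
#' multiples of the time step, so with very large ISI samples the data-led
#' Silverman bandwidth can become narrow enough to resolve the individual
#' quantization atoms of short intervals as a comb of spurious peaks. The
#' `min_bandwidth` floor (default 0.15 in ln units, about the log-spacing
#' of adjacent representable intervals near 1 ms at a 0.125 ms step)
#' merges the comb while leaving genuinely separated burst/inter-burst
#' modes - typically 2-4 ln units apart - untouched.
#'
#' @param report an `isi_report` from [pooled_log_isi()] with at least
#'   `min_isi` intervals.
#' @param bandwidth kernel bandwidth for [stats::density()]; default
#'   `"nrd0"` (Silverman).
#' @param prominence minimal relative prominence for a peak to count
#'   (default 0.05).
#' @param min_isi minimal number of intervals required (default 50); fewer
#'   is an error ("insufficient data").
#' @param min_bandwidth lower bound on the kernel bandwidth in ln(ISI)
#'   units (default 0.15); set to 0 to disable.
#' @return List with `modality` (`"unimodal"` or `"bimodal"`), `n_peaks`,
#'   `peaks_ms` (peak locations back-transformed to ms), `peaks_log`,
#'   `prominences`, `bandwidth`, and the `density` object.
#' @export
classify_modality <- function(report, bandwidth = "nrd0", prominence = 0.05,
                              min_isi = 50, min_bandwidth = 0.15) {
  stopifnot(inherits(report, "isi_report"))
  if (report$n_isi < min_isi)
    stopf("insufficient data: %d ISIs (need >= %d) for modality classification",
          report$n_isi, min_isi)
  if (is.character(bandwidth))
    bandwidth <- switch(bandwidth, nrd0 = stats::bw.nrd0(report$log_isi),
                        nrd = stats::bw.nrd(report$log_isi),
                        stopf("unknown bandwidth rule '%s'", bandwidth))
  den <- stats::density(report$log_isi, bw = max(bandwidth, min_bandwidth), n = 512)
  pk <- peak_prominences(den$y)
  keep <- pk$prominence >= prominence
  idx <- pk$index[keep][order(den$y[pk$index[keep]], decreasing = TRUE)]
  n_peaks <- length(idx)
  list(modality = if (n_peaks >= 2) "bimodal" else "unimodal",
       n_peaks = n_peaks,
       peaks_log = den$x[idx],
       peaks_ms = exp(den$x[idx]),
       prominences = sort(pk$prominence[keep], decreasing = TRUE),
       bandwidth = den$bw,
       density = den)
}

#' Burst fixture specification
#'
#' Parameters for [generate_burst_fixture()]: synthetic spike trains whose
#' ISIs come from a two-component log-normal mixture, the intra-burst
#' component at short intervals and the inter-burst component at long
#' intervals. Defaults put the modes near 5 ms and 100 ms - the two
#' timescales of burst firing in cultured networks.
#'
#' @param n_neurons number of independent trains.
#' @param duration train duration, ms.
#' @param intra_log_mean,intra_log_sd log-scale mean and sd of the
#'   intra-burst ISI component (ms).
#' @param inter_log_mean,inter_log_sd log-scale mean and sd of the
#'   inter-burst ISI component (ms).
#' @param burst_fraction mixture weight of the intra-burst component, in
#'   `[0, 1]`.
#' @param seed optional integer RNG seed.
#' @return A `burst_fixture_spec` list.
#' @export
burst_fixture_spec <- function(n_neurons = 50, duration = 10000,
                               intra_log_mean = log(5), intra_log_sd = 0.3,
                               inter_log_mean = log(100), inter_log_sd = 0.3,
                               burst_fraction = 0.7, seed = NULL) {
  if (burst_fraction < 0 || burst_fraction > 1)
    stopf("burst_fraction must be in [0, 1]")
  if (duration <= 0) stopf("duration must be positive")
  structure(list(n_neurons = as.integer(n_neurons), duration = duration,
                 intra_log_mean = intra_log_mean, intra_log_sd = intra_log_sd,
                 inter_log_mean = inter_log_mean, inter_log_sd = inter_log_sd,
                 burst_fraction = burst_fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "burst_fixture_spec")
}

#' Generate synthetic spike trains with known ISI structure
#'
#' Per neuron, draws i.i.d. ISIs from the two-component log-normal mixture
#' of the spec, accumulates them into spike times, and truncates at the
#' duration. Used as ground truth for the modality classifier.
#'
#' @param spec a [burst_fixture_spec()].
#' @return A [spike_train_set()].
#' @export
generate_burst_fixture <- function(spec) {
  stopifnot(inherits(spec, "burst_fixture_spec"))
  with_seed_if(spec$seed, {
    mean_isi <- spec$burst_fraction *
      exp(spec$intra_log_mean + spec$intra_log_sd^2 / 2) +
      (1 - spec$burst_fraction) *
      exp(spec$inter_log_mean + spec$inter_log_sd^2 / 2)
    neuron <- integer(0)
    time <- numeric(0)
    for (i in seq_len(spec$n_neurons)) {
      tt <- numeric(0)
      t_last <- 0
      while (t_last < spec$duration) {
        n_draw <- max(50L, ceiling(2 * (spec$duration - t_last) / mean_isi))
        intra <- stats::runif(n_draw) < spec$burst_fraction
        isi <- ifelse(intra,
                      stats::rlnorm(n_draw, spec$intra_log_mean, spec$intra_log_sd),
                      stats::rlnorm(n_draw, spec$inter_log_mean, spec$inter_log_sd))
        tt <- c(tt, t_last + cumsum(isi))
        t_last <- tt[length(tt)]
      }
      tt <- tt[tt <= spec$duration]
      neuron <- c(neuron, rep.int(i, length(tt)))
      time <- c(time, tt)
    }
    spike_train_set(neuron, time, spec$n_neurons, spec$duration)
  })
}
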
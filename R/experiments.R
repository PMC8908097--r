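#' Plan for a suppression-sweep experiment
#'
#' Bundles a network source, the grid of suppression (or enhancement)
#' levels, the simulation configuration and the master seed. Per-level
#' simulation seeds are derived deterministically from the master seed with
#' [derive_seed()], so adding a level never perturbs the other levels'
#' noise streams. The default grid is the study's: k = 0.25, 0.5, 1.
#'
#' @param network a [synaptic_network()], or a [long_tail_profile()] from
#'   which one is generated (seeded from the master seed).
#' @param levels numeric vector of non-negative suppression levels.
#' @param mode `"suppress"` or `"enhance"`.
#' @param sim_config a [simulation_config()].
#' @param master_seed integer master seed.
#' @param epsilon unchanged-classification tolerance in spikes/s (default:
#'   one spike over the window).
#' @param common_noise reuse the baseline's noise seed for every level
#'   (default `FALSE`: the baseline and each level use independent derived
#'   streams, as when comparing independent experiments).
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(network, levels = c(0.25, 0.5, 1),
                            mode = c("suppress", "enhance"),
                            sim_config = simulation_config(),
                            master_seed = 1L, epsilon = NULL,
                            common_noise = FALSE) {
  mode <- match.arg(mode)
  if (any(levels < 0)) stopf("suppression levels must be non-negative")
  stopifnot(inherits(network, "synaptic_network") ||
            inherits(network, "longtail_profile"))
  structure(list(network = network, levels = levels, mode = mode,
                 sim_config = sim_config, master_seed = as.integer(master_seed),
                 epsilon = epsilon, common_noise = common_noise),
            class = "experiment_plan")
}

#' Run a full suppression sweep
#'
#' Executes the experiment grid: resolve (or generate) the network, run a
#' baseline simulation (k = 0), then for each level derive the modified
#' network with [suppress_inhibition()], simulate it, and analyze every run
#' with [firing_rates()], [rate_change()] against the baseline,
#' [pooled_log_isi()] and [classify_modality()]. The returned summary table
#' has one row per level with the achieved suppression ratio, the
#' network-average rate, the relative network rate change, the fraction of
#' neurons with increased rate, and the ln(ISI) modality.
#'
#' @param plan an [experiment_plan()].
#' @param progress print one line per stage (default `FALSE`).
#' @return An object of class `suppression_sweep`: list with the resolved
#'   `network`, the `baseline` run (spikes and rate report), per-level
#'   results (`levels`, a list with spikes, reports and modality), and the
#'   `summary` data frame.
#' @export
run_suppression_sweep <- function(plan, progress = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  say <- function(...) if (progress) message(sprintf(...))

  net <- plan$network
  if (inherits(net, "longtail_profile")) {
    net$seed <- derive_seed(plan$master_seed, 0L)
    say("generating network (seed %d)", net$seed)
    net <- generate_longtailed_network(net)
  }
  sigma <- inhibitory_sigma(net)

  cfg0 <- plan$sim_config
  cfg0$seed <- derive_seed(plan$master_seed, 1L)
  say("baseline simulation (seed %d)", cfg0$seed)
  base_spikes <- simulate_network(net, cfg0)
  base_rates <- firing_rates(base_spikes)
  base_isi <- tryCatch(pooled_log_isi(base_spikes), error = function(e) NULL)
  base_modality <- if (!is.null(base_isi))
    tryCatch(classify_modality(base_isi), error = function(e) NULL) else NULL

  results <- vector("list", length(plan$levels))
  rows <- vector("list", length(plan$levels))
  for (li in seq_along(plan$levels)) {
    k <- plan$levels[li]
    say("level k = %g (%s)", k, plan$mode)
    mod_net <- if (k == 0) net else
      suppress_inhibition(net, k, mode = plan$mode, sigma = sigma)
    ratio <- suppression_ratio(net, mod_net)
    cfg <- plan$sim_config
    cfg$seed <- if (plan$common_noise) cfg0$seed else
      derive_seed(plan$master_seed, 1L + li)
    spikes <- simulate_network(mod_net, cfg)
    rates <- firing_rates(spikes)
    resp <- rate_change(base_rates, rates, epsilon = plan$epsilon)
    isi <- tryCatch(pooled_log_isi(spikes), error = function(e) NULL)
    modality <- if (!is.null(isi))
      tryCatch(classify_modality(isi), error = function(e) NULL) else NULL
    results[[li]] <- list(k = k, network = mod_net, suppression_ratio = ratio,
                          spikes = spikes, rates = rates, response = resp,
                          isi = isi, modality = modality)
    rows[[li]] <- data.frame(
      k = k, suppression_ratio = ratio,
      network_mean_rate = rates$network_mean_rate,
      network_rate_ratio = resp$network_rate_ratio,
      fraction_increased = unname(resp$fractions["increased"]),
      fraction_decreased = unname(resp$fractions["decreased"]),
      delta_skewness = resp$delta_skewness,
      modality = if (is.null(modality)) NA_character_ else modality$modality)
  }

  structure(list(network = net, sigma = sigma, plan = plan,
                 baseline = list(spikes = base_spikes, rates = base_rates,
                                 isi = base_isi, modality = base_modality),
                 levels = results,
                 summary = do.call(rbind, rows)),
            class = "suppression_sweep")
}

#' @export
print.suppression_sweep <- function(x, ...) {
  cat(sprintf("<suppression_sweep> %s, baseline mean rate %.4g spikes/s (%s)\n",
              x$plan$mode, x$baseline$rates$network_mean_rate,
              if (is.null(x$baseline$modality)) "modality n/a"
              else x$baseline$modality$modality))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write the outputs of a sweep to a directory
#'
#' Writes the resolved network, every spike file (baseline and per level),
#' per-neuron rate/response tables, ln(ISI) histograms, and the summary
#' table, all as tab-separated text with provenance headers (master seed
#' and plan fingerprint). The directory layout is flat with prefixed file
#' names; the summary lands in `sweep_summary.tsv`.
#'
#' @param sweep a `suppression_sweep`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- fingerprint(list(sweep$plan$master_seed, sweep$plan$levels,
                         sweep$plan$mode, sweep$plan$sim_config))
  prov <- c(master_seed = sweep$plan$master_seed, plan_fingerprint = fp)
  write_network(sweep$network, file.path(dir, "network.tsv"))
  write_spike_trains(sweep$baseline$spikes, file.path(dir, "spikes_baseline.tsv"),
                     provenance = prov)
  wr_rates <- function(rates, path) {
    df <- data.frame(neuron = seq_along(rates$rate) - 1L, rate = rates$rate)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_rates(sweep$baseline$rates, file.path(dir, "rates_baseline.tsv"))
  for (res in sweep$levels) {
    tag <- sprintf("k%s", gsub("\\.", "p", format(res$k)))
    write_spike_trains(res$spikes, file.path(dir, sprintf("spikes_%s.tsv", tag)),
                       provenance = prov)
    wr_rates(res$rates, file.path(dir, sprintf("rates_%s.tsv", tag)))
    df <- data.frame(neuron = seq_along(res$response$delta) - 1L,
                     delta_rate = res$response$delta,
                     class = res$response$class)
    utils::write.table(df, file.path(dir, sprintf("response_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$isi))
      utils::write.table(res$isi$histogram,
                         file.path(dir, sprintf("lnisi_hist_%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sweep$summary, file.path(dir, "sweep_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
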
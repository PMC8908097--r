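# Text file formats: networks as a tab-separated edge list (0-based
# indices) plus a key-value sidecar with neuron count and type labels;
# spike trains as a two-column TSV with a comment header; configurations as
# INI-style "[section] / key = value" text.

type_letters <- c(excitatory = "e", inhibitory = "i", silent = "s")

#' Write a network to an edge-list file
#'
#' Writes `path` as a tab-separated edge list with header
#' `pre<TAB>post<TAB>weight` and 0-based neuron indices, one edge per line,
#' with weights at full float precision (17 significant digits, lossless
#' round trip). A sidecar file `path.meta` records `n_neurons` and the
#' per-neuron type labels (comma-separated single letters e/i/s).
#'
#' @param net a [synaptic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  w <- net$weights
  pre <- rep.int(seq_len(net$n_neurons), diff(w@p)) - 1L
  post <- w@i
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("pre\tpost\tweight", con)
  if (length(post))
    writeLines(sprintf("%d\t%d\t%.17g", pre, post, w@x), con)
  meta <- c(sprintf("n_neurons = %d", net$n_neurons),
            sprintf("neuron_types = %s",
                    paste(type_letters[net$neuron_type], collapse = ",")))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a network from an edge-list file
#'
#' Inverse of [write_network()]; requires the `path.meta` sidecar.
#'
#' @param path edge-list file path.
#' @return A [synaptic_network()].
#' @export
read_network <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stopf("missing sidecar metadata file '%s'", meta_path)
  meta <- parse_keyvals(readLines(meta_path))
  n <- as.integer(meta$n_neurons)
  letters_ <- strsplit(meta$neuron_types, ",", fixed = TRUE)[[1]]
  if (length(letters_) != n) stopf("metadata lists %d types for %d neurons",
                                   length(letters_), n)
  types <- names(type_letters)[match(letters_, type_letters)]
  if (anyNA(types)) stopf("unknown type letter in metadata")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "numeric"))
  w <- Matrix::sparseMatrix(i = df$post + 1L, j = df$pre + 1L, x = df$weight,
                            dims = c(n, n))
  synaptic_network(w, types)
}

#' Write spike trains to a two-column file
#'
#' Tab-separated `neuron<TAB>time_ms` (0-based neuron indices), sorted by
#' time, preceded by `#`-prefixed comment lines recording the neuron count,
#' window length, and any extra provenance entries. Times are written at
#' full float precision.
#'
#' @param spikes a [spike_train_set()].
#' @param path output file path.
#' @param provenance optional named character/numeric vector of extra
#'   header entries (e.g. seed, config fingerprint).
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(spikes, path, provenance = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  hdr <- c(n_neurons = attr(spikes, "n_neurons"),
           total_time = attr(spikes, "total_time"))
  if (!is.null(provenance)) hdr <- c(hdr, provenance)
  writeLines(sprintf("# %s: %s", names(hdr), vapply(hdr, as.character, "")), con)
  writeLines("neuron\ttime_ms", con)
  if (nrow(spikes))
    writeLines(sprintf("%d\t%.17g", spikes$neuron - 1L, spikes$time), con)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#'
#' @param path spike file path.
#' @return A [spike_train_set()]; header entries beyond the dimensions are
#'   attached as attribute `"provenance"`.
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(kv$n_neurons) || is.null(kv$total_time))
    stopf("spike file header must record n_neurons and total_time")
  body <- lines[!is_hdr]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric"))
  out <- spike_train_set(df$neuron + 1L, df$time_ms,
                         as.integer(kv$n_neurons), as.numeric(kv$total_time))
  extra <- kv[setdiff(names(kv), c("n_neurons", "total_time"))]
  if (length(extra)) attr(out, "provenance") <- extra
  out
}

parse_keyvals <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln2 <- trimws(sub("#.*$", "", ln))
    if (!nzchar(ln2)) next
    m <- regmatches(ln2, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln2))[[1]]
    if (length(m) != 3) stopf("malformed key-value line: '%s'", ln)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Read an INI-style configuration file
#'
#' Sections are introduced by `[section]` lines; entries are `key = value`.
#' Blank lines and `#` comments are ignored. Values that parse as numbers
#' are converted; `true`/`false` become logicals. Malformed lines are
#' reported with their line numbers.
#'
#' @param path configuration file path.
#' @return A named list of sections, each a named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  out <- list()
  section <- "global"
  for (k in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[k]))
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stopf("malformed configuration at line %d of '%s': '%s'", k, path, lines[k])
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
              else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
              else val
    out[[section]][[m[2]]] <- parsed
  }
  out
}

#' Write an INI-style configuration file
#'
#' @param config named list of sections, each a named list of scalar
#'   values (inverse of [read_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (sec in names(config)) {
    writeLines(sprintf("[%s]", sec), con)
    entries <- config[[sec]]
    for (key in names(entries)) {
      v <- entries[[key]]
      vs <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      writeLines(sprintf("%s = %s", key, vs), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
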
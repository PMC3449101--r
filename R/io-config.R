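#' Analysis configuration
#'
#' Builds the run configuration holding every tunable parameter of the
#' analysis. Defaults are the method's standard operating values: probe
#' windows of 3--20 probes, an adaptive-threshold ladder from 80% down to 20%
#' in 10% steps, a 5% per-direction coverage target per chromosome (10%
#' overall), a 10-probe upper width for high-level calls, a 75% factor-change
#' classification threshold, and an amplitude-significance cutoff of P < 0.1.
#'
#' @param ... Named parameters overriding the defaults. Recognised keys:
#'   `window_sizes` (integer vector, each >= 2), `at_ladder` (strictly
#'   decreasing percentages in (0, 100]), `target_coverage` (fraction of a
#'   chromosome's probes to gate per direction), `highlevel_max_width`
#'   (probes; abnormal segments at most this wide are called high-level),
#'   `factor_change` (fraction scaling the classification threshold),
#'   `highlevel_amplitude_check` (logical; additionally require
#'   |segment mean| > 2 T for high-level calls), `p_cutoff`,
#'   `n_permutations`, `rng_seed`, `consensus_min_methods`,
#'   `cluster_min_at` (%), `cluster_distance`, `cluster_linkage`,
#'   `n_groups`, `report_window` (window size used for prioritisation and
#'   report plots), `genome_build`, `autosomes` (character vector of allowed
#'   chromosome labels), `fill_segment_gaps` (logical; close inter-segment
#'   gaps by nearest-segment extension instead of erroring).
#' @return A list with class `swat_config`.
#' @examples
#' cfg <- swat_config(at_ladder = c(80, 60, 40, 20))
#' cfg$target_coverage
#' @export
swat_config <- function(...) {
  cfg <- swat_config_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      rlang::abort("All arguments to `swat_config()` must be named.")
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      rlang::abort(sprintf("Unknown configuration key(s): %s",
                           paste(unknown, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

swat_config_defaults <- function() {
  list(
    window_sizes = 3:20,
    at_ladder = seq(80, 20, by = -10),
    target_coverage = 0.05,
    highlevel_max_width = 10L,
    factor_change = 0.75,
    highlevel_amplitude_check = FALSE,
    p_cutoff = 0.1,
    n_permutations = 10000L,
    rng_seed = 1L,
    consensus_min_methods = 2L,
    cluster_min_at = 40,
    cluster_distance = "euclidean",
    cluster_linkage = "ward.D2",
    n_groups = 3L,
    report_window = 3L,
    genome_build = "GRCh37",
    autosomes = as.character(1:22),
    fill_segment_gaps = FALSE
  )
}

validate_config <- function(cfg) {
  ws <- cfg$window_sizes
  if (!is.numeric(ws) || any(ws < 2) || any(ws != round(ws))) {
    rlang::abort("`window_sizes` must be integers >= 2.")
  }
  cfg$window_sizes <- sort(unique(as.integer(ws)))
  lad <- cfg$at_ladder
  if (!is.numeric(lad) || any(lad <= 0) || any(lad > 100)) {
    rlang::abort("`at_ladder` values must be percentages in (0, 100].")
  }
  if (length(lad) > 1 && any(diff(lad) >= 0)) {
    rlang::abort("`at_ladder` must be strictly decreasing.")
  }
  if (cfg$cluster_min_at <= 0 || cfg$cluster_min_at > 100) {
    rlang::abort("`cluster_min_at` must be a percentage in (0, 100].")
  }
  if (cfg$target_coverage <= 0 || cfg$target_coverage > 1) {
    rlang::abort("`target_coverage` must be a fraction in (0, 1].")
  }
  if (cfg$factor_change < 0) rlang::abort("`factor_change` must be >= 0.")
  if (cfg$p_cutoff <= 0 || cfg$p_cutoff > 1) {
    rlang::abort("`p_cutoff` must be in (0, 1].")
  }
  if (cfg$n_permutations < 100) {
    rlang::abort("`n_permutations` must be >= 100.")
  }
  if (cfg$consensus_min_methods < 2) {
    rlang::abort("`consensus_min_methods` must be >= 2.")
  }
  int_keys <- c("highlevel_max_width", "n_permutations", "rng_seed",
                "consensus_min_methods", "n_groups", "report_window")
  cfg[int_keys] <- lapply(cfg[int_keys], function(v) as.integer(v[1]))
  for (k in c("highlevel_amplitude_check", "fill_segment_gaps")) {
    cfg[[k]] <- isTRUE(cfg[[k]]) || identical(cfg[[k]], "true") ||
      identical(cfg[[k]], "TRUE")
  }
  structure(cfg, class = "swat_config")
}

#' @export
print.swat_config <- function(x, ...) {
  cat("<swat_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-26s %s\n", k, paste(format(v), collapse = ",")))
  }
  invisible(x)
}

#' Read a run configuration from a key=value text file
#'
#' Parses a plain-text configuration file with one `key=value` pair per line.
#' Blank lines and lines starting with `#` are ignored. Values may be scalars
#' or comma-separated lists; integer ranges may be written `lo:hi`. Any key
#' not present takes its default (see [swat_config()]). Unknown keys are an
#' error, so typos cannot silently fall back to defaults.
#'
#' @param path Path to the configuration file.
#' @return A `swat_config` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- swat_config_defaults()
  overrides <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!grepl("=", ln, fixed = TRUE)) {
      rlang::abort(sprintf("Configuration line %d is not key=value: '%s'", i, ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) {
      rlang::abort(sprintf("Unknown configuration key '%s' (line %d).", key, i))
    }
    overrides[[key]] <- parse_config_value(key, val, defaults[[key]])
  }
  do.call(swat_config, overrides)
}

parse_config_value <- function(key, val, default) {
  if (is.logical(default)) {
    return(tolower(val) %in% c("true", "yes", "1"))
  }
  if (is.character(default)) {
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    return(parts)
  }
  # numeric-ish: allow "3:20" ranges and comma lists
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  out <- unlist(lapply(parts, function(p) {
    if (grepl("^-?[0-9]+:-?[0-9]+$", p)) {
      rng <- as.integer(strsplit(p, ":", fixed = TRUE)[[1]])
      return(seq(rng[1], rng[2]))
    }
    v <- suppressWarnings(as.numeric(p))
    if (is.na(v)) {
      rlang::abort(sprintf("Cannot parse value '%s' for key '%s'.", p, key))
    }
    v
  }))
  out
}
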
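#' Fingerprint run configuration
#'
#' Bundles every tunable of the pipeline with its default.  `mode`
#' controls the permutation budget: "fast" keeps `n_perm = 10`, "normal"
#' raises it to 100 unless `n_perm` was set explicitly.
#'
#' @param measure similarity backend: "go" (semantic similarity from
#'   annotations) or "precomputed" (user-supplied matrix).
#' @param algorithm node-mapping algorithm: "apcluster", "greedy" or
#'   "external".
#' @param n_perm permutation cycles for the null (default 10).
#' @param tau cross-edge similarity threshold in `[0, 1]`.
#' @param w_topo topology weight of the affinity blend in `[0, 1]`.
#' @param damping affinity propagation damping in `[0.5, 1)`.
#' @param preference affinity propagation preference (number or
#'   "median").
#' @param min_sim greedy-aligner matching threshold.
#' @param alpha enrichment significance threshold.
#' @param mode "fast" or "normal".
#' @param max_iter,convergence_window affinity propagation stopping
#'   parameters.
#' @param external_cmd command template for algorithm = "external".
#' @return A named list of class `fp_config` with all values resolved.
#' @export
fp_config <- function(measure = "go", algorithm = "apcluster",
                      n_perm = NULL, tau = 0.5, w_topo = 0.5,
                      damping = 0.9, preference = "median", min_sim = 0.5,
                      alpha = 0.05, mode = "fast", max_iter = 1000L,
                      convergence_window = 50L, external_cmd = NULL) {
  if (is.null(n_perm)) n_perm <- if (identical(mode, "normal")) 100L else 10L
  cfg <- list(measure = measure, algorithm = algorithm,
              n_perm = as.integer(n_perm), tau = tau, w_topo = w_topo,
              damping = damping, preference = preference, min_sim = min_sim,
              alpha = alpha, mode = mode, max_iter = as.integer(max_iter),
              convergence_window = as.integer(convergence_window),
              external_cmd = external_cmd)
  validate_config(cfg)
  structure(cfg, class = c("fp_config", "list"))
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) config_error(sprintf("config value out of range for '%s': %s",
                                  key, what))
  }
  chk(cfg$measure %in% c("go", "precomputed"), "measure", "must be go|precomputed")
  chk(cfg$algorithm %in% c("apcluster", "greedy", "external"), "algorithm",
      "must be apcluster|greedy|external")
  chk(cfg$n_perm >= 2, "n_perm", "must be >= 2")
  chk(cfg$tau >= 0 && cfg$tau <= 1, "tau", "must be in [0, 1]")
  chk(cfg$w_topo >= 0 && cfg$w_topo <= 1, "w_topo", "must be in [0, 1]")
  chk(cfg$damping >= 0.5 && cfg$damping < 1, "damping", "must be in [0.5, 1)")
  chk(identical(cfg$preference, "median") ||
        (is.numeric(cfg$preference) && is.finite(cfg$preference)),
      "preference", "must be a finite number or 'median'")
  chk(cfg$min_sim >= 0 && cfg$min_sim <= 1, "min_sim", "must be in [0, 1]")
  chk(cfg$alpha >= 0 && cfg$alpha <= 1, "alpha", "must be in [0, 1]")
  chk(cfg$mode %in% c("fast", "normal"), "mode", "must be fast|normal")
  chk(cfg$max_iter >= 1, "max_iter", "must be >= 1")
  chk(cfg$convergence_window >= 1, "convergence_window", "must be >= 1")
  invisible(cfg)
}

config_keys <- function() {
  c("measure", "algorithm", "n_perm", "tau", "w_topo", "damping",
    "preference", "min_sim", "alpha", "mode", "max_iter",
    "convergence_window", "external_cmd")
}

numeric_config_keys <- function() {
  c("n_perm", "tau", "w_topo", "damping", "min_sim", "alpha", "max_iter",
    "convergence_window")
}

#' Resolve a run configuration from flags and an optional config file
#'
#' Precedence: command-line flags override config-file values, which
#' override the package defaults.  The config file may be JSON (a flat
#' object) or `key=value` lines.  Unknown keys and out-of-range values
#' are configuration errors.
#'
#' @param flags named list of explicitly supplied flag values.
#' @param file optional config file path.
#' @return An [fp_config()] with every default materialized.
#' @export
resolve_config <- function(flags = list(), file = NULL) {
  from_file <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) config_error(sprintf("config file not found: %s", file))
    from_file <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
      jsonlite::fromJSON(file, simplifyVector = TRUE)
    } else {
      lines <- readLines(file, warn = FALSE)
      lines <- lines[!grepl("^\\s*(#|$)", lines)]
      kv <- strsplit(lines, "=", fixed = TRUE)
      bad <- vapply(kv, length, 1L) < 2L
      if (any(bad)) config_error("config file lines must be key=value")
      stats::setNames(
        lapply(kv, function(x) trimws(paste(x[-1L], collapse = "="))),
        trimws(vapply(kv, `[[`, "", 1L)))
    }
  }
  merged <- utils::modifyList(as.list(from_file), flags[!vapply(flags, is.null, TRUE)])
  unknown <- setdiff(names(merged), config_keys())
  if (length(unknown) > 0L) {
    config_error(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  for (k in intersect(names(merged), numeric_config_keys())) {
    v <- suppressWarnings(as.numeric(merged[[k]]))
    if (is.na(v)) config_error(sprintf("config value for '%s' is not numeric", k))
    merged[[k]] <- v
  }
  if ("preference" %in% names(merged) && !identical(merged$preference, "median")) {
    v <- suppressWarnings(as.numeric(merged$preference))
    if (is.na(v)) config_error("config value for 'preference' must be numeric or 'median'")
    merged$preference <- v
  }
  do.call(fp_config, merged)
}
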
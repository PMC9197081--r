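config_defaults <- list(
  b = 1, c = 0.2, u = NULL, v = NULL,
  beta = 100, eps = 1e-6, scheme = "uniform", alpha = 0,
  active_search = FALSE, search_cap = 1000,
  steps = 1e6, reps = 10, seed = 1,
  space1 = "M", space2 = "U", spaces = "M,R,U",
  t = 10, n = 1e5, bin = 0.02,
  c_min = 0.05, c_max = 0.95, step = 0.05,
  nu = 5, nv = 5, t_end = 1e4, x0 = NULL, out = "results"
)

#' Load a run configuration
#'
#' Reads a flat key-value YAML file and fills in defaults (`b = 1`,
#' `eps = 1e-6`, `scheme = "uniform"`, `alpha = 0`, ...). Unknown keys and
#' out-of-range values are rejected with the offending key named. Values
#' supplied in `overrides` (e.g. parsed command-line flags) take precedence
#' over file values.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list of values overriding the file.
#' @return A named list with all configuration fields resolved.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults
  file_vals <- if (!is.null(path)) {
    stopifnot(file.exists(path))
    yaml::read_yaml(path) %||% list()
  } else list()
  for (vals in list(file_vals, overrides)) {
    if (length(vals) == 0) next
    unknown <- setdiff(names(vals), names(config_defaults))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- modifyList(cfg, vals)
  }
  check_range <- function(key, ok) {
    if (!ok) stop("config value out of range: `", key, "`", call. = FALSE)
  }
  check_range("beta", cfg$beta >= 0)
  check_range("eps", cfg$eps >= 0 && cfg$eps < 0.5)
  check_range("alpha", cfg$alpha >= 0 && cfg$alpha <= 1)
  check_range("steps", cfg$steps >= 1)
  check_range("reps", cfg$reps >= 1)
  check_range("bin", cfg$bin > 0 && cfg$bin <= 1)
  check_range("scheme", cfg$scheme %in% c(scheme_levels, "avg4", "extreme4"))
  if (cfg$scheme == "avg4") cfg$scheme <- "same_complexity_avg"
  if (cfg$scheme == "extreme4") cfg$scheme <- "same_complexity_extreme"
  cfg
}

round_numeric <- function(df, digits = 3) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Write tournament outputs to a directory
#'
#' Writes the pairwise-average table and the measures table as CSVs (three
#' decimals, matching common table precision), a JSON twin with full
#' precision, and the resolved configuration alongside, so a run can be
#' reproduced exactly from its output directory.
#'
#' @param results A named list of `memdyn_tournament` objects (names become
#'   file stems), or a single tournament.
#' @param outdir Output directory (created if missing).
#' @param config Optional resolved configuration list to serialize next to
#'   the tables.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(results, outdir, config = NULL) {
  if (inherits(results, "memdyn_tournament")) results <- list(tournament = results)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    tr <- results[[nm]]
    pairs <- tidy(tr)
    # flag the winner of each off-diagonal pairing
    pairs$winner <- FALSE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$space[r]; j <- pairs$opponent[r]
      if (i != j) {
        pairs$winner[r] <- tr$pair_payoffs[i, j] >= tr$pair_payoffs[j, i]
      }
    }
    ms <- measures(tr)
    rk <- attr(ms, "ranking")
    ms$ranking_combined <- rk[["combined"]]
    p1 <- file.path(outdir, paste0(nm, "_pairs.csv"))
    p2 <- file.path(outdir, paste0(nm, "_measures.csv"))
    p3 <- file.path(outdir, paste0(nm, ".json"))
    utils::write.csv(round_numeric(pairs), p1, row.names = FALSE)
    utils::write.csv(round_numeric(ms), p2, row.names = FALSE)
    jsonlite::write_json(
      list(spaces = tr$spaces, A = tr$pair_payoffs,
           pair_coop = tr$pair_coop, se = tr$se,
           params = tr$params[setdiff(names(tr$params), "g")],
           game = unclass(tr$params$g)),
      p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p1, p2, p3)
  }
  if (!is.null(config)) {
    pc <- file.path(outdir, "config.yaml")
    yaml::write_yaml(config, pc)
    paths <- c(paths, pc)
  }
  invisible(paths)
}

#' Read a supergame matrix from a JSON file
#'
#' Reads `{"spaces": [...], "A": [[...], ...]}` so printed matrices can be
#' fed directly to the replicator-dynamics tools.
#'
#' @param path JSON file path.
#' @return An `memdyn_supergame`.
#' @export
read_supergame <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(!is.null(obj$A))
  supergame_matrix(obj$A, obj$spaces %||% NULL)
}
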
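#' Read a per-test summary-statistic table
#'
#' Reads a tab-separated file with header columns `test_id`, `stat`,
#' `stat_type` (`"z"` or `"chisq1"`) and `covariate`. Chi-square statistics
#' are converted to z-values on load via [z_transform()] and kept in the `w`
#' column. Row order is preserved; malformed rows are reported with their
#' line numbers.
#'
#' @param path Path to a TSV file.
#' @return A [stat_table()].
#' @export
read_stats_table <- function(path) {
  raw <- readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE)
  if (nrow(raw) == 0L) stop_invalid_input(sprintf("empty stats table: %s", path))
  required <- c("test_id", "stat", "stat_type", "covariate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop_invalid_input(sprintf("missing column(s) in %s: %s", path,
                               paste(missing_cols, collapse = ", ")))
  }
  stat <- suppressWarnings(as.numeric(raw$stat))
  covariate <- suppressWarnings(as.numeric(raw$covariate))
  bad <- which(!is.finite(stat) | !is.finite(covariate) |
                 !raw$stat_type %in% c("z", "chisq1") |
                 (raw$stat_type == "chisq1" & stat < 0))
  if (length(bad) > 0L) {
    # +1 for the header line
    stop_invalid_input(sprintf(
      "malformed row(s) in %s at line(s): %s", path,
      paste(utils::head(bad + 1L, 10L), collapse = ", ")))
  }
  is_chi <- raw$stat_type == "chisq1"
  z <- stat
  w <- rep(NA_real_, nrow(raw))
  if (any(is_chi)) {
    z[is_chi] <- z_transform(stat[is_chi])
    w[is_chi] <- stat[is_chi]
  }
  out <- stat_table(z = z, x = covariate, test_id = raw$test_id)
  if (any(is_chi)) out$w <- w
  out
}

#' Write LFDR estimates to a TSV file
#'
#' Writes one row per test with a `significant` flag (`lfdr <
#' lfdr_threshold`) and a commented metadata header recording the package
#' version and the run configuration.
#'
#' @param estimates A tibble of LFDR estimates as returned by [lfdr_crc()],
#'   [lfdr_arc()] or [lfdr_mle()] (must be nonempty and contain `test_id` and
#'   `lfdr`).
#' @param path Output path.
#' @param lfdr_threshold Discovery threshold in (0, 1); default 0.2.
#' @param config Optional configuration object echoed into the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path, lfdr_threshold = 0.2,
                          config = NULL) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    stop_invalid_input("`estimates` must be nonempty; no file written.")
  }
  if (!all(c("test_id", "lfdr") %in% names(estimates))) {
    stop_invalid_input("`estimates` must contain `test_id` and `lfdr` columns.")
  }
  if (lfdr_threshold <= 0 || lfdr_threshold >= 1) {
    stop_invalid_input("`lfdr_threshold` must lie in (0, 1).")
  }
  out <- tibble::as_tibble(estimates)
  out$significant <- out$lfdr < lfdr_threshold
  header <- c(
    sprintf("# arclfdr %s", as.character(utils::packageVersion("arclfdr"))),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("# lfdr_threshold: %g", lfdr_threshold)
  )
  if (!is.null(config)) {
    cfg <- unlist(config[vapply(config, function(v)
      is.atomic(v) && length(v) == 1L, logical(1))])
    if (length(cfg) > 0L) {
      header <- c(header, sprintf("# %s: %s", names(cfg), as.character(cfg)))
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  # full precision so a read-back round trip is lossless
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a plain key-value scenario file
#'
#' Parses `key = value` lines (one per line, `#` comments allowed) into a
#' [sim_config()] plus the comparison settings. Recognized keys: `N`, `x0`,
#' `pi01`, `pi02`, `delta`, `seed`, `delta0`, `B`, `n_focal`, `grid_points`.
#'
#' @param path Path to the scenario file.
#' @return A list with elements `config` (a [sim_config()]), `delta0`, `B`,
#'   `n_focal`, `grid_points`.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop_invalid_input(sprintf("malformed scenario line(s): %s",
                               paste(lines[bad], collapse = "; ")))
  }
  vals <- stats::setNames(
    suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L))),
    vapply(kv, `[`, "", 1L))
  if (anyNA(vals)) stop_invalid_input("non-numeric scenario value(s).")
  get_or <- function(key, default) if (key %in% names(vals)) unname(vals[key]) else default
  list(
    config = sim_config(
      N = get_or("N", 30000),
      prior = step_prior(get_or("x0", 0.2), get_or("pi01", 0.6),
                         get_or("pi02", 0.95)),
      delta = get_or("delta", 4),
      seed = get_or("seed", 1)
    ),
    delta0 = get_or("delta0", 0.01),
    B = as.integer(get_or("B", 100)),
    n_focal = as.integer(get_or("n_focal", 50)),
    grid_points = as.integer(get_or("grid_points", 10))
  )
}
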
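fmt_num <- function(x) {
  # >= 12 significant digits so downstream metric recomputation is stable
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

trajectory_header <- c("t_min", "IAN_uM", "Ant_uM", "IAA_uM",
                       "TIR1IAA_uM", "TIR1Ant_uM")

#' Read and write trajectory CSV files
#'
#' Column layout `t_min,IAN_uM,Ant_uM,IAA_uM,TIR1IAA_uM,TIR1Ant_uM`, values
#' at 15 significant digits.
#'
#' @param traj An `i3g_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `i3g_trajectory` tibble (baseline taken
#'   from the t = 0 row; `params`/`scenario` attributes are not stored in
#'   the CSV).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  cols <- c("time", state_vars)
  stopifnot(all(cols %in% names(traj)))
  lines <- c(
    paste(trajectory_header, collapse = ","),
    do.call(paste, c(lapply(cols, function(cn) fmt_num(traj[[cn]])),
                     sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(identical(names(df), trajectory_header))
  names(df) <- c("time", state_vars)
  base_row <- df[df$time == 0, ]
  baseline <- if (nrow(base_row) >= 1L) {
    as_state(unlist(base_row[1L, state_vars]))
  } else NULL
  new_trajectory(df, params = NULL, scenario = NULL, baseline = baseline)
}

#' Write response metrics as flat JSON
#'
#' @param metrics An `i3g_metrics` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "i3g_metrics"))
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Export a sweep as long-format CSV plus a JSON manifest
#'
#' Writes one CSV row per grid cell per metric (`cell` columns keep the
#' axis values) and a manifest naming the scenario, the grids and the
#' package version.
#'
#' @param sweep An `i3g_sweep`.
#' @param csv_path,manifest_path Output paths (manifest optional).
#' @return `csv_path`, invisibly.
#' @export
write_sweep <- function(sweep, csv_path, manifest_path = NULL) {
  stopifnot(inherits(sweep, "i3g_sweep"))
  axes <- attr(sweep, "axes")
  df <- as_tibble(sweep)
  metric_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], axes)
  long <- tidyr::pivot_longer(df, dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  long$value <- fmt_num(long$value)
  utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(manifest_path)) {
    sc <- attr(sweep, "scenario")
    manifest <- list(
      scenario = if (is.null(sc)) NULL else unclass(sc),
      axes = as.list(axes),
      grid = lapply(setNames(axes, axes), function(a) unique(df[[a]])),
      n_cells = nrow(df),
      package = "i3gauxin",
      version = as.character(utils::packageVersion("i3gauxin"))
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}
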
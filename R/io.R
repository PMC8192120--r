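#' Load and validate a run configuration
#'
#' Reads a structured YAML configuration describing a simulation run:
#' which built-in model (or scheme fixture file) to use, the condition
#' preset, the protocol block, the output directory and the seed. Unknown
#' keys are rejected by name; missing keys are filled with documented
#' defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A named list of class `run_config` with elements `model`,
#'   `substrate`, `preset`, `protocol` (list with `type` and
#'   type-specific fields), `out_dir`, `seed`, `verbose`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("model", "substrate", "preset", "protocol", "out_dir",
             "seed", "verbose")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(default_config(), raw)
  if (!cfg$model %in% c("DAT", "NET", "SERT") && !file.exists(cfg$model)) {
    stop("unresolvable model reference: ", cfg$model)
  }
  if (!cfg$preset %in% condition_preset_names()) {
    stop("unknown condition preset: ", cfg$preset)
  }
  known_proto <- c("iv", "cr", "two_pulse", "simulate")
  if (!cfg$protocol$type %in% known_proto) {
    stop("unknown protocol type: ", cfg$protocol$type)
  }
  structure(cfg, class = "run_config")
}

default_config <- function() {
  list(model = "DAT", substrate = "APP", preset = "physiological",
       protocol = list(type = "iv",
                       voltages_mV = seq(-90, 30, by = 20),
                       concentration_uM = 30),
       out_dir = ".", seed = 1L, verbose = FALSE)
}

#' @rdname load_config
#' @param cfg A `run_config` list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Write / read two-channel recordings as delimited text
#'
#' Recordings are exchanged as tab-separated tables with header columns
#' `time_s`, `current_A`, `fluorescence_AU` (12 significant digits, so
#' round-trips are lossless to ~1e-12 relative). Additional columns are
#' preserved as annotation columns. Reading rejects tables with missing
#' required columns or non-monotone time.
#'
#' @param recording A tibble with `time`, `current`, `fluorescence`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a tibble of class `recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(all(c("time", "current", "fluorescence") %in% names(recording)))
  df <- as.data.frame(recording)
  names(df)[match(c("time", "current", "fluorescence"), names(df))] <-
    c("time_s", "current_A", "fluorescence_AU")
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 14, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("time_s", "current_A", "fluorescence_AU")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("recording table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("non-monotone time column in ", path)
  }
  extra <- setdiff(names(df), need)
  out <- tibble::tibble(time = df$time_s, current = df$current_A,
                        fluorescence = df$fluorescence_AU)
  for (col in extra) out[[col]] <- df[[col]]
  class(out) <- c("recording", class(out))
  out
}

#' Export / import a trace as delimited text
#'
#' Generic single-channel trace exchange (time, value, component tag),
#' used for current and fluorescence traces.
#'
#' @param trace Tibble with a `time` column and one value column.
#' @param path File path.
#' @param value Name of the value column.
#' @export
write_trace <- function(trace, path, value = setdiff(names(trace),
                                                     c("time", "component"))[1]) {
  df <- data.frame(time_s = trace$time,
                   value = formatC(trace[[value]], digits = 14, format = "g"))
  names(df)[2] <- value
  if ("component" %in% names(trace)) df$component <- trace$component
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an occupancy trajectory as a delimited table
#'
#' Column 1 is time in seconds; one column per state.
#'
#' @param traj An `occupancy_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(tibble::as_tibble(traj))
  names(df)[1] <- "time_s"
  df[] <- lapply(df, function(x) formatC(x, digits = 14, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
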
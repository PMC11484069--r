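# Readers/writers for the plain-text artifacts: infusion schedules and
# measurement tables as CSV, parameter registries as YAML or JSON,
# simulation trajectories as CSV. All round-trip numerically.

#' Read/write an infusion schedule CSV
#'
#' Columns `time_h, rate_mL_per_h, fluid_type`; piecewise-constant,
#' left-closed intervals, strictly increasing times.
#'
#' @param path file path.
#' @return a [infusion_schedule()].
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "rate_mL_per_h")
  if (!all(need %in% names(d))) {
    stop("schedule CSV must have columns time_h, rate_mL_per_h")
  }
  bad <- which(diff(d$time_h) <= 0)
  if (length(bad)) stop("non-increasing time at row ", bad[1] + 1)
  infusion_schedule(d$time_h, d$rate_mL_per_h,
                    if ("fluid_type" %in% names(d)) d$fluid_type else "LR")
}

#' @rdname read_schedule_csv
#' @param schedule a [infusion_schedule()].
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Read/write a measurement CSV
#'
#' Columns `time_h, variable, value`, times non-decreasing within variable.
#'
#' @param path file path.
#' @return a [measurement_set()].
#' @export
read_measurements_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "variable", "value")
  if (!all(need %in% names(d))) {
    stop("measurement CSV must have columns time_h, variable, value")
  }
  for (v in unique(d$variable)) {
    tv <- d$time_h[d$variable == v]
    bad <- which(diff(tv) < 0)
    if (length(bad)) {
      stop("decreasing time for variable '", v, "' at its row ", bad[1] + 1)
    }
  }
  measurement_set(d)
}

#' @rdname read_measurements_csv
#' @param measurements a [measurement_set()].
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(as.data.frame(measurements), path, row.names = FALSE)
  invisible(path)
}

#' Read/write a parameter registry (YAML or JSON)
#'
#' Serialized as a list of `{name, value, lower, upper, class, units,
#' module}` records; values, bounds and class tags round-trip exactly.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return registry tibble.
#' @export
read_params_yaml <- function(path) {
  recs <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    do.call(rbind.data.frame, lapply(yaml::read_yaml(path)$parameters, function(r) {
      r$value <- if (is.null(r$value)) NA_real_ else r$value
      r[c("name", "value", "lower", "upper", "class", "units", "module")]
    }))
  }
  out <- tibble::as_tibble(recs)
  as_num <- function(x) {
    x[x %in% c("NA", "")] <- NA
    as.numeric(x)
  }
  out$value <- as_num(out$value)
  out$lower <- as_num(out$lower)
  out$upper <- as_num(out$upper)
  class(out) <- c("burn_params", class(out))
  out
}

#' @rdname read_params_yaml
#' @param params registry tibble.
#' @export
write_params_yaml <- function(params, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(params), path, auto_unbox = TRUE,
                         digits = I(17), na = "null")
  } else {
    num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
    recs <- lapply(seq_len(nrow(params)), function(i) {
      r <- as.list(params[i, ])
      # numbers as 17-significant-digit strings: exact double round-trip
      r$value <- num(r$value); r$lower <- num(r$lower); r$upper <- num(r$upper)
      r
    })
    yaml::write_yaml(list(parameters = recs), path)
  }
  invisible(path)
}

#' Write a simulation trajectory CSV
#'
#' One row per output time, columns `time_h` then every state and algebraic
#' output of the trajectory tibble.
#'
#' @param sim a `burn_sim`; `path` file path.
#' @return the path, invisibly.
#' @export
write_result_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(sim$trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
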
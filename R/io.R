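# INI-style configuration: "key = value" lines grouped under [section]
# headers; '#' starts a comment. Values are parsed as numbers or
# logicals where possible.

parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- trimws(substr(ln, 2, nchar(ln) - 1))
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) {
      num
    } else if (toupper(val) %in% c("TRUE", "FALSE", "YES", "NO")) {
      toupper(val) %in% c("TRUE", "YES")
    } else {
      val
    }
    if (is.null(out[[section]])) out[[section]] <- list()
    out[[section]][[key]] <- parsed
  }
  out
}

#' Read a model/scenario configuration file
#'
#' Parses a structured text configuration ("key = value" lines under
#' \code{[section]} headers) and returns validated model parameters and,
#' if present, a scenario. Recognized sections: \code{[model]} (any
#' \code{\link{ks_params}} argument), \code{[scenario]} (any
#' \code{\link{ks_scenario}} option; \code{n} and \code{extent} may be
#' comma-separated pairs), \code{[controller]} (any
#' \code{\link{step_controller}} argument), \code{[slowdown]}
#' (\code{tau}). Unknown keys are rejected with an itemized error. An
#' empty file yields the full default calibration.
#'
#' @param path path to the configuration file.
#' @return List with \code{params} (\code{\link{ks_params}}),
#'   \code{scenario} (\code{\link{ks_scenario}} or \code{NULL}),
#'   \code{controller} (\code{\link{step_controller}} or \code{NULL}),
#'   \code{schedule} (\code{\link{slowdown_schedule}} or \code{NULL}).
#' @export
read_ks_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ini <- parse_ini(path)
  known_sections <- c("global", "model", "scenario", "controller",
                      "slowdown")
  bad <- setdiff(names(ini), known_sections)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  model_args <- as.list(c(ini$global, ini$model))
  ok_model <- names(formals(ks_params))
  bad <- setdiff(names(model_args), ok_model)
  if (length(bad))
    stop("unknown model parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- do.call(ks_params, model_args)

  num_pair <- function(x) {
    if (is.character(x)) as.numeric(trimws(strsplit(x, ",")[[1]])) else x
  }
  scenario <- NULL
  if (!is.null(ini$scenario)) {
    sc <- ini$scenario
    for (k in intersect(c("n", "extent", "snapshot_times"), names(sc)))
      sc[[k]] <- num_pair(sc[[k]])
    preset <- if (!is.null(sc$preset)) sc$preset else "custom"
    sc$preset <- NULL
    seed <- if (!is.null(sc$seed)) sc$seed else 1L
    sc$seed <- NULL
    scenario <- do.call(ks_scenario,
                        c(list(preset = preset, seed = seed), sc))
  }
  controller <- NULL
  if (!is.null(ini$controller)) {
    ok <- names(formals(step_controller))
    bad <- setdiff(names(ini$controller), ok)
    if (length(bad))
      stop("unknown controller option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    controller <- do.call(step_controller, ini$controller)
  }
  schedule <- NULL
  if (!is.null(ini$slowdown))
    schedule <- do.call(slowdown_schedule, ini$slowdown)
  if (!is.null(scenario)) {
    scenario$params <- params
    if (!is.null(controller)) scenario$controller <- controller
    if (!is.null(schedule) && schedule$enabled) scenario$tau <- schedule$tau
  }
  list(params = params, scenario = scenario, controller = controller,
       schedule = schedule)
}

# Stable hash of the parameter set for snapshot provenance (djb2 over
# the deparsed parameter values; not cryptographic).
params_hash <- function(params) {
  s <- paste(deparse(unclass(params)), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write a field-state snapshot
#'
#' Serializes a \code{\link{field_state}} with its grid geometry and a
#' parameter hash to an RDS file (the package's native snapshot format;
#' round trips are bit-exact).
#'
#' @param state a \code{\link{field_state}}.
#' @param path output file path.
#' @param grid the \code{\link{periodic_grid}} the state lives on.
#' @param params the \code{\link{ks_params}} in force (hashed for
#'   provenance checks on read).
#' @return \code{path}, invisibly.
#' @export
write_snapshot <- function(state, path, grid, params) {
  obj <- list(t = state$t, rho = state$rho, U_a = state$U_a,
              U_r = state$U_r, dim = grid$dim, n = grid$n,
              extent = grid$extent, params_hash = params_hash(params),
              format = "wormKS-snapshot-1")
  saveRDS(obj, path)
  invisible(path)
}

#' Read a field-state snapshot
#'
#' @param path file written by \code{\link{write_snapshot}}.
#' @param params optional \code{\link{ks_params}}; when supplied, a
#'   parameter-hash mismatch with the snapshot raises a warning.
#' @return List with \code{state} (\code{\link{field_state}}) and
#'   \code{grid} (\code{\link{periodic_grid}}).
#' @export
read_snapshot <- function(path, params = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read snapshot '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!identical(obj$format, "wormKS-snapshot-1"))
    stop("not a wormKS snapshot: ", path, call. = FALSE)
  grid <- periodic_grid(obj$n, obj$extent)
  if (!is.null(params) && !identical(params_hash(params), obj$params_hash))
    warning("snapshot parameter hash does not match current parameters",
            call. = FALSE)
  state <- field_state(obj$t, obj$rho, obj$U_a, obj$U_r, grid)
  list(state = state, grid = grid)
}

#' Run manifest
#'
#' Collects everything needed to rerun a scenario bit-identically:
#' configuration snapshot, parameter hash, seed, software version,
#' timings and the output file inventory.
#'
#' @param result a \code{\link{run_scenario}} result.
#' @param files character vector of output files written for this run.
#' @param timings optional named numeric vector of per-stage wall times
#'   (s).
#' @return An object of class \code{"ks_manifest"} (a list).
#' @export
run_manifest <- function(result, files = character(0), timings = NULL) {
  structure(list(
    package = "wormKS",
    version = as.character(utils::packageVersion("wormKS")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    preset = result$scenario$preset,
    seed = result$seed,
    params_hash = params_hash(result$params),
    scenario = unclass(result$scenario)[
      !vapply(result$scenario, is.null, TRUE)],
    steps = result$steps,
    rejected = result$rejected,
    mass_drift = max(abs(result$mass / result$mass[1] - 1)),
    timings = timings,
    files = files), class = "ks_manifest")
}

#' Write a manifest as plain text
#'
#' @param manifest a \code{\link{run_manifest}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  fmt <- function(x) {
    if (is.list(x)) {
      paste(vapply(names(x),
                   function(k) paste0(k, "=", fmt(x[[k]])), ""),
            collapse = "; ")
    } else paste(format(x, digits = 15), collapse = ",")
  }
  lines <- vapply(names(manifest), function(k) {
    paste0(k, " = ", fmt(manifest[[k]]))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Scenario summary table
#'
#' Per-snapshot summary of a run: time, total mass, field extrema and
#' maximum speed; the table the command-line tools write as CSV.
#'
#' @param result a \code{\link{run_scenario}} result.
#' @return Data frame with one row per snapshot.
#' @export
result_summary <- function(result) {
  rows <- lapply(seq_along(result$snapshots), function(i) {
    st <- result$snapshots[[i]]
    v <- velocity_field(st, result$params, result$grid)
    data.frame(t = result$times[i],
               mass = result$mass[i],
               rho_min = min(st$rho), rho_max = max(st$rho),
               U_a_min = min(st$U_a), U_a_max = max(st$U_a),
               U_r_min = if (!is.null(st$U_r)) min(st$U_r) else NA,
               U_r_max = if (!is.null(st$U_r)) max(st$U_r) else NA,
               v_max = max(v$speed))
  })
  do.call(rbind, rows)
}
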
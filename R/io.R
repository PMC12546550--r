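## Plain-text I/O: YAML run configurations, tab-separated snapshot and report
## files, and a structured metadata sidecar.

.CONFIG_KEYS <- list(
  top = c("grid", "time", "parameters", "initial_conditions", "monitoring",
          "scenario"),
  grid = c("L_f", "M"),
  time = c("dt", "t_final"),
  monitoring = c("monitor_every", "snapshot_times")
)

#' Write a run configuration to a YAML file
#'
#' @param config A [run_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_run_config()]
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(
    grid = list(L_f = config$L_f, M = config$M),
    time = list(dt = config$dt, t_final = config$t_final),
    parameters = unclass(config$params)[setdiff(names(config$params), "L_f")],
    initial_conditions = unclass(config$ics),
    monitoring = list(monitor_every = config$monitor_every,
                      snapshot_times = as.list(config$snapshot_times)),
    scenario = config$scenario
  )
  writeLines(yaml::as.yaml(obj, precision = 15L), path)
  invisible(path)
}

.reject_unknown <- function(obj, allowed, where) {
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown)) {
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
}

#' Read a run configuration from a YAML file
#'
#' The schema is validated strictly: unknown keys anywhere are rejected, and
#' the sign constraints on parameters and initial conditions are enforced on
#' load. `read_run_config(write_run_config(config, path))` reproduces
#' `config`.
#'
#' @param path Path to a YAML file produced by [write_run_config()] (or
#'   written by hand to the same schema).
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  .reject_unknown(obj, .CONFIG_KEYS$top, "config")
  .reject_unknown(obj$grid, .CONFIG_KEYS$grid, "grid")
  .reject_unknown(obj$time, .CONFIG_KEYS$time, "time")
  .reject_unknown(obj$monitoring, .CONFIG_KEYS$monitoring, "monitoring")
  par_args <- obj$parameters
  .reject_unknown(par_args, setdiff(names(formals(model_parameters)),
                                    c("L_f", "strict")), "parameters")
  ic_args <- obj$initial_conditions
  .reject_unknown(ic_args, names(formals(initial_conditions)),
                  "initial_conditions")
  params <- do.call(model_parameters, c(par_args, list(L_f = obj$grid$L_f)))
  ics <- do.call(initial_conditions, ic_args)
  run_config(L_f = obj$grid$L_f, M = obj$grid$M,
             dt = obj$time$dt, t_final = obj$time$t_final,
             params = params, ics = ics,
             monitor_every = obj$monitoring$monitor_every,
             snapshot_times = unlist(obj$monitoring$snapshot_times),
             scenario = obj$scenario)
}

## Two-lane polynomial rolling hash over a string, reported as 16 hex digits;
## used only to fingerprint configurations in metadata files.
.config_fingerprint <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Write run snapshots and reports as plain-text files
#'
#' One tab-separated file per snapshot time with columns `x, C, P, I, F, O`
#' (full double precision, so reading a file back reproduces the state), the
#' bounds/energy series (if recorded) as `bounds.tsv`, and a `metadata.yaml`
#' recording the full configuration (every defaulted parameter spelled out
#' and flagged with its provenance), a configuration fingerprint, and package
#' and R versions.
#'
#' @param result A [run_simulation()] / [run_scenario()] result.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_snapshots <- function(result, directory) {
  if (!dir.exists(directory) && !dir.create(directory, recursive = TRUE)) {
    stop("cannot create output directory: ", directory, call. = FALSE)
  }
  grid <- result$grid
  fmt <- function(v) sprintf("%.17g", v)
  for (i in seq_along(result$states)) {
    st <- result$states[[i]]
    d <- data.frame(x = fmt(grid$x), C = fmt(st$C), P = fmt(st$P),
                    I = fmt(st$I), F = fmt(st$F), O = fmt(st$O),
                    stringsAsFactors = FALSE)
    f <- file.path(directory,
                   sprintf("snapshot_t%s.tsv", format(result$times[i])))
    write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$bounds)) {
    write.table(result$bounds, file.path(directory, "bounds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(
    scenario = if (!is.null(result$config)) result$config$scenario else "custom",
    grid = list(L_f = grid$L_f, M = grid$M, dx = grid$dx),
    dt = result$dt, step_count = result$step_count, engine = result$engine,
    snapshot_times = as.list(result$times),
    versions = list(package = as.character(packageVersion("angiomol")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  if (!is.null(result$config)) {
    ptab <- parameter_table(result$config$params)
    meta$parameters <- lapply(seq_len(nrow(ptab)), function(i) {
      list(name = ptab$parameter[i], value = ptab$value[i],
           source = ptab$source[i])
    })
    meta$initial_conditions <- unclass(result$config$ics)
    cfg_yaml <- yaml::as.yaml(list(
      grid = list(L_f = result$config$L_f, M = result$config$M),
      time = list(dt = result$config$dt, t_final = result$config$t_final),
      parameters = unclass(result$config$params),
      initial_conditions = unclass(result$config$ics)
    ), precision = 15L)
    meta$config_hash <- .config_fingerprint(cfg_yaml)
  }
  yaml::write_yaml(meta, file.path(directory, "metadata.yaml"))
  invisible(directory)
}

#' Read a snapshot file back
#'
#' @param path Path to a `snapshot_t*.tsv` written by [write_snapshots()].
#' @return A data frame with columns `x, C, P, I, F, O`.
#' @export
read_snapshot <- function(path) {
  read.table(path, header = TRUE, sep = "\t", colClasses = "numeric")
}
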
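#' Load a run configuration from YAML or JSON
#'
#' A configuration resolves to baseline parameter defaults plus any
#' overrides, an optional protocol (inline spec or named preset), solver
#' options and the week-to-model-time conversion. Unknown keys at any level
#' are rejected by name rather than silently ignored.
#'
#' Recognised top-level keys: `params`, `protocol`, `preset`, `solver`
#' (`rtol`, `atol`, `sample_dt`), `time_units_per_week`, `init`
#' (`C`, `v`), `output_dir`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields pure defaults.
#' @return A `bmg_config` list with fully resolved fields.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  resolve_config(raw)
}

resolve_config <- function(raw) {
  known <- c("params", "protocol", "preset", "solver",
             "time_units_per_week", "init", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- do.call(model_params, as.list(raw$params %||% list()))

  protocol <- NULL
  if (!is.null(raw$preset)) {
    if (!is.null(raw$protocol))
      stop("config may give either 'preset' or 'protocol', not both",
           call. = FALSE)
    protocol <- protocol_preset(raw$preset)
  } else if (!is.null(raw$protocol)) {
    pr <- raw$protocol
    pr_known <- c("variant", "phases", "threshold", "visit_interval",
                  "horizon", "off_threshold", "lead_in")
    bad <- setdiff(names(pr), pr_known)
    if (length(bad))
      stop("unknown protocol key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!is.null(pr$phases)) pr$phases <- as.data.frame(pr$phases)
    protocol <- do.call(protocol_spec, pr)
  }

  solver <- raw$solver %||% list()
  s_known <- c("rtol", "atol", "sample_dt")
  bad <- setdiff(names(solver), s_known)
  if (length(bad))
    stop("unknown solver key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  solver <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10,
                                   sample_dt = 0.25), solver)

  init <- raw$init %||% list(C = 0.1, v = 1)
  bad <- setdiff(names(init), c("C", "v"))
  if (length(bad))
    stop("unknown init key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  init <- c(C = init$C %||% 0.1, v = init$v %||% 1)
  if (init[["C"]] < 0 || init[["v"]] <= 0)
    stop("config invariant violation: init requires C >= 0 and v > 0",
         call. = FALSE)

  tupw <- raw$time_units_per_week %||% 100
  if (!is.numeric(tupw) || tupw <= 0)
    stop("config invariant violation: time_units_per_week must be positive",
         call. = FALSE)

  structure(list(params = params, protocol = protocol,
                 preset = raw$preset %||% NULL,
                 solver = solver, init = init,
                 time_units_per_week = tupw,
                 output_dir = raw$output_dir %||% "."),
            class = "bmg_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the full
#' parameter set, the protocol, solver options, initial state, conversion
#' factor and package version.
#'
#' @param config a `bmg_config`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  stopifnot(inherits(config, "bmg_config"))
  proto <- config$protocol
  manifest <- list(
    package_version = as.character(utils::packageVersion("biomarkergame")),
    params = unclass(config$params),
    protocol = if (is.null(proto)) NULL else {
      pl <- unclass(proto)
      if (!is.null(pl$phases)) pl$phases <- as.list(pl$phases)
      pl
    },
    preset = config$preset,
    solver = config$solver,
    init = as.list(config$init),
    time_units_per_week = config$time_units_per_week
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Re-create a configuration from a manifest
#'
#' @param path a manifest JSON written by [write_manifest()].
#' @return A `bmg_config` equivalent to the one that produced the manifest.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- list(params = m$params, solver = m$solver, init = m$init,
              time_units_per_week = m$time_units_per_week)
  if (!is.null(m$preset)) {
    raw$preset <- m$preset
  } else if (!is.null(m$protocol)) {
    pr <- m$protocol
    raw$protocol <- pr[!names(pr) %in% "decision_delay"]
  }
  resolve_config(raw)
}
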
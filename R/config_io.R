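# Configuration file I/O.
#
# YAML/JSON schema:
#   settings:   named map, subset of the settings in caries_parameters()
#   parameters: list of records with keys
#               name, arm, base, [low, high | rel_bounds], [dist], [scale], [source]
#   scenarios:  optional named map; each entry a list of {name, arm, value}
# CSV schema: flat table with columns name, arm, base, low, high, dist, scale
# (optional source); settings take their defaults.

.PARAM_KEYS <- c("name", "arm", "base", "low", "high", "rel_bounds",
                 "dist", "scale", "source")

#' Read a model parameter configuration
#'
#' Reads YAML (`.yaml`/`.yml`), JSON (`.json`) or flat CSV (`.csv`)
#' configurations and returns a validated [caries_parameters()] object.
#' Unknown keys are rejected; settings omitted from the file take their
#' documented defaults. A parameter record may give `rel_bounds: 0.15`
#' instead of explicit bounds, in which case `low`/`high` are computed as
#' base × (1 ∓ 0.15) at load time.
#'
#' @param path configuration file path.
#' @return a `caries_params` object; named scenario definitions, if present,
#'   are attached as `attr(x, "scenarios")`.
#' @seealso [write_parameters()], [default_config_path()]
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml", "json")) {
    raw <- if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
    .params_from_list(raw)
  } else if (ext == "csv") {
    .params_from_csv(path)
  } else {
    stop("unsupported configuration format: .", ext)
  }
}

.params_from_list <- function(raw) {
  bad <- setdiff(names(raw), c("settings", "parameters", "scenarios"))
  if (length(bad)) stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$parameters)) stop("configuration has no 'parameters' section")
  rows <- lapply(raw$parameters, function(r) {
    bad <- setdiff(names(r), .PARAM_KEYS)
    if (length(bad)) {
      stop("parameter '", r$name %||% "?", "': unknown key(s): ",
           paste(bad, collapse = ", "))
    }
    for (k in c("name", "base")) {
      if (is.null(r[[k]])) stop("parameter record missing required key '", k, "'")
    }
    if (!is.null(r$rel_bounds)) {
      if (!is.null(r$low) || !is.null(r$high)) {
        stop("parameter '", r$name, "': give either rel_bounds or low/high, not both")
      }
      r$low <- r$base * (1 - r$rel_bounds)
      r$high <- r$base * (1 + r$rel_bounds)
    }
    .param_row(r$name, r$arm %||% "shared", as.numeric(r$base),
               as.numeric(r$low %||% NA_real_), as.numeric(r$high %||% NA_real_),
               r$dist %||% "fixed", r$scale %||% .guess_scale(r$name),
               r$source %||% "")
  })
  rows <- do.call(rbind, rows)
  settings <- .default_settings()
  if (!is.null(raw$settings)) {
    bad <- setdiff(names(raw$settings), names(settings))
    if (length(bad)) stop("unknown setting(s): ", paste(bad, collapse = ", "))
    settings[names(raw$settings)] <- raw$settings
  }
  x <- validate_parameters(structure(list(params = rows, settings = settings),
                                     class = "caries_params"))
  if (!is.null(raw$scenarios)) attr(x, "scenarios") <- raw$scenarios
  x
}

.params_from_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "arm", "base", "low", "high", "dist", "scale")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("CSV configuration missing column(s): ", paste(miss, collapse = ", "))
  if (!"source" %in% names(tab)) tab$source <- ""
  tab <- tab[, .PARAM_COLS]
  tab$base <- as.numeric(tab$base)
  tab$low <- as.numeric(tab$low)
  tab$high <- as.numeric(tab$high)
  validate_parameters(structure(list(params = tab, settings = .default_settings()),
                                class = "caries_params"))
}

.guess_scale <- function(name) {
  if (startsWith(name, "cost_")) "currency"
  else if (startsWith(name, "utility_")) "utility"
  else "probability"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter configuration
#'
#' Serialises a `caries_params` object to YAML, JSON or CSV (chosen by file
#' extension). YAML/JSON round-trip the full object including settings; CSV
#' stores the parameter table only.
#'
#' @param x a `caries_params` object.
#' @param path output path ending in `.yaml`, `.yml`, `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(x, path) {
  validate_parameters(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(x$params, path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(seq_len(nrow(x$params)), function(i) {
    r <- as.list(x$params[i, ])
    if (!is.finite(r$low)) r$low <- NULL
    if (!is.finite(r$high)) r$high <- NULL
    if (identical(r$source, "")) r$source <- NULL
    r
  })
  out <- list(settings = x$settings, parameters = rows)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(out, path)
  } else if (ext == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unsupported configuration format: .", ext)
  }
  invisible(path)
}

#' Path to the shipped default configuration
#'
#' @return path of the YAML configuration installed with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_parameters.yaml", package = "cariescua",
              mustWork = TRUE)
}
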
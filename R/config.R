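# Service configuration, read from a Java-style .properties file at
# startup.  Every tunable of the other modules funnels through here:
# field schema, linkage rates and thresholds, the three generator keys
# per id-type, API keys, tentative-match policy, server port.

#' Read a properties file
#'
#' Minimal `key=value` reader: one pair per line, `#` or `!` starts a
#' comment, surrounding whitespace is trimmed, later keys override
#' earlier ones. No escape processing beyond that — configuration for
#' this service is flat ASCII.
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_properties <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#!]", lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1L, eq - 1L))
    out[[key]] <- trimws(substr(ln, eq + 1L, nchar(ln)))
  }
  out
}

#' Write a properties file
#'
#' Inverse of [read_properties()]; used by fixtures and the command
#' line tools to materialise configurations.
#'
#' @param props named list of scalar values.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_properties <- function(props, path) {
  writeLines(sprintf("%s=%s", names(props), vapply(props, as.character, "")),
             path)
  invisible(path)
}

#' Build the service configuration
#'
#' Assembles the full configuration of a patient list from a properties
#' list (as returned by [read_properties()]), filling unset keys with
#' defaults. Recognised keys:
#'
#' * `idgen.k1`, `idgen.k2`, `idgen.k3` — the three secret generator
#'   keys (30-bit integers) of the default id-type `pid`;
#'   `idgen.<type>.k1` ... for additional id-types.
#' * `idgen.id_types` — comma-separated id-type names (default `pid`).
#' * `api.keys` — comma-separated accepted API keys.
#' * `field.<name>.kind`, `field.<name>.required` — field schema.
#' * `linkage.<name>.error_rate`, `linkage.<name>.frequency`,
#'   `linkage.threshold_match`, `linkage.threshold_nonmatch`,
#'   `linkage.exchange_groups` (semicolon-separated comma pairs).
#' * `matching.on_tentative` — `create` (default) or `reject`.
#' * `callback.secret` — shared secret sent to callback URLs in the
#'   `pseudolistCallbackAuth` header (empty = header omitted).
#' * `server.port` — port for [pl_serve()].
#' * `storage.file` — SQLite database path (default in-memory).
#'
#' @param props named list, e.g. from [read_properties()]; `NULL` for
#'   all defaults.
#' @return an object of class `pl_config`.
#' @export
#' @examples
#' cfg <- pl_config(list(`idgen.k1` = 123, `api.keys` = "sesame"))
#' cfg$id_types
pl_config <- function(props = NULL) {
  props <- props %||% list()
  p <- function(key, default = NULL) {
    if (!is.null(props[[key]])) props[[key]] else default
  }

  # field schema
  schema <- default_schema()
  custom <- grep("^field\\.[^.]+\\.kind$", names(props), value = TRUE)
  if (length(custom)) {
    nms <- sub("^field\\.([^.]+)\\.kind$", "\\1", custom)
    schema <- tibble::tibble(
      name = nms,
      kind = vapply(custom, function(k) props[[k]], ""),
      required = vapply(nms, function(n)
        !identical(tolower(p(sprintf("field.%s.required", n), "true")), "false"),
        TRUE)
    )
    if (!any(schema$required)) {
      stop("at least one field must be required", call. = FALSE)
    }
  }

  # linkage parameters
  er <- list(); fr <- list()
  for (n in schema$name) {
    v <- p(sprintf("linkage.%s.error_rate", n))
    if (!is.null(v)) er[[n]] <- as.numeric(v)
    v <- p(sprintf("linkage.%s.frequency", n))
    if (!is.null(v)) fr[[n]] <- as.numeric(v)
  }
  eg <- p("linkage.exchange_groups")
  exchange_groups <- if (is.null(eg)) {
    if (all(c("first_name", "last_name") %in% schema$name)) {
      list(c("first_name", "last_name"))
    } else list()
  } else if (!nzchar(eg)) {
    list()
  } else {
    lapply(strsplit(strsplit(eg, ";", fixed = TRUE)[[1]], ",", fixed = TRUE),
           trimws)
  }
  linkage <- linkage_config(
    schema = schema, error_rate = er, frequency = fr,
    t_match = as.numeric(p("linkage.threshold_match", 0.95)),
    t_nonmatch = as.numeric(p("linkage.threshold_nonmatch", 0.60)),
    exchange_groups = exchange_groups
  )

  # id-types and their generator keys
  id_types <- trimws(strsplit(p("idgen.id_types", "pid"), ",", fixed = TRUE)[[1]])
  keys <- list()
  for (it in id_types) {
    pick <- function(part) {
      v <- if (it == id_types[1L]) {
        p(sprintf("idgen.%s", part), p(sprintf("idgen.%s.%s", it, part)))
      } else {
        p(sprintf("idgen.%s.%s", it, part))
      }
      if (is.null(v)) {
        stop(sprintf("missing generator key idgen.%s.%s", it, part),
             call. = FALSE)
      }
      as.numeric(v)
    }
    keys[[it]] <- pid_keys(pick("k1"), pick("k2"), pick("k3"))
  }

  on_tentative <- match.arg(p("matching.on_tentative", "create"),
                            c("create", "reject"))

  structure(list(
    schema = schema,
    linkage = linkage,
    id_types = id_types,
    keys = keys,
    api_keys = trimws(strsplit(p("api.keys", "sesame"), ",", fixed = TRUE)[[1]]),
    on_tentative = on_tentative,
    callback_secret = p("callback.secret", ""),
    port = as.integer(p("server.port", 8080)),
    storage_file = p("storage.file", ":memory:")
  ), class = "pl_config")
}

#' Default configuration with randomly drawn generator keys
#'
#' Convenience constructor for examples and tests: the default schema
#' and linkage parameters, one id-type `pid`, and generator keys drawn
#' from R's RNG (so `set.seed()` makes them reproducible).
#'
#' @param api_keys accepted API keys.
#' @param ... further properties passed through to [pl_config()].
#' @return a `pl_config`.
#' @export
default_config <- function(api_keys = "sesame", ...) {
  ks <- floor(stats::runif(3) * PID_COUNTER_MODULUS)
  pl_config(list(`idgen.k1` = ks[1], `idgen.k2` = ks[2], `idgen.k3` = ks[3],
                 `api.keys` = paste(api_keys, collapse = ","), ...))
}

#' @export
print.pl_config <- function(x, ...) {
  cat("<pl_config>\n")
  cat(sprintf("  id-types: %s\n", paste(x$id_types, collapse = ", ")))
  cat(sprintf("  fields: %s\n", paste(x$schema$name, collapse = ", ")))
  cat(sprintf("  tentative policy: %s\n", x$on_tentative))
  invisible(x)
}
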
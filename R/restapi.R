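# The HTTP surface of the patient list.
#
# The routing core is a pure(ish) function from a parsed request to a
# response object, so every verb-semantics and authorization property
# is testable in-process; httpuv supplies the actual socket transport
# through a thin Rook adapter.  Resources:
#
#   POST   /sessions                      create a session   (API key)
#   GET    /sessions/{sid}                inspect a session  (API key)
#   DELETE /sessions/{sid}                delete + invalidate tokens
#   POST   /sessions/{sid}/tokens         mint a token       (API key)
#   POST   /patients?tokenId=...          PID request        (addPatient token)
#   GET    /patients?tokenId=...          projected views    (readPatients token)
#   GET    /html/addPatient?tokenId=...   minimal IDAT entry form

API_KEY_HEADER <- "mainzellisteApiKey"
CALLBACK_AUTH_HEADER <- "pseudolistCallbackAuth"

#' Create a patient list application
#'
#' Bundles configuration, the patient store and the session registry
#' into one service object that [pl_handle()] routes requests against
#' and [pl_serve()] exposes over HTTP.
#'
#' @param config a [pl_config()].
#' @param store optionally an already-open [open_store()] (default: a
#'   fresh store on `config$storage_file`).
#' @param callback_sender function `(url, payload_json, secret)` used to
#'   deliver addPatient callbacks; the default POSTs the JSON with curl.
#'   Injectable so tests can observe deliveries without a network.
#' @param quiet suppress the per-request log line.
#' @return an object of class `patient_list`.
#' @export
#' @examples
#' app <- patient_list(default_config())
#' r <- pl_handle(app, "POST", "/sessions",
#'                headers = list(mainzellisteApiKey = "sesame"))
#' r$status
patient_list <- function(config, store = NULL,
                         callback_sender = curl_callback_sender,
                         quiet = FALSE) {
  app <- new.env(parent = emptyenv())
  app$config <- config
  app$store <- store %||% open_store(config)
  app$registry <- new_session_registry(config)
  app$callback_sender <- callback_sender
  app$quiet <- quiet
  class(app) <- "patient_list"
  app
}

#' @export
print.patient_list <- function(x, ...) {
  cat(sprintf("<patient_list> %d patient(s), %d session(s)\n",
              n_patients(x$store), length(ls(x$registry$sessions))))
  invisible(x)
}

# default callback transport: a plain HTTP POST, 5 s budget
curl_callback_sender <- function(url, payload_json, secret = "") {
  h <- curl::new_handle()
  hdrs <- c("Content-Type" = "application/json")
  if (nzchar(secret)) hdrs[CALLBACK_AUTH_HEADER] <- secret
  curl::handle_setheaders(h, .list = as.list(hdrs))
  curl::handle_setopt(h, post = TRUE, postfields = payload_json,
                      timeout = 5L, connecttimeout = 5L)
  res <- curl::curl_fetch_memory(url, handle = h)
  if (res$status_code >= 300) {
    stop(sprintf("callback endpoint answered %d", res$status_code), call. = FALSE)
  }
  invisible(TRUE)
}

json_body <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null")
}

pl_response <- function(status, body = NULL, content_type = "application/json",
                        headers = list()) {
  list(status = status,
       body = if (is.null(body)) "" else
         if (is.character(body)) body else as.character(json_body(body)),
       content_type = content_type,
       headers = headers)
}

api_error <- function(status, message) {
  pl_response(status, list(error = message))
}

# case-insensitive header lookup
get_header <- function(headers, name) {
  hit <- which(tolower(names(headers)) == tolower(name))
  if (length(hit)) headers[[hit[1L]]] else NULL
}

# query-string / form-urlencoded parser
parse_query <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts[nzchar(parts)]) {
    eq <- regexpr("=", p, fixed = TRUE)
    key <- if (eq < 0) p else substr(p, 1L, eq - 1L)
    val <- if (eq < 0) "" else substr(p, eq + 1L, nchar(p))
    out[[utils::URLdecode(chartr("+", " ", key))]] <-
      utils::URLdecode(chartr("+", " ", val))
  }
  out
}

# request body -> named list, by content type (JSON or form-encoded)
parse_body <- function(body, content_type) {
  if (is.null(body) || (is.character(body) && !nzchar(body)) ||
      (is.raw(body) && length(body) == 0L)) {
    return(list())
  }
  if (is.raw(body)) body <- rawToChar(body)
  ct <- tolower(content_type %||% "application/json")
  if (grepl("application/x-www-form-urlencoded", ct, fixed = TRUE)) {
    parse_query(body)
  } else {
    jsonlite::fromJSON(body, simplifyVector = FALSE)
  }
}

#' Route one request through the patient list
#'
#' The transport-independent request handler: everything the HTTP
#' server does, minus sockets. Outcomes depend only on stored resource
#' state and the request itself — there is no connection identity — so
#' any client holding a session URI or token id gets the same answer.
#'
#' @param app a [patient_list()].
#' @param method HTTP verb.
#' @param path resource path (no query string).
#' @param query named list of query parameters.
#' @param headers named list of request headers (names case-insensitive).
#' @param body request body (string or raw).
#' @param content_type body content type (JSON and form-encoded are
#'   understood).
#' @return a response list: `status`, `body` (string), `content_type`,
#'   `headers`.
#' @export
pl_handle <- function(app, method, path, query = list(), headers = list(),
                      body = NULL, content_type = "application/json") {
  res <- tryCatch(
    route_request(app, toupper(method), path, query, headers, body, content_type),
    pl_auth_error = function(e) api_error(401L, conditionMessage(e)),
    pl_not_found = function(e) api_error(404L, conditionMessage(e)),
    pl_validation_error = function(e) api_error(400L, conditionMessage(e)),
    pl_conflict = function(e) api_error(409L, conditionMessage(e)),
    error = function(e) api_error(500L, conditionMessage(e))
  )
  if (!isTRUE(app$quiet)) {
    tok <- query$tokenId
    ttype <- if (!is.null(tok) && !is.null(app$registry$tokens[[tok]])) {
      app$registry$tokens[[tok]]$type
    } else ""
    # structured request log; never IDAT values
    message(sprintf("pseudolist: %s %s -> %d %s", toupper(method), path,
                    res$status, ttype))
  }
  res
}

route_request <- function(app, method, path, query, headers, body, content_type) {
  api_key <- get_header(headers, API_KEY_HEADER)
  reg <- app$registry

  if (path == "/sessions" && method == "POST") {
    s <- create_session(reg, api_key)
    return(pl_response(201L, list(sessionId = s$session_id, uri = s$uri),
                       headers = list(Location = s$uri)))
  }
  m <- regmatches(path, regexec("^/sessions/([^/]+)$", path))[[1]]
  if (length(m) == 2L) {
    sid <- m[2L]
    if (method == "GET") {
      s <- get_session(reg, sid, api_key)
      return(pl_response(200L, list(sessionId = s$session_id, uri = s$uri)))
    }
    if (method == "DELETE") {
      delete_session(reg, sid, api_key)
      return(pl_response(204L, content_type = NULL))
    }
  }
  m <- regmatches(path, regexec("^/sessions/([^/]+)/tokens$", path))[[1]]
  if (length(m) == 2L && method == "POST") {
    payload <- parse_body(body, content_type)
    tok <- create_token(reg, m[2L], api_key, payload$type,
                        payload$data %||% list(), store = app$store)
    return(pl_response(201L,
                       list(id = tok$token_id, type = tok$type,
                            data = external_token_data(tok$data)),
                       headers = list(Location = tok$uri)))
  }
  if (path == "/patients" && method == "POST") {
    return(handle_add_patient(app, query, body, content_type))
  }
  if (path == "/patients" && method == "GET") {
    return(handle_read_patients(app, query))
  }
  if (path == "/html/addPatient" && method == "GET") {
    return(handle_entry_form(app, query))
  }
  not_found(sprintf("no resource %s %s", method, path))
}

# internal_id never leaves the service
external_token_data <- function(data) {
  if (!is.null(data$patients)) {
    data$patients <- lapply(data$patients, function(r) {
      r$internal_id <- NULL
      r
    })
  }
  data
}

handle_add_patient <- function(app, query, body, content_type) {
  grant <- authorize(app$registry, query$tokenId, "addPatient")
  idat <- parse_body(body, content_type)
  idat$tokenId <- NULL
  result <- tryCatch(add_or_match_patient(app$store, idat),
                     error = function(e) {
                       if (inherits(e, "pl_conflict")) stop(e)
                       validation_fail(conditionMessage(e))
                     })
  wanted <- grant$data$id_types %||% app$config$id_types
  ids <- result$ids[intersect(app$config$id_types, c(app$config$id_types[1L], wanted))]
  id_list <- lapply(names(ids), function(it) {
    list(idType = it, idString = ids[[it]], tentative = result$tentative)
  })

  callback_status <- NULL
  if (!is.null(grant$data$callback)) {
    payload <- json_body(list(tokenId = grant$token_id, ids = id_list))
    callback_status <- tryCatch({
      app$callback_sender(grant$data$callback, as.character(payload),
                          app$config$callback_secret)
      "success"
    }, error = function(e) {
      warning(sprintf("pseudolist: callback to %s failed: %s",
                      grant$data$callback, conditionMessage(e)), call. = FALSE)
      "failed"
    })
  }

  resp <- list(newId = result$pid, tentative = result$tentative,
               ids = id_list)
  if (!is.null(callback_status)) resp$callbackStatus <- callback_status
  if (!is.null(grant$data$redirect)) {
    loc <- gsub("{id}", result$pid, grant$data$redirect, fixed = TRUE)
    return(pl_response(303L, resp, headers = list(Location = loc)))
  }
  pl_response(201L, resp)
}

handle_read_patients <- function(app, query) {
  grant <- authorize(app$registry, query$tokenId, "readPatients")
  views <- lapply(grant$data$patients, function(ref) {
    v <- get_patient(app$store, ref$id_string, ref$id_type,
                     fields_filter = grant$data$fields,
                     ids_filter = grant$data$ids)
    out <- list(fields = v$fields, ids = v$ids)
    out
  })
  pl_response(200L, views)
}

handle_entry_form <- function(app, query) {
  # rendering must not consume the single-use token; submission does
  authorize(app$registry, query$tokenId, "addPatient", consume = FALSE)
  schema <- app$config$schema
  inputs <- paste(vapply(seq_len(nrow(schema)), function(i) {
    sprintf('    <label>%s <input name="%s"%s></label><br>',
            schema$name[i], schema$name[i],
            if (schema$required[i]) " required" else "")
  }, ""), collapse = "\n")
  html <- sprintf(paste0(
    "<!DOCTYPE html>\n<html><head><title>PID request</title></head><body>\n",
    "  <h1>Request a pseudonym</h1>\n",
    "  <form method=\"POST\" action=\"/patients?tokenId=%s\">\n%s\n",
    "    <button type=\"submit\">Request PID</button>\n",
    "  </form>\n</body></html>"),
    utils::URLencode(query$tokenId, reserved = TRUE), inputs)
  pl_response(200L, html, content_type = "text/html; charset=utf-8")
}

# ---- httpuv transport -------------------------------------------------

# Rook request environment -> pl_handle arguments
rook_call <- function(app) {
  force(app)
  function(req) {
    headers <- list()
    for (nm in ls(req)) {
      if (startsWith(nm, "HTTP_")) {
        headers[[chartr("_", "-", sub("^HTTP_", "", nm))]] <- req[[nm]]
      }
    }
    body <- tryCatch(req$rook.input$read(), error = function(e) raw(0))
    res <- pl_handle(app,
                     method = req$REQUEST_METHOD,
                     path = req$PATH_INFO,
                     query = parse_query(req$QUERY_STRING),
                     headers = headers,
                     body = body,
                     content_type = req$CONTENT_TYPE %||% "application/json")
    hdr <- res$headers
    if (!is.null(res$content_type)) hdr[["Content-Type"]] <- res$content_type
    if (res$status == 204L) {
      # close after a bodyless response: keeps keep-alive framing sound
      hdr[["Connection"]] <- "close"
    }
    list(status = res$status, headers = hdr, body = res$body)
  }
}

#' Serve the patient list over HTTP
#'
#' Binds plain HTTP on `host:port` and blocks, routing every request
#' through [pl_handle()]. Transport security (TLS) is deployment scope:
#' run it behind a reverse proxy.
#'
#' @param app a [patient_list()].
#' @param port TCP port (default from the config).
#' @param host bind address.
#' @return does not return until interrupted.
#' @export
pl_serve <- function(app, port = app$config$port, host = "127.0.0.1") {
  httpuv::runServer(host, port, list(call = rook_call(app)))
}

#' Hash of the full service state
#'
#' Digest over the exported store state plus the session/token registry
#' contents. Used by the test suite to prove that GET requests never
#' mutate state (safe-verb semantics).
#'
#' @param app a [patient_list()].
#' @return a character scalar (SHA-1 of the serialized state).
#' @export
pl_state_hash <- function(app) {
  tokens <- lapply(sort(ls(app$registry$tokens)), function(tid) {
    tok <- app$registry$tokens[[tid]]
    list(id = tok$token_id, type = tok$type, consumed = tok$consumed,
         session = tok$session_id)
  })
  sessions <- lapply(sort(ls(app$registry$sessions)), function(sid) {
    s <- app$registry$sessions[[sid]]
    list(id = s$session_id, tokens = sort(s$tokens))
  })
  state <- list(store = export_store(app$store), sessions = sessions,
                tokens = tokens,
                counters = lapply(app$config$id_types,
                                  function(it) store_counter(app$store, it)))
  digest_sha1(jsonlite::toJSON(state, auto_unbox = TRUE))
}

# small SHA-1 over a string via serialize-free sum; uses digest if
# available, else a stable fallback on the raw bytes
digest_sha1 <- function(x) {
  if (requireNamespace("digest", quietly = TRUE)) {
    digest::digest(as.character(x), algo = "sha1", serialize = FALSE)
  } else {
    paste(as.integer(charToRaw(as.character(x))), collapse = "-")
  }
}
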
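# Delegated authorization: sessions and single-purpose bearer tokens.
#
# The MDAT server authenticates with an API key and manages sessions;
# browsers never hold the key — they act through tokens whose random
# UUID is the only credential ("No other authentication is required
# other than knowing the token identifier").  Tokens live in memory
# only: a restart invalidates every session, which is the safe failure
# mode for bearer credentials.

TOKEN_TYPES <- c("addPatient", "readPatients")

#' Session and token registry
#'
#' In-memory container for sessions and their tokens. All operations
#' check the caller's API key against the configured set; token use
#' itself needs no key (bearer semantics).
#'
#' @param config a [pl_config()] (supplies the accepted API keys).
#' @return an object of class `session_registry`.
#' @export
new_session_registry <- function(config) {
  reg <- new.env(parent = emptyenv())
  reg$config <- config
  reg$sessions <- new.env(parent = emptyenv())
  reg$tokens <- new.env(parent = emptyenv())
  class(reg) <- "session_registry"
  reg
}

#' @export
print.session_registry <- function(x, ...) {
  cat(sprintf("<session_registry> %d session(s), %d token(s)\n",
              length(ls(x$sessions)), length(ls(x$tokens))))
  invisible(x)
}

auth_fail <- function(msg = "authentication failed") {
  stop(structure(class = c("pl_auth_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

not_found <- function(msg = "no such resource") {
  stop(structure(class = c("pl_not_found", "error", "condition"),
                 list(message = msg, call = NULL)))
}

validation_fail <- function(msg) {
  stop(structure(class = c("pl_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_api_key <- function(registry, api_key) {
  if (is.null(api_key) || !isTRUE(api_key %in% registry$config$api_keys)) {
    auth_fail("invalid or missing API key")
  }
}

#' Create a session
#'
#' @param registry a [new_session_registry()].
#' @param api_key the caller's API key (sent on the wire in the
#'   `mainzellisteApiKey` header).
#' @return a list with `session_id` (version-4 UUID) and `uri`.
#' @export
create_session <- function(registry, api_key) {
  check_api_key(registry, api_key)
  sid <- uuid::UUIDgenerate()
  s <- new.env(parent = emptyenv())
  s$session_id <- sid
  s$created_at <- Sys.time()
  s$tokens <- character(0)
  assign(sid, s, envir = registry$sessions)
  list(session_id = sid, uri = paste0("/sessions/", sid))
}

#' Retrieve a session
#' @inheritParams create_session
#' @param session_id session UUID.
#' @return a list with `session_id`, `uri` and `tokens` (token ids).
#' @export
get_session <- function(registry, session_id, api_key) {
  check_api_key(registry, api_key)
  s <- registry$sessions[[session_id %||% ""]]
  if (is.null(s)) not_found("no such session")
  list(session_id = s$session_id, uri = paste0("/sessions/", s$session_id),
       tokens = s$tokens)
}

#' Delete a session, invalidating all its tokens
#' @inheritParams get_session
#' @return `TRUE`, invisibly.
#' @export
delete_session <- function(registry, session_id, api_key) {
  check_api_key(registry, api_key)
  s <- registry$sessions[[session_id %||% ""]]
  if (is.null(s)) not_found("no such session")
  for (tid in s$tokens) {
    if (exists(tid, envir = registry$tokens)) rm(list = tid, envir = registry$tokens)
  }
  rm(list = session_id, envir = registry$sessions)
  invisible(TRUE)
}

# syntactic URL check for callback/redirect values
valid_url <- function(u) grepl("^https?://[^ ]+$", u)

#' Create a token within a session
#'
#' Token types:
#' * `addPatient` — authorizes one PID request. `data` may carry
#'   `callback` (URL the list notifies of the result), `redirect` (URL
#'   template with an `{id}` placeholder for the browser flow), and
#'   `id_types` (id-types to return; default all configured).
#' * `readPatients` — authorizes reading projected patient views.
#'   `data` must carry `patients` (list of `{id_type, id_string}`
#'   references, resolved and frozen at creation), and may restrict
#'   `fields` and `ids` (both default empty: nothing is exposed unless
#'   listed).
#'
#' @inheritParams get_session
#' @param type token type string.
#' @param data named list, per type above.
#' @param store a `patient_store`, needed to resolve `readPatients`
#'   references.
#' @return a list with `token_id`, `type`, `data`, `uri`.
#' @export
create_token <- function(registry, session_id, api_key, type, data = list(),
                         store = NULL) {
  check_api_key(registry, api_key)
  s <- registry$sessions[[session_id %||% ""]]
  if (is.null(s)) not_found("no such session")
  if (!isTRUE(type %in% TOKEN_TYPES)) {
    validation_fail(sprintf("unknown token type '%s'", type %||% ""))
  }
  data <- data %||% list()
  if (type == "addPatient") {
    for (k in c("callback", "redirect")) {
      if (!is.null(data[[k]]) && !valid_url(data[[k]])) {
        validation_fail(sprintf("malformed %s URL", k))
      }
    }
  } else {
    refs <- data$patients %||% list()
    if (!length(refs)) validation_fail("readPatients token needs patient references")
    resolved <- lapply(refs, function(r) {
      it <- r$id_type %||% registry$config$id_types[1L]
      if (is.null(r$id_string)) validation_fail("patient reference needs id_string")
      iid <- if (!is.null(store)) lookup_internal_id(store, it, r$id_string) else NA
      if (is.na(iid)) validation_fail("unresolvable patient reference")
      list(id_type = it, id_string = r$id_string, internal_id = iid)
    })
    data$patients <- resolved
    data$fields <- as.character(data$fields %||% character(0))
    data$ids <- as.character(data$ids %||% character(0))
  }
  tid <- uuid::UUIDgenerate()
  tok <- new.env(parent = emptyenv())
  tok$token_id <- tid
  tok$type <- type
  tok$data <- data
  tok$session_id <- session_id
  tok$consumed <- FALSE
  assign(tid, tok, envir = registry$tokens)
  s$tokens <- c(s$tokens, tid)
  list(token_id = tid, type = type, data = data,
       uri = paste0("/sessions/", session_id, "/tokens/", tid))
}

#' Authorize an action with a token
#'
#' Grants iff the token exists, its session is alive, its type matches,
#' it is unconsumed (addPatient tokens are single-use and are atomically
#' consumed by a grant), and the requested projection is covered by the
#' token's data. Every failure raises the same authorization error:
#' callers get no oracle for token existence.
#'
#' @param registry a [new_session_registry()].
#' @param token_id bearer token UUID.
#' @param required_type expected token type.
#' @param requested named list; for `readPatients`, `fields` and `ids`
#'   that must be subsets of the token's data.
#' @param consume whether a grant consumes a single-use token (`TRUE`
#'   for actual use; `FALSE` for non-consuming checks such as rendering
#'   the entry form).
#' @return the token's `data` list, invisibly wrapped with its id.
#' @export
authorize <- function(registry, token_id, required_type,
                      requested = list(), consume = TRUE) {
  tok <- registry$tokens[[token_id %||% ""]]
  if (is.null(tok)) auth_fail("authorization failed")
  if (!exists(tok$session_id, envir = registry$sessions)) auth_fail("authorization failed")
  if (!identical(tok$type, required_type)) auth_fail("authorization failed")
  if (tok$type == "addPatient" && tok$consumed) auth_fail("authorization failed")
  if (required_type == "readPatients") {
    if (!all(requested$fields %||% character(0) %in% tok$data$fields) ||
        !all(requested$ids %||% character(0) %in% tok$data$ids)) {
      auth_fail("authorization failed")
    }
  }
  if (tok$type == "addPatient" && consume) tok$consumed <- TRUE
  list(token_id = tok$token_id, type = tok$type, data = tok$data)
}
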
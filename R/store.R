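# Patient store: the persistent heart of the patient list.
#
# Backing storage is a single-file embedded relational database
# (SQLite).  The linkage scan needs every normalized record on every
# insert, so the store keeps an in-memory tibble mirror of the
# normalized fields, rebuilt on open and appended on insert; SQLite
# remains the source of truth and the two are committed together.
#
# Schema:
#   patients(internal_id INTEGER PK, tentative INTEGER, created_at TEXT)
#   patient_fields(internal_id, name, raw, norm)
#   patient_ids(internal_id, id_type, pid)
#   counters(id_type TEXT PK, next_counter INTEGER)

#' Open a patient store
#'
#' Opens (creating if necessary) the store backing a patient list. A
#' store persists patients, their raw and normalized identifying
#' fields, one pseudonym per configured id-type, and the generator
#' counter per id-type. Counters and records commit in one transaction,
#' so a crash can never leave an issued PID without its patient or vice
#' versa.
#'
#' @param config a [pl_config()].
#' @param path SQLite file path; default taken from the config
#'   (`storage.file`, in-memory if unset).
#' @return an object of class `patient_store`.
#' @export
#' @examples
#' st <- open_store(default_config())
#' add_or_match_patient(st, list(first_name = "Ada", last_name = "Lovelace",
#'   birth_day = "10", birth_month = "12", birth_year = "1815"))
#' close_store(st)
open_store <- function(config, path = config$storage_file) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  tryCatch({
    DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
    DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS patients (
        internal_id INTEGER PRIMARY KEY,
        tentative INTEGER NOT NULL DEFAULT 0,
        created_at TEXT NOT NULL)")
    DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS patient_fields (
        internal_id INTEGER NOT NULL REFERENCES patients(internal_id),
        name TEXT NOT NULL, raw TEXT NOT NULL, norm TEXT NOT NULL,
        PRIMARY KEY (internal_id, name))")
    DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS patient_ids (
        internal_id INTEGER NOT NULL REFERENCES patients(internal_id),
        id_type TEXT NOT NULL, pid TEXT NOT NULL,
        PRIMARY KEY (internal_id, id_type),
        UNIQUE (id_type, pid))")
    DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS counters (
        id_type TEXT PRIMARY KEY, next_counter INTEGER NOT NULL)")
    for (it in config$id_types) {
      DBI::dbExecute(con,
        "INSERT OR IGNORE INTO counters (id_type, next_counter) VALUES (?, 0)",
        params = list(it))
    }
    ok <- TRUE
  }, error = function(e) {
    stop("refusing to start on unreadable or corrupt storage: ",
         conditionMessage(e), call. = FALSE)
  }, finally = if (!ok) try(DBI::dbDisconnect(con), silent = TRUE))

  st <- new.env(parent = emptyenv())
  st$con <- con
  st$config <- config
  st$mirror <- load_mirror(con, config)
  class(st) <- "patient_store"
  st
}

# rebuild the in-memory normalized mirror from the database
load_mirror <- function(con, config) {
  pats <- DBI::dbGetQuery(con,
    "SELECT internal_id, tentative FROM patients ORDER BY internal_id")
  cols <- c(list(internal_id = pats$internal_id,
                 tentative = as.logical(pats$tentative)),
            stats::setNames(
              rep(list(character(nrow(pats))), nrow(config$schema)),
              config$schema$name))
  mirror <- tibble::as_tibble(cols)
  if (nrow(pats)) {
    flds <- DBI::dbGetQuery(con, "SELECT internal_id, name, norm FROM patient_fields")
    for (nm in config$schema$name) {
      sub <- flds[flds$name == nm, ]
      mirror[[nm]][match(sub$internal_id, mirror$internal_id)] <- sub$norm
    }
  }
  mirror
}

#' @rdname open_store
#' @param store a `patient_store`.
#' @export
close_store <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.patient_store <- function(x, ...) {
  cat(sprintf("<patient_store> %d patient(s), id-types: %s\n",
              nrow(x$mirror), paste(x$config$id_types, collapse = ", ")))
  invisible(x)
}

#' Number of stored patients
#' @param store a `patient_store`.
#' @return integer count.
#' @export
n_patients <- function(store) nrow(store$mirror)

# validate required fields after normalization; returns normalized record
check_required <- function(norm, schema) {
  missing_req <- schema$name[schema$required & !nzchar(norm[schema$name])]
  if (length(missing_req)) {
    stop(sprintf("missing required field(s): %s",
                 paste(missing_req, collapse = ", ")), call. = FALSE)
  }
  invisible(norm)
}

#' Add a patient or return the existing pseudonym
#'
#' The service's core transaction. Normalizes the submitted IDAT, runs
#' the linkage scan against every stored record, and then:
#' * `MATCH` — returns the stored patient's PIDs (`is_new = FALSE`);
#' * `NON_MATCH` — issues a fresh PID for every configured id-type and
#'   stores the record;
#' * `TENTATIVE` — policy `create` (default) stores a new record with
#'   fresh PIDs flagged tentative; policy `reject` raises a conflict
#'   condition (`pl_conflict`), surfaced upstream as HTTP 409.
#'
#' Counter increments and the record insert commit in one transaction.
#'
#' @param store a `patient_store` from [open_store()].
#' @param idat named list of raw field values.
#' @return a list with `pid` (of the first configured id-type), `ids`
#'   (named list of all PIDs), `tentative`, `is_new`, `score` and
#'   `decision` from the linkage stage.
#' @export
add_or_match_patient <- function(store, idat) {
  config <- store$config
  norm <- normalize_record(idat, config$schema)
  check_required(norm, config$schema)
  m <- find_best_match(as.list(norm), store$mirror, config$linkage)

  if (m$decision == "MATCH") {
    iid <- store$mirror$internal_id[m$index]
    ids <- DBI::dbGetQuery(store$con,
      "SELECT id_type, pid FROM patient_ids WHERE internal_id = ?",
      params = list(iid))
    idl <- stats::setNames(as.list(ids$pid), ids$id_type)
    return(list(pid = idl[[config$id_types[1L]]], ids = idl,
                tentative = isTRUE(store$mirror$tentative[m$index]),
                is_new = FALSE, score = m$score, decision = m$decision))
  }
  if (m$decision == "TENTATIVE" && config$on_tentative == "reject") {
    stop(structure(class = c("pl_conflict", "error", "condition"),
                   list(message = sprintf(
                     "tentative match (score %.3f) and policy is reject", m$score),
                     call = NULL)))
  }
  tentative <- m$decision == "TENTATIVE"

  con <- store$con
  idl <- NULL
  iid <- NULL
  DBI::dbWithTransaction(con, {
    counters <- DBI::dbGetQuery(con, "SELECT id_type, next_counter FROM counters")
    idl <- list()
    for (it in config$id_types) {
      ctr <- counters$next_counter[counters$id_type == it]
      if (ctr >= PID_COUNTER_MODULUS) {
        stop("PID counter exhausted for id-type ", it, call. = FALSE)
      }
      idl[[it]] <- pid_from_counter(ctr, config$keys[[it]])
      DBI::dbExecute(con,
        "UPDATE counters SET next_counter = next_counter + 1 WHERE id_type = ?",
        params = list(it))
    }
    DBI::dbExecute(con,
      "INSERT INTO patients (tentative, created_at) VALUES (?, ?)",
      params = list(as.integer(tentative),
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")))
    iid <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id
    DBI::dbExecute(con,
      "INSERT INTO patient_fields (internal_id, name, raw, norm) VALUES (?, ?, ?, ?)",
      params = list(rep(iid, nrow(config$schema)), config$schema$name,
                    vapply(config$schema$name, function(n)
                      as.character(idat[[n]] %||% ""), ""),
                    unname(norm[config$schema$name])))
    DBI::dbExecute(con,
      "INSERT INTO patient_ids (internal_id, id_type, pid) VALUES (?, ?, ?)",
      params = list(rep(iid, length(idl)), names(idl),
                    unlist(idl, use.names = FALSE)))
  })
  store$mirror <- dplyr::bind_rows(
    store$mirror,
    tibble::as_tibble(c(list(internal_id = iid, tentative = tentative),
                        as.list(norm))))
  list(pid = idl[[config$id_types[1L]]], ids = idl, tentative = tentative,
       is_new = TRUE, score = m$score, decision = m$decision)
}

# internal id for a (id_type, pid) pair, or NA
lookup_internal_id <- function(store, id_type, pid) {
  r <- DBI::dbGetQuery(store$con,
    "SELECT internal_id FROM patient_ids WHERE id_type = ? AND pid = ?",
    params = list(id_type, pid))
  if (nrow(r) == 0L) NA_integer_ else r$internal_id[1L]
}

#' Projected view of a stored patient
#'
#' Returns only the requested identifying fields and id-types; the
#' projection is enforced here, beneath the HTTP layer, so token
#' permission checks are testable without a server. An empty
#' `fields_filter` yields a view without any IDAT (the second-level
#' pseudonymization case: pseudonym-to-pseudonym mapping only).
#'
#' @param store a `patient_store`.
#' @param pid pseudonym string.
#' @param id_type id-type of `pid` (default: the first configured).
#' @param fields_filter character vector of field names to expose.
#' @param ids_filter character vector of id-type names to expose.
#' @return a list with `fields` (named list of normalized values) and
#'   `ids` (named list of pseudonyms), plus `tentative`.
#' @export
get_patient <- function(store, pid, id_type = store$config$id_types[1L],
                        fields_filter = character(0),
                        ids_filter = character(0)) {
  iid <- lookup_internal_id(store, id_type, pid)
  if (is.na(iid)) stop("unknown PID for id-type ", id_type, call. = FALSE)
  fields_filter <- intersect(fields_filter, store$config$schema$name)
  ids_filter <- intersect(ids_filter, store$config$id_types)
  flds <- DBI::dbGetQuery(store$con,
    "SELECT name, norm FROM patient_fields WHERE internal_id = ?",
    params = list(iid))
  ids <- DBI::dbGetQuery(store$con,
    "SELECT id_type, pid FROM patient_ids WHERE internal_id = ?",
    params = list(iid))
  tent <- DBI::dbGetQuery(store$con,
    "SELECT tentative FROM patients WHERE internal_id = ?",
    params = list(iid))$tentative == 1
  list(
    fields = stats::setNames(
      as.list(flds$norm[match(fields_filter, flds$name)]), fields_filter),
    ids = stats::setNames(
      as.list(ids$pid[match(ids_filter, ids$id_type)]), ids_filter),
    tentative = tent
  )
}

#' Export / import the store as JSON
#'
#' `export_store()` writes the full state — patients with raw and
#' normalized fields, pseudonyms and counters — as pretty-printed JSON
#' with stable key order, suitable for diffing and for fixtures.
#' `import_store()` loads such a file into an empty store.
#'
#' @param store a `patient_store`.
#' @param path JSON file path; `NULL` returns the list instead.
#' @return `export_store()`: the state list (invisibly if written).
#' @export
export_store <- function(store, path = NULL) {
  con <- store$con
  pats <- DBI::dbGetQuery(con,
    "SELECT internal_id, tentative FROM patients ORDER BY internal_id")
  flds <- DBI::dbGetQuery(con,
    "SELECT internal_id, name, raw, norm FROM patient_fields")
  ids <- DBI::dbGetQuery(con, "SELECT internal_id, id_type, pid FROM patient_ids")
  counters <- DBI::dbGetQuery(con,
    "SELECT id_type, next_counter FROM counters ORDER BY id_type")
  schema_order <- store$config$schema$name
  patients <- lapply(seq_len(nrow(pats)), function(i) {
    iid <- pats$internal_id[i]
    f <- flds[flds$internal_id == iid, ]
    id <- ids[ids$internal_id == iid, ]
    id <- id[order(match(id$id_type, store$config$id_types)), ]
    list(
      ids = stats::setNames(as.list(id$pid), id$id_type),
      fields = stats::setNames(
        as.list(f$raw[match(schema_order, f$name)]), schema_order),
      tentative = pats$tentative[i] == 1
    )
  })
  state <- list(patients = patients,
                counters = stats::setNames(as.list(counters$next_counter),
                                           counters$id_type))
  if (is.null(path)) return(state)
  jsonlite::write_json(state, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(state)
}

#' @rdname export_store
#' @export
import_store <- function(store, path) {
  if (n_patients(store) > 0L) {
    stop("import requires an empty store", call. = FALSE)
  }
  state <- jsonlite::read_json(path)
  con <- store$con
  config <- store$config
  DBI::dbWithTransaction(con, {
    for (p in state$patients) {
      norm <- normalize_record(p$fields, config$schema)
      DBI::dbExecute(con,
        "INSERT INTO patients (tentative, created_at) VALUES (?, ?)",
        params = list(as.integer(isTRUE(p$tentative)),
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")))
      iid <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id
      DBI::dbExecute(con,
        "INSERT INTO patient_fields (internal_id, name, raw, norm) VALUES (?, ?, ?, ?)",
        params = list(rep(iid, nrow(config$schema)), config$schema$name,
                      vapply(config$schema$name, function(n)
                        as.character(p$fields[[n]] %||% ""), ""),
                      unname(norm[config$schema$name])))
      DBI::dbExecute(con,
        "INSERT INTO patient_ids (internal_id, id_type, pid) VALUES (?, ?, ?)",
        params = list(rep(iid, length(p$ids)), names(p$ids),
                      unlist(p$ids, use.names = FALSE)))
    }
    for (it in names(state$counters)) {
      DBI::dbExecute(con,
        "INSERT OR REPLACE INTO counters (id_type, next_counter) VALUES (?, ?)",
        params = list(it, state$counters[[it]]))
    }
  })
  store$mirror <- load_mirror(con, config)
  invisible(store)
}

#' Current generator counter for an id-type
#' @param store a `patient_store`.
#' @param id_type id-type name.
#' @return the next counter value to be issued.
#' @export
store_counter <- function(store, id_type = store$config$id_types[1L]) {
  DBI::dbGetQuery(store$con,
    "SELECT next_counter FROM counters WHERE id_type = ?",
    params = list(id_type))$next_counter
}
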
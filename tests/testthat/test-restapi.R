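# The HTTP surface, exercised through the in-process handler: verb
# semantics, status codes, authorization, callbacks, redirects, and
# content negotiation.

api_fixture <- function(props = list()) {
  defaults <- list(`idgen.k1` = 123456789, `idgen.k2` = 987654321,
                   `idgen.k3` = 192837465, `api.keys` = "sesame")
  cfg <- pl_config(utils::modifyList(defaults, props))
  app <- patient_list(cfg, quiet = TRUE)
  withr::defer(close_store(app$store), envir = parent.frame())
  app
}

hdr <- list(mainzellisteApiKey = "sesame")

post_json <- function(app, path, payload, query = list(), headers = hdr) {
  pl_handle(app, "POST", path, query = query, headers = headers,
            body = jsonlite::toJSON(payload, auto_unbox = TRUE))
}

body_of <- function(res) jsonlite::fromJSON(res$body, simplifyVector = FALSE)

new_session <- function(app) {
  body_of(pl_handle(app, "POST", "/sessions", headers = hdr))$sessionId
}

new_token <- function(app, sid, type = "addPatient", data = NULL) {
  body_of(post_json(app, paste0("/sessions/", sid, "/tokens"),
                    if (is.null(data)) list(type = type)
                    else list(type = type, data = data)))$id
}

table1_json <- list(
  list(first_name = "Ivan Peter", last_name = "Fellegi",
       birth_day = "22", birth_month = "06", birth_year = "1935"),
  list(first_name = "Ivan", last_name = "Felligi",
       birth_day = "22", birth_month = "06", birth_year = "1935"))

test_that("session resource honours verb semantics and the API key header", {
  app <- api_fixture()
  r <- pl_handle(app, "POST", "/sessions", headers = hdr)
  expect_identical(r$status, 201L)
  b <- body_of(r)
  expect_match(r$headers$Location, "^/sessions/")
  expect_identical(b$uri, r$headers$Location)

  # the request body is ignored: no parameters are defined for sessions
  r2 <- pl_handle(app, "POST", "/sessions", headers = hdr,
                  body = '{"ignored": true}')
  expect_identical(r2$status, 201L)

  expect_identical(pl_handle(app, "POST", "/sessions")$status, 401L)
  expect_identical(
    pl_handle(app, "POST", "/sessions",
              headers = list(mainzellisteApiKey = "wrong"))$status, 401L)
  # header name matching is case-insensitive as HTTP requires
  expect_identical(
    pl_handle(app, "POST", "/sessions",
              headers = list(MAINZELLISTEAPIKEY = "sesame"))$status, 201L)

  del <- pl_handle(app, "DELETE", paste0("/sessions/", b$sessionId),
                   headers = hdr)
  expect_identical(del$status, 204L)
  expect_identical(del$body, "")
  expect_identical(pl_handle(app, "DELETE", paste0("/sessions/", b$sessionId),
                             headers = hdr)$status, 404L)
})

test_that("token minting validates payloads and reports 201 with a body", {
  app <- api_fixture()
  sid <- new_session(app)
  r <- post_json(app, paste0("/sessions/", sid, "/tokens"),
                 list(type = "addPatient",
                      data = list(callback = "https://mdat-server.org/cb")))
  expect_identical(r$status, 201L)
  b <- body_of(r)
  expect_identical(b$type, "addPatient")
  expect_identical(b$data$callback, "https://mdat-server.org/cb")

  # data absent is fine: callback and redirect are optional
  r2 <- post_json(app, paste0("/sessions/", sid, "/tokens"),
                  list(type = "addPatient"))
  expect_identical(r2$status, 201L)

  expect_identical(post_json(app, paste0("/sessions/", sid, "/tokens"),
                             list(type = "frobnicate"))$status, 400L)
  expect_identical(post_json(app, "/sessions/none/tokens",
                             list(type = "addPatient"))$status, 404L)
  expect_identical(post_json(app, paste0("/sessions/", sid, "/tokens"),
                             list(type = "addPatient"),
                             headers = list())$status, 401L)
})

test_that("the duplicate pair yields one PID through the HTTP layer", {
  app <- api_fixture()
  sid <- new_session(app)
  pids <- vapply(table1_json, function(row) {
    tid <- new_token(app, sid)
    r <- post_json(app, "/patients", row, query = list(tokenId = tid))
    expect_identical(r$status, 201L)
    body_of(r)$newId
  }, "")
  expect_identical(pids[1], pids[2])
  expect_identical(n_patients(app$store), 1L)
})

test_that("GET requests never mutate service state", {
  app <- api_fixture()
  sid <- new_session(app)
  tid <- new_token(app, sid)
  post_json(app, "/patients", table1_json[[1]], query = list(tokenId = tid))
  pid <- body_of(post_json(app, "/patients", table1_json[[2]],
                           query = list(tokenId = new_token(app, sid))))$newId
  rt <- new_token(app, sid, "readPatients",
                  list(patients = list(list(id_type = "pid", id_string = pid)),
                       fields = list("first_name"), ids = list("pid")))
  gets <- list(
    list("GET", paste0("/sessions/", sid), hdr, list()),
    list("GET", "/patients", list(), list(tokenId = rt)),
    list("GET", "/html/addPatient", list(),
         list(tokenId = new_token(app, sid))),
    list("GET", "/patients", list(), list(tokenId = "bogus"))
  )
  for (g in gets) {
    h0 <- pl_state_hash(app)
    res <- pl_handle(app, g[[1]], g[[2]], headers = g[[3]], query = g[[4]])
    expect_identical(pl_state_hash(app), h0)
  }
})

test_that("form-encoded and JSON submissions produce identical patients", {
  app_a <- api_fixture()
  app_b <- api_fixture()
  sid_a <- new_session(app_a)
  sid_b <- new_session(app_b)
  r1 <- post_json(app_a, "/patients", table1_json[[1]],
                  query = list(tokenId = new_token(app_a, sid_a)))
  form <- paste0("first_name=Ivan+Peter&last_name=Fellegi&birth_day=22",
                 "&birth_month=06&birth_year=1935")
  r2 <- pl_handle(app_b, "POST", "/patients",
                  query = list(tokenId = new_token(app_b, sid_b)),
                  body = form,
                  content_type = "application/x-www-form-urlencoded")
  expect_identical(r1$status, 201L)
  expect_identical(r2$status, 201L)
  # same keys, same normalized store content (PIDs agree: same counter)
  expect_identical(body_of(r1)$newId, body_of(r2)$newId)
  s_a <- export_store(app_a$store)
  s_b <- export_store(app_b$store)
  expect_identical(s_a$patients, s_b$patients)
})

test_that("missing required fields give a 400 listing the field names", {
  app <- api_fixture()
  sid <- new_session(app)
  r <- post_json(app, "/patients", list(first_name = "Max"),
                 query = list(tokenId = new_token(app, sid)))
  expect_identical(r$status, 400L)
  expect_match(body_of(r)$error, "last_name")
  expect_match(body_of(r)$error, "birth_year")
  # validation failure still consumed the token (one use per round-trip)
  r2 <- post_json(app, "/patients", table1_json[[1]],
                  query = list(tokenId = new_token(app, sid)))
  expect_identical(r2$status, 201L)
})

test_that("the callback fires exactly once, without IDAT, before responding", {
  app <- api_fixture()
  calls <- list()
  app$callback_sender <- function(url, payload, secret) {
    calls[[length(calls) + 1L]] <<- list(url = url, payload = payload,
                                         secret = secret, t = Sys.time())
    TRUE
  }
  sid <- new_session(app)
  tid <- new_token(app, sid, data = list(callback = "https://mdat-server.org/cb"))
  r <- post_json(app, "/patients", table1_json[[1]],
                 query = list(tokenId = tid))
  expect_identical(r$status, 201L)
  expect_length(calls, 1L)
  expect_identical(calls[[1]]$url, "https://mdat-server.org/cb")
  payload <- jsonlite::fromJSON(calls[[1]]$payload, simplifyVector = FALSE)
  expect_identical(payload$tokenId, tid)
  expect_identical(payload$ids[[1]]$idString, body_of(r)$newId)
  # the callback payload never carries identifying data
  expect_false(grepl("Fellegi", calls[[1]]$payload, ignore.case = TRUE))
  expect_false(grepl("first_name", calls[[1]]$payload))

  # no callback configured -> no outbound request
  tid2 <- new_token(app, sid)
  post_json(app, "/patients", table1_json[[2]], query = list(tokenId = tid2))
  expect_length(calls, 1L)
})

test_that("a failing callback is reported but the patient is kept", {
  app <- api_fixture()
  app$callback_sender <- function(url, payload, secret) stop("boom")
  sid <- new_session(app)
  tid <- new_token(app, sid, data = list(callback = "https://mdat-server.org/cb"))
  expect_warning(
    r <- post_json(app, "/patients", table1_json[[1]],
                   query = list(tokenId = tid)),
    "callback")
  expect_identical(r$status, 201L)
  expect_identical(body_of(r)$callbackStatus, "failed")
  expect_identical(n_patients(app$store), 1L)
})

test_that("a redirect template turns the response into a 303 with {id}", {
  app <- api_fixture()
  sid <- new_session(app)
  tid <- new_token(app, sid,
                   data = list(redirect = "https://mdat-server.org/patient/{id}"))
  r <- post_json(app, "/patients", table1_json[[1]],
                 query = list(tokenId = tid))
  expect_identical(r$status, 303L)
  pid <- body_of(r)$newId
  expect_identical(r$headers$Location,
                   paste0("https://mdat-server.org/patient/", pid))
})

test_that("tentative reject policy surfaces as HTTP 409", {
  app <- api_fixture(list(`matching.on_tentative` = "reject"))
  sid <- new_session(app)
  post_json(app, "/patients", table1_json[[1]],
            query = list(tokenId = new_token(app, sid)))
  shifted <- table1_json[[1]]
  shifted$birth_month <- "07"
  r <- post_json(app, "/patients", shifted,
                 query = list(tokenId = new_token(app, sid)))
  expect_identical(r$status, 409L)
  expect_identical(n_patients(app$store), 1L)
})

test_that("readPatients projection flows through GET /patients", {
  app <- api_fixture(list(`idgen.id_types` = "pid,pid2",
                          `idgen.pid2.k1` = 44, `idgen.pid2.k2` = 55,
                          `idgen.pid2.k3` = 66))
  sid <- new_session(app)
  r <- body_of(post_json(app, "/patients", table1_json[[1]],
                         query = list(tokenId = new_token(app, sid))))
  # fields-only token: exactly the permitted keys, no id strings
  t1 <- new_token(app, sid, "readPatients",
                  list(patients = list(list(id_type = "pid",
                                            id_string = r$newId)),
                       fields = list("first_name", "last_name")))
  v <- body_of(pl_handle(app, "GET", "/patients", query = list(tokenId = t1)))
  expect_length(v, 1L)
  expect_setequal(names(v[[1]]$fields), c("first_name", "last_name"))
  expect_length(v[[1]]$ids, 0L)

  # ids-only token: second-level pseudonymization without IDAT
  t2 <- new_token(app, sid, "readPatients",
                  list(patients = list(list(id_type = "pid",
                                            id_string = r$newId)),
                       ids = list("pid2")))
  v2 <- body_of(pl_handle(app, "GET", "/patients", query = list(tokenId = t2)))
  expect_identical(names(v2[[1]]$ids), "pid2")
  expect_length(v2[[1]]$fields, 0L)
  expect_false(identical(v2[[1]]$ids$pid2, r$newId))

  expect_identical(pl_handle(app, "GET", "/patients",
                             query = list(tokenId = "nope"))$status, 401L)
  # session deletion cuts access
  pl_handle(app, "DELETE", paste0("/sessions/", sid), headers = hdr)
  expect_identical(pl_handle(app, "GET", "/patients",
                             query = list(tokenId = t2))$status, 401L)
})

test_that("the HTML form renders schema fields and posts like JSON", {
  app <- api_fixture()
  sid <- new_session(app)
  tid <- new_token(app, sid)
  r <- pl_handle(app, "GET", "/html/addPatient", query = list(tokenId = tid))
  expect_identical(r$status, 200L)
  expect_match(r$content_type, "text/html")
  for (f in app$config$schema$name) {
    expect_match(r$body, sprintf('name="%s"', f))
  }
  expect_match(r$body, sprintf("/patients\\?tokenId=%s", tid))
  # rendering did not consume the token; the form submission works
  form <- paste0("first_name=K%C3%A4the&last_name=M%C3%BCller&birth_day=3",
                 "&birth_month=4&birth_year=1999")
  pr <- pl_handle(app, "POST", "/patients", query = list(tokenId = tid),
                  body = form,
                  content_type = "application/x-www-form-urlencoded")
  expect_identical(pr$status, 201L)
  v <- get_patient(app$store, body_of(pr)$newId,
                   fields_filter = c("first_name", "last_name"))
  expect_identical(v$fields$first_name, "KAETHE")
  expect_identical(v$fields$last_name, "MUELLER")
  expect_identical(pl_handle(app, "GET", "/html/addPatient",
                             query = list(tokenId = "bad"))$status, 401L)
})

test_that("unknown resources are 404 and bodies are always valid JSON", {
  app <- api_fixture()
  r <- pl_handle(app, "GET", "/nothing/here", headers = hdr)
  expect_identical(r$status, 404L)
  expect_silent(jsonlite::fromJSON(r$body))
  r2 <- pl_handle(app, "PUT", "/sessions", headers = hdr)
  expect_identical(r2$status, 404L)
})
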
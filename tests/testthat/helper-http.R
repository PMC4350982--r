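# Real-server harness: a patient list and a callback receiver, each in
# a background R process, driven over genuine HTTP from the test
# process.  Only the protocol tests use this; everything else exercises
# the in-process handler.

pl_test_port <- function() httpuv::randomPort()

# start a patient list server; returns list(process, port, url, props)
start_pl_server <- function(props = list(), port = pl_test_port()) {
  defaults <- list(`idgen.k1` = 123456789, `idgen.k2` = 987654321,
                   `idgen.k3` = 192837465, `api.keys` = "sesame")
  props <- utils::modifyList(defaults, props)
  props_path <- tempfile(fileext = ".properties")
  pseudolist::write_properties(props, props_path)
  proc <- callr::r_bg(function(props_path, port) {
    library(pseudolist)
    cfg <- pl_config(read_properties(props_path))
    app <- patient_list(cfg, quiet = TRUE)
    pl_serve(app, port = port)
  }, args = list(props_path = props_path, port = port),
  supervise = TRUE)
  url <- sprintf("http://127.0.0.1:%d", port)
  wait_until_up(url, proc)
  list(process = proc, port = port, url = url, props = props)
}

# start a callback receiver that appends each POSTed body (one line of
# JSON) to `outfile`; returns list(process, port, url, outfile)
start_callback_receiver <- function(port = pl_test_port(),
                                    outfile = tempfile(fileext = ".log")) {
  file.create(outfile)
  proc <- callr::r_bg(function(port, outfile) {
    httpuv::runServer("127.0.0.1", port, list(call = function(req) {
      body <- tryCatch(rawToChar(req$rook.input$read()),
                       error = function(e) "")
      cat(gsub("\n", " ", body), "\n", sep = "", file = outfile, append = TRUE)
      list(status = 200L, headers = list("Content-Type" = "application/json"),
           body = "{}")
    }))
  }, args = list(port = port, outfile = outfile), supervise = TRUE)
  url <- sprintf("http://127.0.0.1:%d", port)
  wait_until_up(url, proc, expect_status = 200L)
  list(process = proc, port = port, url = url, outfile = outfile)
}

wait_until_up <- function(url, proc, expect_status = NULL, timeout = 20) {
  deadline <- Sys.time() + timeout
  while (Sys.time() < deadline) {
    if (!proc$is_alive()) {
      stop("server process died during startup: ", proc$read_all_error())
    }
    st <- tryCatch(httr::status_code(httr::GET(url, httr::timeout(2))),
                   error = function(e) NA_integer_)
    if (!is.na(st) && (is.null(expect_status) || st == expect_status ||
                       st %in% c(401L, 404L))) {
      return(invisible(TRUE))
    }
    Sys.sleep(0.1)
  }
  proc$kill()
  stop("server did not come up at ", url)
}

stop_server <- function(srv) {
  if (!is.null(srv$process) && srv$process$is_alive()) srv$process$kill()
  invisible(NULL)
}
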
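Package: pseudolist
Title: RESTful First-Level Pseudonymization Service with Record Linkage
    and Error-Correcting Patient Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trusted-third-party "patient list" for medical research
    networks: accepts identifying data (IDAT) over a resource-oriented
    HTTP interface, decides via probabilistic record linkage (EpiLink-style
    weighted field similarities with two decision thresholds) whether the
    person is already known, and returns a non-speaking, error-correcting
    8-character pseudonym (PID) generated by keyed encryption of a counter
    and protected by two check characters over GF(32). Sessions and
    single-purpose bearer tokens (addPatient, readPatients) delegate
    authentication to the medical-data server. Includes a deterministic
    synthetic-IDAT generator with a typo model for benchmarking linkage
    quality without any real patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    curl,
    DBI,
    dplyr,
    httpuv,
    jsonlite,
    RSQLite,
    stats,
    stringi,
    tibble,
    utils,
    uuid,
    withr
Suggests:
    callr,
    digest,
    ggplot2,
    httr,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
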
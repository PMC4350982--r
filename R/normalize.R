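# Field preprocessing.  Everything that feeds the record linkage scorer
# passes through normalize_field() exactly once, at intake; raw values
# are retained separately for audit.

# explicit German transliterations applied before any generic stripping,
# so the result never depends on locale or ICU version drift
GERMAN_TRANSLIT <- c(
  "Ä" = "AE", "ä" = "ae", # A/a umlaut
  "Ö" = "OE", "ö" = "oe", # O/o umlaut
  "Ü" = "UE", "ü" = "ue", # U/u umlaut
  "ß" = "SS", "ẞ" = "SS"  # sharp s
)

#' Normalize an identifying field
#'
#' Canonical preprocessing applied to every incoming IDAT value before
#' record linkage: trim surrounding whitespace, collapse internal
#' whitespace runs to a single space, transliterate German umlauts and
#' sharp s (Ä→AE, Ö→OE, Ü→UE, ß→SS), strip remaining diacritics to base
#' letters, and uppercase. Date parts are zero-padded to fixed width
#' (2 for day and month, 4 for year). Vectorised.
#'
#' @param value character vector of raw values.
#' @param kind field kind: `"text"`, `"name"` (multi-component text), or
#'   `"date-part"`.
#' @param width pad width for date parts (derived from the field name in
#'   the schema: 2 for day/month, 4 for year).
#' @return character vector of normalized values; empty input stays
#'   empty (a legal value for non-required fields).
#' @export
#' @examples
#' normalize_field("  Müller ", "name")
#' normalize_field("7", "date-part", width = 2)
normalize_field <- function(value, kind = c("text", "name", "date-part"),
                            width = 2L) {
  kind <- match.arg(kind)
  x <- as.character(value)
  x[is.na(x)] <- ""
  x <- gsub("\\s+", " ", trimws(x))
  if (kind == "date-part") {
    pad <- x != ""
    x[pad] <- stringi::stri_pad_left(x[pad], width, "0")
    return(x)
  }
  for (ch in names(GERMAN_TRANSLIT)) {
    x <- gsub(ch, GERMAN_TRANSLIT[[ch]], x, fixed = TRUE)
  }
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  toupper(x)
}

# width of a date-part field, by convention of the default schema
datepart_width <- function(field_name) {
  if (grepl("year", field_name)) 4L else 2L
}

# normalize a named list/vector of raw values against a field schema
normalize_record <- function(raw, schema) {
  out <- character(nrow(schema))
  names(out) <- schema$name
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- if (!is.null(raw[[nm]])) raw[[nm]] else ""
    out[[nm]] <- normalize_field(v, schema$kind[i], datepart_width(nm))
  }
  out
}
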
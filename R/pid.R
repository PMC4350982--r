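# The PID code: 8 characters over a 32-symbol alphabet, of which the
# first six carry the base-32 expansion of the encrypted counter and the
# last two are check characters over GF(32).
#
# Writing c_1..c_8 for the symbols' alphabet indices read as elements of
# GF(32) and g for the primitive element x, a word is a codeword iff
#
#     sum_{j=1..8}       c_j = 0     and     sum_{j=1..8} g^j c_j = 0 .
#
# The parity columns (1, g^j) are pairwise linearly independent (g has
# order 31 and the exponents 1..8 are distinct), so the code has minimum
# distance >= 3: every 1- or 2-symbol corruption has a nonzero syndrome
# (detection), and a single substitution is locatable from the syndrome
# ratio (correction).  Detection and correction are distinct operating
# modes — a distance-3 code does not offer both on the same word — and
# the service itself only ever uses detection.

#' PID alphabet
#'
#' The 32 symbols a PID may contain: digits and uppercase letters with
#' B, I, O, S removed because they are easily confused with 8, 1, 0, 5.
#' Symbol at position `i + 1` represents the GF(32) element `i`.
#'
#' @format a single string of 32 distinct characters.
#' @export
PID_ALPHABET <- "0123456789ACDEFGHJKLMNPQRTUVWXYZ"

PID_ALPHABET_CHARS <- strsplit(PID_ALPHABET, "")[[1]]

# g^j for j = 1..8, precomputed
PID_GPOW <- vapply(1:8, function(j) gf32_pow(2L, j), integer(1))

# multipliers of the closed-form check solution:
#   c7 = (s1 + g^8 s0) / (g^7 + g^8),   c8 = s0 + c7
PID_C7_S0 <- gf32_mul(PID_GPOW[8], gf32_inv(bitwXor(PID_GPOW[7], PID_GPOW[8])))
PID_C7_S1 <- gf32_inv(bitwXor(PID_GPOW[7], PID_GPOW[8]))

#' Base-32 payload expansion
#'
#' `payload_symbols()` expands an encrypted counter into the six payload
#' symbols (big-endian, most significant first, left-padded with the
#' zero symbol); `payload_value()` inverts it.
#'
#' @param cipher numeric vector of values in `[0, 2^30)`.
#' @return `payload_symbols()`: character vector of 6-character strings.
#' @export
payload_symbols <- function(cipher) {
  check_counter_range(cipher, "cipher")
  idx <- payload_indices(cipher)
  apply(idx, 1L, function(i) paste(PID_ALPHABET_CHARS[i + 1L], collapse = ""))
}

# n x 6 integer matrix of alphabet indices, most significant first
payload_indices <- function(cipher) {
  matrix(vapply(5:0, function(p) (as.double(cipher) %/% 32^p) %% 32,
                numeric(length(cipher))),
         nrow = length(cipher), ncol = 6L)
}

#' @rdname payload_symbols
#' @param payload character vector of 6-character payload strings.
#' @export
payload_value <- function(payload) {
  idx <- symbol_indices(payload, 6L)
  if (anyNA(idx)) stop("payload contains characters outside the PID alphabet", call. = FALSE)
  as.double(idx %*% 32^(5:0))
}

# character vector -> n x width matrix of alphabet indices (NA if foreign)
symbol_indices <- function(x, width) {
  if (any(nchar(x) != width)) {
    stop(sprintf("expected strings of length %d", width), call. = FALSE)
  }
  m <- matrix(NA_integer_, length(x), width)
  for (j in seq_len(width)) {
    m[, j] <- match(substring(x, j, j), PID_ALPHABET_CHARS) - 1L
  }
  m
}

#' Check characters of a PID payload
#'
#' Solves the two parity equations over GF(32) for the unique pair of
#' check symbols that completes a 6-symbol payload into a codeword.
#'
#' @param payload character vector of 6-character payload strings.
#' @return character vector of 2-character check strings.
#' @export
#' @examples
#' compute_check("000000") # the all-zero word is a codeword
compute_check <- function(payload) {
  idx <- symbol_indices(payload, 6L)
  if (anyNA(idx)) stop("payload contains characters outside the PID alphabet", call. = FALSE)
  ck <- check_indices(idx)
  paste0(PID_ALPHABET_CHARS[ck[, 1L] + 1L], PID_ALPHABET_CHARS[ck[, 2L] + 1L])
}

# n x 6 index matrix -> n x 2 matrix of check indices (c7, c8)
check_indices <- function(idx) {
  n <- nrow(idx)
  s0 <- integer(n)
  s1 <- integer(n)
  for (j in 1:6) {
    s0 <- bitwXor(s0, idx[, j])
    s1 <- bitwXor(s1, gf32_mul(PID_GPOW[j], idx[, j]))
  }
  c7 <- bitwXor(gf32_mul(PID_C7_S1, s1), gf32_mul(PID_C7_S0, s0))
  cbind(c7, bitwXor(s0, c7))
}

# n x 8 index matrix -> n x 2 syndrome matrix (S0, S1); zero iff codeword
pid_syndrome <- function(idx) {
  s0 <- integer(nrow(idx))
  s1 <- integer(nrow(idx))
  for (j in 1:8) {
    s0 <- bitwXor(s0, idx[, j])
    s1 <- bitwXor(s1, gf32_mul(PID_GPOW[j], idx[, j]))
  }
  cbind(s0, s1)
}

#' Derive the PID for a given counter value
#'
#' The pure issuance map: encrypt the counter, expand to six payload
#' symbols, append the two check characters. Counter state management
#' lives in the patient store; this function has no side effects and is
#' vectorised.
#'
#' @param counter numeric vector of counter values in `[0, 2^30)`.
#' @param keys a [pid_keys()] triple.
#' @return character vector of 8-character PIDs.
#' @export
#' @examples
#' pid_from_counter(0:4, pid_keys(1, 2, 3))
pid_from_counter <- function(counter, keys) {
  idx <- payload_indices(encrypt_counter(counter, keys))
  ck <- check_indices(idx)
  full <- cbind(idx, ck)
  apply(full, 1L, function(i) paste(PID_ALPHABET_CHARS[i + 1L], collapse = ""))
}

#' Recover the issuing counter from a PID
#'
#' Inverts [pid_from_counter()] for audit purposes (e.g. detecting
#' duplicate issuance). The check characters are verified first.
#'
#' @param pid character vector of 8-character PIDs.
#' @inheritParams pid_from_counter
#' @return numeric vector of counter values.
#' @export
pid_to_counter <- function(pid, keys) {
  if (!all(validate_pid(pid))) stop("invalid PID", call. = FALSE)
  decrypt_counter(payload_value(substr(pid, 1L, 6L)), keys)
}

#' Sequential PID generator
#'
#' A stateful issuer around [pid_from_counter()]: each call to
#' `generate_pid()` consumes the next counter value. Counters start at 0
#' and issuance fails hard at 2^30 — silent wraparound would reissue
#' pseudonyms. The patient store persists its counters in the database;
#' this standalone generator backs the `pidtool` command line and tests.
#'
#' @param keys a [pid_keys()] triple.
#' @param start first counter value to issue (default 0).
#' @return `new_pid_generator()`: an object of class `pid_generator`.
#' @export
#' @examples
#' gen <- new_pid_generator(pid_keys(1, 2, 3))
#' generate_pid(gen, 3)
new_pid_generator <- function(keys, start = 0) {
  stopifnot(inherits(keys, "pid_keys"))
  check_counter_range(start)
  env <- new.env(parent = emptyenv())
  env$keys <- keys
  env$next_counter <- as.double(start)
  structure(env, class = "pid_generator")
}

#' @rdname new_pid_generator
#' @param generator a `pid_generator`.
#' @param n number of PIDs to issue.
#' @return `generate_pid()`: character vector of `n` fresh PIDs.
#' @export
generate_pid <- function(generator, n = 1L) {
  stopifnot(inherits(generator, "pid_generator"), n >= 0)
  if (n == 0) return(character(0))
  if (generator$next_counter + n > PID_COUNTER_MODULUS) {
    stop("PID counter exhausted: the 2^30 identifier space is used up", call. = FALSE)
  }
  counters <- generator$next_counter + seq_len(n) - 1
  generator$next_counter <- generator$next_counter + n
  pid_from_counter(counters, generator$keys)
}

#' @export
print.pid_generator <- function(x, ...) {
  cat(sprintf("<pid_generator> next counter: %.0f of %.0f\n",
              x$next_counter, PID_COUNTER_MODULUS))
  invisible(x)
}

#' Validate PID strings
#'
#' Pure detection: a candidate is valid iff it is 8 characters long,
#' drawn from the PID alphabet, and satisfies both parity equations.
#' Because the code's minimum distance is at least 3, any corruption of
#' a valid PID in one or two symbol positions is reported invalid.
#' Vectorised; never throws on malformed input.
#'
#' @param candidate character vector.
#' @return logical vector.
#' @export
#' @examples
#' validate_pid(c("00000000", "10000000", "BIOSBIOS"))
validate_pid <- function(candidate) {
  out <- !is.na(candidate) & nchar(candidate) == 8L
  if (!any(out)) return(out)
  sub <- candidate[out]
  m <- matrix(NA_integer_, length(sub), 8L)
  for (j in 1:8) m[, j] <- match(substring(sub, j, j), PID_ALPHABET_CHARS) - 1L
  ok <- !apply(is.na(m), 1L, any)
  syn <- matrix(1L, length(sub), 2L)
  if (any(ok)) syn[ok, ] <- pid_syndrome(m[ok, , drop = FALSE])
  out[out] <- ok & syn[, 1L] == 0L & syn[, 2L] == 0L
  out
}

#' Correct a corrupted PID
#'
#' Attempts to repair a transcription error in an 8-character candidate:
#' first syndrome decoding of a single substitution (a character outside
#' the alphabet counts as the erroneous position), then — only when no
#' substitution explains the word — a swap of each of the 7 adjacent
#' pairs is tried. An ambiguous word (no unique repair) is refused;
#' guessing is never acceptable for an identifier.
#'
#' @param candidate a single 8-character string.
#' @return a list with `status` (`"ok"`, `"corrected"`, or
#'   `"uncorrectable"`), `pid` (the valid PID, or `NA`), and
#'   `correction` (human-readable description of the repair).
#' @export
#' @examples
#' pid <- pid_from_counter(7, pid_keys(1, 2, 3))
#' broken <- sub("^.", "Z", pid)
#' correct_pid(broken)
correct_pid <- function(candidate) {
  if (length(candidate) != 1L || is.na(candidate)) {
    stop("correct_pid() expects one candidate string", call. = FALSE)
  }
  if (nchar(candidate) != 8L) {
    stop("PID candidates must be exactly 8 characters", call. = FALSE)
  }
  idx <- match(strsplit(candidate, "")[[1]], PID_ALPHABET_CHARS) - 1L
  foreign <- which(is.na(idx))
  if (length(foreign) > 1L) {
    return(list(status = "uncorrectable", pid = NA_character_,
                correction = "more than one character outside the alphabet"))
  }
  # a foreign character is an error at a known position; decode with the
  # zero symbol standing in, then require the located error to be there
  idx[foreign] <- 0L
  syn <- pid_syndrome(matrix(idx, 1L))
  s0 <- syn[1L]; s1 <- syn[2L]
  if (s0 == 0L && s1 == 0L) {
    if (length(foreign) > 0L) {
      # word is only a codeword because the stand-in symbol happens to fit
      pid <- paste(PID_ALPHABET_CHARS[idx + 1L], collapse = "")
      return(list(status = "corrected", pid = pid,
                  correction = sprintf("substitution at position %d", foreign)))
    }
    return(list(status = "ok", pid = candidate, correction = "no error"))
  }
  if (s0 != 0L) {
    if (s1 == 0L) {
      # a single substitution always moves both syndrome components
      return(list(status = "uncorrectable", pid = NA_character_,
                  correction = "no unique single-symbol repair"))
    }
    # single substitution of magnitude s0 at position log_g(s1/s0)
    j <- (GF32_LOG[gf32_mul(s1, gf32_inv(s0)) + 1L]) %% 31L
    if (j >= 1L && j <= 8L && (length(foreign) == 0L || foreign == j)) {
      fixed <- idx
      fixed[j] <- bitwXor(fixed[j], s0)
      pid <- paste(PID_ALPHABET_CHARS[fixed + 1L], collapse = "")
      return(list(status = "corrected", pid = pid,
                  correction = sprintf("substitution at position %d", j)))
    }
    return(list(status = "uncorrectable", pid = NA_character_,
                correction = "no unique single-symbol repair"))
  }
  # s0 == 0, s1 != 0: consistent with an adjacent transposition, never
  # with a single substitution; try the 7 swaps and demand uniqueness
  if (length(foreign) == 0L) {
    hits <- integer(0)
    for (j in 1:7) {
      sw <- idx
      sw[c(j, j + 1L)] <- sw[c(j + 1L, j)]
      s <- pid_syndrome(matrix(sw, 1L))
      if (s[1L] == 0L && s[2L] == 0L) hits <- c(hits, j)
    }
    if (length(hits) == 1L) {
      sw <- idx
      sw[c(hits, hits + 1L)] <- sw[c(hits + 1L, hits)]
      pid <- paste(PID_ALPHABET_CHARS[sw + 1L], collapse = "")
      return(list(status = "corrected", pid = pid,
                  correction = sprintf("transposition of positions %d and %d",
                                       hits, hits + 1L)))
    }
  }
  list(status = "uncorrectable", pid = NA_character_,
       correction = "no unique repair found")
}
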
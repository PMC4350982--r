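# Keyed 30-bit permutation used to turn the patient counter into a
# non-speaking payload.
#
# The requirement on this primitive is deliberately modest: it must be a
# deterministic keyed bijection on [0, 2^30) so that (a) every counter
# yields a distinct PID and (b) neither issuance order nor counter value
# is readable from a PID without the three secret keys.  Cryptographic
# attack resistance is a non-goal; pseudonym secrecy rests on the server
# never disclosing the mapping, not on cipher strength.
#
# Construction: an 8-round substitution-permutation network on the
# 30-bit word, viewed as six 5-bit lanes.  Each round XORs a round key
# derived from (k1, k2, k3), pushes every lane through a fixed 5-bit
# S-box, and rotates the word left by 7 bits (7 is coprime to 30, so
# lane contents disperse across lane boundaries between rounds).  A
# single-lane input difference widens by roughly one lane per round;
# eight rounds carry it across all six lanes, so PIDs of nearby counters
# share no visible structure.

PID_COUNTER_MODULUS <- 2^30

# Fixed 5-bit S-box: multiplicative inversion in GF(32) (with 0 -> 0),
# then XOR 0x15.  A permutation of 0..31 with no fixed points.
PID_SBOX <- c(21L, 20L, 7L, 9L, 28L, 2L, 27L, 25L, 3L, 17L, 12L, 5L, 18L,
              26L, 19L, 24L, 30L, 13L, 23L, 8L, 11L, 15L, 29L, 16L, 4L,
              31L, 0L, 10L, 22L, 6L, 1L, 14L)

PID_SBOX_INV <- local({
  inv <- integer(32L)
  inv[PID_SBOX + 1L] <- 0:31
  inv
})

#' Generator key triple
#'
#' Bundles the three secret keys of the pseudonym generator. Keys are
#' 30-bit unsigned integers read from configuration; they are never
#' exposed through the API.
#'
#' @param k1,k2,k3 integers in `[0, 2^30)`.
#' @return an object of class `pid_keys`.
#' @export
#' @examples
#' pid_keys(1, 2, 3)
pid_keys <- function(k1, k2, k3) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3)
  if (any(is.na(ks)) || any(ks != floor(ks)) || any(ks < 0) || any(ks >= PID_COUNTER_MODULUS)) {
    stop("generator keys must be integers in [0, 2^30)", call. = FALSE)
  }
  structure(list(k1 = as.double(k1), k2 = as.double(k2), k3 = as.double(k3)),
            class = "pid_keys")
}

#' @export
print.pid_keys <- function(x, ...) {
  cat("<pid_keys> (3 secret 30-bit keys, values not shown)\n")
  invisible(x)
}

# round keys: k1, k2, k3, k1 xor k2 xor k3, cycled over the 8 rounds
round_keys <- function(keys) {
  stopifnot(inherits(keys, "pid_keys"))
  rk <- c(keys$k1, keys$k2, keys$k3,
          as.double(bitwXor(bitwXor(as.integer(keys$k1), as.integer(keys$k2)),
                            as.integer(keys$k3))))
  rep(rk, 2L)
}

# 30-bit rotate left by 7, vectorised; exact in doubles (values < 2^30)
rotl30_7 <- function(x) (x %% 2^23) * 2^7 + x %/% 2^23

rotr30_7 <- function(x) (x %% 2^7) * 2^23 + x %/% 2^7

# apply a 32-entry lane table to each of the six 5-bit lanes, vectorised
sub_lanes <- function(x, table) {
  out <- 0
  for (i in 0:5) {
    lane <- (x %/% 32^i) %% 32
    out <- out + table[lane + 1L] * 32^i
  }
  out
}

xor30 <- function(x, k) as.double(bitwXor(as.integer(x), as.integer(k)))

check_counter_range <- function(x, what = "counter") {
  if (any(is.na(x)) || any(x != floor(x)) || any(x < 0) || any(x >= PID_COUNTER_MODULUS)) {
    stop(sprintf("%s out of range [0, 2^30)", what), call. = FALSE)
  }
}

#' Encrypt / decrypt a 30-bit counter
#'
#' `encrypt_counter()` maps a counter value through the keyed 30-bit
#' permutation; `decrypt_counter()` is its exact inverse. For fixed keys
#' the map is a bijection on `[0, 2^30)`, so consecutive counters yield
#' scattered, key-dependent values: the basis of non-speaking pseudonyms.
#' Both functions are vectorised over the first argument.
#'
#' @param counter,cipher numeric vector of values in `[0, 2^30)`.
#' @param keys a [pid_keys()] triple.
#' @return numeric vector of values in `[0, 2^30)`.
#' @export
#' @examples
#' k <- pid_keys(11, 22, 33)
#' decrypt_counter(encrypt_counter(0:9, k), k)
encrypt_counter <- function(counter, keys) {
  check_counter_range(counter)
  rk <- round_keys(keys)
  x <- as.double(counter)
  for (r in 1:8) {
    x <- xor30(x, rk[r])
    x <- sub_lanes(x, PID_SBOX)
    x <- rotl30_7(x)
  }
  x
}

#' @rdname encrypt_counter
#' @export
decrypt_counter <- function(cipher, keys) {
  check_counter_range(cipher, "cipher")
  rk <- round_keys(keys)
  x <- as.double(cipher)
  for (r in 8:1) {
    x <- rotr30_7(x)
    x <- sub_lanes(x, PID_SBOX_INV)
    x <- xor30(x, rk[r])
  }
  x
}
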
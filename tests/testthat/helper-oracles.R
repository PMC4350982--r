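# Independent oracles used to freeze expected values.
#
# The cipher oracle below is a deliberate straight-line, bit-vector
# transcription of the round function: every step works on logical
# vectors of length 30 (LSB first) and the S-box is re-derived from
# GF(32) arithmetic implemented as polynomial bit operations, sharing
# no code path with the package.

# small name pools for similarity spot checks (umlauts included)
FIRST_NAME_POOL_TEST <- c("Anna", "Jörg", "Ivan", "Peter", "Maria", "Sören",
                          "Greta", "Heinz", "Ulrike", "Björn", "Karl", "Elena")
LAST_NAME_POOL_TEST <- c("Müller", "Fellegi", "Schmidt", "Weiß", "Krüger",
                         "Schneider", "Vogel", "Böhm", "Wagner", "Straßburger")

# the fixed key triple used across the regression fixtures
test_keys <- function() {
  pid_keys(bitwAnd(0x12345678L, as.integer(2^30 - 1)),
           bitwAnd(0x0FEDCBA9L, as.integer(2^30 - 1)),
           0x0000FFFFL)
}

oracle_to_bits <- function(x, n = 30L) {
  bits <- logical(n)
  for (i in seq_len(n)) {
    bits[i] <- (x %% 2) == 1
    x <- x %/% 2
  }
  bits
}

oracle_from_bits <- function(bits) {
  v <- 0
  for (i in rev(seq_along(bits))) v <- v * 2 + as.numeric(bits[i])
  v
}

# GF(2)[x] multiplication of 5-bit polynomials, reduced mod x^5+x^2+1
oracle_gf_mul <- function(a_bits, b_bits) {
  prod <- logical(9)
  for (i in 1:5) {
    if (a_bits[i]) {
      for (j in 1:5) {
        if (b_bits[j]) prod[i + j - 1] <- xor(prod[i + j - 1], TRUE)
      }
    }
  }
  # reduce: x^(5+k) = x^(2+k) + x^k
  for (d in 9:6) {
    if (prod[d]) {
      prod[d] <- FALSE
      prod[d - 3] <- xor(prod[d - 3], TRUE)
      prod[d - 5] <- xor(prod[d - 5], TRUE)
    }
  }
  prod[1:5]
}

# inversion as a^30 by square-and-multiply (a^31 = 1 for a != 0)
oracle_gf_inv <- function(a_bits) {
  acc <- oracle_to_bits(1, 5L)
  sq <- a_bits
  for (e in 1:4) { # 30 = 2 + 4 + 8 + 16
    sq <- oracle_gf_mul(sq, sq)
    acc <- oracle_gf_mul(acc, sq)
  }
  acc
}

oracle_sbox <- function(lane_bits) {
  if (!any(lane_bits)) {
    inv <- logical(5)
  } else {
    inv <- oracle_gf_inv(lane_bits)
  }
  xor(inv, oracle_to_bits(21, 5L))
}

oracle_encrypt <- function(counter, keys) {
  state <- oracle_to_bits(counter, 30L)
  k1 <- oracle_to_bits(keys$k1, 30L)
  k2 <- oracle_to_bits(keys$k2, 30L)
  k3 <- oracle_to_bits(keys$k3, 30L)
  k4 <- xor(xor(k1, k2), k3)
  rks <- list(k1, k2, k3, k4, k1, k2, k3, k4)
  for (r in 1:8) {
    state <- xor(state, rks[[r]])
    for (lane in 0:5) {
      span <- lane * 5 + 1:5
      state[span] <- oracle_sbox(state[span])
    }
    # rotate left by 7: bit i moves to position (i + 7) mod 30
    rotated <- logical(30)
    for (i in 0:29) rotated[(i + 7) %% 30 + 1] <- state[i + 1]
    state <- rotated
  }
  oracle_from_bits(state)
}

# brute-force check characters: search all 32 x 32 candidate pairs for
# the one making both parity sums vanish
oracle_check <- function(payload) {
  alphabet <- strsplit(pseudolist::PID_ALPHABET, "")[[1]]
  idx <- match(strsplit(payload, "")[[1]], alphabet) - 1L
  gpow <- lapply(1:8, function(j) {
    b <- oracle_to_bits(2, 5L)
    out <- oracle_to_bits(1, 5L)
    for (k in seq_len(j)) out <- oracle_gf_mul(out, b)
    out
  })
  hits <- character(0)
  for (c7 in 0:31) {
    for (c8 in 0:31) {
      word <- c(idx, c7, c8)
      s0 <- logical(5)
      s1 <- logical(5)
      for (j in 1:8) {
        cb <- oracle_to_bits(word[j], 5L)
        s0 <- xor(s0, cb)
        s1 <- xor(s1, oracle_gf_mul(gpow[[j]], cb))
      }
      if (!any(s0) && !any(s1)) {
        hits <- c(hits, paste0(alphabet[c7 + 1], alphabet[c8 + 1]))
      }
    }
  }
  hits
}

# textbook dynamic-programming Levenshtein, for spot-checking adist
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(ca) + 1L, length(cb) + 1L)
  d[, 1L] <- 0:length(ca)
  d[1L, ] <- 0:length(cb)
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + as.integer(ca[i] != cb[j]))
    }
  }
  d[length(ca) + 1L, length(cb) + 1L]
}

# optimal one-to-one component assignment by exhaustive permutation
oracle_name_similarity <- function(a, b) {
  ca <- strsplit(a, " ", fixed = TRUE)[[1]]
  cb <- strsplit(b, " ", fixed = TRUE)[[1]]
  if (length(ca) > length(cb)) {
    tmp <- ca; ca <- cb; cb <- tmp
  }
  k <- length(ca)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (sel in utils::combn(seq_along(cb), k, simplify = FALSE)) {
    for (p in perms(sel)) {
      s <- mean(vapply(seq_len(k), function(i) {
        1 - oracle_levenshtein(ca[i], cb[p[i]]) /
          max(nchar(ca[i]), nchar(cb[p[i]]))
      }, 0))
      best <- max(best, s)
    }
  }
  best
}
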
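# Exhaustive symbol-corruption enumerators for the PID code tests.

# all 8 x 31 single-symbol substitutions of an 8-character PID
single_substitutions <- function(pid, alphabet) {
  out <- character(0)
  for (j in 1:8) {
    orig <- substr(pid, j, j)
    repl <- setdiff(alphabet, orig)
    x <- rep(pid, length(repl))
    substr(x, j, j) <- repl
    out <- c(out, x)
  }
  out
}

# all C(8,2) x 31^2 two-symbol substitutions
double_substitutions <- function(pid, alphabet) {
  out <- vector("list", 28L)
  k <- 0L
  for (j1 in 1:7) {
    for (j2 in (j1 + 1L):8) {
      k <- k + 1L
      r1 <- setdiff(alphabet, substr(pid, j1, j1))
      r2 <- setdiff(alphabet, substr(pid, j2, j2))
      x <- rep(pid, length(r1) * length(r2))
      substr(x, j1, j1) <- rep(r1, each = length(r2))
      substr(x, j2, j2) <- rep(r2, times = length(r1))
      out[[k]] <- x
    }
  }
  unlist(out)
}
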
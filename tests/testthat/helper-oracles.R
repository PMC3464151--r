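# Independent oracles, deliberately written without package internals:
# a plain recursive permutation enumerator and a loop-based average moving
# range, used to cross-check the package's vectorised brute force and the
# closed forms on tiny instances.

enumerate_permutations <- function(v) {
  if (length(v) == 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (rest in enumerate_permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

loop_mr_bar <- function(y) {
  total <- 0
  for (j in seq_len(length(y) - 1)) total <- total + abs(y[j + 1] - y[j])
  total / (length(y) - 1)
}

exhaustive_mr_range <- function(v) {
  mrs <- vapply(enumerate_permutations(v), loop_mr_bar, numeric(1))
  c(min = min(mrs), max = max(mrs))
}

random_dataset <- function(n, seed, integers = FALSE) {
  withr::with_seed(seed, {
    if (integers) sample(0:9, n, replace = TRUE) else round(runif(n, 0, 100), 3)
  })
}
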
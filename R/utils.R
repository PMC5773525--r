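# Internal validation and seeding helpers.

check_prob <- function(x, name, len_ok = TRUE) {
  if (!is.numeric(x) || (!len_ok && length(x) != 1) || anyNA(x) ||
      any(x < 0) || any(x > 1)) {
    stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != floor(x))) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a temporary seed when one is supplied, leaving the
# caller's RNG state untouched; otherwise use the current RNG stream.
run_seeded <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic child seeds: one per (combination index, replicate index).
# Distinct integer seeds give effectively independent Mersenne-Twister
# streams after R's seed scrambling.
child_seed <- function(root, combo, rep) {
  as.integer((as.double(root) + 7919 * as.double(combo) + as.double(rep)) %%
               2147483646) + 1L
}

winner_labels <- c("PCD+", "PCD-", "both_extinct", "timeout_majority_PCD+",
                   "timeout_majority_PCD-", "timeout_tie")

decode_winner <- function(code) winner_labels[code]

decode_target <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == 0] <- "A"
  out[code == 1] <- "B"
  out
}

binom_se <- function(phat, n) sqrt(pmax(phat * (1 - phat), 0) / pmax(n, 1))
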
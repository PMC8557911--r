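# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-visible randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# seed arithmetic stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 7 + offset) %% 2147483647
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

# DNA alphabet check: strict A/C/G/T after uppercasing, no ambiguity codes
validate_dna <- function(sequences, what = "sequence") {
  if (!is.character(sequences) || any(is.na(sequences)) || any(!nzchar(sequences))) {
    stop(sprintf("every %s must be a nonempty character string", what), call. = FALSE)
  }
  up <- toupper(sequences)
  bad <- grepl("[^ACGT]", up)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T} (ambiguity codes are rejected): %s",
                 what, paste(utils::head(which(bad), 3L), collapse = ", ")),
         call. = FALSE)
  }
  up
}
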
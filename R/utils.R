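# Internal helpers shared across modules.

AA_STANDARD <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
SS_STATES <- c("H", "E", "C")
SHAPE_STATES <- c("S", "R", "U", "V", "K", "A", "T", "G")
SHAPE_STATES_X <- c(SHAPE_STATES, "X")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map non-standard amino-acid letters to X, uppercasing first.
normalize_aa <- function(sequence) {
  s <- chars(toupper(sequence))
  s[!s %in% AA_STANDARD] <- "X"
  paste(s, collapse = "")
}

stop_bt <- function(...) stop(sprintf(...), call. = FALSE)
warn_bt <- function(...) warning(sprintf(...), call. = FALSE)
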
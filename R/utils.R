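# internal constants and small helpers shared across modules

# the 20 standard amino acids, in the conventional alphabetical one-letter order
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AAX <- c(AA20, "X")
GAP <- "-"

`%||%` <- function(a, b) if (is.null(a)) b else a

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# first offending position of a character outside `allowed`, or 0L if clean
first_bad_char <- function(x, allowed) {
  ch <- str_chars(x)
  bad <- which(!ch %in% allowed)
  if (length(bad)) bad[1] else 0L
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_kin <- function(...) stop(sprintf(...), call. = FALSE)

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
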
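# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
sigmoid <- function(x) stats::plogis(x)

# Clip probabilities away from {0,1} before taking logs.
clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL leaves the
# ambient stream untouched (draws advance it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Guess the field delimiter of a delimited text line: tab wins over comma.
sniff_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

stop_dims <- function(what, got, want) {
  stop(sprintf("%s: expected dimensions %s, got %s", what,
               paste(want, collapse = "x"), paste(got, collapse = "x")),
       call. = FALSE)
}
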
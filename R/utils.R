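# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize a stream to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific 31-bit seed from a global one, so one experiment seed
# drives every stochastic stage deterministically but independently.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- utils::head(utf8ToInt(stage), 16L)
  x <- (as.double(seed) %% 2147483647) + 1
  for (ch in h) x <- (x * 69069 + ch) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed-precision numeric rendering used across the text channel ("10.2", not
# "10.2000"); vectorized, locale-independent.
render_num <- function(x, digits = 1L) {
  out <- formatC(x, format = "f", digits = digits)
  gsub(" ", "", out, fixed = TRUE)
}

round_half_up <- function(x, digits = 1L) {
  # round() half-to-even would make rendered and stored values disagree for
  # .x5 cases; the text channel needs one convention end to end.
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), jsonlite::fromJSON, simplifyVector = TRUE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
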
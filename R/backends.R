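#' Generative text backend contract
#'
#' A backend is anything that can (a) be fine-tuned on input/target text
#' pairs and (b) sample `k` completions for a prompt. Three implementations
#' ship with the package:
#' \describe{
#'   \item{[backend_echo()]}{deterministic copy-forward through the text
#'     channel: answers with schema-compliant JSON repeating each target's
#'     last value found in the prompt's history section (training median when
#'     absent). Fine-tuning is a no-op that records corpus statistics.}
#'   \item{[backend_tinylm()]}{a tiny trainable causal transformer language
#'     model (Rcpp), fine-tuned with next-token cross entropy masked to the
#'     target text.}
#'   \item{[backend_external()]}{an adapter wrapping any external
#'     instruction-tuned LLM behind a user-supplied generation function; no
#'     weights ship with the package.}
#' }
#'
#' @param backend A backend object.
#' @param pairs List of `encoded_example` objects (nonempty).
#' @param ... Passed to methods.
#' @return `fine_tune` returns the trained backend; `generate_text` a
#'   character vector of exactly `k` completions.
#' @name backend
NULL

#' @rdname backend
#' @export
fine_tune <- function(backend, pairs, ...) UseMethod("fine_tune")

#' @rdname backend
#' @param prompt Input text.
#' @param k Number of completions (>= 1).
#' @param schema Optional decode schema (consumed by the echo backend, which
#'   must know which cells to emit).
#' @param seed Optional seed; stochastic backends are reproducible given it.
#' @export
generate_text <- function(backend, prompt, k = 1L, schema = NULL,
                          seed = NULL, ...) UseMethod("generate_text")

# ---- echo backend ----------------------------------------------------------

#' Copy-forward echo backend
#'
#' A pure text-channel baseline: its completions are valid JSON produced by
#' reading the prompt's history section and repeating, for every schema cell,
#' the last observed value of that variable (the training-split median,
#' recorded during `fine_tune`, when the variable never appears in the
#' prompt). All `k` completions are identical. Running the full pipeline with
#' this backend must reproduce the native copy-forward baseline exactly,
#' which pins down the correctness of the encode/generate/decode channel.
#'
#' @param precision Decimal rendering precision (must match the template).
#' @return A backend of class `echo_backend`.
#' @export
backend_echo <- function(precision = 1L) {
  structure(list(precision = as.integer(precision), medians = numeric(0)),
            class = c("echo_backend", "twin_backend"))
}

#' @export
fine_tune.echo_backend <- function(backend, pairs, ...) {
  stopifnot(length(pairs) > 0L)
  pool <- list()
  for (p in pairs) {
    if (is.null(p$target)) next
    dec <- decode_forecast(p$target, p$schema)
    for (v in names(dec$values)) {
      pool[[v]] <- c(pool[[v]], unname(dec$values[[v]]))
    }
  }
  backend$medians <- vapply(pool, function(x) {
    round_half_up(stats::median(x), backend$precision)
  }, numeric(1L))
  backend$n_pairs <- length(pairs)
  backend
}

# Last "variable=<number>" occurrence in the prompt, per variable; prompt
# history lines are chronological so the last match is the latest bin.
prompt_last_values <- function(prompt, variables) {
  out <- stats::setNames(rep(NA_real_, length(variables)), variables)
  for (v in variables) {
    pat <- paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", v),
                  "=(-?[0-9]+\\.?[0-9]*)")
    m <- gregexpr(pat, prompt, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    last <- length(m)
    frag <- substr(prompt, m[last],
                   m[last] + attr(m, "match.length")[last] - 1L)
    out[[v]] <- as.numeric(sub(pat, "\\1", frag, perl = TRUE))
  }
  out
}

#' @export
generate_text.echo_backend <- function(backend, prompt, k = 1L, schema = NULL,
                                       seed = NULL, ...) {
  stopifnot(k >= 1L)
  if (is.null(schema) || nrow(schema) == 0L) {
    return(rep("{}", k))
  }
  vars <- unique(schema$variable)
  last <- prompt_last_values(prompt, vars)
  parts <- vapply(vars, function(v) {
    val <- last[[v]]
    if (is.na(val)) val <- backend$medians[[v]] %||% NA_real_
    sub <- schema[schema$variable == v, , drop = FALSE]
    cells <- paste0('"', sub$label, '": ',
                    if (is.na(val)) "null" else
                      render_num(val, backend$precision))
    paste0('"', v, '": {', paste(cells, collapse = ", "), "}")
  }, character(1L))
  rep(paste0("{", paste(parts, collapse = ", "), "}"), k)
}

# ---- external adapter ------------------------------------------------------

#' External LLM adapter backend
#'
#' Wraps an arbitrary text-generation function (e.g. an API client for an
#' instruction-tuned LLM) in the backend contract. The function receives
#' `(prompt, k, seed)` and must return `k` completion strings. Fine-tuning is
#' not performed through the adapter; `fine_tune` records the corpus size and
#' returns the backend unchanged.
#'
#' @param generate_fun `function(prompt, k, seed)` returning `character(k)`.
#' @return A backend of class `external_backend`.
#' @export
backend_external <- function(generate_fun) {
  stopifnot(is.function(generate_fun))
  structure(list(generate_fun = generate_fun),
            class = c("external_backend", "twin_backend"))
}

#' @export
fine_tune.external_backend <- function(backend, pairs, ...) {
  backend$n_pairs <- length(pairs)
  backend
}

#' @export
generate_text.external_backend <- function(backend, prompt, k = 1L,
                                           schema = NULL, seed = NULL, ...) {
  out <- backend$generate_fun(prompt, k, seed)
  if (!is.character(out) || length(out) != k) {
    stop("external backend must return exactly k completion strings")
  }
  out
}

#' Canned-response backend
#'
#' Test double for the external adapter: returns the supplied responses
#' cyclically, ignoring the prompt.
#'
#' @param responses Character vector of responses to cycle through.
#' @return An `external_backend`.
#' @export
backend_canned <- function(responses) {
  stopifnot(is.character(responses), length(responses) >= 1L)
  i <- 0L
  backend_external(function(prompt, k, seed) {
    idx <- ((i + seq_len(k) - 1L) %% length(responses)) + 1L
    i <<- i + k
    responses[idx]
  })
}
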
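#' Prompt template for serializing examples to text
#'
#' The input serialization has four sections, rendered deterministically:
#' (1) patient history -- one line per time bin, chronological, listing only
#' the observed `variable=value` pairs (missing cells are simply absent, no
#' imputation); (2) patient information -- the static attributes; (3) forecast
#' dates -- the requested horizon offsets; (4) the instruction sentence fixing
#' the JSON output contract. Offsets are rendered as `"<unit> <k>"`
#' (e.g. `"week 3"`); numbers with a fixed decimal precision.
#'
#' @param precision Decimal places for numeric values in prompts and targets.
#' @param headers Named character vector with elements `history`, `statics`,
#'   `dates` (unique section headers).
#' @return An object of class `prompt_template`.
#' @export
prompt_template <- function(precision = 1L,
                            headers = c(history = "Patient history:",
                                        statics = "Patient information:",
                                        dates = "Forecast dates:")) {
  stopifnot(all(c("history", "statics", "dates") %in% names(headers)),
            !anyDuplicated(headers))
  structure(list(precision = as.integer(precision), headers = headers),
            class = "prompt_template")
}

offset_label <- function(unit_label, offset) paste(unit_label, offset)

render_value <- function(value, precision) {
  num <- suppressWarnings(as.numeric(value))
  ifelse(is.na(num), as.character(value), render_num(num, precision))
}

#' Serialize a forecast example's input to prompt text
#'
#' @param example A `forecast_example` (binned, landmark at time 0).
#' @param template A [prompt_template()].
#' @return A single character string.
#' @export
encode_input <- function(example, template = prompt_template()) {
  stopifnot(inherits(example, "forecast_example"),
            inherits(template, "prompt_template"))
  unit <- example$unit_label
  hdr <- template$headers
  lines <- character(0)

  hist <- example$history
  if (nrow(hist)) {
    lines <- c(lines, hdr[["history"]])
    for (t in sort(unique(hist$time))) {
      rows <- hist[hist$time == t, , drop = FALSE]
      rows <- rows[order(match(rows$variable, unique(hist$variable))), , drop = FALSE]
      pairs <- paste0(rows$variable, "=",
                      render_value(rows$value, template$precision))
      lines <- c(lines, paste0(offset_label(unit, t), ": ",
                               paste(pairs, collapse = "; ")))
    }
  }

  lines <- c(lines, hdr[["statics"]])
  if (length(example$statics)) {
    lines <- c(lines, paste(paste0(names(example$statics), "=",
                                   example$statics), collapse = "; "))
  }
  lines <- c(lines, hdr[["dates"]],
             paste(vapply(example$horizons, offset_label,
                          character(1L), unit_label = unit),
                   collapse = ", "),
             paste0("Predict the values of ",
                    paste(example$targets, collapse = ", "),
                    " at the forecast dates. Answer with a JSON object ",
                    "mapping each variable name to an object mapping each ",
                    "forecast date to the predicted value."))
  paste(lines, collapse = "\n")
}

#' Output schema of an encoded example
#'
#' The ordered (target variable, horizon offset) cells expected in the JSON
#' output: all configured targets x horizons at prediction time, or only the
#' observed truth cells for a training target.
#'
#' @param example A `forecast_example`.
#' @param observed_only Restrict to cells with observed truth.
#' @return data.frame with columns `variable`, `offset`, `label`.
#' @export
target_schema <- function(example, observed_only = FALSE) {
  rows <- lapply(example$targets, function(v) {
    offs <- if (observed_only) {
      if (is.null(example$truth[[v]])) integer(0) else
        as.integer(names(example$truth[[v]]))
    } else {
      example$horizons
    }
    if (length(offs) == 0L) return(NULL)
    data.frame(variable = v, offset = offs,
               label = offset_label(example$unit_label, offs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(variable = character(), offset = integer(),
                      label = character())
}

#' Serialize observed future targets to JSON text
#'
#' Produces the training target: a JSON object mapping each target variable
#' to an object of `"<unit> <offset>": value` pairs, containing exactly the
#' observed truth cells, in fixed key order (task target order, ascending
#' offsets), numbers rendered at template precision.
#'
#' @inheritParams encode_input
#' @return A JSON string.
#' @export
encode_target <- function(example, template = prompt_template()) {
  stopifnot(inherits(example, "forecast_example"))
  if (length(example$truth) == 0L) {
    stop("example has no observed future target values")
  }
  parts <- vapply(example$targets[example$targets %in% names(example$truth)],
                  function(v) {
    tv <- example$truth[[v]]
    tv <- tv[order(as.integer(names(tv)))]
    cells <- paste0('"', offset_label(example$unit_label, names(tv)), '": ',
                    render_num(tv, template$precision))
    paste0('"', v, '": {', paste(cells, collapse = ", "), "}")
  }, character(1L))
  paste0("{", paste(parts, collapse = ", "), "}")
}

#' Encode an example to an input/target text pair
#'
#' @inheritParams encode_input
#' @param observed_only Schema restricted to observed truth cells (training
#'   convention) or the full target x horizon grid (prediction convention).
#' @return An `encoded_example`: list with `input`, `target` (JSON string or
#'   `NULL` when the example carries no truth and `observed_only = FALSE`),
#'   `schema`, and the originating `example`.
#' @export
encode_example <- function(example, template = prompt_template(),
                           observed_only = TRUE) {
  structure(list(
    input = encode_input(example, template),
    target = if (length(example$truth)) encode_target(example, template) else NULL,
    schema = target_schema(example, observed_only = observed_only),
    example = example, template = template),
    class = "encoded_example")
}

# Balanced-brace candidate JSON substrings of `text`, in order of start.
json_candidates <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  starts <- which(chars == "{")
  out <- character(0)
  used_end <- -1L
  for (s in starts) {
    if (s <= used_end) next
    depth <- 0L; in_str <- FALSE; esc <- FALSE
    for (i in s:length(chars)) {
      ch <- chars[i]
      if (in_str) {
        if (esc) esc <- FALSE
        else if (ch == "\\") esc <- TRUE
        else if (ch == '"') in_str <- FALSE
      } else if (ch == '"') in_str <- TRUE
      else if (ch == "{") depth <- depth + 1L
      else if (ch == "}") {
        depth <- depth - 1L
        if (depth == 0L) {
          out <- c(out, substr(text, s, i))
          used_end <- i
          break
        }
      }
    }
  }
  out
}

#' Tolerantly decode generated text into forecast values
#'
#' Locates the first parseable JSON object in the text (prose before or after
#' is ignored) and extracts a numeric value for every schema cell present.
#' Missing or non-numeric cells are skipped; parse failures are data, not
#' errors.
#'
#' @param text Generated text.
#' @param schema Schema data.frame from [target_schema()].
#' @return A `decoded_forecast`: list with `values` (named list
#'   variable -> named numeric vector by offset), `status`
#'   (`"ok"`/`"partial"`/`"failed"`), `n_expected`, `n_extracted`.
#' @export
decode_forecast <- function(text, schema) {
  n_expected <- nrow(schema)
  parsed <- NULL
  if (is_string(text) && nzchar(text)) {
    for (cand in json_candidates(text)) {
      parsed <- tryCatch(jsonlite::fromJSON(cand, simplifyVector = FALSE),
                         error = function(e) NULL)
      if (is.list(parsed)) break
      parsed <- NULL
    }
  }
  values <- list()
  n_extracted <- 0L
  if (is.list(parsed)) {
    for (v in unique(schema$variable)) {
      sub <- schema[schema$variable == v, , drop = FALSE]
      node <- parsed[[v]]
      if (!is.list(node)) next
      got <- numeric(0)
      for (j in seq_len(nrow(sub))) {
        cell <- node[[sub$label[j]]]
        num <- suppressWarnings(as.numeric(cell))
        if (length(num) == 1L && is.finite(num)) {
          got[as.character(sub$offset[j])] <- num
        }
      }
      if (length(got)) {
        values[[v]] <- got
        n_extracted <- n_extracted + length(got)
      }
    }
  }
  status <- if (n_extracted == 0L) "failed"
            else if (n_extracted == n_expected) "ok" else "partial"
  structure(list(values = values, status = status,
                 n_expected = n_expected, n_extracted = n_extracted),
            class = "decoded_forecast")
}

#' Inject random misspellings into text
#'
#' Applies `n` independent single-character edit operations, each drawn
#' uniformly from perturbation (adjacent-character swap), insertion, deletion
#' and replacement, at uniformly chosen positions, with inserted/replacement
#' characters drawn uniformly from the ASCII letters and digits. The whole
#' text is eligible, including dates, variable names and values. One
#' operation is one misspelling. Operations infeasible on the current text
#' (deletion/swap on too-short text) are re-drawn as insertions.
#'
#' @param text Input text.
#' @param n Number of operations (>= 0).
#' @param seed Optional seed for reproducibility.
#' @return The perturbed text, with the operation log as attribute `"ops"`
#'   (data.frame: op, position).
#' @export
inject_misspellings <- function(text, n, seed = NULL) {
  stopifnot(is_string(text), n >= 0)
  alphabet <- c(letters, LETTERS, as.character(0:9))
  ops_pool <- c("perturbation", "insertion", "deletion", "replacement")
  with_seed(seed, {
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    log <- vector("list", n)
    for (j in seq_len(n)) {
      op <- sample(ops_pool, 1L)
      len <- length(chars)
      if ((op %in% c("deletion", "replacement") && len < 1L) ||
          (op == "perturbation" && len < 2L)) {
        op <- "insertion"
      }
      pos <- switch(op,
        insertion = sample.int(len + 1L, 1L),
        perturbation = sample.int(len - 1L, 1L),
        sample.int(len, 1L))
      chars <- switch(op,
        perturbation = { tmp <- chars[pos]; chars[pos] <- chars[pos + 1L]
                         chars[pos + 1L] <- tmp; chars },
        insertion = append(chars, sample(alphabet, 1L), after = pos - 1L),
        deletion = chars[-pos],
        replacement = { chars[pos] <- sample(alphabet, 1L); chars })
      log[[j]] <- data.frame(op = op, position = pos)
    }
    out <- paste(chars, collapse = "")
    attr(out, "ops") <- if (n > 0) do.call(rbind, log) else
      data.frame(op = character(), position = integer())
    out
  })
}

#' Randomly mask history observations
#'
#' Removes each history observation independently with the given probability,
#' emulating additional input missingness on top of the dataset's own. The
#' future truth and the recorded evaluation constants (baseline values) are
#' never touched.
#'
#' @param example A `forecast_example`.
#' @param fraction Masking probability in `[0, 1]`.
#' @param seed Optional seed.
#' @return The example with thinned history.
#' @export
mask_observations <- function(example, fraction, seed = NULL) {
  stopifnot(inherits(example, "forecast_example"),
            fraction >= 0, fraction <= 1)
  if (fraction == 0 || nrow(example$history) == 0L) return(example)
  with_seed(seed, {
    keep <- stats::runif(nrow(example$history)) >= fraction
    example$history <- example$history[keep, , drop = FALSE]
    example
  })
}

#' Build a zero-shot forecasting prompt
#'
#' Appends, to the standard input serialization, an instruction to forecast a
#' variable the model was never trained to output, at the requested offsets,
#' under the same JSON output contract, so the answer decodes through
#' [decode_forecast()].
#'
#' @param example A `forecast_example`.
#' @param registry A [variable_registry()]; the variable must exist in it.
#' @param variable New variable to forecast.
#' @param offsets Requested horizon offsets.
#' @param template A [prompt_template()].
#' @return List with `text` and the expected `schema`.
#' @export
build_zero_shot_prompt <- function(example, registry, variable, offsets,
                                   template = prompt_template()) {
  if (is.null(registry[[variable]])) stop("unknown variable: ", variable)
  labels <- offset_label(example$unit_label, offsets)
  base <- encode_input(example, template)
  text <- paste0(
    base, "\n",
    "Now predict the values of ", variable, " at ",
    paste(labels, collapse = ", "),
    ". Answer with a JSON object mapping the variable name to an object ",
    "mapping each forecast date to the predicted value.")
  list(text = text,
       schema = data.frame(variable = variable, offset = as.integer(offsets),
                           label = labels, stringsAsFactors = FALSE))
}

#' Build an explanation-request prompt
#'
#' Asks, in the context of a completed forecast, for the most important
#' variables influencing the predicted trajectory.
#'
#' @param example A `forecast_example`.
#' @param forecast_text The model's forecast answer (JSON text) to carry in
#'   the chat context.
#' @param template A [prompt_template()].
#' @return A single character string.
#' @export
build_explanation_prompt <- function(example, forecast_text,
                                     template = prompt_template()) {
  paste0(encode_input(example, template), "\n",
         "Forecast: ", forecast_text, "\n",
         "Which variables were most important in influencing the predicted ",
         "trajectory? List them in order of importance.")
}

#' Extract ranked variable mentions from an explanation
#'
#' Scans a free-text explanation for mentions of registry variable names
#' (case-insensitive) and returns them in order of first appearance. An
#' answer mentioning no registry variable is a failed extraction.
#'
#' @param text Model response text.
#' @param registry A [variable_registry()].
#' @return Character vector of variable names in mention order, with
#'   attribute `"status"` (`"ok"` or `"failed"`).
#' @export
parse_explanation <- function(text, registry) {
  if (!is_string(text)) text <- ""
  low <- tolower(text)
  pos <- vapply(names(registry), function(v) {
    hit <- regexpr(tolower(v), low, fixed = TRUE)
    as.integer(hit)
  }, integer(1L))
  found <- pos[pos > 0L]
  out <- names(sort(found))
  attr(out, "status") <- if (length(out)) "ok" else "failed"
  out
}
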
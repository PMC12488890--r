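# Word-level reversible tokenizer for the tiny causal LM. A token is a
# newline, a numeric literal, a word, or a single punctuation character, each
# optionally absorbing one leading space (GPT-style), so that concatenating
# tokens reproduces the text byte for byte.
TLM_TOKEN_PATTERN <- "\n| ?-?[0-9]+(\\.[0-9]+)?| ?[A-Za-z_/][A-Za-z0-9_/]*| ?[^A-Za-z0-9 \n]| "

tlm_tokenize <- function(text) {
  m <- gregexpr(TLM_TOKEN_PATTERN, text, perl = TRUE)[[1L]]
  toks <- regmatches(text, list(m))[[1L]]
  if (paste(toks, collapse = "") != text) {
    stop("tokenizer failed to cover text losslessly")
  }
  toks
}

# Special ids (1-based in R; the C++ core is 0-based).
TLM_UNK <- 1L
TLM_BOS <- 2L
TLM_EOS <- 3L

tlm_build_vocab <- function(token_lists) {
  toks <- sort(unique(unlist(token_lists)))
  c("<unk>", "<bos>", "<eos>", toks)
}

tlm_ids <- function(tokens, vocab) {
  idx <- match(tokens, vocab)
  idx[is.na(idx)] <- TLM_UNK
  idx
}

#' Tiny trainable causal language-model backend
#'
#' A small causal transformer (token + positional embeddings, pre-norm
#' self-attention blocks, ReLU feed-forward, tied-size output head)
#' implemented in compiled code and trained with next-token cross entropy
#' masked so the gradient flows only from the target-text tokens -- the same
#' text-channel learning contract a large fine-tuned LLM follows, at a scale
#' trainable on one CPU in minutes. Sampling uses temperature plus nucleus
#' (top-p) truncation; all randomness is governed by R's RNG, so a seed makes
#' training and generation fully reproducible.
#'
#' @param d_model Embedding width. @param n_heads Attention heads.
#' @param d_ff Feed-forward width. @param n_layers Transformer blocks.
#' @param max_len Maximum sequence length (prompt + target + specials).
#' @param epochs,lr,batch_size Training schedule (Adam).
#' @param temperature,top_p Sampling parameters.
#' @param truncation `"error"` rejects over-length training pairs (reporting
#'   the pair index); `"truncate"` drops tokens from the front of the input
#'   section.
#' @return A backend of class `tinylm_backend`.
#' @export
backend_tinylm <- function(d_model = 64L, n_heads = 2L, d_ff = 128L,
                           n_layers = 1L, max_len = 320L, epochs = 10L,
                           lr = 2e-3, batch_size = 16L, temperature = 1,
                           top_p = 0.9, truncation = c("error", "truncate")) {
  truncation <- match.arg(truncation)
  stopifnot(temperature > 0, top_p > 0, top_p <= 1)
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_ff = as.integer(d_ff), n_layers = as.integer(n_layers),
                 max_len = as.integer(max_len), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 temperature = temperature, top_p = top_p,
                 truncation = truncation, model = NULL, vocab = NULL),
            class = c("tinylm_backend", "twin_backend"))
}

# Compose one training sequence: <bos> input target <eos>; loss positions are
# the 0-based indices whose next token lies in the target (incl. <eos>).
tlm_make_sequence <- function(input_ids, target_ids, max_len, truncation,
                              pair_index) {
  n_over <- length(input_ids) + length(target_ids) + 2L - max_len
  if (n_over > 0L) {
    if (truncation == "error") {
      stop("training pair ", pair_index, " exceeds max_len by ", n_over,
           " tokens")
    }
    if (n_over >= length(input_ids)) {
      stop("training pair ", pair_index, " cannot fit even after input truncation")
    }
    input_ids <- input_ids[-seq_len(n_over)]
  }
  seq_ids <- c(TLM_BOS, input_ids, target_ids, TLM_EOS)
  n_in <- length(input_ids)
  # 0-based positions predicting target tokens and <eos>
  mask0 <- seq.int(n_in + 1L, length(seq_ids) - 1L) - 1L
  list(ids = seq_ids, mask = mask0)
}

#' @export
fine_tune.tinylm_backend <- function(backend, pairs, seed = NULL, ...) {
  stopifnot(length(pairs) > 0L)
  inputs <- lapply(pairs, function(p) tlm_tokenize(p$input))
  targets <- lapply(pairs, function(p) {
    if (is.null(p$target)) stop("tinylm fine-tuning needs target texts")
    tlm_tokenize(p$target)
  })
  vocab <- tlm_build_vocab(c(inputs, targets))
  seqs <- vector("list", length(pairs))
  masks <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    s <- tlm_make_sequence(tlm_ids(inputs[[i]], vocab),
                           tlm_ids(targets[[i]], vocab),
                           backend$max_len, backend$truncation, i)
    seqs[[i]] <- s$ids - 1L # 0-based for the compiled core
    masks[[i]] <- s$mask
  }
  with_seed(seed, {
    model <- tlm_init_cpp(length(vocab), backend$d_model, backend$n_heads,
                          backend$d_ff, backend$n_layers, backend$max_len)
    model <- tlm_train_cpp(model, seqs, masks, backend$epochs, backend$lr,
                           backend$batch_size)
  })
  backend$model <- model
  backend$vocab <- vocab
  backend$loss_curve <- as.numeric(model$epoch_loss)
  backend$max_new <- max(vapply(targets, length, integer(1L))) + 2L
  backend$n_pairs <- length(pairs)
  backend
}

#' @export
generate_text.tinylm_backend <- function(backend, prompt, k = 1L,
                                         schema = NULL, seed = NULL, ...) {
  if (is.null(backend$model)) stop("backend has not been fine-tuned")
  stopifnot(k >= 1L)
  ids <- c(TLM_BOS, tlm_ids(tlm_tokenize(prompt), backend$vocab))
  max_new <- backend$max_new %||% 64L
  room <- backend$max_len - max_new
  if (length(ids) > room) ids <- c(TLM_BOS, utils::tail(ids[-1L], room - 1L))
  gen <- with_seed(seed, {
    tlm_generate_cpp(backend$model, ids - 1L, as.integer(k),
                     as.integer(max_new), backend$temperature, backend$top_p,
                     TLM_EOS - 1L)
  })
  vapply(gen, function(g) {
    g <- g + 1L
    g <- g[g != TLM_EOS]
    paste(backend$vocab[g], collapse = "")
  }, character(1L))
}

# Mean per-token loss of the backend on one encoded pair (diagnostics).
tinylm_pair_loss <- function(backend, pair) {
  s <- tlm_make_sequence(tlm_ids(tlm_tokenize(pair$input), backend$vocab),
                         tlm_ids(tlm_tokenize(pair$target), backend$vocab),
                         backend$max_len, backend$truncation, 1L)
  mean(tlm_position_loss_cpp(backend$model, s$ids - 1L, s$mask))
}
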
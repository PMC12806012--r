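#' Transformer model configuration
#'
#' Hyperparameters of the pair transformer. Defaults follow the method's
#' reference setting: 3 layers, 8 heads, dropout 0.2, learning rate 1e-4,
#' batch size 20. The feed-forward width defaults to `2 * d_model`, sized
#' for the desk-scale problems the package targets (the reference
#' configuration pins the other settings but not this one). The model
#' dimension is the encoding width: 72 for SPE (64 node-embedding + 8 GPE
#' columns), 64 for NoPE/LPE.
#'
#' @param layers Encoder and decoder layer count.
#' @param heads Attention heads; must divide `d_model`.
#' @param d_model Token dimension.
#' @param ff_dim Feed-forward hidden width.
#' @param dropout Dropout rate on each sublayer output.
#' @param lr Adam learning rate.
#' @param batch_size Pairs per gradient step.
#' @return A `model_config` list.
#' @export
model_config <- function(layers = 3L, heads = 8L, d_model = 72L,
                         ff_dim = 2L * d_model, dropout = 0.2,
                         lr = 1e-4, batch_size = 20L) {
  stopifnot(layers >= 1, heads >= 1, d_model >= 1, ff_dim >= 1,
            dropout >= 0, dropout < 1, lr >= 0, batch_size >= 1)
  if (d_model %% heads != 0) abort("d_model must be divisible by heads")
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 d_model = as.integer(d_model), ff_dim = as.integer(ff_dim),
                 dropout = dropout, lr = lr, batch_size = as.integer(batch_size)),
            class = "model_config")
}

#' Initialize a pair-transformer model
#'
#' Allocates Xavier-initialized parameters for the encoder-decoder
#' transformer and its scoring head, reproducibly from `seed`.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `tspe_model`: list with `params` (flat
#'   numeric vector), `cfg` and `seed`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  structure(list(params = tspe_init_cpp(unclass(cfg), as.integer(seed)),
                 cfg = cfg, seed = as.integer(seed)),
            class = "tspe_model")
}

#' @export
print.tspe_model <- function(x, ...) {
  cat(sprintf("<tspe_model> %d layers, %d heads, d_model %d, %d parameters\n",
              x$cfg$layers, x$cfg$heads, x$cfg$d_model, length(x$params)))
  invisible(x)
}

#' Run the encoder-decoder over one disease pair
#'
#' The first disease's token matrix feeds the encoder (self-attention),
#' the second the decoder (unmasked self-attention plus cross-attention
#' to the encoder memory). No positional order is injected inside the
#' transformer, so token order is immaterial up to numerical noise.
#' Padded positions, when masks are supplied, are excluded from attention
#' as keys and dropped from the output, so they cannot influence real
#' tokens. Inference mode: dropout is off.
#'
#' @param model A `tspe_model`.
#' @param Ea Token matrix of disease A (`n_A x d_model`).
#' @param Eb Token matrix of disease B (`n_B x d_model`).
#' @param mask_a,mask_b Optional logical vectors marking *real* (TRUE) vs
#'   padded (FALSE) rows of `Ea` / `Eb`.
#' @return The interaction matrix `X` (`d_model x n_B_real`): column `j`
#'   is the decoder output for the `j`-th real token of disease B.
#' @export
encode_decode <- function(model, Ea, Eb, mask_a = NULL, mask_b = NULL) {
  out <- forward_pair(model, Ea, Eb, mask_a, mask_b)
  out$X
}

#' Full forward pass for one disease pair
#'
#' Composes the transformer with the scoring head: softmax over squared
#' column norms of the interaction matrix, score-weighted pooling, and a
#' linear + sigmoid read-out.
#'
#' @inheritParams encode_decode
#' @return List with `X` (interaction matrix), `s` (simplex score vector),
#'   `y_pool` (pooled vector), `logit` and `prob`.
#' @export
forward_pair <- function(model, Ea, Eb, mask_a = NULL, mask_b = NULL) {
  stopifnot(inherits(model, "tspe_model"))
  Ea <- as.matrix(Ea); Eb <- as.matrix(Eb)
  if (nrow(Ea) < 1 || nrow(Eb) < 1) abort("each disease needs at least one node")
  if (!is.null(mask_a)) mask_a <- as.numeric(mask_a)
  if (!is.null(mask_b)) {
    if (sum(mask_b) < 1) abort("mask_b leaves no real token")
    mask_b <- as.numeric(mask_b)
  }
  out <- tspe_forward_cpp(model$params, Ea, Eb, unclass(model$cfg), mask_a, mask_b)
  out$s <- as.numeric(out$s)
  out$y_pool <- as.numeric(out$y_pool)
  out
}

#' Column-norm softmax scores of an interaction matrix
#'
#' Reference implementation of the scoring step: `s_j` is the softmax of
#' the squared L2 norms of the columns of `X`. Returns a simplex vector
#' (sums to 1).
#'
#' @param X Interaction matrix (`m x n`), `n >= 1`.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' column_scores(cbind(c(1, 0), c(0, 1)))  # c(0.5, 0.5)
column_scores <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 0) abort("interaction matrix has no columns")
  if (!all(is.finite(X))) abort("interaction matrix has non-finite entries")
  cn <- colSums(X^2)
  e <- exp(cn - max(cn))
  e / sum(e)
}

#' Score-weighted pooling of an interaction matrix
#'
#' `y' = sum_j s_j X[, j]`, i.e. the row sums of `X %*% diag(s)`.
#'
#' @param X Interaction matrix (`m x n`).
#' @param s Simplex weight vector of length `n`.
#' @return Numeric vector of length `m`.
#' @export
weighted_pool <- function(X, s) {
  X <- as.matrix(X)
  if (length(s) != ncol(X)) abort("weight vector length must equal column count")
  as.numeric(X %*% s)
}

#' Linear + sigmoid read-out
#'
#' @param y_pool Pooled vector (length `m`).
#' @param w Head weights (length `m`).
#' @param b Head bias (scalar).
#' @return List with `logit`, `prob` and the score provenance.
#' @export
predict_logit <- function(y_pool, w, b = 0) {
  if (length(w) != length(y_pool)) abort("head weight length mismatch")
  logit <- sum(w * y_pool) + b
  list(logit = logit, prob = 1 / (1 + exp(-logit)))
}

#' Binary cross-entropy loss from logits
#'
#' Mean of `-[y log p + (1 - y) log(1 - p)]` with `p = sigmoid(logit)`,
#' computed in the numerically stable fused form
#' `max(l, 0) - l y + log(1 + exp(-|l|))`.
#'
#' @param logits Numeric vector of logits.
#' @param labels Vector of 0/1 labels, same length.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' bce_loss(0, 1)  # log(2)
bce_loss <- function(logits, labels) {
  if (length(logits) != length(labels)) abort("logits and labels differ in length")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

# mean batch loss and flat gradient; training-time entry point
batch_loss_grad <- function(model, Ea_list, Eb_list, labels, dropout, seed) {
  tspe_loss_grad_cpp(model$params, Ea_list, Eb_list, as.numeric(labels),
                     unclass(model$cfg), dropout, as.integer(seed))
}

#' Predict comorbidity probabilities for disease pairs
#'
#' @param object A trained `tspe_model` (or `tspe_fit`).
#' @param pairs Data frame with `disease_a`, `disease_b` (disease indices).
#' @param enc An `encoding_bundle`.
#' @param dm A `disease_map`.
#' @param ... Unused.
#' @return The pairs tibble with `logit` and `prob` columns added.
#' @export
predict.tspe_model <- function(object, pairs, enc, dm, ...) {
  stopifnot(inherits(enc, "encoding_bundle"), inherits(dm, "disease_map"))
  toks <- disease_tokens(enc, dm)
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    forward_pair(object, toks[[pairs$disease_a[i]]], toks[[pairs$disease_b[i]]])
  })
  out <- tibble::as_tibble(pairs)
  out$logit <- vapply(res, `[[`, numeric(1), "logit")
  out$prob <- vapply(res, `[[`, numeric(1), "prob")
  out
}

# per-disease token matrices (rows of E for each disease module)
disease_tokens <- function(enc, dm) {
  lapply(dm$members, function(m) enc$E[m, , drop = FALSE])
}
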
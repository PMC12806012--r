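#' Training-run configuration
#'
#' Settings of one training run: the validation fraction carved out of the
#' training pairs (used for early stopping and for fitting the Youden
#' threshold, never the test fold), the epoch budget, early-stopping
#' patience on validation loss, and a burn-in before which no checkpoint
#' is eligible. The burn-in matters when the validation split is small:
#' an untrained model's loss sits near `log(2)` and can win "best
#' validation loss" by noise before the optimizer has moved at all, so
#' epochs below `min_epochs` are logged but neither checkpointed nor
#' counted toward patience.
#'
#' @param valid_frac Fraction of training pairs held out for validation.
#' @param max_epochs Maximum epochs.
#' @param patience Epochs without validation improvement before stopping.
#' @param min_epochs Burn-in epochs excluded from checkpoint selection.
#' @param augment_swap Add the swapped orientation of every training pair
#'   (after the validation split, so no orientation of a validation pair
#'   is trained on). The architecture is not symmetric in the pair order;
#'   training on both orientations imposes the symmetry of the comorbidity
#'   relation as an inductive prior, which matters in small-sample
#'   regimes where order-specific memorization otherwise dominates.
#' @param seed Integer seed driving the split, batch shuffling and dropout.
#' @return A `train_run` list.
#' @export
train_run <- function(valid_frac = 0.1, max_epochs = 100L, patience = 10L,
                      min_epochs = 1L, augment_swap = FALSE, seed = 1L) {
  stopifnot(valid_frac > 0, valid_frac < 1, max_epochs >= 1, patience >= 1,
            min_epochs >= 1, min_epochs <= max_epochs,
            is.logical(augment_swap))
  structure(list(valid_frac = valid_frac, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 augment_swap = isTRUE(augment_swap), seed = as.integer(seed)),
            class = "train_run")
}

# stratified validation split; redraws (with a warning) if a class ends up
# empty on either side
split_validation <- function(labels, valid_frac, seed) {
  n <- length(labels)
  n_valid <- max(2L, round(valid_frac * n))
  for (try in 0:24) {
    withr::with_seed(seed + try, {
      idx_pos <- which(labels == 1)
      idx_neg <- which(labels == 0)
      k_pos <- round(n_valid * length(idx_pos) / n)
      k_pos <- min(max(k_pos, 1L), length(idx_pos) - 1L)
      k_neg <- n_valid - k_pos
      k_neg <- min(max(k_neg, 1L), length(idx_neg) - 1L)
      valid <- c(sample(idx_pos, k_pos), sample(idx_neg, k_neg))
    })
    train <- setdiff(seq_len(n), valid)
    ok <- length(unique(labels[train])) == 2 && length(unique(labels[valid])) == 2
    if (ok) {
      if (try > 0) warn("validation split emptied a class; re-split with a shifted seed")
      return(list(train = train, valid = sort(valid)))
    }
  }
  abort("could not build a validation split containing both classes")
}

#' Train the pair transformer on labelled disease pairs
#'
#' Optimizes the fused sigmoid + binary cross-entropy loss with Adam,
#' holding out a stratified validation split for early stopping. The
#' checkpoint with the best validation loss is kept, and the Youden
#' classification threshold is fitted on the validation scores of that
#' checkpoint — test data is never touched.
#'
#' @param pairs Data frame with `disease_a`, `disease_b`, `label`.
#' @param enc An `encoding_bundle` whose `d_model` matches `cfg$d_model`.
#' @param dm A `disease_map`.
#' @param cfg A [model_config()].
#' @param run A [train_run()].
#' @param init_seed Seed for parameter initialization (defaults to
#'   `run$seed`), kept separate so ablation variants can share it.
#' @return An object of class `tspe_fit`: list with `model` (best
#'   checkpoint), `history` (per-epoch tibble), `threshold`,
#'   `threshold_provenance`, `best_epoch`, `valid_scores`.
#' @export
train_fold <- function(pairs, enc, dm, cfg, run = train_run(),
                       init_seed = NULL) {
  stopifnot(inherits(enc, "encoding_bundle"), inherits(dm, "disease_map"),
            inherits(cfg, "model_config"), inherits(run, "train_run"))
  if (enc$d_model != cfg$d_model) {
    abort(sprintf("encoding d_model %d != model d_model %d",
                  enc$d_model, cfg$d_model))
  }
  if (any(lengths(dm$members) == 0)) abort("disease with no member nodes")
  toks <- disease_tokens(enc, dm)
  labels <- pairs$label
  sp <- split_validation(labels, run$valid_frac, derive_seed(run$seed, "valid_split"))
  tr_idx <- sp$train; va_idx <- sp$valid
  tr_a <- pairs$disease_a[tr_idx]; tr_b <- pairs$disease_b[tr_idx]
  y_tr <- labels[tr_idx]
  if (run$augment_swap) {   # both orientations, training side only
    tmp_a <- c(tr_a, tr_b); tr_b <- c(tr_b, tr_a); tr_a <- tmp_a
    y_tr <- c(y_tr, y_tr)
  }
  Ea_tr <- toks[tr_a]
  Eb_tr <- toks[tr_b]
  Ea_va <- toks[pairs$disease_a[va_idx]]
  Eb_va <- toks[pairs$disease_b[va_idx]]
  y_va <- labels[va_idx]

  model <- init_model(cfg, seed = init_seed %||% derive_seed(run$seed, "init"))
  np <- length(model$params)
  m_state <- numeric(np); v_state <- numeric(np)
  step <- 0L
  best_loss <- Inf; best_params <- model$params; best_epoch <- 0L
  history <- vector("list", run$max_epochs)
  wait <- 0L
  n_tr <- length(y_tr)
  for (epoch in seq_len(run$max_epochs)) {
    ord <- withr::with_seed(derive_seed(run$seed, paste0("epoch", epoch)),
                            sample.int(n_tr))
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1, n_tr, by = cfg$batch_size)) {
      sel <- ord[b0:min(b0 + cfg$batch_size - 1, n_tr)]
      step <- step + 1L
      out <- batch_loss_grad(model, Ea_tr[sel], Eb_tr[sel], y_tr[sel],
                             cfg$dropout, derive_seed(run$seed, paste0("drop", step)))
      tspe_adam_cpp(model$params, out$grad, m_state, v_state, step,
                    cfg$lr, 0.9, 0.999, 1e-8)
      ep_loss <- ep_loss + out$loss; n_batches <- n_batches + 1L
    }
    va_logits <- eval_logits(model, Ea_va, Eb_va)
    va_loss <- bce_loss(va_logits, y_va)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = ep_loss / n_batches,
                                       valid_loss = va_loss)
    if (epoch < run$min_epochs) next   # burn-in: not checkpoint-eligible
    if (va_loss < best_loss - 1e-12) {
      best_loss <- va_loss; best_params <- model$params + 0  # force copy
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= run$patience) break
    }
  }
  if (best_epoch == 0L) {   # max_epochs == min_epochs - 1 cannot happen; guard anyway
    best_params <- model$params + 0
    best_epoch <- run$max_epochs
  }
  model$params <- best_params
  va_scores <- 1 / (1 + exp(-eval_logits(model, Ea_va, Eb_va)))
  thr <- if (length(unique(y_va)) == 2) youden_threshold(va_scores, y_va)$threshold else 0.5
  structure(list(model = model, cfg = cfg, run = run,
                 history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
                 threshold = thr, threshold_provenance = "youden_on_validation",
                 best_epoch = best_epoch, best_valid_loss = best_loss,
                 valid_scores = tibble::tibble(score = va_scores, label = y_va)),
            class = "tspe_fit")
}

eval_logits <- function(model, Ea_list, Eb_list) {
  vapply(seq_along(Ea_list), function(i) {
    tspe_forward_cpp(model$params, Ea_list[[i]], Eb_list[[i]],
                     unclass(model$cfg), NULL, NULL)$logit
  }, numeric(1))
}

#' @export
print.tspe_fit <- function(x, ...) {
  cat(sprintf("<tspe_fit> best epoch %d, valid loss %.4f, threshold %.4f\n",
              x$best_epoch, x$best_valid_loss, x$threshold))
  invisible(x)
}

#' @export
#' @rdname predict.tspe_model
predict.tspe_fit <- function(object, pairs, enc, dm, ...) {
  predict(object$model, pairs, enc, dm, ...)
}
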
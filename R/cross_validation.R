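#' Stratified k-fold assignment of labelled pairs
#'
#' Shuffles each label class under the seed and deals it round-robin into
#' `k` folds, so every per-fold positive count is within one pair of the
#' proportional share. Deterministic under `seed`.
#'
#' @param pairs Data frame with a `label` column.
#' @param k Fold count.
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `k`, `seed` and `assignments`
#'   (integer fold id per pair row).
#' @export
stratified_folds <- function(pairs, k = 10L, seed = 1L) {
  labels <- pairs$label
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  for (cls in c(0, 1)) {
    if (sum(labels == cls) < k) {
      abort(sprintf("class %d has %d pairs, fewer than k = %d folds",
                    cls, sum(labels == cls), k))
    }
  }
  assignments <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignments = assignments),
            class = "fold_plan")
}

#' Stratified k-fold cross-validation of the pair transformer
#'
#' Trains one model per fold on the remaining folds (with an inner
#' validation split for early stopping and threshold fitting) and scores
#' the held-out fold. Reports per-fold ROC AUC, AUPRC, accuracy (at the
#' fold's Youden threshold, with accuracy at 0.5 also emitted) and MCC,
#' plus mean/sd aggregates and aggregates after dropping the single most
#' outlying fold on the primary metric.
#'
#' @param pairs Data frame with `disease_a`, `disease_b`, `label`.
#' @param enc An `encoding_bundle`.
#' @param dm A `disease_map`.
#' @param cfg A [model_config()].
#' @param run A [train_run()]; the fold index is folded into its seed so
#'   folds train independently but reproducibly.
#' @param plan A [stratified_folds()] plan covering `pairs`.
#' @param outlier_metric Metric used by [remove_outlier_fold()].
#' @param init_seeds Optional integer vector (length `k`) of per-fold
#'   initialization seeds, letting ablation variants share initializations.
#' @param dual_order Average each test pair's probability over both pair
#'   orientations at inference (the architecture itself is asymmetric).
#' @return An object of class `tspe_cv`: list with `per_fold` (tibble),
#'   `aggregate`, `aggregate_outlier_removed`, `dropped_fold`, `plan`,
#'   `predictions` (per-pair out-of-fold scores).
#' @export
cross_validate <- function(pairs, enc, dm, cfg, run = train_run(), plan = NULL,
                           outlier_metric = "roc_auc", init_seeds = NULL,
                           dual_order = FALSE) {
  plan <- plan %||% stratified_folds(pairs, seed = derive_seed(run$seed, "folds"))
  if (length(plan$assignments) != nrow(pairs)) abort("fold plan does not cover the pairs")
  k <- plan$k
  init_seeds <- init_seeds %||%
    vapply(seq_len(k), function(f) derive_seed(run$seed, paste0("init_fold", f)),
           integer(1))
  per_fold <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(plan$assignments == f)
    tr <- which(plan$assignments != f)
    fold_run <- train_run(valid_frac = run$valid_frac,
                          max_epochs = run$max_epochs,
                          patience = run$patience,
                          min_epochs = run$min_epochs,
                          augment_swap = run$augment_swap,
                          seed = derive_seed(run$seed, paste0("fold", f)))
    fit <- train_fold(pairs[tr, , drop = FALSE], enc, dm, cfg, fold_run,
                      init_seed = init_seeds[f])
    sc <- predict(fit, pairs[te, , drop = FALSE], enc, dm)
    if (dual_order) {
      sw <- pairs[te, , drop = FALSE]
      tmp <- sw$disease_a; sw$disease_a <- sw$disease_b; sw$disease_b <- tmp
      sc$prob <- (sc$prob + predict(fit, sw, enc, dm)$prob) / 2
    }
    y <- sc$label
    per_fold[[f]] <- tibble::tibble(
      fold = f,
      roc_auc = roc_auc(sc$prob, y),
      auprc = auprc(sc$prob, y),
      accuracy = accuracy_at_threshold(sc$prob, y, fit$threshold),
      accuracy_05 = accuracy_at_threshold(sc$prob, y, 0.5),
      mcc = mcc_at_threshold(sc$prob, y, fit$threshold),
      threshold = fit$threshold,
      best_epoch = fit$best_epoch
    )
    preds[[f]] <- dplyr::mutate(sc, fold = f)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  agg <- aggregate_folds(per_fold)
  out_rm <- remove_outlier_fold(per_fold, outlier_metric)
  structure(list(per_fold = per_fold, aggregate = agg,
                 aggregate_outlier_removed = out_rm$aggregate,
                 dropped_fold = out_rm$dropped_fold,
                 outlier_metric = outlier_metric,
                 plan = plan, cfg = cfg, run = run,
                 variant = enc$variant,
                 predictions = dplyr::bind_rows(preds)),
            class = "tspe_cv")
}

metric_cols <- c("roc_auc", "auprc", "accuracy", "accuracy_05", "mcc")

aggregate_folds <- function(per_fold) {
  per_fold |>
    dplyr::select(dplyr::all_of(metric_cols)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
}

#' Re-aggregate fold metrics after dropping the most outlying fold
#'
#' Removes the single fold whose value of `metric` deviates most (in
#' absolute terms) from the across-fold mean, then recomputes mean/sd of
#' all metrics.
#'
#' @param per_fold Tibble of per-fold metrics (from [cross_validate()]).
#' @param metric Column used to pick the outlier.
#' @return List with `aggregate` (tibble) and `dropped_fold`.
#' @export
remove_outlier_fold <- function(per_fold, metric = "roc_auc") {
  if (nrow(per_fold) < 3) abort("need at least 3 folds to drop an outlier")
  x <- per_fold[[metric]]
  drop <- which.max(abs(x - mean(x)))
  list(aggregate = aggregate_folds(per_fold[-drop, , drop = FALSE]),
       dropped_fold = per_fold$fold[drop])
}

#' @export
print.tspe_cv <- function(x, ...) {
  cat(sprintf("<tspe_cv> variant %s, %d folds\n", x$variant, x$plan$k))
  print(x$aggregate)
  invisible(x)
}

#' @export
tidy.tspe_cv <- function(x, ...) x$per_fold

#' @export
glance.tspe_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::mutate(wide, variant = x$variant, k = x$plan$k, .before = 1)
}

#' Positional-encoding ablation under shared fold plans
#'
#' Runs cross-validation for several encoding variants (and optionally
#' several seeds) with identical fold plans, per-fold initialization seeds
#' and batch orders, so metric differences isolate the encoding. Node
#' embeddings are shared across variants. Emits per-fold paired
#' differences and paired t-test p-values of the first variant against
#' each other variant.
#'
#' @param g An `interactome`.
#' @param dm A `disease_map`.
#' @param pairs Labelled pair tibble.
#' @param variants Encoding variants to compare (first = reference).
#' @param seeds Integer vector of replicate seeds.
#' @param walk_cfg A [walk_config()] (its seed is re-derived per replicate).
#' @param gpe_dim GPE dimension for the SPE variant.
#' @param layers,heads,dropout,lr,batch_size Model settings shared by all
#'   variants (d_model/ff_dim follow each variant's encoding width).
#' @param run_template A [train_run()] giving valid_frac/epochs/patience
#'   and the augmentation flag.
#' @param dual_order Passed to [cross_validate()].
#' @param folds Fold count.
#' @return An `tspe_ablation` object: list with `runs` (named list of
#'   `tspe_cv` by "variant/seed"), `summary` tibble, `paired` tibble of
#'   per-fold differences, and `tests` (paired t-tests on ROC AUC and MCC).
#' @export
compare_encodings <- function(g, dm, pairs, variants = c("SPE", "NoPE"),
                              seeds = 1L, walk_cfg = walk_config(),
                              gpe_dim = 8L, layers = 3L, heads = 8L,
                              dropout = 0.2, lr = 1e-4, batch_size = 20L,
                              run_template = train_run(), folds = 10L,
                              dual_order = FALSE) {
  runs <- list()
  for (seed in seeds) {
    wc <- walk_cfg; wc$seed <- derive_seed(seed, "embed")
    M <- embed_nodes(g, wc)
    plan <- stratified_folds(pairs, k = folds, seed = derive_seed(seed, "folds"))
    init_seeds <- vapply(seq_len(folds),
                         function(f) derive_seed(seed, paste0("init_fold", f)),
                         integer(1))
    for (v in variants) {
      enc <- build_encoding(g, dm, variant = v, M = M, gpe_dim = gpe_dim)
      cfg <- model_config(layers = layers, heads = heads,
                          d_model = enc$d_model, dropout = dropout,
                          lr = lr, batch_size = batch_size)
      run <- train_run(valid_frac = run_template$valid_frac,
                       max_epochs = run_template$max_epochs,
                       patience = run_template$patience,
                       min_epochs = run_template$min_epochs,
                       augment_swap = run_template$augment_swap, seed = seed)
      runs[[paste(v, seed, sep = "/")]] <-
        cross_validate(pairs, enc, dm, cfg, run, plan, init_seeds = init_seeds,
                       dual_order = dual_order)
    }
  }
  summary <- purrr::imap(runs, function(cv, id) {
    parts <- strsplit(id, "/")[[1]]
    dplyr::mutate(cv$aggregate, variant = parts[1],
                  seed = as.integer(parts[2]), .before = 1)
  }) |> dplyr::bind_rows()
  ref <- variants[1]
  paired <- purrr::map(seeds, function(seed) {
    ref_pf <- runs[[paste(ref, seed, sep = "/")]]$per_fold
    purrr::map(setdiff(variants, ref), function(v) {
      other <- runs[[paste(v, seed, sep = "/")]]$per_fold
      tibble::tibble(seed = seed, comparison = paste(ref, "-", v),
                     fold = ref_pf$fold,
                     d_roc_auc = ref_pf$roc_auc - other$roc_auc,
                     d_auprc = ref_pf$auprc - other$auprc,
                     d_accuracy = ref_pf$accuracy - other$accuracy,
                     d_mcc = ref_pf$mcc - other$mcc)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  tests <- paired |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      mean_d_roc_auc = mean(.data$d_roc_auc),
      p_roc_auc = tryCatch(t.test(.data$d_roc_auc)$p.value, error = function(e) NA_real_),
      mean_d_mcc = mean(.data$d_mcc),
      p_mcc = tryCatch(t.test(.data$d_mcc)$p.value, error = function(e) NA_real_),
      .groups = "drop")
  structure(list(runs = runs, summary = summary, paired = paired,
                 tests = tests, variants = variants, seeds = seeds),
            class = "tspe_ablation")
}

#' @export
print.tspe_ablation <- function(x, ...) {
  cat(sprintf("<tspe_ablation> variants %s over %d seed(s)\n",
              paste(x$variants, collapse = ", "), length(x$seeds)))
  agg <- x$summary |>
    dplyr::filter(.data$metric == "roc_auc") |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(roc_auc = mean(.data$mean), .groups = "drop")
  print(agg)
  invisible(x)
}
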
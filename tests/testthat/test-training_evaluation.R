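test_that("stratified folds deal classes evenly and deterministically", {
  pairs <- tibble::tibble(disease_a = 1, disease_b = 2,
                          label = rep(c(1L, 0L), c(60, 40)))
  plan <- stratified_folds(pairs, k = 10, seed = 3)
  for (f in 1:10) {
    sel <- plan$assignments == f
    expect_equal(sum(sel & pairs$label == 1), 6)
    expect_equal(sum(sel & pairs$label == 0), 4)
  }
  expect_setequal(unlist(lapply(1:10, function(f) which(plan$assignments == f))),
                  seq_len(100))
  plan2 <- stratified_folds(pairs, k = 10, seed = 3)
  expect_identical(plan, plan2)
  expect_error(stratified_folds(pairs, k = 50, seed = 1), "fewer than k")
})

test_that("fold positive fractions stay within one pair of the global share", {
  withr::local_seed(53)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    pairs <- tibble::tibble(disease_a = 1, disease_b = 2,
                            label = sample(0:1, n, replace = TRUE,
                                           prob = c(0.3, 0.7)))
    k <- 5
    if (min(table(pairs$label)) < k) next
    plan <- stratified_folds(pairs, k = k, seed = i)
    npos <- sum(pairs$label)
    for (f in seq_len(k)) {
      sel <- plan$assignments == f
      expect_lte(abs(sum(pairs$label[sel]) - npos * sum(sel) / n), 1)
    }
  }
})

test_that("zero learning rate leaves parameters untouched", {
  prob <- random_pair_problem(6, 16, 12, seed = 57)
  cfg <- tiny_model_config(lr = 0, batch_size = 4L)
  run <- train_run(valid_frac = 0.25, max_epochs = 2, patience = 2, seed = 5)
  fit <- train_fold(prob$pairs, prob$enc, prob$dm, cfg, run, init_seed = 99)
  ref <- init_model(cfg, seed = 99)
  expect_identical(fit$model$params, ref$params)
})

test_that("the kept checkpoint never exceeds the first validation loss", {
  prob <- random_pair_problem(8, 16, 24, seed = 59)
  cfg <- tiny_model_config(lr = 1e-3, batch_size = 8L)
  run <- train_run(valid_frac = 0.25, max_epochs = 10, patience = 10, seed = 7)
  fit <- train_fold(prob$pairs, prob$enc, prob$dm, cfg, run)
  expect_lte(fit$best_valid_loss, fit$history$valid_loss[1])
  expect_lte(fit$best_epoch, run$max_epochs)
  expect_equal(fit$threshold_provenance, "youden_on_validation")
})

test_that("the Youden threshold is a function of validation data only", {
  prob <- random_pair_problem(8, 16, 24, seed = 61)
  cfg <- tiny_model_config(lr = 1e-3, batch_size = 8L)
  run <- train_run(valid_frac = 0.25, max_epochs = 3, patience = 3, seed = 9)
  fit <- train_fold(prob$pairs, prob$enc, prob$dm, cfg, run)
  # recomputable from the stored validation scores alone
  expect_equal(fit$threshold,
               youden_threshold(fit$valid_scores$score,
                                fit$valid_scores$label)$threshold)
})

test_that("cross-validation report structure and aggregation identities", {
  prob <- random_pair_problem(10, 16, 45, seed = 63)
  # make both classes big enough for 3 folds
  prob$pairs$label <- rep_len(c(0L, 1L), nrow(prob$pairs))
  cfg <- tiny_model_config(lr = 1e-3, batch_size = 8L)
  run <- train_run(valid_frac = 0.2, max_epochs = 2, patience = 2, seed = 11)
  plan <- stratified_folds(prob$pairs, k = 3, seed = 13)
  cv <- cross_validate(prob$pairs, prob$enc, prob$dm, cfg, run, plan)
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(sort(unique(cv$predictions$fold)), 1:3)
  expect_equal(nrow(cv$predictions), nrow(prob$pairs))
  agg <- cv$aggregate
  expect_equal(agg$mean[agg$metric == "roc_auc"], mean(cv$per_fold$roc_auc),
               tolerance = 1e-12)
  expect_true(all(cv$per_fold$roc_auc >= 0 & cv$per_fold$roc_auc <= 1))
  expect_true(all(cv$per_fold$mcc >= -1 & cv$per_fold$mcc <= 1))
  # tidy/glance accessors
  expect_identical(tidy(cv), cv$per_fold)
  expect_true("mean_roc_auc" %in% names(glance(cv)))
})

test_that("cross-validation is bit-reproducible under a fixed seed", {
  prob <- random_pair_problem(8, 16, 28, seed = 67)
  prob$pairs$label <- rep_len(c(0L, 1L), nrow(prob$pairs))
  cfg <- tiny_model_config(lr = 1e-3, batch_size = 8L, dropout = 0.1)
  run <- train_run(valid_frac = 0.2, max_epochs = 2, patience = 2, seed = 15)
  plan <- stratified_folds(prob$pairs, k = 3, seed = 17)
  cv1 <- cross_validate(prob$pairs, prob$enc, prob$dm, cfg, run, plan)
  cv2 <- cross_validate(prob$pairs, prob$enc, prob$dm, cfg, run, plan)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$aggregate, cv2$aggregate)
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("outlier-fold removal drops the largest deviation", {
  pf <- tibble::tibble(fold = 1:4, roc_auc = c(0.8, 0.8, 0.8, 0.2),
                       auprc = 0.5, accuracy = 0.5, accuracy_05 = 0.5,
                       mcc = 0, threshold = 0.5)
  out <- remove_outlier_fold(pf, "roc_auc")
  expect_equal(out$dropped_fold, 4)
  expect_equal(out$aggregate$mean[out$aggregate$metric == "roc_auc"], 0.8)

  pf2 <- dplyr::mutate(pf, roc_auc = 0.7)
  out2 <- remove_outlier_fold(pf2, "roc_auc")
  expect_equal(out2$aggregate$mean[out2$aggregate$metric == "roc_auc"], 0.7)

  withr::local_seed(69)
  for (i in 1:10) {
    pf3 <- dplyr::mutate(pf, roc_auc = runif(4))
    got <- remove_outlier_fold(pf3, "roc_auc")$dropped_fold
    # brute-force scan oracle
    devs <- abs(pf3$roc_auc - mean(pf3$roc_auc))
    expect_equal(got, pf3$fold[which.max(devs)])
  }
})

test_that("the ablation harness shares fold plans and initial parameters", {
  cfg <- sim_config(n_nodes = 150, n_communities = 4, p_in = 0.3,
                    p_out = 0.004, n_diseases = 8, size_range = c(5L, 10L),
                    seed = 3)
  b <- suppressMessages(make_benchmark(cfg))
  pairs <- label_pairs(b$pairs, "RR1")
  if (min(table(pairs$label)) < 3) pairs$label[1:3] <- 1L - pairs$label[1:3]
  ab <- compare_encodings(b$graph, b$disease_map, pairs,
                          variants = c("SPE", "NoPE"), seeds = 1,
                          walk_cfg = walk_config(dim = 16, walk_length = 10,
                                                 walks_per_node = 3, epochs = 1),
                          gpe_dim = 4, layers = 1, heads = 4,
                          run_template = train_run(valid_frac = 0.2,
                                                   max_epochs = 2, patience = 2),
                          folds = 3)
  expect_identical(ab$runs[["SPE/1"]]$plan, ab$runs[["NoPE/1"]]$plan)
  expect_equal(nrow(ab$paired), 3)
  expect_true(all(c("comparison", "p_roc_auc", "p_mcc") %in% names(ab$tests)))
  expect_equal(ab$paired$d_roc_auc,
               ab$runs[["SPE/1"]]$per_fold$roc_auc -
                 ab$runs[["NoPE/1"]]$per_fold$roc_auc)
})
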
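#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the end-to-end workbench:
#' simulation, node embedding, encoding variant, model, training and
#' cross-validation. Per-stage seeds are derived from the single global
#' seed by stable hashing of stage names, so adding a stage never shifts
#' another stage's randomness.
#'
#' @param seed Global integer seed.
#' @param sim A [sim_config()] (its seed is overridden from `seed`).
#' @param walk A [walk_config()] (seed overridden from `seed`).
#' @param variant Encoding variant for the `encode`/`cv` stages.
#' @param gpe_dim GPE dimension.
#' @param layers,heads,dropout,lr,batch_size Model settings.
#' @param valid_frac,max_epochs,patience,min_epochs Training settings.
#' @param folds Cross-validation folds.
#' @param mode RR labelling mode.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, sim = sim_config(), walk = walk_config(),
                       variant = c("SPE", "LPE", "NoPE"), gpe_dim = 8L,
                       layers = 3L, heads = 8L, dropout = 0.2, lr = 1e-4,
                       batch_size = 20L, valid_frac = 0.1, max_epochs = 100L,
                       patience = 10L, min_epochs = 1L, folds = 10L,
                       mode = c("RR1", "RR0")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  sim$seed <- derive_seed(seed, "simulate")
  walk$seed <- derive_seed(seed, "embed")
  structure(list(seed = as.integer(seed), sim = sim, walk = walk,
                 variant = variant, gpe_dim = as.integer(gpe_dim),
                 layers = as.integer(layers), heads = as.integer(heads),
                 dropout = dropout, lr = lr, batch_size = as.integer(batch_size),
                 valid_frac = valid_frac, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs), folds = as.integer(folds),
                 mode = mode),
            class = "run_config")
}

file_hash <- function(path) unname(tools::md5sum(path))

meta_path <- function(out_dir, stage) file.path(out_dir, paste0(stage, ".meta.json"))

write_stage_meta <- function(out_dir, stage, cfg_hash, inputs, outputs) {
  meta <- list(stage = stage, config_hash = cfg_hash,
               inputs = as.list(vapply(inputs, file_hash, character(1))),
               outputs = as.list(vapply(outputs, file_hash, character(1))))
  jsonlite::write_json(meta, meta_path(out_dir, stage), auto_unbox = TRUE)
}

stage_fresh <- function(out_dir, stage, cfg_hash, inputs, outputs) {
  mp <- meta_path(out_dir, stage)
  if (!file.exists(mp) || !all(file.exists(unlist(outputs)))) return(FALSE)
  meta <- jsonlite::fromJSON(mp)
  if (!identical(meta$config_hash, cfg_hash)) return(FALSE)
  cur_in <- vapply(inputs, file_hash, character(1))
  cur_out <- vapply(outputs, file_hash, character(1))
  identical(as.list(cur_in), meta$inputs[names(cur_in)]) &&
    identical(as.list(cur_out), meta$outputs[names(cur_out)])
}

# verify that the inputs a stage consumes still match the hashes their
# producing stage recorded; a mismatch means a stale or corrupted artifact
check_upstream <- function(out_dir, producer, files) {
  mp <- meta_path(out_dir, producer)
  if (!file.exists(mp)) {
    abort(sprintf("stage '%s' artifacts missing; include '%s' in the stage list",
                  producer, producer))
  }
  meta <- jsonlite::fromJSON(mp)
  for (nm in names(files)) {
    if (!file.exists(files[[nm]]) ||
        !identical(file_hash(files[[nm]]), meta$outputs[[nm]])) {
      abort(sprintf(paste0("artifact hash mismatch for '%s' (%s): stale or ",
                           "corrupted; regenerate by re-running stage '%s'"),
                    nm, files[[nm]], producer))
    }
  }
  invisible(TRUE)
}

#' Run the end-to-end pipeline with artifact caching
#'
#' Executes the requested stages (`simulate`, `embed`, `encode`, `cv`) in
#' dependency order. Each stage writes its artifacts plus a metadata
#' sidecar recording config and content hashes; a stage whose config,
#' inputs and outputs are all unchanged is skipped. A downstream stage
#' refuses to consume an artifact whose hash no longer matches what its
#' producer recorded.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param stages Ordered subset of `c("simulate", "embed", "encode", "cv")`.
#' @return A manifest tibble (stage, artifact, path, hash, status),
#'   invisibly carrying the `tspe_cv` result in attribute `"cv"` when the
#'   `cv` stage ran.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "embed", "encode", "cv")) {
  stopifnot(inherits(config, "run_config"))
  known <- c("simulate", "embed", "encode", "cv")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- known[known %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  sim_files <- list(edges = p("edges.tsv"), associations = p("associations.tsv"),
                    pairs = p("pairs.tsv"), truth = p("truth.tsv"),
                    config = p("sim_config.json"))
  emb_file <- list(embedding = p("embedding.tsv"))
  enc_file <- list(encoding = p("encoding.tsv"))
  cv_files <- list(per_fold = p("cv_per_fold.tsv"), aggregate = p("cv_aggregate.json"))
  manifest <- list()
  note <- function(stage, files, status) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, artifact = names(files),
      path = unlist(files, use.names = FALSE),
      hash = vapply(files, file_hash, character(1)), status = status)
  }
  cv_result <- NULL

  if ("simulate" %in% stages) {
    ch <- obj_hash(config$sim)
    if (stage_fresh(out_dir, "simulate", ch, list(), sim_files)) {
      note("simulate", sim_files, "skipped")
    } else {
      make_benchmark(config$sim, dir = out_dir)
      write_stage_meta(out_dir, "simulate", ch, list(), sim_files)
      note("simulate", sim_files, "computed")
    }
  }
  if ("embed" %in% stages) {
    check_upstream(out_dir, "simulate", sim_files["edges"])
    ch <- obj_hash(config$walk)
    ins <- sim_files["edges"]
    if (stage_fresh(out_dir, "embed", ch, ins, emb_file)) {
      note("embed", emb_file, "skipped")
    } else {
      g <- read_edge_list(sim_files$edges)
      M <- embed_nodes(g, config$walk)
      write_matrix_tsv(M, emb_file$embedding,
                       meta = list(config_hash = ch, dim = ncol(M)))
      write_stage_meta(out_dir, "embed", ch, ins, emb_file)
      note("embed", emb_file, "computed")
    }
  }
  if ("encode" %in% stages) {
    check_upstream(out_dir, "simulate", sim_files[c("edges", "associations")])
    check_upstream(out_dir, "embed", emb_file)
    ch <- obj_hash(list(config$variant, config$gpe_dim))
    ins <- c(sim_files[c("edges", "associations")], emb_file)
    if (stage_fresh(out_dir, "encode", ch, ins, enc_file)) {
      note("encode", enc_file, "skipped")
    } else {
      g <- read_edge_list(sim_files$edges)
      dm <- read_disease_associations(sim_files$associations, g)
      M <- read_matrix_tsv(emb_file$embedding)$matrix
      enc <- build_encoding(g, dm, variant = config$variant, M = M,
                            gpe_dim = config$gpe_dim)
      write_matrix_tsv(enc$E, enc_file$encoding,
                       meta = list(variant = enc$variant, d_model = enc$d_model,
                                   config_hash = ch))
      write_stage_meta(out_dir, "encode", ch, ins, enc_file)
      note("encode", enc_file, "computed")
    }
  }
  if ("cv" %in% stages) {
    check_upstream(out_dir, "simulate", sim_files[c("edges", "associations", "pairs")])
    check_upstream(out_dir, "embed", emb_file)   # transitive provenance
    check_upstream(out_dir, "encode", enc_file)
    ch <- obj_hash(config[c("layers", "heads", "dropout", "lr", "batch_size",
                            "valid_frac", "max_epochs", "patience",
                            "min_epochs", "folds", "mode", "seed")])
    ins <- c(sim_files[c("pairs", "associations", "edges")], enc_file)
    if (stage_fresh(out_dir, "cv", ch, ins, cv_files)) {
      note("cv", cv_files, "skipped")
    } else {
      g <- read_edge_list(sim_files$edges)
      dm <- read_disease_associations(sim_files$associations, g)
      em <- read_matrix_tsv(enc_file$encoding)
      enc <- structure(list(variant = em$meta$variant, E = em$matrix,
                            d_model = em$meta$d_model),
                       class = "encoding_bundle")
      pairs <- label_pairs(read_pair_scores(sim_files$pairs, dm), config$mode)
      cfg <- model_config(layers = config$layers, heads = config$heads,
                          d_model = enc$d_model, dropout = config$dropout,
                          lr = config$lr, batch_size = config$batch_size)
      run <- train_run(valid_frac = config$valid_frac,
                       max_epochs = config$max_epochs,
                       patience = config$patience,
                       min_epochs = config$min_epochs, seed = config$seed)
      plan <- stratified_folds(pairs, k = config$folds,
                               seed = derive_seed(config$seed, "folds"))
      cv_result <- cross_validate(pairs, enc, dm, cfg, run, plan)
      utils::write.table(cv_result$per_fold, cv_files$per_fold, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(aggregate = cv_result$aggregate,
             aggregate_outlier_removed = cv_result$aggregate_outlier_removed,
             dropped_fold = cv_result$dropped_fold,
             variant = enc$variant, seed = config$seed,
             config_hash = ch),
        cv_files$aggregate, auto_unbox = TRUE, digits = NA)
      write_stage_meta(out_dir, "cv", ch, ins, cv_files)
      note("cv", cv_files, "computed")
    }
  }
  out <- dplyr::bind_rows(manifest)
  attr(out, "cv") <- cv_result
  out
}
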
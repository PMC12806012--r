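# shared fixtures, all generated in code

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# path graph g1-g2-...-gn as an interactome
path_interactome <- function(n) {
  ids <- sprintf("g%02d", seq_len(n))
  tspe:::interactome_from_pairs(ids[-n], ids[-1])
}

# Erdos-Renyi interactome with deterministic seed
random_interactome <- function(n, p, seed) {
  withr::with_seed(seed, {
    ig <- igraph::sample_gnp(n, p)
    el <- igraph::as_edgelist(ig, names = FALSE)
    while (nrow(el) == 0) {    # ensure at least one edge
      ig <- igraph::sample_gnp(n, min(1, p * 2))
      el <- igraph::as_edgelist(ig, names = FALSE)
    }
    ids <- sprintf("g%03d", seq_len(n))
    tspe:::interactome_from_pairs(ids[el[, 1]], ids[el[, 2]])
  })
}

# disease map straight from a named list of node-index vectors
manual_disease_map <- function(members) {
  structure(list(diseases = names(members), members = members,
                 K = length(members)),
            class = "disease_map")
}

# small model configuration used by fast transformer tests
tiny_model_config <- function(d_model = 16L, dropout = 0, ...) {
  model_config(layers = 2L, heads = 4L, d_model = d_model,
               ff_dim = 2L * d_model, dropout = dropout, ...)
}

# random pair-tokens problem for head/training tests: n_d "diseases" with
# random token matrices and random labels
random_pair_problem <- function(n_d, d_model, n_pairs, seed) {
  withr::with_seed(seed, {
    sizes <- sample(2:5, n_d, replace = TRUE)
    E <- matrix(rnorm(sum(sizes) * d_model), ncol = d_model)
    offs <- cumsum(c(0, sizes))
    members <- lapply(seq_len(n_d), function(j) (offs[j] + 1):offs[j + 1])
    names(members) <- sprintf("D%02d", seq_len(n_d))
    cmb <- utils::combn(n_d, 2)
    sel <- sample(ncol(cmb), n_pairs)
    pairs <- tibble::tibble(disease_a = cmb[1, sel], disease_b = cmb[2, sel],
                            label = sample(0:1, n_pairs, replace = TRUE))
    # guarantee both classes
    if (length(unique(pairs$label)) < 2) pairs$label[1:2] <- c(0L, 1L)
    list(enc = structure(list(variant = "NoPE", E = E, d_model = d_model),
                         class = "encoding_bundle"),
         dm = manual_disease_map(members),
         pairs = pairs)
  })
}
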
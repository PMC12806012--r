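#' Synthetic interactome benchmark configuration
#'
#' Parameters of the planted-module benchmark: a stochastic block model
#' stands in for a sparse protein-protein interaction network with
#' community structure, disease modules are node subsets drawn mostly from
#' one home community (`locality`), and relative-risk-like pair scores are
#' driven by module overlap plus network proximity with additive Gaussian
#' noise. Defaults give a 400-node, 8-community graph with 20 diseases of
#' 8-25 genes at locality 0.8 and score noise 0.2. The default edge
#' probabilities (dense modules, very sparse inter-module links) make the
#' community meta-graph sparse, so module separations spread widely and
#' the planted signal dominates the score noise.
#'
#' @param n_nodes Nodes before largest-component filtering.
#' @param n_communities Equal-sized SBM blocks.
#' @param p_in Within-community edge probability.
#' @param p_out Between-community edge probability (`p_out < p_in`).
#' @param n_diseases Number of disease modules.
#' @param size_range Min/max module size.
#' @param locality Fraction of each module drawn from its home community.
#' @param noise_sd SD of the Gaussian noise added to pair scores.
#' @param alpha,beta Weights of the overlap (Jaccard) and proximity terms
#'   of the latent comorbidity signal.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_nodes = 400L, n_communities = 8L, p_in = 0.25,
                       p_out = 3e-4, n_diseases = 20L, size_range = c(8L, 25L),
                       locality = 0.8, noise_sd = 0.2, alpha = 1, beta = 1,
                       seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            locality >= 0, locality <= 1, noise_sd >= 0,
            length(size_range) == 2, size_range[1] >= 2,
            size_range[2] >= size_range[1], size_range[2] <= n_nodes,
            n_diseases >= 2, n_communities >= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_communities = as.integer(n_communities),
                 p_in = p_in, p_out = p_out,
                 n_diseases = as.integer(n_diseases),
                 size_range = as.integer(size_range),
                 locality = locality, noise_sd = noise_sd,
                 alpha = alpha, beta = beta, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic interactome
#'
#' Samples a stochastic block model with `n_communities` (near-)equal
#' blocks, keeps the largest connected component, and labels nodes with
#' synthetic gene-like IDs. The community of each retained node is kept in
#' attribute `"community"` for module planting.
#'
#' @param cfg A [sim_config()].
#' @return An `interactome` with a `"community"` attribute.
#' @export
generate_graph <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- rep(cfg$n_nodes %/% cfg$n_communities, cfg$n_communities)
  rem <- cfg$n_nodes - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  pm <- matrix(cfg$p_out, cfg$n_communities, cfg$n_communities)
  diag(pm) <- cfg$p_in
  withr::local_seed(derive_seed(cfg$seed, "sbm"))
  ig <- igraph::sample_sbm(cfg$n_nodes, pref.matrix = pm, block.sizes = sizes)
  comm_all <- rep(seq_len(cfg$n_communities), sizes)
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 10) {
    abort("largest connected component has fewer than 10 nodes; increase p_in")
  }
  sub <- igraph::induced_subgraph(ig, keep)
  ids <- sprintf("G%05d", keep)
  el <- igraph::as_edgelist(sub, names = FALSE)
  g <- interactome_from_pairs(ids[el[, 1]], ids[el[, 2]])
  # interactome sorts node IDs; zero-padded IDs keep the original order
  comm <- comm_all[keep][match(g$node_ids, ids)]
  attr(g, "community") <- comm
  g
}

#' Plant (possibly overlapping) disease modules
#'
#' Draws each disease's size uniformly from `size_range`, takes a
#' `locality` fraction of members from its home community (cycling through
#' communities) and the rest uniformly from the remaining nodes. Modules
#' may overlap, exercising multi-disease membership downstream.
#'
#' @param g An `interactome` from [generate_graph()] (needs the
#'   `"community"` attribute).
#' @param cfg A [sim_config()].
#' @return A `disease_map` with synthetic disease IDs.
#' @export
plant_diseases <- function(g, cfg) {
  comm <- attr(g, "community")
  if (is.null(comm)) abort("graph lacks community metadata; use generate_graph()")
  if (cfg$size_range[2] > g$N) abort("size_range exceeds the retained node count")
  withr::local_seed(derive_seed(cfg$seed, "diseases"))
  diseases <- sprintf("D%03d", seq_len(cfg$n_diseases))
  members <- vector("list", cfg$n_diseases)
  for (j in seq_len(cfg$n_diseases)) {
    size <- sample(seq(cfg$size_range[1], cfg$size_range[2]), 1)
    home <- (j - 1) %% cfg$n_communities + 1
    pool_home <- which(comm == home)
    n_home <- min(round(cfg$locality * size), length(pool_home))
    mem <- sample(pool_home, n_home)
    pool_rest <- setdiff(seq_len(g$N), mem)
    mem <- c(mem, sample(pool_rest, size - n_home))
    members[[j]] <- sort(mem)
  }
  names(members) <- diseases
  structure(list(diseases = diseases, members = members,
                 K = cfg$n_diseases),
            class = "disease_map")
}

#' Score disease pairs with an RR-like surrogate
#'
#' The latent comorbidity signal of a pair is
#' `alpha * Jaccard(members_A, members_B) + beta * (1 - d_AB / max(d))`,
#' where `d_AB` is the symmetrized mean minimum shortest-path distance
#' between the member sets (the canonical disease-module separation
#' measure: for every member of one module take the distance to the
#' closest member of the other, and average both directions) and `max(d)`
#' is the largest separation among the emitted pairs, so the proximity
#' term spans the full unit interval. Unreachable node pairs count as
#' `diameter + 1`. Identical modules have `d_AB = 0`. The emitted RR-like
#' score is `2 * signal + N(0, noise_sd)`, so identical modules at zero
#' noise score 4 and the most separated disjoint modules score near 0.
#' All unordered disease pairs are emitted.
#'
#' @param g An `interactome`.
#' @param dm A `disease_map`.
#' @param cfg A [sim_config()].
#' @return Tibble with `disease_a`, `disease_b` (indices, a < b), `rr`
#'   and the noise-free `signal`.
#' @export
score_pairs <- function(g, dm, cfg) {
  stopifnot(inherits(dm, "disease_map"))
  ig <- as_igraph(g)
  D <- igraph::distances(ig)
  diam <- max(D[is.finite(D)])
  D[!is.finite(D)] <- diam + 1
  combs <- utils::combn(dm$K, 2)
  withr::local_seed(derive_seed(cfg$seed, "scores"))
  n_pairs <- ncol(combs)
  jac <- numeric(n_pairs)
  d_ab <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- dm$members[[combs[1, i]]]
    b <- dm$members[[combs[2, i]]]
    jac[i] <- length(intersect(a, b)) / length(union(a, b))
    Dab <- D[a, b, drop = FALSE]
    d_ab[i] <- (sum(apply(Dab, 1, min)) + sum(apply(Dab, 2, min))) /
      (length(a) + length(b))
  }
  d_max <- max(d_ab)
  prox <- if (d_max > 0) 1 - d_ab / d_max else rep(1, n_pairs)
  sig <- cfg$alpha * jac + cfg$beta * prox
  rr <- 2 * sig + rnorm(n_pairs, sd = cfg$noise_sd)
  tibble::tibble(disease_a = as.integer(combs[1, ]),
                 disease_b = as.integer(combs[2, ]),
                 rr = rr, signal = sig)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Composes [generate_graph()], [plant_diseases()] and [score_pairs()];
#' optionally writes the three standard TSV inputs (edge list,
#' disease-gene associations, scored pairs), a truth table and a JSON
#' config snapshot to `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory for the TSV artifacts.
#' @return A `sim_bundle`: list with `graph`, `disease_map`, `pairs`
#'   (tibble with `rr`), `truth` (tibble with the latent `signal`), `cfg`
#'   and (if written) `files`.
#' @export
make_benchmark <- function(cfg = sim_config(), dir = NULL) {
  g <- generate_graph(cfg)
  dm <- plant_diseases(g, cfg)
  sc <- score_pairs(g, dm, cfg)
  pairs <- dplyr::select(sc, "disease_a", "disease_b", "rr")
  truth <- dplyr::select(sc, "disease_a", "disease_b", "signal")
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(edges = file.path(dir, "edges.tsv"),
               associations = file.path(dir, "associations.tsv"),
               pairs = file.path(dir, "pairs.tsv"),
               truth = file.path(dir, "truth.tsv"),
               config = file.path(dir, "sim_config.json"))
    write_edge_list(g, files["edges"])
    assoc <- tibble::tibble(
      disease = rep(dm$diseases, lengths(dm$members)),
      gene = g$node_ids[unlist(dm$members)])
    utils::write.table(assoc, files["associations"], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    ptab <- dplyr::mutate(pairs,
                          disease_a = dm$diseases[.data$disease_a],
                          disease_b = dm$diseases[.data$disease_b])
    utils::write.table(ptab, files["pairs"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(truth, files["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(unclass(cfg), files["config"], auto_unbox = TRUE)
  }
  structure(list(graph = g, disease_map = dm, pairs = pairs, truth = truth,
                 cfg = cfg, files = files),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d nodes, %d diseases, %d scored pairs\n",
              x$graph$N, x$disease_map$K, nrow(x$pairs)))
  invisible(x)
}
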
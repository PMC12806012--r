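#' Random-walk / skip-gram configuration
#'
#' Settings for the biased second-order random walks and the skip-gram
#' embedding trainer. The neutral defaults `p = 1`, `q = 1` make the walk a
#' plain unbiased random walk (no preference for local or global
#' exploration); `window = 2` keeps the skip-gram context local, and the
#' embedding dimension defaults to 64. Walk length, walk count and epochs
#' are not pinned by the method and are exposed here so they are auditable.
#'
#' @param p Return parameter (> 0). Higher values discourage revisiting the
#'   previous node.
#' @param q In-out parameter (> 0). Lower values push the walk outward.
#' @param walk_length Steps per walk.
#' @param walks_per_node Walks started from every node.
#' @param window Skip-gram context window size.
#' @param dim Embedding dimension.
#' @param epochs Skip-gram training epochs.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial skip-gram learning rate.
#' @param seed Integer seed driving both walks and training.
#' @return A `walk_config` list.
#' @export
walk_config <- function(p = 1, q = 1, walk_length = 30L, walks_per_node = 10L,
                        window = 2L, dim = 64L, epochs = 5L, negative = 5L,
                        alpha = 0.025, seed = 1L) {
  stopifnot(p > 0, q > 0, walk_length >= 1, walks_per_node >= 1,
            window >= 1, dim >= 1, epochs >= 1, negative >= 0, alpha > 0)
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window), dim = as.integer(dim),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate biased second-order random walks
#'
#' Starts `walks_per_node` walks from every node. After the first
#' (uniform) step, the unnormalized weight of moving from the current node
#' `v` to a candidate neighbour `x`, given the previous node `t`, is
#' `1/p` if `x == t`, `1` if `x` is adjacent to `t`, and `1/q` otherwise.
#' With `p = q = 1` this is an ordinary random walk. A walk stops early at
#' a node without neighbours; an isolated start node yields a length-1
#' walk. The walk set is reproducible from `cfg$seed`.
#'
#' @param g An `interactome`.
#' @param cfg A [walk_config()].
#' @return List of integer vectors of node indices.
#' @export
generate_walks <- function(g, cfg = walk_config()) {
  stopifnot(inherits(g, "interactome"), inherits(cfg, "walk_config"))
  if (g$N == 0) abort("cannot walk on an empty graph")
  nbr <- vector("list", g$N)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  nbr <- lapply(nbr, function(x) if (is.null(x)) integer(0) else sort(x))
  withr::local_seed(cfg$seed)
  walks <- vector("list", g$N * cfg$walks_per_node)
  w_i <- 0L
  for (rep in seq_len(cfg$walks_per_node)) {
    for (start in seq_len(g$N)) {
      walk <- integer(cfg$walk_length)
      walk[1] <- start
      len <- 1L
      if (length(nbr[[start]]) > 0 && cfg$walk_length > 1) {
        walk[2] <- nbr[[start]][sample.int(length(nbr[[start]]), 1L)]
        len <- 2L
        while (len < cfg$walk_length) {
          v <- walk[len]; t_prev <- walk[len - 1L]
          cand <- nbr[[v]]
          if (length(cand) == 0) break
          w <- ifelse(cand == t_prev, 1 / cfg$p,
                      ifelse(cand %in% nbr[[t_prev]], 1, 1 / cfg$q))
          nxt <- cand[sample.int(length(cand), 1L, prob = w)]
          len <- len + 1L
          walk[len] <- nxt
        }
      }
      w_i <- w_i + 1L
      walks[[w_i]] <- walk[seq_len(len)]
    }
  }
  walks
}

#' Train node embeddings from random walks
#'
#' Runs single-threaded skip-gram with negative sampling over the walk
#' corpus and returns the input-embedding matrix aligned to the
#' interactome index space. Training is bit-reproducible for a fixed
#' `cfg$seed`.
#'
#' @param walks List of integer node-index walks (from [generate_walks()]).
#' @param n_nodes Number of nodes in the index space.
#' @param cfg A [walk_config()].
#' @return An `N x dim` numeric matrix of class `node_embedding` with the
#'   config stored in attribute `"config"`.
#' @export
train_node_embeddings <- function(walks, n_nodes, cfg = walk_config()) {
  stopifnot(inherits(cfg, "walk_config"), n_nodes >= 1)
  seen <- unique(unlist(walks))
  missing <- setdiff(seq_len(n_nodes), seen)
  if (length(missing) > 0) {
    abort(sprintf("node(s) absent from every walk: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  M <- sgns_train_cpp(walks, n_nodes, cfg$dim, cfg$window, cfg$epochs,
                      cfg$negative, cfg$alpha, cfg$seed)
  structure(M, class = c("node_embedding", "matrix", "array"), config = cfg)
}

#' Node2vec-style embedding of an interactome
#'
#' Convenience wrapper composing [generate_walks()] and
#' [train_node_embeddings()].
#'
#' @inheritParams generate_walks
#' @return See [train_node_embeddings()].
#' @export
embed_nodes <- function(g, cfg = walk_config()) {
  train_node_embeddings(generate_walks(g, cfg), g$N, cfg)
}

#' Write / read an embedding (or encoding) matrix as TSV with a JSON header
#'
#' The first line is a `#`-prefixed JSON header carrying the dimension and
#' a content hash of the generating configuration; the rest is one
#' tab-separated row per node. The artifact is loadable independently of
#' the graph.
#'
#' @param M A numeric matrix.
#' @param path Output path.
#' @param meta Named list of extra header fields.
#' @return `path` invisibly (`write_matrix_tsv`); a list with `matrix` and
#'   `meta` (`read_matrix_tsv`).
#' @export
write_matrix_tsv <- function(M, path, meta = list()) {
  hdr <- c(list(nrow = nrow(M), ncol = ncol(M)), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)), con)
  utils::write.table(M, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) abort("missing matrix header line")
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  M <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(M) <- NULL
  if (nrow(M) != meta$nrow || ncol(M) != meta$ncol) {
    abort("matrix dimensions disagree with header")
  }
  list(matrix = M, meta = meta)
}
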
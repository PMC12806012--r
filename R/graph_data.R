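#' Read an interactome from a two-column edge list
#'
#' Builds an undirected protein-protein interaction graph from a
#' whitespace/tab-delimited file with two gene identifiers per line.
#' Lines starting with `#` (or trailing `#` comments) are ignored.
#' Duplicate edges (including reversed duplicates) are collapsed and
#' self-loops are dropped with a message. Node identifiers are sorted so
#' that the node index space is identical across runs and platforms; all
#' downstream matrices (adjacency, Laplacian, embeddings, encodings) share
#' this index space.
#'
#' @param path Path to the edge-list file.
#' @return An object of class `interactome`: a list with `node_ids`
#'   (sorted character vector), `edges` (integer matrix, two columns,
#'   each row an unordered edge with smaller index first) and `N`
#'   (node count).
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("g1 g2", "g2 g3", "g2 g1"), tf)
#' g <- read_edge_list(tf)
#' g$N
read_edge_list <- function(path) {
  tbl <- read_table_lines(path)
  if (length(tbl$lines) == 0) {
    abort(paste0("empty edge list: ", path))
  }
  fields <- split_fields(tbl$lines)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    abort(sprintf("edge list line %d has %d fields (expected 2)",
                  tbl$line_no[bad], nf[bad]))
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  interactome_from_pairs(a, b)
}

interactome_from_pairs <- function(a, b) {
  node_ids <- sort(unique(c(a, b)))
  ia <- match(a, node_ids)
  ib <- match(b, node_ids)
  self <- ia == ib
  n_self <- sum(self)
  if (n_self > 0) {
    inform(sprintf("dropped %d self-loop(s)", n_self))
    ia <- ia[!self]; ib <- ib[!self]
  }
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  keep <- !duplicated(cbind(lo, hi))
  edges <- cbind(lo[keep], hi[keep])
  o <- order(edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("from", "to")
  structure(list(node_ids = node_ids, edges = edges, N = length(node_ids)),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d nodes, %d edges\n", x$N, nrow(x$edges)))
  invisible(x)
}

#' Write an interactome back to edge-list format
#'
#' Inverse of [read_edge_list()]: the written file reloads to an identical
#' graph (isolated nodes, which cannot be expressed in an edge list, are
#' emitted as a commented header so information is not silently lost).
#'
#' @param g An `interactome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "interactome"))
  iso <- setdiff(seq_len(g$N), unique(as.vector(g$edges)))
  hdr <- character(0)
  if (length(iso) > 0) {
    hdr <- paste0("# isolated: ", paste(g$node_ids[iso], collapse = " "))
  }
  lines <- paste(g$node_ids[g$edges[, 1]], g$node_ids[g$edges[, 2]], sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Node degrees of an interactome
#' @param g An `interactome`.
#' @return Integer vector of length `g$N`.
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "interactome"))
  tabulate(as.vector(g$edges), nbins = g$N)
}

#' Convert an interactome to an igraph object
#' @param g An `interactome`.
#' @return An undirected `igraph` graph whose vertex order matches the
#'   interactome index space.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "interactome"))
  ig <- igraph::make_empty_graph(n = g$N, directed = FALSE)
  ig <- igraph::add_edges(ig, t(g$edges))
  igraph::set_vertex_attr(ig, "name", value = g$node_ids)
}

#' Adjacency matrix of an interactome
#'
#' Binary, symmetric, zero-diagonal \eqn{N \times N} matrix \eqn{A};
#' row sums equal node degrees. This is the matrix entering both the
#' normalized Laplacian \eqn{\tilde L = I - D^{-1/2} A D^{-1/2}} and the
#' graph encoder embedding \eqn{Z = A W}.
#'
#' @param g An `interactome`.
#' @return A dense numeric matrix with node IDs as dimnames.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "interactome"))
  A <- matrix(0, g$N, g$N, dimnames = list(g$node_ids, g$node_ids))
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

#' Read disease-gene associations into a disease map
#'
#' Reads a two-column (disease ID, gene ID) table and maps each disease to
#' the set of interactome node indices of its associated genes (its disease
#' module). Genes absent from the interactome are dropped with a message;
#' diseases left without any mapped gene are removed with a warning. A gene
#' may belong to several diseases.
#'
#' @param path Path to the association table.
#' @param g The `interactome` defining the node index space.
#' @return An object of class `disease_map`: list with `diseases` (ordered
#'   character vector), `members` (list of integer node-index vectors) and
#'   `K` (disease count).
#' @export
read_disease_associations <- function(path, g) {
  stopifnot(inherits(g, "interactome"))
  tbl <- read_table_lines(path)
  if (length(tbl$lines) == 0) abort(paste0("empty association table: ", path))
  fields <- split_fields(tbl$lines)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    abort(sprintf("association line %d has %d fields (expected 2)",
                  tbl$line_no[bad], nf[bad]))
  }
  dis <- vapply(fields, `[`, character(1), 1L)
  gene <- vapply(fields, `[`, character(1), 2L)
  idx <- match(gene, g$node_ids)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    inform(sprintf("dropped %d association(s) to genes absent from the interactome",
                   dropped))
  }
  keep <- !is.na(idx)
  disease_map_from_pairs(dis[keep], idx[keep], dropped_all = unique(dis[!keep]))
}

disease_map_from_pairs <- function(dis, idx, dropped_all = character(0)) {
  diseases <- sort(unique(dis))
  members <- lapply(diseases, function(d) sort(unique(idx[dis == d])))
  names(members) <- diseases
  empty <- lengths(members) == 0
  lost <- setdiff(dropped_all, diseases)
  if (length(lost) > 0 || any(empty)) {
    gone <- sort(unique(c(lost, diseases[empty])))
    warn(sprintf("removed %d disease(s) with no mapped genes: %s",
                 length(gone), paste(gone, collapse = ", ")))
    diseases <- diseases[!empty]
    members <- members[!empty]
  }
  if (length(diseases) == 0) abort("no disease retains at least one mapped gene")
  structure(list(diseases = diseases, members = members, K = length(diseases)),
            class = "disease_map")
}

#' @export
print.disease_map <- function(x, ...) {
  cat(sprintf("<disease_map> %d diseases, module sizes %d-%d\n",
              x$K, min(lengths(x$members)), max(lengths(x$members))))
  invisible(x)
}

#' Read a disease-pair table with relative-risk scores
#'
#' Reads a three-column (disease A, disease B, RR) table and returns a
#' tibble of unordered pairs, canonicalized so the smaller disease index
#' comes first. Pairs involving diseases absent from the disease map are
#' dropped with a message; duplicated unordered pairs and self-pairs are
#' errors.
#'
#' @param path Path to the pair table.
#' @param dm A `disease_map` defining disease indices.
#' @return A tibble with columns `disease_a`, `disease_b` (integer disease
#'   indices, `disease_a < disease_b`) and `rr` (numeric relative risk).
#' @export
read_pair_scores <- function(path, dm) {
  stopifnot(inherits(dm, "disease_map"))
  tbl <- read_table_lines(path)
  if (length(tbl$lines) == 0) abort(paste0("empty pair table: ", path))
  fields <- split_fields(tbl$lines)
  nf <- lengths(fields)
  if (any(nf != 3)) {
    bad <- which(nf != 3)[1]
    abort(sprintf("pair table line %d has %d fields (expected 3)",
                  tbl$line_no[bad], nf[bad]))
  }
  da <- vapply(fields, `[`, character(1), 1L)
  db <- vapply(fields, `[`, character(1), 2L)
  rr <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  ia <- match(da, dm$diseases)
  ib <- match(db, dm$diseases)
  known <- !is.na(ia) & !is.na(ib)
  if (any(!known)) {
    inform(sprintf("dropped %d pair(s) involving unknown diseases", sum(!known)))
  }
  ia <- ia[known]; ib <- ib[known]; rr <- rr[known]
  if (any(ia == ib)) abort("pair table contains a self-pair (disease paired with itself)")
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  if (anyDuplicated(cbind(lo, hi)) > 0) {
    abort("pair table contains a duplicated unordered disease pair")
  }
  tibble::tibble(disease_a = as.integer(lo), disease_b = as.integer(hi), rr = rr)
}

#' Label disease pairs under an RR-threshold mode
#'
#' Converts relative-risk scores into binary comorbidity labels. Under
#' `"RR0"` a pair is positive iff \eqn{RR > 0}; under `"RR1"` a pair is
#' positive iff \eqn{RR \ge 1}. These are the two benchmark regimes for
#' comorbidity classification on the human interactome.
#'
#' @param pairs A data frame with columns `disease_a`, `disease_b`, `rr`.
#' @param mode `"RR0"` or `"RR1"`.
#' @return The input tibble with an integer `label` column (1 = comorbid)
#'   and the mode recorded in attribute `"mode"`.
#' @export
#' @examples
#' p <- tibble::tibble(disease_a = 1L, disease_b = 2L, rr = 0.5)
#' label_pairs(p, "RR0")$label  # 1
#' label_pairs(p, "RR1")$label  # 0
label_pairs <- function(pairs, mode = c("RR0", "RR1")) {
  mode <- match.arg(mode)
  stopifnot(all(c("disease_a", "disease_b", "rr") %in% names(pairs)))
  bad <- which(!is.finite(pairs$rr))
  if (length(bad) > 0) {
    abort(sprintf("non-finite RR for pair (%s, %s) at row %d",
                  pairs$disease_a[bad[1]], pairs$disease_b[bad[1]], bad[1]))
  }
  lab <- if (mode == "RR0") as.integer(pairs$rr > 0) else as.integer(pairs$rr >= 1)
  out <- tibble::as_tibble(pairs)
  out$label <- lab
  attr(out, "mode") <- mode
  out
}
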
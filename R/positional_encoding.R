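#' Normalized graph Laplacian
#'
#' Computes \eqn{\tilde L = I - D^{-1/2} A D^{-1/2}} from a symmetric,
#' nonnegative, zero-diagonal adjacency matrix. For a zero-degree node the
#' \eqn{D^{-1/2}} entry is taken as 0, so an isolated node contributes a
#' row equal to the identity row \eqn{e_i} (eigenvalue 1 for that
#' direction). Eigenvalues of \eqn{\tilde L} lie in \eqn{[0, 2]} and the
#' multiplicity of eigenvalue 0 equals the number of connected components.
#'
#' @param A Adjacency matrix (symmetric, nonnegative, zero diagonal).
#' @param zero_tol Relative threshold under which an eigenvalue counts as
#'   zero (scaled by the largest eigenvalue when the spectrum is used).
#' @return An object of class `norm_laplacian`: list with `L` (the matrix)
#'   and `zero_tol`.
#' @export
normalized_laplacian <- function(A, zero_tol = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || !isTRUE(all.equal(A, t(A), tolerance = 1e-10,
                                              check.attributes = FALSE))) {
    abort("adjacency matrix must be symmetric")
  }
  if (any(A < 0)) abort("adjacency matrix must be nonnegative")
  if (any(diag(A) != 0)) abort("adjacency matrix must have a zero diagonal")
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(nrow(A)) - (dinv * A) %*% diag(dinv, nrow(A))
  L <- (L + t(L)) / 2   # enforce exact symmetry against round-off
  dimnames(L) <- dimnames(A)
  structure(list(L = L, zero_tol = zero_tol), class = "norm_laplacian")
}

# eigenvalues ascending + matching vectors, deterministic sign
laplacian_spectrum <- function(NL) {
  e <- eigen(NL$L, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord],
       vectors = fix_signs(e$vectors[, ord, drop = FALSE]))
}

# sign convention: the largest-magnitude entry of each column is positive
# (first such entry on ties), replacing the usual arbitrary solver sign
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Laplacian eigenvector positional encoding (LPE)
#'
#' Eigendecomposes the normalized Laplacian and returns the eigenvectors
#' of the `k` smallest eigenvalues *strictly above* the zero threshold
#' (zero eigenvalues only locate connected components and carry no
#' intra-component position, so they are excluded). Columns are sorted by
#' ascending eigenvalue and sign-fixed so the largest-magnitude entry of
#' each is positive, making the encoding deterministic.
#'
#' @param NL A [normalized_laplacian()] result.
#' @param k Number of eigenvectors to keep.
#' @return An object of class `lpe`: list with `vectors` (`N x k`),
#'   `eigenvalues` (ascending) and `k`.
#' @export
laplacian_pe <- function(NL, k) {
  stopifnot(inherits(NL, "norm_laplacian"), k >= 1)
  sp <- laplacian_spectrum(NL)
  tol <- NL$zero_tol * max(abs(sp$values), 1)
  nz <- which(sp$values > tol)
  if (k > length(nz)) {
    abort(sprintf("k = %d exceeds the %d available nonzero eigenvalues", k,
                  length(nz)))
  }
  sel <- nz[seq_len(k)]
  structure(list(vectors = sp$vectors[, sel, drop = FALSE],
                 eigenvalues = sp$values[sel], k = as.integer(k)),
            class = "lpe")
}

#' Disease-label weight matrix for the graph encoder embedding
#'
#' Builds the `N x K` matrix with \eqn{W_{ij} = 1/n_j} when node `i`
#' belongs to disease module `j` (of size \eqn{n_j}) and 0 otherwise.
#' Each non-empty disease column sums to 1; a node in no disease has an
#' all-zero row, and a node in several diseases has several nonzero
#' entries.
#'
#' @param dm A `disease_map`.
#' @param N Node count of the interactome.
#' @return An `N x K` numeric matrix with disease IDs as column names.
#' @export
gee_weight_matrix <- function(dm, N) {
  stopifnot(inherits(dm, "disease_map"))
  if (any(lengths(dm$members) == 0)) abort("disease map contains an empty disease")
  if (max(unlist(dm$members)) > N) abort("disease member index exceeds node count")
  W <- matrix(0, N, dm$K, dimnames = list(NULL, dm$diseases))
  for (j in seq_len(dm$K)) {
    mem <- dm$members[[j]]
    W[mem, j] <- 1 / length(mem)
  }
  W
}

#' Graph encoder embedding (GEE)
#'
#' The label-aware embedding \eqn{Z = A W}: entry \eqn{(i, j)} equals the
#' number of neighbours of node `i` inside disease module `j`, divided by
#' the module size \eqn{n_j}.
#'
#' @param A Adjacency matrix (`N x N`).
#' @param W Weight matrix from [gee_weight_matrix()] (`N x K`).
#' @return The `N x K` embedding matrix.
#' @export
gee_embedding <- function(A, W) {
  A <- as.matrix(A)
  if (ncol(A) != nrow(W)) {
    abort(sprintf("non-conformable shapes: A is %dx%d, W is %dx%d",
                  nrow(A), ncol(A), nrow(W), ncol(W)))
  }
  A %*% W
}

#' GEE-based positional encoding (GPE)
#'
#' Compresses the `N x K` graph encoder embedding by singular value
#' decomposition, keeping the `d` left singular vectors of the largest
#' singular values (descending). Columns are sign-fixed like LPE columns.
#'
#' @param Z GEE matrix (`N x K`).
#' @param d Number of singular vectors to keep, `1 <= d <= min(N, K)`.
#' @return An object of class `gpe`: list with `vectors` (`N x d`),
#'   `singular_values` (nonincreasing) and `d`.
#' @export
gpe <- function(Z, d) {
  Z <- as.matrix(Z)
  if (d < 1 || d > min(dim(Z))) {
    abort(sprintf("d = %d out of range [1, %d]", d, min(dim(Z))))
  }
  sv <- svd(Z, nu = min(dim(Z)), nv = 0)
  structure(list(vectors = fix_signs(sv$u[, seq_len(d), drop = FALSE]),
                 singular_values = sv$d[seq_len(d)], d = as.integer(d)),
            class = "gpe")
}

#' Assemble the per-node transformer input encoding
#'
#' Combines the node-embedding matrix `M` with the positional encodings
#' according to the requested variant:
#' \describe{
#'   \item{NoPE}{`E = M` (model dimension = embedding dimension).}
#'   \item{LPE}{`E = M + LPE`, requiring `k = ncol(M)`.}
#'   \item{SPE}{`E = [(M + LPE), GPE]`, the subgraph positional encoding:
#'     the additive Laplacian term injects cluster structure and the
#'     concatenated GPE block injects disease-label structure, giving
#'     model dimension `ncol(M) + d`.}
#' }
#'
#' @param M Node embedding matrix (`N x dim`).
#' @param lpe An `lpe` object (required for variants LPE and SPE).
#' @param gpe_m A `gpe` object (required for variant SPE).
#' @param variant One of `"NoPE"`, `"LPE"`, `"SPE"`.
#' @return An object of class `encoding_bundle`: list with `variant`, `E`
#'   (`N x d_model`) and `d_model`.
#' @export
assemble_encoding <- function(M, lpe = NULL, gpe_m = NULL,
                              variant = c("SPE", "LPE", "NoPE")) {
  variant <- match.arg(variant)
  M <- unclass(M)
  attr(M, "config") <- NULL
  if (variant %in% c("LPE", "SPE")) {
    if (is.null(lpe)) abort(sprintf("variant %s requires an LPE matrix", variant))
    stopifnot(inherits(lpe, "lpe"))
    if (lpe$k != ncol(M)) {
      abort(sprintf("LPE dimension k = %d must equal embedding dimension %d",
                    lpe$k, ncol(M)))
    }
    if (nrow(lpe$vectors) != nrow(M)) abort("LPE row count does not match M")
  }
  E <- switch(variant,
    NoPE = M,
    LPE = M + lpe$vectors,
    SPE = {
      if (is.null(gpe_m)) abort("variant SPE requires a GPE matrix")
      stopifnot(inherits(gpe_m, "gpe"))
      if (nrow(gpe_m$vectors) != nrow(M)) abort("GPE row count does not match M")
      cbind(M + lpe$vectors, gpe_m$vectors)
    }
  )
  dimnames(E) <- NULL
  structure(list(variant = variant, E = E, d_model = ncol(E)),
            class = "encoding_bundle")
}

#' @export
print.encoding_bundle <- function(x, ...) {
  cat(sprintf("<encoding_bundle> variant %s, %d nodes, d_model %d\n",
              x$variant, nrow(x$E), x$d_model))
  invisible(x)
}

#' Build the per-node encoding for a graph + disease map in one call
#'
#' Convenience pipeline: node embedding (or a supplied one), normalized
#' Laplacian eigenvectors, GEE/GPE, and assembly for the chosen variant.
#'
#' @param g An `interactome`.
#' @param dm A `disease_map` (needed for SPE).
#' @param variant Encoding variant.
#' @param M Optional precomputed node-embedding matrix; computed with
#'   [embed_nodes()] under `walk_cfg` when missing.
#' @param walk_cfg A [walk_config()].
#' @param gpe_dim GPE dimension `d`.
#' @return An `encoding_bundle`.
#' @export
build_encoding <- function(g, dm = NULL, variant = c("SPE", "LPE", "NoPE"),
                           M = NULL, walk_cfg = walk_config(), gpe_dim = 8L) {
  variant <- match.arg(variant)
  if (is.null(M)) M <- embed_nodes(g, walk_cfg)
  if (variant == "NoPE") return(assemble_encoding(M, variant = "NoPE"))
  A <- adjacency_matrix(g)
  NL <- normalized_laplacian(A)
  pe <- laplacian_pe(NL, k = ncol(M))
  if (variant == "LPE") return(assemble_encoding(M, lpe = pe, variant = "LPE"))
  if (is.null(dm)) abort("variant SPE requires a disease map")
  W <- gee_weight_matrix(dm, g$N)
  Z <- gee_embedding(A, W)
  assemble_encoding(M, lpe = pe, gpe_m = gpe(Z, gpe_dim), variant = "SPE")
}
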
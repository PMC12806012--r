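adj_of <- function(g) unname(adjacency_matrix(g))

test_that("normalized Laplacian matches closed forms", {
  p2 <- normalized_laplacian(adj_of(path_interactome(2)))
  expect_equal(p2$L, matrix(c(1, -1, -1, 1) / 1, 2), tolerance = 1e-12)
  expect_equal(sort(eigen(p2$L, symmetric = TRUE)$values), c(0, 2),
               tolerance = 1e-12)

  k3 <- tspe:::interactome_from_pairs(c("a", "b", "c"), c("b", "c", "a"))
  ev <- sort(eigen(normalized_laplacian(adj_of(k3))$L, symmetric = TRUE)$values)
  expect_equal(ev, c(0, 1.5, 1.5), tolerance = 1e-12)

  two_edges <- tspe:::interactome_from_pairs(c("a", "c"), c("b", "d"))
  ev2 <- sort(eigen(normalized_laplacian(adj_of(two_edges))$L,
                    symmetric = TRUE)$values)
  expect_equal(sum(abs(ev2) < 1e-10), 2)   # one zero per component
})

test_that("normalized Laplacian validates input and handles isolated nodes", {
  expect_error(normalized_laplacian(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(normalized_laplacian(matrix(c(1, 0, 0, 0), 2)), "zero diagonal")
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1   # node 3 isolated
  L <- normalized_laplacian(A)$L
  expect_equal(L[3, ], c(0, 0, 1))
})

test_that("spectral pairs satisfy the eigen equation on random graphs", {
  withr::local_seed(31)
  for (i in 1:50) {
    n <- sample(8:60, 1)
    g <- random_interactome(n, runif(1, 0.05, 0.3), seed = 1000 + i)
    NL <- normalized_laplacian(adjacency_matrix(g))
    sp <- tspe:::laplacian_spectrum(NL)
    expect_true(all(diff(sp$values) >= -1e-12))
    expect_true(all(sp$values > -1e-8 & sp$values < 2 + 1e-8))
    # oracle: residual of the eigen equation, not the solver itself
    R <- NL$L %*% sp$vectors - sp$vectors %*% diag(sp$values, length(sp$values))
    expect_lt(max(abs(R)), 1e-8)
    G <- crossprod(sp$vectors) - diag(g$N)
    expect_lt(max(abs(G)), 1e-8)
    # multiplicity of 0 = connected components (igraph as the oracle)
    n_zero <- sum(abs(sp$values) < 1e-8)
    expect_equal(n_zero, igraph::components(as_igraph(g))$no)
  }
})

test_that("zero-eigenvalue multiplicity equals component count on forests", {
  withr::local_seed(37)
  for (i in 1:10) {
    n_trees <- sample(1:4, 1)
    pairs_a <- character(0); pairs_b <- character(0)
    for (t in seq_len(n_trees)) {
      sz <- sample(2:8, 1)
      ids <- sprintf("t%d_n%02d", t, seq_len(sz))
      parent <- vapply(2:sz, function(k) sample(k - 1, 1), integer(1))
      pairs_a <- c(pairs_a, ids[parent]); pairs_b <- c(pairs_b, ids[-1])
    }
    g <- tspe:::interactome_from_pairs(pairs_a, pairs_b)
    sp <- tspe:::laplacian_spectrum(normalized_laplacian(adjacency_matrix(g)))
    expect_equal(sum(abs(sp$values) < 1e-8), n_trees)
  }
})

test_that("LPE selects the smallest nonzero eigenpairs with fixed signs", {
  NL <- normalized_laplacian(adj_of(path_interactome(2)))
  pe <- laplacian_pe(NL, 1)
  expect_equal(as.numeric(pe$vectors), c(1, -1) / sqrt(2), tolerance = 1e-10)
  expect_equal(pe$eigenvalues, 2, tolerance = 1e-12)
  expect_error(laplacian_pe(NL, 2), "1 available nonzero")

  g <- random_interactome(30, 0.2, 7)
  NL2 <- normalized_laplacian(adjacency_matrix(g))
  pe2 <- laplacian_pe(NL2, 5)
  expect_true(all(pe2$eigenvalues > 1e-8))
  expect_lt(max(abs(crossprod(pe2$vectors) - diag(5))), 1e-8)
  # eigen equation residual against the stored eigenvalues
  R <- NL2$L %*% pe2$vectors - pe2$vectors %*% diag(pe2$eigenvalues)
  expect_lt(max(abs(R)), 1e-6)
})

test_that("GEE weight matrix implements 1/n_j membership weighting", {
  dm <- manual_disease_map(list(dX = c(1L, 2L), dY = 3L))
  W <- gee_weight_matrix(dm, 3)
  expect_equal(unname(W), cbind(c(0.5, 0.5, 0), c(0, 0, 1)))
  expect_equal(unname(colSums(W)), c(1, 1))

  dm2 <- manual_disease_map(list(dX = c(1L, 2L), dY = c(1L, 3L)))
  W2 <- gee_weight_matrix(dm2, 4)
  expect_equal(sum(W2[1, ] > 0), 2)       # overlapping node
  expect_equal(unname(rowSums(W2)[4]), 0) # node in no disease
  expect_equal(unname(colSums(W2)), c(1, 1))
})

test_that("GEE embedding equals the hand-computed product on P3", {
  g <- path_interactome(3)
  A <- adjacency_matrix(g)
  dm <- manual_disease_map(list(dX = c(1L, 2L), dY = 3L))
  Z <- gee_embedding(A, gee_weight_matrix(dm, 3))
  expect_equal(unname(Z), cbind(c(0.5, 0.5, 0.5), c(0, 1, 0)))
  # counting interpretation and the degree bound
  deg <- node_degrees(g)
  for (j in 1:2) {
    nj <- length(dm$members[[j]])
    expect_true(all(Z[, j] <= deg / nj + 1e-12))
  }
  expect_error(gee_embedding(A, matrix(0, 4, 2)), "non-conformable")
  A0 <- matrix(0, 3, 3)
  expect_true(all(gee_embedding(A0, gee_weight_matrix(dm, 3)) == 0))
})

test_that("GPE keeps the top singular subspace", {
  g <- gpe(diag(c(3, 2, 1)), 2)
  expect_equal(g$singular_values, c(3, 2))
  expect_equal(abs(unname(g$vectors)), cbind(c(1, 0, 0), c(0, 1, 0)),
               tolerance = 1e-12)

  u <- rnorm(6); v <- rnorm(4)
  g1 <- gpe(outer(u, v), 1)
  expect_lt(min(sum((g1$vectors - u / sqrt(sum(u^2)))^2),
                sum((g1$vectors + u / sqrt(sum(u^2)))^2)), 1e-20)

  withr::local_seed(41)
  for (i in 1:10) {
    Z <- matrix(rnorm(160), 20, 8)
    d <- 4
    gp <- gpe(Z, d)
    # oracle: best rank-d approximation error from a full SVD
    sv <- svd(Z)
    best <- sv$u[, 1:d] %*% diag(sv$d[1:d]) %*% t(sv$v[, 1:d])
    proj <- gp$vectors %*% crossprod(gp$vectors, Z)
    expect_lt(abs(norm(Z - proj, "F") - norm(Z - best, "F")), 1e-8)
    expect_true(all(diff(gp$singular_values) <= 1e-12))
  }
  expect_error(gpe(matrix(1, 3, 2), 3), "out of range")
})

test_that("encoding assembly follows the variant contracts", {
  withr::local_seed(43)
  g <- random_interactome(40, 0.2, 5)
  M <- matrix(rnorm(40 * 6), 40, 6)
  NL <- normalized_laplacian(adjacency_matrix(g))
  pe <- laplacian_pe(NL, 6)
  dm <- manual_disease_map(list(dA = 1:5, dB = 6:12, dC = c(3L, 13L, 14L)))
  Z <- gee_embedding(adjacency_matrix(g), gee_weight_matrix(dm, 40))
  gp <- gpe(Z, 2)

  none <- assemble_encoding(M, variant = "NoPE")
  expect_identical(none$E, M)
  lpe_b <- assemble_encoding(M, lpe = pe, variant = "LPE")
  expect_equal(lpe_b$E, M + pe$vectors)
  spe <- assemble_encoding(M, lpe = pe, gpe_m = gp, variant = "SPE")
  expect_equal(spe$d_model, 8)
  expect_equal(spe$E[, 1:6], M + pe$vectors)
  expect_equal(spe$E[, 7:8], unname(gp$vectors))

  gp0 <- gp; gp0$vectors <- gp$vectors * 0
  spe0 <- assemble_encoding(M, lpe = pe, gpe_m = gp0, variant = "SPE")
  expect_true(all(spe0$E[, 7:8] == 0))

  pe_bad <- laplacian_pe(NL, 5)
  expect_error(assemble_encoding(M, lpe = pe_bad, variant = "LPE"),
               "must equal embedding dimension")
})

test_that("default SPE dimensions compose to d_model 72", {
  # 64-dim embedding + k = 64 LPE + d = 8 GPE
  g <- random_interactome(80, 0.2, 9)
  dm <- manual_disease_map(split(1:40, rep(1:10, each = 4)))
  M <- matrix(rnorm(g$N * 64), g$N, 64)
  enc <- build_encoding(g, dm, "SPE", M = M, gpe_dim = 8)
  expect_equal(enc$d_model, 72)
})

test_that("disease permutation permutes GEE columns identically", {
  g <- random_interactome(30, 0.2, 13)
  A <- adjacency_matrix(g)
  dm <- manual_disease_map(list(d1 = 1:4, d2 = 5:10, d3 = c(2L, 11L)))
  Z <- gee_embedding(A, gee_weight_matrix(dm, g$N))
  perm <- c(3, 1, 2)
  dmp <- manual_disease_map(dm$members[perm])
  Zp <- gee_embedding(A, gee_weight_matrix(dmp, g$N))
  expect_equal(unname(Zp), unname(Z[, perm]))
  # column permutation leaves singular values and left subspace unchanged
  g1 <- gpe(Z, 2); g2 <- gpe(Zp, 2)
  expect_equal(g1$singular_values, g2$singular_values, tolerance = 1e-10)
  P1 <- g1$vectors %*% t(g1$vectors); P2 <- g2$vectors %*% t(g2$vectors)
  expect_lt(max(abs(P1 - P2)), 1e-8)
})

test_that("node relabelling permutes all encodings by the same permutation", {
  withr::local_seed(47)
  g <- random_interactome(25, 0.25, 17)
  A <- adjacency_matrix(g)
  dm <- manual_disease_map(list(d1 = 1:6, d2 = 7:15))
  perm <- sample(25)
  Ap <- A[perm, perm]
  dmp <- manual_disease_map(lapply(dm$members, function(m) match(m, perm)))

  W <- gee_weight_matrix(dm, 25); Wp <- gee_weight_matrix(dmp, 25)
  Z <- gee_embedding(A, W); Zp <- gee_embedding(Ap, Wp)
  expect_equal(unname(Zp), unname(Z[perm, ]))

  k <- 4
  pe <- laplacian_pe(normalized_laplacian(A), k)
  pep <- laplacian_pe(normalized_laplacian(Ap), k)
  expect_equal(pep$eigenvalues, pe$eigenvalues, tolerance = 1e-10)
  for (j in seq_len(k)) {
    dpos <- max(abs(pep$vectors[, j] - pe$vectors[perm, j]))
    dneg <- max(abs(pep$vectors[, j] + pe$vectors[perm, j]))
    expect_lt(min(dpos, dneg), 1e-7)   # equal up to per-column sign
  }
})
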
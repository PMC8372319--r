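# Triangle parameterization, eigensolver contract, diagonalization gradient,
# sum pooling, and end-to-end prediction symmetries.

test_that("triangle <-> symmetric matrix is an exact bitwise round trip", {
  set.seed(21)
  for (n in c(2L, 4L, 6L)) {
    tri <- rnorm(n * (n + 1) / 2)
    H <- tri_to_symmetric(tri, n)
    expect_identical(H, t(H))                  # bitwise symmetric
    expect_identical(symmetric_to_tri(H), tri)
  }
})

test_that("eigenvalues_from_matrix honors the spec worked examples and oracle", {
  expect_equal(eigenvalues_from_matrix(diag(3)), c(1, 1, 1))
  expect_equal(eigenvalues_from_matrix(matrix(c(0, 1, 1, 0), 2)), c(-1, 1))
  expect_error(eigenvalues_from_matrix(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  set.seed(22)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    H <- rand_sym(n, scale = 3)
    vals <- eigenvalues_from_matrix(H)
    expect_false(is.unsorted(vals))
    expect_lt(max(abs(vals - charpoly_eigen(H))), 1e-8)
    e <- eigenvalues_from_matrix(H, vectors = TRUE)
    recon <- e$vectors %*% diag(e$values, n) %*% t(e$vectors)
    expect_lt(max(abs(recon - H)), 1e-8)
  }
})

test_that("the diagonalization gradient is the eigenvector outer product", {
  # decoupled diagonal case
  g <- eigenvalue_gradient(diag(c(-2, 0, 5)), 1)
  expect_equal(unclass(g), diag(c(1, 0, 0)), ignore_attr = TRUE)
  # analytic 2x2 case: lower eigenvector (1, -1)/sqrt(2)
  g2 <- eigenvalue_gradient(matrix(c(0, 1, 1, 0), 2), 1)
  expect_equal(unclass(g2), 0.5 * matrix(c(1, -1, -1, 1), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(attr(g2, "degenerate"), 0L)
  expect_identical(attr(eigenvalue_gradient(diag(2), 1), "degenerate"), 1L)
  # finite differences on well-gapped random matrices
  set.seed(23)
  h <- 1e-5
  tried <- 0L
  while (tried < 10L) {
    H <- rand_sym(5, scale = 2)
    if (min(diff(eigenvalues_from_matrix(H))) <= 1e-2) next
    tried <- tried + 1L
    i <- sample(5, 1)
    g <- eigenvalue_gradient(H, i)
    for (rep in 1:3) {
      a <- sample(5, 1); b <- sample(5, 1)
      Hp <- H; Hp[a, b] <- Hp[a, b] + h; Hp[b, a] <- Hp[a, b]
      Hm <- H; Hm[a, b] <- Hm[a, b] - h; Hm[b, a] <- Hm[a, b]
      fd <- (eigenvalues_from_matrix(Hp)[i] - eigenvalues_from_matrix(Hm)[i]) /
        (2 * h)
      analytic <- if (a == b) g[a, a] else 2 * g[a, b]
      expect_lt(abs(fd - analytic) / max(1, abs(fd)), 1e-4)
    }
  }
})

test_that("head_predict and head_backward agree with the scalar algebra", {
  hc <- head_config("hamiltonian", n_max = 4L)
  set.seed(24)
  out <- matrix(rnorm(3 * hc$n_out, sd = 2), 3, hc$n_out)
  fwd <- head_predict(out, hc)
  for (m in 1:3) {
    H <- tri_to_symmetric(out[m, ], 4L)
    expect_equal(fwd$pred[m, ], eigenvalues_from_matrix(H), tolerance = 1e-12)
  }
  # backward vs finite differences through sorted eigenvalues
  w <- matrix(rnorm(3 * 4), 3, 4)
  d_out <- head_backward(out, hc, fwd, w)
  h <- 1e-6
  for (m in 1:3) for (q in sample(hc$n_out, 4)) {
    op <- out[m, ]; op[q] <- op[q] + h
    om <- out[m, ]; om[q] <- om[q] - h
    fd <- sum(w[m, ] * (eigenvalues_from_matrix(tri_to_symmetric(op, 4L)) -
                          eigenvalues_from_matrix(tri_to_symmetric(om, 4L)))) /
      (2 * h)
    expect_lt(abs(fd - d_out[m, q]) / max(1, abs(fd)), 1e-4)
  }
  # the multistate head passes gradients through unchanged
  hm <- head_config("multistate", n_max = 4L)
  expect_identical(head_backward(w, hm, list(pred = w), w), w)
})

test_that("heads sum-pool: two far-apart copies double a zero-bias output", {
  enc <- encoder_config(n_features = 10L, n_blocks = 1L, n_rbf = 6L,
                        cutoff = 4)
  w <- tiny_water()
  two <- atomic_structure(c(w$elements, w$elements),
                          rbind(w$positions, w$positions +
                                  matrix(c(50, 0, 0), 3, 3, byrow = TRUE)))
  for (type in c("hamiltonian", "multistate", "single")) {
    hc <- head_config(type, n_max = 3L)
    model <- init_model(enc, hc, seed = 25)       # bias stays zero
    b1 <- assemble_batch(list(mol_graph(w, enc)))
    b2 <- assemble_batch(list(mol_graph(two, enc)))
    o1 <- net_forward(model$params, enc, hc, b1)$out
    o2 <- net_forward(model$params, enc, hc, b2)$out
    expect_equal(o2, 2 * o1, tolerance = 1e-10)
  }
})

test_that("predicted eigenvalues are invariant, ascending, and n_max-shaped", {
  enc <- encoder_config(n_features = 12L, n_blocks = 2L, n_rbf = 8L)
  hc <- head_config("hamiltonian", n_max = 5L)
  model <- init_model(enc, hc, seed = 26, bias_init = c(-9, -6, -3, 0, 2))
  set.seed(26)
  structures <- lapply(1:5, function(k) .random_chain(sample(2:8, 1),
                                                      sprintf("p%d", k)))
  pred <- predict_eigenvalues(model, structures)
  expect_equal(dim(pred), c(5L, 5L))             # n_max columns for any N_a
  expect_true(all(apply(pred, 1, function(r) !is.unsorted(r))))
  for (s in structures) {
    p0 <- predict_eigenvalues(model, s)
    expect_lt(max(abs(predict_eigenvalues(model, random_rigid(s)) - p0)), 1e-8)
    perm <- sample(length(s$elements))
    sp <- atomic_structure(s$elements[perm], s$positions[perm, , drop = FALSE])
    expect_lt(max(abs(predict_eigenvalues(model, sp) - p0)), 1e-8)
  }
  mats <- predict_eigenvalues(model, structures, matrices = TRUE)$matrices
  for (H in mats) expect_identical(H, t(H))      # bitwise symmetry
  # conformers generally differ (non-degenerate model)
  expect_gt(stats::sd(pred[, 1]), 0)
})

test_that("init_model centers each head on the supplied mean spectrum", {
  enc <- encoder_config(n_features = 8L, n_blocks = 1L, n_rbf = 6L)
  mu <- c(-12, -8, -5)
  mh <- init_model(enc, head_config("hamiltonian", 3L), seed = 3,
                   bias_init = mu)
  expect_equal(diag(tri_to_symmetric(mh$params$head$bias, 3L)), mu)
  mm <- init_model(enc, head_config("multistate", 3L), seed = 3,
                   bias_init = mu)
  expect_equal(mm$params$head$bias, mu)
  m1 <- init_model(enc, head_config("single", 3L, slot = 2L), seed = 3,
                   bias_init = mu)
  expect_equal(m1$params$head$bias, -8)
})
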
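# Independent oracles used across test files.

# Characteristic polynomial coefficients by the Faddeev-LeVerrier recursion
# (trace-based; independent of any eigensolver). Returns c0..cn with
# p(x) = sum_k c_k x^k, leading coefficient 1.
charpoly_coeffs <- function(A) {
  n <- nrow(A)
  cf <- numeric(n + 1)
  cf[n + 1] <- 1
  M <- diag(n)
  for (k in seq_len(n)) {
    AM <- A %*% M
    cf[n + 1 - k] <- -sum(diag(AM)) / k
    M <- AM + cf[n + 1 - k] * diag(n)
  }
  cf
}

# Eigenvalues of a symmetric matrix as roots of its characteristic
# polynomial (polyroot), sorted ascending. Accurate for generic (simple)
# spectra; at multiple roots polyroot degrades to ~sqrt(machine eps), so
# degenerate spectra are checked with charpoly_residual instead.
charpoly_eigen <- function(A) {
  sort(Re(polyroot(charpoly_coeffs(A))))
}

# Residuals of the (shift-and-scale normalized) characteristic polynomial
# evaluated at candidate eigenvalues: |p((v - mu)/s)| with the polynomial
# of (A - mu I)/s. Robust to eigenvalue multiplicities because it never
# extracts roots.
charpoly_residual <- function(A, vals) {
  n <- nrow(A)
  mu <- mean(diag(A))
  s <- max(abs(A - mu * diag(n)), 1e-12)
  cf <- charpoly_coeffs((A - mu * diag(n)) / s)
  vapply((vals - mu) / s, function(x) abs(sum(cf * x^(0:n))), 0)
}

# Brute-force all-pairs neighbor enumeration.
brute_force_pairs <- function(positions, cutoff) {
  n <- nrow(positions)
  out <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    d <- sqrt(sum((positions[a, ] - positions[b, ])^2))
    if (d <= cutoff) out <- rbind(out, c(a, b, d))
  }
  out
}

# Random symmetric matrix.
rand_sym <- function(n, scale = 1) {
  A <- matrix(rnorm(n * n, sd = scale), n, n)
  (A + t(A)) / 2
}

# Random rigid motion applied to a structure.
random_rigid <- function(structure) {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, sd = 3)
  atomic_structure(structure$elements,
                   structure$positions %*% Q +
                     matrix(shift, nrow(structure$positions), 3, byrow = TRUE),
                   id = structure$id)
}

# Tiny water-like structure shared by several files.
tiny_water <- function() {
  atomic_structure(c(8L, 1L, 1L),
                   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                   id = "w")
}

# Small trained-model cache so several test files can share one short
# training run instead of refitting.
.fit_cache <- new.env()
cached_small_fit <- function(head = "hamiltonian") {
  key <- paste0("fit_", head)
  if (is.null(.fit_cache[[key]])) {
    suite <- make_benchmark_suite(seed = 42, sizes = list(A = 120L), only = "A")
    ctl <- train_control(lr = 1e-2, batch_size = 32, max_epochs = 40,
                         patience = 40, seed = 5)
    enc <- encoder_config(n_features = 16, n_blocks = 2, n_rbf = 12, cutoff = 5)
    .fit_cache[[key]] <- pseudoham(suite$A, head = head, encoder = enc,
                                   control = ctl, seed = 5)
    .fit_cache[[paste0("data_", head)]] <- suite$A
  }
  list(fit = .fit_cache[[key]], data = .fit_cache[[paste0("data_", head)]])
}
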
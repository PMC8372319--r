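# Continuous-filter message-passing network (SchNet family) with three
# output heads, implemented with explicit forward/backward passes in
# vectorized base R. Everything is a function of interatomic distances, so
# predictions are invariant to rigid motions by construction and
# permutation-equivariant at the feature level.

#' Encoder configuration
#'
#' @param n_features atomic feature width F.
#' @param n_blocks number of interaction blocks T.
#' @param n_rbf number of Gaussian radial basis functions K.
#' @param cutoff interaction cutoff in Angstrom; the cosine cutoff makes
#'   messages vanish smoothly there.
#' @param gamma Gaussian basis width parameter (1/Angstrom^2); default
#'   places the basis widths at the center spacing.
#' @param z_max largest atomic number in the element-embedding table.
#' @return list of class \code{"encoder_config"}.
#' @export
encoder_config <- function(n_features = 128L, n_blocks = 3L, n_rbf = 25L,
                           cutoff = 5.0, gamma = NULL, z_max = 10L) {
  stopifnot(n_features >= 1, n_blocks >= 0, n_rbf >= 1, cutoff > 0)
  mu <- seq(0, cutoff, length.out = n_rbf)
  if (is.null(gamma)) gamma <- 1 / (2 * (mu[2] - mu[1])^2)
  structure(list(n_features = as.integer(n_features),
                 n_blocks = as.integer(n_blocks),
                 n_rbf = as.integer(n_rbf), cutoff = cutoff,
                 gamma = gamma, mu = mu, z_max = as.integer(z_max)),
            class = "encoder_config")
}

#' Shifted softplus nonlinearity
#'
#' ssp(x) = ln(0.5 e^x + 0.5); smooth, ssp(0) = 0, derivative sigmoid(x).
#' @param x numeric.
#' @keywords internal
ssp <- function(x) pmax(x, 0) + log1p(exp(-abs(x))) - log(2)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Gaussian radial basis expansion of a distance
#'
#' K Gaussians exp(-gamma (d - mu_k)^2) on evenly spaced centers in
#' [0, cutoff]; every entry lies in (0, 1].
#'
#' @param d numeric vector of distances (Angstrom, >= 0).
#' @param config an \code{encoder_config}.
#' @return length(d) x K matrix.
#' @export
rbf_expand <- function(d, config) {
  stopifnot(all(d >= 0))
  exp(-config$gamma * outer(d, config$mu, "-")^2)
}

#' Smooth cosine cutoff function
#'
#' 0.5 (cos(pi d / cutoff) + 1) for d < cutoff, 0 beyond; continuously
#' differentiable damping of messages at the graph boundary.
#' @param d distances (Angstrom).
#' @param cutoff cutoff radius (Angstrom).
#' @keywords internal
cosine_cutoff <- function(d, cutoff) {
  ifelse(d < cutoff, 0.5 * (cos(pi * d / cutoff) + 1), 0)
}

# scatter-add rows of m into an n-row zero matrix by index
index_sum <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  if (length(idx)) {
    s <- rowsum(m, idx)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

uniform_init <- function(nr, nc, fan_in = nr) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

#' Head configuration
#'
#' @param type "hamiltonian" (pseudo-Hamiltonian head, eigenvalues of a
#'   learned n_max x n_max symmetric matrix), "multistate" (direct
#'   n_max-vector regression) or "single" (one scalar output for one slot).
#' @param n_max number of eigenvalue slots.
#' @param n_hidden hidden width of the two atom-wise output layers; NULL
#'   picks the multistate default (n_features / 2).
#' @param slot target slot index for a "single" head.
#' @return list of class \code{"head_config"}.
#' @export
head_config <- function(type = c("hamiltonian", "multistate", "single"),
                        n_max, n_hidden = NULL, slot = 1L) {
  type <- match.arg(type)
  n_out <- switch(type, hamiltonian = n_max * (n_max + 1L) / 2L,
                  multistate = n_max, single = 1L)
  # precomputed index maps for the triangle <-> symmetric-matrix algebra
  ut <- upper.tri(matrix(0, n_max, n_max), diag = TRUE)
  tri_map <- matrix(0L, n_max, n_max)
  tri_map[ut] <- seq_len(sum(ut))
  tri_map[lower.tri(tri_map)] <- t(tri_map)[lower.tri(tri_map)]
  dbl <- matrix(2, n_max, n_max); diag(dbl) <- 1
  structure(list(type = type, n_max = as.integer(n_max),
                 n_hidden = if (is.null(n_hidden)) NULL else as.integer(n_hidden),
                 n_out = as.integer(n_out), slot = as.integer(slot),
                 tri_map = as.integer(tri_map), ut_idx = which(ut),
                 dbl = dbl),
            class = "head_config")
}

# Pick the hamiltonian-head hidden width so its parameter count matches a
# multistate head of hidden width f2_ms as closely as possible ("almost the
# same number of parameters" across compared heads).
match_budget_hidden <- function(encoder, n_max, f2_ms) {
  f <- encoder$n_features
  npair <- n_max * (n_max + 1L) / 2L
  ms_count <- f2_ms * (f + 1L + n_max) + n_max
  max(1L, round((ms_count - npair) / (f + 1L + npair)))
}

#' Initialize a pseudo-Hamiltonian network model
#'
#' Weights use uniform fan-in scaling; the post-pooling output bias is
#' initialized to a supplied mean spectrum (for the hamiltonian head it is
#' placed on the matrix diagonal) so early training starts on the right
#' energy scale.
#'
#' @param encoder an \code{encoder_config}.
#' @param head a \code{head_config}.
#' @param seed integer seed for the parameter draw.
#' @param bias_init optional numeric vector of length n_max (mean training
#'   spectrum, eV); for a "single" head, a scalar.
#' @return list of class \code{"ph_model"}.
#' @export
init_model <- function(encoder, head, seed = 1L, bias_init = NULL) {
  f <- encoder$n_features; k <- encoder$n_rbf
  f2 <- if (!is.null(head$n_hidden)) head$n_hidden else max(1L, f %/% 2L)
  with_seed(seed, {
    params <- list(
      emb = matrix(stats::runif(encoder$z_max * f, -0.5, 0.5),
                   encoder$z_max, f),
      blocks = lapply(seq_len(encoder$n_blocks), function(t) list(
        Wf1 = uniform_init(k, f), bf1 = numeric(f),
        Wf2 = uniform_init(f, f), bf2 = numeric(f),
        W_in = uniform_init(f, f),
        W1 = uniform_init(f, f), b1 = numeric(f),
        W2 = uniform_init(f, f), b2 = numeric(f))),
      head = list(A1 = uniform_init(f, f2), c1 = numeric(f2),
                  A2 = uniform_init(f2, head$n_out) * 0.1,
                  bias = numeric(head$n_out)))
    if (!is.null(bias_init)) {
      if (head$type == "hamiltonian") {
        b <- matrix(0, head$n_max, head$n_max)
        diag(b) <- bias_init
        params$head$bias <- b[upper.tri(b, diag = TRUE)]
      } else if (head$type == "multistate") {
        params$head$bias <- as.numeric(bias_init)
      } else {
        params$head$bias <- as.numeric(bias_init)[head$slot]
      }
    }
    structure(list(encoder = encoder, head = head, params = params,
                   n_hidden = f2, seed = as.integer(seed)),
              class = "ph_model")
  })
}

#' Count trainable parameters of a model
#' @param model a \code{ph_model}.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(unlist(model$params, recursive = TRUE), length, 1L))
}

# ---- batched molecular graphs -------------------------------------------

# Precompute the invariant (parameter-free) graph of one structure.
mol_graph <- function(structure, encoder) {
  nb <- build_neighbor_list(structure, encoder$cutoff)
  list(z = structure$elements, n = n_atoms(structure),
       i = nb$i, j = nb$j, d = nb$d,
       rb = rbf_expand(nb$d, encoder),
       fc = cosine_cutoff(nb$d, encoder$cutoff))
}

# Concatenate a list of molecular graphs into one batch with global indices.
assemble_batch <- function(graphs) {
  ns <- vapply(graphs, `[[`, 0L, "n")
  off <- cumsum(c(0L, ns[-length(ns)]))
  list(z = unlist(lapply(graphs, `[[`, "z")),
       mol = rep(seq_along(graphs), ns),
       n_atoms = sum(ns), n_mol = length(graphs),
       i = unlist(mapply(function(g, o) g$i + o, graphs, off,
                         SIMPLIFY = FALSE)),
       j = unlist(mapply(function(g, o) g$j + o, graphs, off,
                         SIMPLIFY = FALSE)),
       d = unlist(lapply(graphs, `[[`, "d")),
       rb = do.call(rbind, lapply(graphs, `[[`, "rb")),
       fc = unlist(lapply(graphs, `[[`, "fc")))
}

# ---- forward pass --------------------------------------------------------

# Forward through embedding + interaction blocks + atom-wise head layers and
# sum-pooling. Returns pooled outputs (n_mol x n_out) and, if requested, the
# cache needed by net_backward.
net_forward <- function(params, encoder, head_cfg, batch, keep_cache = FALSE) {
  x <- params$emb[batch$z, , drop = FALSE]
  cache <- if (keep_cache) list(x0 = x, blocks = vector("list", encoder$n_blocks))
  for (t in seq_len(encoder$n_blocks)) {
    p <- params$blocks[[t]]
    x_in <- x
    pre_f <- sweep(batch$rb %*% p$Wf1, 2, p$bf1, "+")
    sf <- ssp(pre_f)
    wd <- (sweep(sf %*% p$Wf2, 2, p$bf2, "+")) * batch$fc
    xin <- x %*% p$W_in
    msg <- xin[batch$i, , drop = FALSE] * wd     # message from neighbor i -> center j? see below
    agg <- index_sum(msg, batch$j, batch$n_atoms)
    pre1 <- sweep(agg %*% p$W1, 2, p$b1, "+")
    h1 <- ssp(pre1)
    x <- x_in + sweep(h1 %*% p$W2, 2, p$b2, "+")
    if (keep_cache)
      cache$blocks[[t]] <- list(x_in = x_in, pre_f = pre_f, sf = sf, wd = wd,
                                xin = xin, agg = agg, pre1 = pre1, h1 = h1)
  }
  hp <- params$head
  pre_h <- sweep(x %*% hp$A1, 2, hp$c1, "+")
  y1 <- ssp(pre_h)
  y2 <- y1 %*% hp$A2
  pooled <- index_sum(y2, batch$mol, batch$n_mol)
  out <- sweep(pooled, 2, hp$bias, "+")
  if (keep_cache) {
    cache$x <- x; cache$pre_h <- pre_h; cache$y1 <- y1
    list(out = out, cache = cache)
  } else list(out = out)
}

# ---- backward pass -------------------------------------------------------

# d_out: n_mol x n_out gradient of the loss w.r.t. the pooled outputs.
# Returns gradients in the same nested structure as params.
net_backward <- function(params, encoder, head_cfg, batch, cache, d_out) {
  hp <- params$head
  g <- list(head = list(), blocks = vector("list", encoder$n_blocks))
  g$head$bias <- colSums(d_out)
  dy2 <- d_out[batch$mol, , drop = FALSE]
  g$head$A2 <- crossprod(cache$y1, dy2)
  dy1 <- dy2 %*% t(hp$A2)
  dpre_h <- dy1 * sigmoid(cache$pre_h)
  g$head$A1 <- crossprod(cache$x, dpre_h)
  g$head$c1 <- colSums(dpre_h)
  dx <- dpre_h %*% t(hp$A1)
  for (t in rev(seq_len(encoder$n_blocks))) {
    p <- params$blocks[[t]]; cb <- cache$blocks[[t]]
    du2 <- dx                                  # gradient w.r.t. the block update
    g$blocks[[t]] <- list()
    g$blocks[[t]]$W2 <- crossprod(cb$h1, du2)
    g$blocks[[t]]$b2 <- colSums(du2)
    dh1 <- du2 %*% t(p$W2)
    dpre1 <- dh1 * sigmoid(cb$pre1)
    g$blocks[[t]]$W1 <- crossprod(cb$agg, dpre1)
    g$blocks[[t]]$b1 <- colSums(dpre1)
    dagg <- dpre1 %*% t(p$W1)
    dmsg <- dagg[batch$j, , drop = FALSE]
    dwd <- dmsg * cb$xin[batch$i, , drop = FALSE]
    dxin <- index_sum(dmsg * cb$wd, batch$i, batch$n_atoms)
    g$blocks[[t]]$W_in <- crossprod(cb$x_in, dxin)
    # filter network
    dft <- dwd * batch$fc
    g$blocks[[t]]$Wf2 <- crossprod(cb$sf, dft)
    g$blocks[[t]]$bf2 <- colSums(dft)
    dsf <- dft %*% t(p$Wf2)
    dpre_f <- dsf * sigmoid(cb$pre_f)
    g$blocks[[t]]$Wf1 <- crossprod(batch$rb, dpre_f)
    g$blocks[[t]]$bf1 <- colSums(dpre_f)
    dx <- dx + dxin %*% t(p$W_in)              # residual + message path
  }
  g$emb <- index_sum(dx, batch$z, encoder$z_max)
  g[c("emb", "blocks", "head")]
}

# ---- head algebra --------------------------------------------------------

#' Assemble a pseudo-Hamiltonian from its unique upper-triangle entries
#'
#' The head predicts the n_max(n_max+1)/2 unique entries; mirroring makes
#' the matrix exactly symmetric by construction (bitwise H_ij == H_ji).
#'
#' @param tri numeric vector of upper-triangle entries (column-major,
#'   diagonal included).
#' @param n_max matrix dimension.
#' @return n_max x n_max symmetric matrix (eV).
#' @export
tri_to_symmetric <- function(tri, n_max) {
  H <- matrix(0, n_max, n_max)
  H[upper.tri(H, diag = TRUE)] <- tri
  H[lower.tri(H)] <- t(H)[lower.tri(H)]
  H
}

symmetric_to_tri <- function(H) H[upper.tri(H, diag = TRUE)]

#' Eigenvalues of a pseudo-Hamiltonian
#'
#' Ascending eigenvalues of the real symmetric eigenproblem (LAPACK);
#' the sorted diagonal of U^T H U.
#'
#' @param H symmetric numeric matrix (eV).
#' @param vectors also return the eigenvectors (columns matching the
#'   ascending values).
#' @return numeric vector of ascending eigenvalues, or (with
#'   \code{vectors = TRUE}) a list with \code{values} and \code{vectors}.
#' @export
eigenvalues_from_matrix <- function(H, vectors = FALSE) {
  if (!isSymmetric(unname(H), tol = 1e-10))
    stop("pseudo-Hamiltonian must be symmetric")
  e <- eigen(H, symmetric = TRUE, only.values = !vectors)
  idx <- rev(seq_along(e$values))              # LAPACK returns descending
  if (!vectors) return(e$values[idx])
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

#' Gradient of one eigenvalue with respect to the matrix
#'
#' For a simple eigenvalue eps_i of a symmetric H, d eps_i / dH is the outer
#' product u_i u_i^T of its eigenvector: the backpropagation rule through
#' the diagonalization. Near-degenerate eigenvalues (gap < 1e-8 eV) are
#' handled by the same formula with LAPACK's orthogonal eigenvectors and
#' counted in the returned attribute \code{"degenerate"}.
#'
#' @param H symmetric numeric matrix.
#' @param i eigenvalue index (1 = lowest).
#' @return matrix d eps_i / dH with attribute \code{"degenerate"} (0/1).
#' @export
eigenvalue_gradient <- function(H, i) {
  e <- eigenvalues_from_matrix(H, vectors = TRUE)
  u <- e$vectors[, i]
  gaps <- abs(e$values - e$values[i]); gaps[i] <- Inf
  grad <- tcrossprod(u)
  attr(grad, "degenerate") <- as.integer(min(gaps) < 1e-8)
  grad
}

# Batched head evaluation: pooled outputs -> per-molecule eigenvalue
# predictions. For the hamiltonian head also returns eigenvectors for the
# backward pass.
head_predict <- function(out, head_cfg) {
  if (head_cfg$type != "hamiltonian")
    return(list(pred = out))
  n_mol <- nrow(out); n_max <- head_cfg$n_max
  pred <- matrix(0, n_mol, n_max)
  vecs <- vector("list", n_mol)
  rv <- n_max:1                                # LAPACK descending -> ascending
  for (m in seq_len(n_mol)) {
    H <- matrix(out[m, head_cfg$tri_map], n_max, n_max)
    e <- eigen(H, symmetric = TRUE)
    pred[m, ] <- e$values[rv]
    vecs[[m]] <- e$vectors[, rv, drop = FALSE]
  }
  list(pred = pred, vectors = vecs)
}

# Map per-molecule eigenvalue gradients (n_mol x n_max) back to gradients
# w.r.t. the pooled triangle entries, via dL/dH = U diag(g) U^T and the
# chain rule of the mirror parameterization (off-diagonal entries feed two
# matrix positions). Counts non-finite backward events and falls back to a
# jittered re-diagonalization.
head_backward <- function(out, head_cfg, fwd, d_pred, degeneracy_counter = NULL) {
  if (head_cfg$type != "hamiltonian") return(d_pred)
  n_mol <- nrow(out); n_max <- head_cfg$n_max
  d_out <- matrix(0, n_mol, head_cfg$n_out)
  for (m in seq_len(n_mol)) {
    U <- fwd$vectors[[m]]
    G <- U %*% (d_pred[m, ] * t(U))
    if (!all(is.finite(G))) {
      if (!is.null(degeneracy_counter))
        degeneracy_counter$jitter <- degeneracy_counter$jitter + 1L
      H <- tri_to_symmetric(out[m, ], n_max)
      diag(H) <- diag(H) + stats::runif(n_max, -1e-10, 1e-10)
      e <- eigenvalues_from_matrix(H, vectors = TRUE)
      U <- e$vectors
      G <- U %*% (d_pred[m, ] * t(U))
    }
    d_out[m, ] <- (G * head_cfg$dbl)[head_cfg$ut_idx]
  }
  d_out
}

#' Per-atom features of a structure
#'
#' Runs the element embedding and the interaction blocks (no head): the
#' learned atom-wise representation x_a.
#'
#' @param model a \code{ph_model}.
#' @param structure an \code{atomic_structure}.
#' @return N_a x F numeric matrix.
#' @export
encode <- function(model, structure) {
  if (any(structure$elements > model$encoder$z_max))
    stop("element outside embedding table (z_max = ", model$encoder$z_max,
         "); supported z <= ", model$encoder$z_max)
  batch <- assemble_batch(list(mol_graph(structure, model$encoder)))
  params <- model$params
  x <- params$emb[batch$z, , drop = FALSE]
  for (t in seq_len(model$encoder$n_blocks)) {
    p <- params$blocks[[t]]
    pre_f <- sweep(batch$rb %*% p$Wf1, 2, p$bf1, "+")
    wd <- (sweep(ssp(pre_f) %*% p$Wf2, 2, p$bf2, "+")) * batch$fc
    xin <- x %*% p$W_in
    agg <- index_sum(xin[batch$i, , drop = FALSE] * wd, batch$j, batch$n_atoms)
    x <- x + sweep(ssp(sweep(agg %*% p$W1, 2, p$b1, "+")) %*% p$W2, 2, p$b2, "+")
  }
  x
}

#' Predict eigenvalues (and pseudo-Hamiltonians) for structures
#'
#' Full forward pass: encode, head, and for the hamiltonian head the
#' diagonalization. Output rows are ascending; the prediction covers all
#' n_max slots (consumers apply reference masks).
#'
#' @param model a \code{ph_model}.
#' @param structures an \code{atomic_structure} or list of them.
#' @param matrices for the hamiltonian head, also return the predicted
#'   pseudo-Hamiltonian matrices.
#' @return n x n_max matrix of eigenvalues in eV (with
#'   \code{matrices = TRUE}, a list with \code{values} and
#'   \code{matrices}).
#' @export
predict_eigenvalues <- function(model, structures, matrices = FALSE) {
  if (inherits(structures, "atomic_structure")) structures <- list(structures)
  batch <- assemble_batch(lapply(structures, mol_graph, encoder = model$encoder))
  out <- net_forward(model$params, model$encoder, model$head, batch)$out
  if (model$head$type == "hamiltonian") {
    fwd <- head_predict(out, model$head)
    pred <- fwd$pred
    if (matrices) {
      mats <- lapply(seq_len(nrow(out)), function(m)
        tri_to_symmetric(out[m, ], model$head$n_max))
      return(list(values = pred, matrices = mats))
    }
    pred
  } else if (ncol(out) > 1L) {
    matrix(apply(out, 1, sort), nrow = nrow(out), byrow = TRUE)
  } else {
    out                                        # single-slot head
  }
}
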
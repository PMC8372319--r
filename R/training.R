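# Masked eigenvalue loss, first-order optimization, and the pseudoham()
# fitting interface.

#' Masked mean-squared eigenvalue loss
#'
#' Mean over the masked-true slots of (pred_i - ref_i)^2, slots matched
#' index-wise with both sides ascending. Padding slots contribute exactly
#' zero, including zero gradient.
#'
#' @param pred numeric n_max-vector of predicted energies (eV), ascending.
#' @param ref an \code{eigen_record}.
#' @return scalar loss (eV^2).
#' @export
masked_l2_loss <- function(pred, ref) {
  if (!any(ref$mask)) stop("record has no valid slots")
  mean((pred[ref$mask] - ref$values[ref$mask])^2)
}

#' Training control parameters
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (molecules).
#' @param max_epochs maximum epochs.
#' @param patience early-stopping patience on validation loss (epochs).
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is decayed.
#' @param lr_decay multiplicative decay factor.
#' @param min_lr floor for the learning rate.
#' @param seed seed for shuffling (parameter init has its own seed).
#' @param verbose print a line every \code{verbose} epochs (0 = silent).
#' @return list of class \code{"train_control"}.
#' @export
train_control <- function(lr = 5e-3, batch_size = 32L, max_epochs = 200L,
                          patience = 30L, lr_patience = 12L, lr_decay = 0.5,
                          min_lr = 1e-4, seed = 1L, verbose = 0L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_patience = as.integer(lr_patience), lr_decay = lr_decay,
                 min_lr = min_lr, seed = as.integer(seed),
                 verbose = as.integer(verbose)),
            class = "train_control")
}

# recursive map over parameter structures (lists of numeric leaves)
map_params <- function(f, ...) {
  ls <- list(...)
  a <- ls[[1]]
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (k in seq_along(a))
      out[[k]] <- do.call(map_params,
                          c(list(f), lapply(ls, function(x)
                            if (!is.null(names(a))) x[[names(a)[k]]] else x[[k]])))
    out
  } else do.call(f, ls)
}

adam_init <- function(params)
  list(m = map_params(function(x) x * 0, params),
       v = map_params(function(x) x * 0, params), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# Per-batch loss and gradient w.r.t. predictions under the mean convention:
# mean over molecules of the per-molecule mean over valid slots.
batch_loss_grad <- function(pred, ref, mask, nvalid) {
  resid <- (pred - ref) * mask
  per_mol <- rowSums(resid^2) / nvalid
  list(loss = mean(per_mol),
       d_pred = 2 * resid / (nvalid * length(nvalid)))
}

# Forward + masked loss for a fixed batch (no gradient), used for
# validation.
eval_loss <- function(params, encoder, head_cfg, batch, ref, mask, nvalid) {
  out <- net_forward(params, encoder, head_cfg, batch)$out
  pred <- head_predict(out, head_cfg)$pred
  resid <- (pred - ref) * mask
  loss <- mean(rowSums(resid^2) / nvalid)
  mae <- sum(abs(resid)) / sum(nvalid)
  list(loss = loss, mae = mae)
}

# Core optimization loop over a prepared dataset. targets$ref / targets$mask
# are n x n_out matrices aligned with `graphs`.
fit_network <- function(model, graphs, targets, idx_train, idx_val, control) {
  ref <- targets$ref; mask <- targets$mask
  nvalid_all <- rowSums(mask)
  if (any(nvalid_all[c(idx_train, idx_val)] < 1))
    stop("every training/validation record needs at least one valid slot")
  params <- model$params
  state <- adam_init(params)
  lr <- control$lr
  degeneracy <- new.env(); degeneracy$jitter <- 0L
  val_batch <- assemble_batch(graphs[idx_val])
  best <- list(val = Inf, params = params, epoch = 0L)
  since_improve <- 0L; since_decay <- 0L
  hist <- vector("list", control$max_epochs)
  with_seed(control$seed, {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample(idx_train)
      nb <- ceiling(length(ord) / control$batch_size)
      tr_loss <- 0
      for (b in seq_len(nb)) {
        take <- ord[((b - 1L) * control$batch_size + 1L):
                      min(b * control$batch_size, length(ord))]
        batch <- assemble_batch(graphs[take])
        fw <- net_forward(params, model$encoder, model$head, batch,
                          keep_cache = TRUE)
        hp <- head_predict(fw$out, model$head)
        lg <- batch_loss_grad(hp$pred, ref[take, , drop = FALSE],
                              mask[take, , drop = FALSE], nvalid_all[take])
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (loss not finite) at epoch %d, lr %.2g",
                       epoch, lr))
        d_out <- head_backward(fw$out, model$head, hp, lg$d_pred, degeneracy)
        grads <- net_backward(params, model$encoder, model$head, batch,
                              fw$cache, d_out)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
        tr_loss <- tr_loss + lg$loss * length(take)
      }
      tr_loss <- tr_loss / length(ord)
      vl <- eval_loss(params, model$encoder, model$head, val_batch,
                      ref[idx_val, , drop = FALSE],
                      mask[idx_val, , drop = FALSE], nvalid_all[idx_val])
      hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss,
                         val_loss = vl$loss, val_mae = vl$mae, lr = lr)
      if (control$verbose > 0 && epoch %% control$verbose == 0)
        message(sprintf("epoch %4d  train %.5f  val %.5f  lr %.2g",
                        epoch, tr_loss, vl$loss, lr))
      if (vl$loss < best$val - 1e-12) {
        best <- list(val = vl$loss, params = params, epoch = epoch)
        since_improve <- 0L; since_decay <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_decay <- since_decay + 1L
        if (since_decay >= control$lr_patience && lr > control$min_lr) {
          lr <- max(control$min_lr, lr * control$lr_decay)
          since_decay <- 0L
        }
        if (since_improve >= control$patience) break
      }
    }
  })
  model$params <- best$params
  list(model = model,
       history = as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)])),
       best_epoch = best$epoch, best_val = best$val,
       degenerate_backward = degeneracy$jitter)
}

# Mask-weighted mean spectrum of the training records (bias initialization).
mean_spectrum <- function(ref, mask, idx) {
  num <- colSums(ref[idx, , drop = FALSE] * mask[idx, , drop = FALSE])
  den <- colSums(mask[idx, , drop = FALSE])
  mu <- ifelse(den > 0, num / pmax(den, 1), 0)
  # padding-only slots inherit the last informed slot so the bias stays sorted
  for (k in seq_along(mu)) if (den[k] == 0 && k > 1) mu[k] <- mu[k - 1]
  mu
}

records_to_matrices <- function(records) {
  n_max <- length(records[[1]]$values)
  list(ref = t(vapply(records, `[[`, numeric(n_max), "values")),
       mask = t(vapply(records, function(r) as.numeric(r$mask),
                       numeric(n_max))))
}

#' Fit a pseudo-Hamiltonian eigenvalue model
#'
#' Trains a continuous-filter message-passing network with one of three
#' output heads on masked eigenvalue targets: \code{"hamiltonian"} predicts
#' a symmetric n_max x n_max matrix whose ascending eigenvalues are the
#' targets (with backpropagation through the diagonalization),
#' \code{"multistate"} regresses the n_max-vector directly, and
#' \code{"single"} fits one slot with a scalar output. The loss is the mean
#' over valid slots and molecules of the squared index-wise error.
#'
#' @param data a \code{ph_dataset} (structures plus eigenvalue records).
#' @param head output head type.
#' @param encoder an \code{encoder_config}.
#' @param n_hidden hidden width of the head's atom-wise layers; for the
#'   hamiltonian head, \code{NULL} picks a width whose parameter count
#'   matches a multistate head on the same encoder.
#' @param slot target slot (1-based) for the \code{"single"} head.
#' @param control a \code{train_control}.
#' @param split a \code{dataset_split}; default splits 80/10/10 with
#'   \code{seed}.
#' @param seed master seed (parameter initialization and default split).
#' @return an object of class \code{"pseudoham"}: the trained model,
#'   training history, split, and the data it was fitted to.
#' @seealso \code{\link{predict.pseudoham}}, \code{\link{evaluate}},
#'   \code{\link{delta_fit}}
#' @export
pseudoham <- function(data, head = c("hamiltonian", "multistate", "single"),
                      encoder = encoder_config(), n_hidden = NULL,
                      slot = 1L, control = train_control(), split = NULL,
                      seed = 1L) {
  stopifnot(inherits(data, "ph_dataset"))
  head <- match.arg(head)
  if (is.null(split))
    split <- split_dataset(length(data), c(0.8, 0.1, 0.1), seed = seed)
  tm <- records_to_matrices(data$records)
  n_max <- data$n_max
  if (head == "single") {
    slot <- as.integer(slot)
    targets <- list(ref = tm$ref[, slot, drop = FALSE],
                    mask = tm$mask[, slot, drop = FALSE])
  } else targets <- tm
  f2 <- n_hidden
  if (is.null(f2) && head == "hamiltonian")
    f2 <- match_budget_hidden(encoder, n_max, max(1L, encoder$n_features %/% 2L))
  hc <- head_config(switch(head, hamiltonian = "hamiltonian",
                           multistate = "multistate", single = "single"),
                    n_max = n_max, n_hidden = f2, slot = slot)
  mu <- mean_spectrum(tm$ref, tm$mask, split$train)
  model <- init_model(encoder, hc, seed = seed, bias_init = mu)
  graphs <- lapply(data$structures, mol_graph, encoder = encoder)
  ctl <- control
  fit <- fit_network(model, graphs, targets, split$train, split$validation, ctl)
  structure(list(model = fit$model, head = head, history = fit$history,
                 best_epoch = fit$best_epoch, best_val = fit$best_val,
                 degenerate_backward = fit$degenerate_backward,
                 split = split, data = data, control = ctl,
                 seed = as.integer(seed), call = match.call()),
            class = "pseudoham")
}

#' @export
print.pseudoham <- function(x, ...) {
  cat(sprintf("Pseudo-Hamiltonian eigenvalue model (head: %s)\n", x$head))
  cat(sprintf("  n_max %d, %d parameters, %d/%d/%d train/val/test molecules\n",
              x$model$head$n_max, count_params(x$model),
              length(x$split$train), length(x$split$validation),
              length(x$split$test)))
  cat(sprintf("  best validation loss %.5g eV^2 at epoch %d of %d\n",
              x$best_val, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
summary.pseudoham <- function(object, ...) {
  m <- evaluate(object, subset_dataset(object$data, object$split$test))
  out <- list(fit = object, test_metrics = m)
  class(out) <- "summary.pseudoham"
  out
}

#' @export
print.summary.pseudoham <- function(x, ...) {
  print(x$fit)
  cat("Held-out test metrics:\n")
  print(x$test_metrics)
  invisible(x)
}

#' @export
coef.pseudoham <- function(object, ...) {
  p <- object$model$params
  attr(p, "n_parameters") <- count_params(object$model)
  p
}

#' Predict eigenvalues from a fitted model
#'
#' @param object a fitted \code{pseudoham} model.
#' @param newdata a \code{ph_dataset}, a list of \code{atomic_structure},
#'   or a single structure; default: the training data.
#' @param type \code{"values"} for the n x n_max eigenvalue matrix (eV),
#'   \code{"matrix"} for the predicted pseudo-Hamiltonians as well
#'   (hamiltonian head only).
#' @param ... unused.
#' @return eigenvalue matrix, or list with \code{values} and
#'   \code{matrices}.
#' @export
predict.pseudoham <- function(object, newdata = NULL,
                              type = c("values", "matrix"), ...) {
  type <- match.arg(type)
  structures <- if (is.null(newdata)) object$data$structures
  else if (inherits(newdata, "ph_dataset")) newdata$structures
  else if (inherits(newdata, "atomic_structure")) list(newdata)
  else newdata
  if (type == "matrix") {
    if (object$head != "hamiltonian")
      stop("pseudo-Hamiltonian matrices exist only for the hamiltonian head")
    predict_eigenvalues(object$model, structures, matrices = TRUE)
  } else {
    predict_eigenvalues(object$model, structures)
  }
}

#' @export
fitted.pseudoham <- function(object, ...) {
  predict(object, subset_dataset(object$data, object$split$train))
}

#' @export
residuals.pseudoham <- function(object, ...) {
  ds <- object$data
  pred <- predict(object, ds)
  tm <- records_to_matrices(ds$records)
  if (object$head == "single") {
    r <- pred[, 1] - tm$ref[, object$model$head$slot]
    r[tm$mask[, object$model$head$slot] == 0] <- NA_real_
    return(r)
  }
  r <- pred - tm$ref
  r[tm$mask == 0] <- NA_real_
  r
}

#' @export
plot.pseudoham <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"), log = "y",
                    xlab = "epoch", ylab = "masked L2 loss (eV^2)", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Mask-aware error metrics of a model on a dataset
#'
#' Per-slot and aggregate MAE/RMSE over unmasked entries, the per-molecule
#' worst-case error, and HOMO/LUMO slot errors (HOMO slot = the record's
#' occupation count, LUMO the next slot).
#'
#' @param object a fitted \code{pseudoham} (or a raw \code{ph_model}).
#' @param data a \code{ph_dataset} to score.
#' @param records optional replacement records (same structures).
#' @return list of class \code{"ph_metrics"}.
#' @export
evaluate <- function(object, data, records = NULL) {
  model <- if (inherits(object, "pseudoham")) object$model else object
  recs <- if (is.null(records)) data$records else records
  if (length(recs) == 0L) stop("empty evaluation split")
  pred <- predict_eigenvalues(model, data$structures)
  tm <- records_to_matrices(recs)
  if (model$head$type == "single") {
    tm$ref <- tm$ref[, model$head$slot, drop = FALSE]
    tm$mask <- tm$mask[, model$head$slot, drop = FALSE]
  }
  err <- (pred - tm$ref)
  err[tm$mask == 0] <- NA
  per_slot <- data.frame(
    slot = seq_len(ncol(err)),
    mae = apply(err, 2, function(e) mean(abs(e), na.rm = TRUE)),
    rmse = apply(err, 2, function(e) sqrt(mean(e^2, na.rm = TRUE))),
    n = colSums(tm$mask))
  homo_err <- lumo_err <- rep(NA_real_, length(recs))
  for (r in seq_along(recs)) {
    no <- recs[[r]]$n_occupied
    nv <- sum(recs[[r]]$mask)
    if (model$head$type != "single") {
      if (no >= 1L) homo_err[r] <- abs(err[r, no])
      if (no + 1L <= nv) lumo_err[r] <- abs(err[r, no + 1L])
    }
  }
  structure(list(per_slot = per_slot,
                 mae = mean(abs(err), na.rm = TRUE),
                 rmse = sqrt(mean(err^2, na.rm = TRUE)),
                 worst = apply(abs(err), 1, max, na.rm = TRUE),
                 homo_mae = mean(homo_err, na.rm = TRUE),
                 lumo_mae = mean(lumo_err, na.rm = TRUE),
                 n_molecules = length(recs)),
            class = "ph_metrics")
}

#' @export
print.ph_metrics <- function(x, ...) {
  cat(sprintf("ph_metrics over %d molecules: MAE %.4f eV, RMSE %.4f eV\n",
              x$n_molecules, x$mae, x$rmse))
  if (is.finite(x$homo_mae))
    cat(sprintf("  HOMO MAE %.4f eV, LUMO MAE %.4f eV, worst per-molecule (median) %.4f eV\n",
                x$homo_mae, x$lumo_mae, stats::median(x$worst)))
  invisible(x)
}
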
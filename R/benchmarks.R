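# End-to-end benchmark workflows on the synthetic suite: the three-head
# comparison (single-state vs multistate vs pseudo-Hamiltonian) and the
# delta-learning recovery experiment. Problem sizes default to desk-scale
# settings documented in the methods vignette.

#' Default desk-scale settings for the benchmark workflows
#' @return list with \code{encoder} and \code{control}.
#' @keywords internal
benchmark_defaults <- function() {
  list(encoder = encoder_config(n_features = 32L, n_blocks = 2L,
                                n_rbf = 20L, cutoff = 5.0),
       control = train_control(lr = 1e-2, batch_size = 64L,
                               max_epochs = 400L, patience = 30L,
                               lr_patience = 12L))
}

#' Three-head comparison on the single-molecule ensemble (dataset A)
#'
#' Trains, at matched parameter budgets and identical training budgets, the
#' pseudo-Hamiltonian head, the multistate head, and a family of
#' single-state models (one per slot) on the perturbed water-like ensemble,
#' repeating over \code{n_seeds} model seeds on a fixed split. Reports
#' per-slot and aggregate test MAEs and the head ranking.
#'
#' @param seed master seed (data generation and first model seed).
#' @param n_seeds number of model seeds (median reported).
#' @param n_molecules ensemble size.
#' @param train_sizes training-set sizes for the learning curve; the
#'   largest is used for the head comparison.
#' @param encoder,control network and optimizer settings shared by all
#'   heads.
#' @param single_state also train the per-slot single-state models (the
#'   most expensive third of the comparison; trained at the first model
#'   seed only to keep the workflow inside a desk-scale time budget).
#' @param data optionally reuse a pre-generated dataset A.
#' @return object of class \code{"ph_benchmark_fig1"}: \code{$report}
#'   (one row per model and seed), \code{$per_slot}, \code{$median}
#'   (median aggregate test MAE per head), \code{$learning_curve}.
#' @export
run_benchmark_fig1 <- function(seed = 1L, n_seeds = 3L, n_molecules = 1000L,
                               train_sizes = c(200L, 800L),
                               encoder = NULL, control = NULL,
                               single_state = TRUE, data = NULL) {
  d <- benchmark_defaults()
  if (is.null(encoder)) encoder <- d$encoder
  if (is.null(control)) control <- d$control
  if (is.null(data)) {
    suite <- make_benchmark_suite(seed, sizes = list(A = n_molecules,
                                                     B_pool = 0L, C = 0L),
                                  only = "A")
    data <- suite$A
  }
  n_max <- data$n_max
  split_full <- split_dataset(length(data), c(0.8, 0.1, 0.1), seed = seed)
  n_big <- max(train_sizes)
  if (n_big > length(split_full$train))
    stop("largest train size exceeds the train split")
  rows <- list(); slot_rows <- list(); lc_rows <- list()
  for (s in seq_len(n_seeds)) {
    mseed <- seed + s - 1L
    ctl <- control; ctl$seed <- mseed
    for (nt in train_sizes) {
      split <- split_full
      split$train <- split_full$train[seq_len(nt)]
      for (hd in c("hamiltonian", "multistate")) {
        fit <- pseudoham(data, head = hd, encoder = encoder, control = ctl,
                         split = split, seed = mseed)
        m <- evaluate(fit, subset_dataset(data, split$test))
        lc_rows[[length(lc_rows) + 1L]] <-
          data.frame(head = hd, seed = mseed, n_train = nt, test_mae = m$mae)
        if (nt == n_big) {
          rows[[length(rows) + 1L]] <-
            data.frame(head = hd, seed = mseed, test_mae = m$mae,
                       test_rmse = m$rmse, homo_mae = m$homo_mae,
                       lumo_mae = m$lumo_mae,
                       n_params = count_params(fit$model))
          slot_rows[[length(slot_rows) + 1L]] <-
            data.frame(head = hd, seed = mseed,
                       slot = m$per_slot$slot, mae = m$per_slot$mae)
        }
      }
    }
    if (single_state && s == 1L) {
      split <- split_full
      split$train <- split_full$train[seq_len(n_big)]
      slot_mae <- numeric(n_max); np <- 0L
      for (k in seq_len(n_max)) {
        fit1 <- pseudoham(data, head = "single", slot = k, encoder = encoder,
                          control = ctl, split = split, seed = mseed)
        m1 <- evaluate(fit1, subset_dataset(data, split$test))
        slot_mae[k] <- m1$mae
        np <- np + count_params(fit1$model)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(head = "single", seed = mseed, test_mae = mean(slot_mae),
                   test_rmse = NA_real_, homo_mae = NA_real_,
                   lumo_mae = NA_real_, n_params = np)
      slot_rows[[length(slot_rows) + 1L]] <-
        data.frame(head = "single", seed = mseed, slot = seq_len(n_max),
                   mae = slot_mae)
    }
  }
  report <- do.call(rbind, rows)
  per_slot <- do.call(rbind, slot_rows)
  lc <- do.call(rbind, lc_rows)
  med <- tapply(report$test_mae, report$head, stats::median)
  structure(list(report = report, per_slot = per_slot, median = med,
                 learning_curve = lc, seed = as.integer(seed),
                 n_train = n_big),
            class = "ph_benchmark_fig1")
}

#' @export
print.ph_benchmark_fig1 <- function(x, ...) {
  cat(sprintf("Head comparison on the perturbed-ensemble dataset (%d train molecules)\n",
              x$n_train))
  cat("Median aggregate test MAE (eV) over seeds:\n")
  for (h in names(x$median))
    cat(sprintf("  %-12s %.4f\n", h, x$median[h]))
  invisible(x)
}

#' Delta-learning recovery experiment on the two-level dataset (dataset D)
#'
#' Trains a pseudo-Hamiltonian base model on the base-level labels of the
#' cross-compound set, a multistate delta corrector on a small fraction of
#' the high-level labels (the base/delta size ratio mirrors a 12:1 design),
#' and, for reference, a model trained directly on that same small
#' high-level subset. Reports held-out MAEs against the high level and the
#' base/high/corrected Gaussian envelopes.
#'
#' @param seed master seed.
#' @param n_molecules size of the cross-compound set.
#' @param delta_fraction fraction of the training split used for the
#'   corrector (default 1/12).
#' @param encoder,control shared network and optimizer settings.
#' @param suite optionally reuse a pre-generated benchmark suite (uses
#'   \code{$D}).
#' @return object of class \code{"ph_benchmark_delta"} with the fitted
#'   models, MAEs (\code{base_mae} = uncorrected base predictions vs the
#'   high level, \code{corrected_mae}, \code{direct_mae}), sign checks of
#'   the applied correction, and envelopes.
#' @export
run_benchmark_delta <- function(seed = 1L, n_molecules = 2000L,
                                delta_fraction = 1 / 12,
                                encoder = NULL, control = NULL,
                                suite = NULL) {
  d <- benchmark_defaults()
  if (is.null(encoder)) encoder <- d$encoder
  if (is.null(control)) control <- d$control
  if (is.null(suite))
    suite <- make_benchmark_suite(seed, sizes = list(A = 0L, B_pool = 0L,
                                                     C = n_molecules),
                                  only = "D")
  D <- suite$D
  split <- split_dataset(length(D), c(0.8, 0.1, 0.1), seed = seed)
  ctl <- control; ctl$seed <- seed

  base <- pseudoham(D, head = "hamiltonian", encoder = encoder,
                    control = ctl, split = split, seed = seed)

  n_delta <- max(12L, round(length(split$train) * delta_fraction))
  delta_idx <- split$train[seq_len(n_delta)]
  delta <- delta_fit(base, D, D$records_high, subset = delta_idx,
                     encoder = encoder, control = ctl, seed = seed)

  # direct training on the small high-level subset alone
  direct_data <- ph_dataset(D$structures, D$records_high)
  dsplit <- split_dataset(n_delta, c(0.8, 0.1, 0.1), seed = seed)
  dsplit$train <- delta_idx[dsplit$train]
  dsplit$validation <- delta_idx[dsplit$validation]
  dsplit$test <- split$test
  direct <- pseudoham(direct_data, head = "hamiltonian", encoder = encoder,
                      control = ctl, split = dsplit, seed = seed)

  test <- subset_dataset(D, split$test)
  high_test <- D$records_high[split$test]
  base_pred <- predict(base, test)
  corrected <- predict(delta, test)
  m_base <- evaluate(base, test, records = high_test)
  m_corr <- .metrics_from_pred(corrected, high_test)
  m_direct <- evaluate(direct, test, records = high_test)

  # sign of the applied correction per test molecule
  sign_ok <- vapply(seq_along(high_test), function(k) {
    r <- high_test[[k]]
    dlt <- corrected[k, ] - base_pred[k, ]
    occ_ok <- r$n_occupied == 0L ||
      all(dlt[seq_len(r$n_occupied)] < 0)
    nv <- sum(r$mask)
    vir_ok <- nv == r$n_occupied ||
      all(dlt[(r$n_occupied + 1L):nv] > 0)
    occ_ok && vir_ok
  }, logical(1))

  env_base <- gaussian_envelope(D$records[split$test], width = 0.5)
  env_high <- gaussian_envelope(high_test, width = 0.5,
                                from = min(env_base$energy),
                                to = max(env_base$energy))
  structure(list(base = base, delta = delta, direct = direct,
                 base_mae = m_base$mae, corrected_mae = m_corr$mae,
                 direct_mae = m_direct$mae,
                 corrected_rmse = m_corr$rmse,
                 sign_ok = sign_ok, n_delta = n_delta,
                 test_idx = split$test,
                 envelopes = list(base = env_base, high = env_high),
                 seed = as.integer(seed)),
            class = "ph_benchmark_delta")
}

#' Smoothness diagnostic along the bond-scan path (dataset B)
#'
#' Trains a pseudo-Hamiltonian model on the noisy ensemble around the
#' interpolation path and examines the trained model along the path itself:
#' the sorted predicted eigenvalue curves must stay continuous (frame-to-
#' frame jumps bounded by the path's tight-binding Lipschitz constant) even
#' though the reference spectrum contains an eigenvalue crossing inside the
#' window.
#'
#' @param seed master seed.
#' @param n_pool size of the noisy training ensemble.
#' @param encoder,control shared network and optimizer settings.
#' @param suite optionally reuse a pre-generated benchmark suite (uses
#'   \code{$B}).
#' @return object of class \code{"ph_benchmark_path"}: held-out-pool and
#'   path MAEs, the model's maximum frame-to-frame eigenvalue jump, the
#'   tight-binding Lipschitz bound (max spectral norm of the frame-to-frame
#'   Hamiltonian difference), and the minimum adjacent-level gap of the
#'   reference along the path.
#' @export
run_benchmark_path <- function(seed = 1L, n_pool = 400L,
                               encoder = NULL, control = NULL, suite = NULL) {
  d <- benchmark_defaults()
  if (is.null(encoder)) encoder <- d$encoder
  if (is.null(control)) control <- d$control
  if (is.null(suite))
    suite <- make_benchmark_suite(seed, sizes = list(A = 0L, B_pool = n_pool,
                                                     C = 0L), only = "B")
  B <- suite$B
  pool <- B$train_pool
  split <- split_dataset(length(pool), c(0.8, 0.1, 0.1), seed = seed)
  ctl <- control; ctl$seed <- seed
  fit <- pseudoham(pool, head = "hamiltonian", encoder = encoder,
                   control = ctl, split = split, seed = seed)
  test_mae <- evaluate(fit, subset_dataset(pool, split$test))$mae

  path_pred <- predict(fit, B)
  path_mae <- .metrics_from_pred(path_pred, B$records)$mae
  max_jump <- max(abs(diff(path_pred)))      # column-wise frame-to-frame

  # Lipschitz constant of the reference along the path: by Weyl's
  # inequality every sorted eigenvalue moves by at most the spectral norm
  # of the Hamiltonian difference between adjacent frames.
  Hs <- lapply(B$structures, tb_hamiltonian)
  lipschitz <- max(vapply(seq_len(length(Hs) - 1L), function(k)
    norm(Hs[[k + 1L]] - Hs[[k]], type = "2"), 0))

  # minimum adjacent-level gap of the reference inside the window
  min_gap <- Inf; gap_slot <- NA_integer_
  for (r in B$records) {
    v <- r$values[r$mask]
    if (length(v) >= 2L) {
      gaps <- diff(v)
      if (min(gaps) < min_gap) {
        min_gap <- min(gaps); gap_slot <- which.min(gaps)
      }
    }
  }
  structure(list(fit = fit, test_mae = test_mae, path_mae = path_mae,
                 max_jump = max_jump, lipschitz = lipschitz,
                 min_gap = min_gap, gap_slot = gap_slot,
                 n_frames = length(B), seed = as.integer(seed)),
            class = "ph_benchmark_path")
}

#' @export
print.ph_benchmark_path <- function(x, ...) {
  cat("Smoothness diagnostic along the bond-scan path\n")
  cat(sprintf("  held-out pool MAE %.4f eV, path MAE %.4f eV\n",
              x$test_mae, x$path_mae))
  cat(sprintf("  max frame-to-frame predicted jump %.4f eV (Lipschitz bound %.4f eV)\n",
              x$max_jump, x$lipschitz))
  cat(sprintf("  reference min adjacent gap along path %.4g eV (below slot %d)\n",
              x$min_gap, x$gap_slot))
  invisible(x)
}

# metrics for an externally computed prediction matrix
.metrics_from_pred <- function(pred, records) {
  tm <- records_to_matrices(records)
  err <- pred - tm$ref
  err[tm$mask == 0] <- NA
  list(mae = mean(abs(err), na.rm = TRUE),
       rmse = sqrt(mean(err^2, na.rm = TRUE)))
}

#' @export
print.ph_benchmark_delta <- function(x, ...) {
  cat("Delta-learning recovery experiment (held-out molecules, vs high level)\n")
  cat(sprintf("  base model (uncorrected)    MAE %.4f eV\n", x$base_mae))
  cat(sprintf("  base + delta corrector      MAE %.4f eV (delta set: %d molecules)\n",
              x$corrected_mae, x$n_delta))
  cat(sprintf("  direct small-set training   MAE %.4f eV\n", x$direct_mae))
  cat(sprintf("  correction sign correct for %d/%d test molecules\n",
              sum(x$sign_ok), length(x$sign_ok)))
  invisible(x)
}
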
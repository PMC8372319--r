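# Masked loss, optimizer, the fitting interface and its S3 surface.

test_that("masked_l2_loss follows the stated mean convention exactly", {
  ref <- eigen_record(c(1, 2, 0), c(TRUE, TRUE, FALSE), n_occupied = 1)
  expect_equal(masked_l2_loss(c(1, 3, 99), ref), 0.5)
  expect_equal(masked_l2_loss(c(1, 2, -5), ref), 0)
  # a masked-false slot never contributes, whatever it carries
  expect_equal(masked_l2_loss(c(1, 3, 1e6), ref),
               masked_l2_loss(c(1, 3, -1e6), ref))
  all_false <- eigen_record(c(0, 0), c(FALSE, FALSE), n_occupied = 0)
  expect_error(masked_l2_loss(c(0, 0), all_false), "no valid slots")
})

test_that("batch gradients match finite differences and respect the mask", {
  set.seed(31)
  pred <- matrix(rnorm(12), 3, 4)
  ref <- matrix(rnorm(12), 3, 4)
  mask <- matrix(rbinom(12, 1, 0.7), 3, 4)
  mask[, 1] <- 1                               # at least one valid per row
  nvalid <- rowSums(mask)
  lg <- batch_loss_grad(pred, ref, mask, nvalid)
  # loss equals the mean over molecules of per-molecule masked means
  per_mol <- rowSums(((pred - ref) * mask)^2) / nvalid
  expect_equal(lg$loss, mean(per_mol))
  h <- 1e-6
  for (q in sample(12, 6)) {
    pp <- pred; pp[q] <- pp[q] + h
    pm <- pred; pm[q] <- pm[q] - h
    fd <- (batch_loss_grad(pp, ref, mask, nvalid)$loss -
             batch_loss_grad(pm, ref, mask, nvalid)$loss) / (2 * h)
    expect_lt(abs(fd - lg$d_pred[q]), 1e-8)
  }
  # masked entries get exactly zero gradient
  expect_true(all(lg$d_pred[mask == 0] == 0))
})

test_that("batch-size-1 accumulation equals the full-batch loss", {
  set.seed(32)
  pred <- matrix(rnorm(20), 5, 4); ref <- matrix(rnorm(20), 5, 4)
  mask <- matrix(1, 5, 4); nvalid <- rowSums(mask)
  full <- batch_loss_grad(pred, ref, mask, nvalid)$loss
  acc <- mean(vapply(1:5, function(r)
    batch_loss_grad(pred[r, , drop = FALSE], ref[r, , drop = FALSE],
                    mask[r, , drop = FALSE], nvalid[r])$loss, 0))
  expect_lt(abs(full - acc), 1e-10)
  # molecule order within the batch is irrelevant
  perm <- sample(5)
  expect_equal(full, batch_loss_grad(pred[perm, ], ref[perm, ],
                                     mask[perm, ], nvalid[perm])$loss)
})

test_that("the Adam implementation minimizes a simple quadratic", {
  params <- list(a = 5, b = list(c = matrix(c(-3, 2), 1)))
  state <- adam_init(params)
  for (k in 1:2000) {
    grads <- list(a = 2 * params$a, b = list(c = 2 * params$b$c))
    upd <- adam_step(params, grads, state, lr = 0.05)
    params <- upd$params; state <- upd$state
  }
  expect_lt(abs(params$a), 1e-4)
  expect_lt(max(abs(params$b$c)), 1e-4)
})

test_that("mean_spectrum weights by mask and fills padding-only slots", {
  ref <- rbind(c(-10, -5, 0), c(-12, -7, 0))
  mask <- rbind(c(1, 1, 0), c(1, 1, 0))
  mu <- mean_spectrum(ref, mask, 1:2)
  expect_equal(mu, c(-11, -6, -6))             # slot 3 inherits slot 2
  mask2 <- rbind(c(1, 1, 1), c(1, 0, 0))
  expect_equal(mean_spectrum(ref, mask2, 1:2), c(-11, -5, 0))
})

test_that("a constant-target dataset is learned to near zero error", {
  g <- generate_geometries(tiny_water(), 40, sigma = 0.05, seed = 6)
  rec <- lapply(seq_along(g), function(k)
    eigen_record(c(-10, -4, 1), rep(TRUE, 3), n_occupied = 2,
                 id = g[[k]]$id))
  ds <- ph_dataset(g, rec)
  fit <- pseudoham(ds, head = "multistate",
                   encoder = encoder_config(n_features = 8L, n_blocks = 1L,
                                            n_rbf = 8L),
                   control = train_control(lr = 1e-2, batch_size = 16,
                                           max_epochs = 50, seed = 2),
                   seed = 2)
  m <- evaluate(fit, ds)
  expect_lt(m$mae, 5e-3)
})

test_that("training is deterministic given the seed", {
  g <- generate_geometries(tiny_water(), 30, sigma = 0.05, seed = 7)
  rec <- label_structures(g, tb_params(), window_low = -70,
                          states_above_homo = 2L, n_max = 6L)
  ds <- ph_dataset(g, rec)
  enc <- encoder_config(n_features = 8L, n_blocks = 1L, n_rbf = 8L)
  ctl <- train_control(lr = 5e-3, batch_size = 8, max_epochs = 8, seed = 3)
  f1 <- pseudoham(ds, head = "hamiltonian", encoder = enc, control = ctl,
                  seed = 3)
  f2 <- pseudoham(ds, head = "hamiltonian", encoder = enc, control = ctl,
                  seed = 3)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the fitted-model S3 surface behaves like a classic R model object", {
  cf <- cached_small_fit("hamiltonian")
  fit <- cf$fit; ds <- cf$data
  expect_s3_class(fit, "pseudoham")
  expect_output(print(fit), "Pseudo-Hamiltonian eigenvalue model")
  # training made real progress over the bias-only start
  expect_lt(fit$best_val, 0.5 * fit$history$val_loss[1])
  # coef: the full parameter structure with a reported count
  cc <- coef(fit)
  expect_identical(attr(cc, "n_parameters"), count_params(fit$model))
  # predict: dataset, list, single structure
  p_all <- predict(fit, ds)
  expect_equal(dim(p_all), c(length(ds), ds$n_max))
  p_one <- predict(fit, ds$structures[[1]])
  expect_equal(p_all[1, ], p_one[1, ])
  pm <- predict(fit, ds$structures[[1]], type = "matrix")
  expect_identical(pm$matrices[[1]], t(pm$matrices[[1]]))
  expect_equal(pm$values[1, ], eigenvalues_from_matrix(pm$matrices[[1]]))
  # fitted/residuals shapes and masking
  expect_equal(nrow(fitted(fit)), length(fit$split$train))
  r <- residuals(fit)
  expect_equal(dim(r), c(length(ds), ds$n_max))
  tm <- records_to_matrices(ds$records)
  expect_true(all(is.na(r[tm$mask == 0])))
  # summary and plot run cleanly
  expect_output(print(summary(fit)), "Held-out test metrics")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("evaluate matches an independent per-record recomputation", {
  cf <- cached_small_fit("hamiltonian")
  fit <- cf$fit; ds <- cf$data
  idx <- fit$split$test
  m <- evaluate(fit, subset_dataset(ds, idx))
  pred <- predict(fit, subset_dataset(ds, idx))
  errs <- c(); homo <- c()
  for (k in seq_along(idx)) {
    r <- ds$records[[idx[k]]]
    e <- pred[k, r$mask] - r$values[r$mask]
    errs <- c(errs, e)
    homo <- c(homo, abs(e[r$n_occupied]))
  }
  expect_equal(m$mae, mean(abs(errs)), tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(mean(errs^2)), tolerance = 1e-12)
  expect_equal(m$homo_mae, mean(homo), tolerance = 1e-12)
  expect_true(all(m$per_slot$rmse + 1e-15 >= m$per_slot$mae))
  # constant-offset predictor: MAE = RMSE = offset, exactly
  tm2 <- records_to_matrices(ds$records[idx])
  m2 <- .metrics_from_pred(tm2$ref + 0.1, ds$records[idx])
  expect_equal(m2$mae, 0.1)
  expect_equal(m2$rmse, 0.1)
})

test_that("a single-state model fits one slot with a scalar output", {
  cfd <- cached_small_fit("hamiltonian")$data
  fit1 <- pseudoham(cfd, head = "single", slot = 6L,
                    encoder = encoder_config(n_features = 8L, n_blocks = 1L,
                                             n_rbf = 8L),
                    control = train_control(lr = 1e-2, batch_size = 32,
                                            max_epochs = 30, seed = 4),
                    seed = 4)
  p <- predict(fit1, cfd)
  expect_equal(ncol(p), 1L)
  m <- evaluate(fit1, cfd)
  expect_lt(m$mae, 1)
  expect_equal(nrow(m$per_slot), 1L)
})
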
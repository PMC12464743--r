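# Reconstruction model: splits, loss, forward pass, gradients, training.

test_that("cv splits are subject-exclusive partitions", {
  subs <- sprintf("s%02d", 1:10)
  splits <- make_cv_splits(subs, k = 5, seed = 1)
  tests <- lapply(1:5, function(f) cv_subjects(splits, f, "test"))
  expect_true(all(lengths(tests) == 2))
  expect_setequal(unlist(tests), subs)
  expect_equal(anyDuplicated(unlist(tests)), 0L)
  for (f in 1:5) {
    roles <- lapply(c("train", "val", "test"), cv_subjects,
                    splits = splits, fold = f)
    expect_equal(anyDuplicated(unlist(roles)), 0L)
    expect_setequal(unlist(roles), subs)
    expect_true(all(lengths(roles) >= 1))
  }
  expect_identical(splits, make_cv_splits(subs, k = 5, seed = 1))
  expect_false(identical(splits, make_cv_splits(subs, k = 5, seed = 2)))
  expect_error(make_cv_splits(c("a", "b"), k = 5), "fewer subjects")
})

test_that("cv fractions approximate 68/12/20 at scale", {
  splits <- make_cv_splits(sprintf("s%03d", 1:375), k = 5, seed = 3)
  n <- sapply(c("train", "val", "test"), function(r)
    length(cv_subjects(splits, 1, r)))
  expect_equal(unname(n / 375), c(0.68, 0.12, 0.20), tolerance = 0.01)
})

test_that("recon_loss follows the masked two-task MSE contract", {
  rv <- sin(1:50); hr <- cos(1:50)
  expect_equal(recon_loss(rv, hr, rv, hr), 0)
  expect_equal(recon_loss(rv, hr + 1, rv, hr), 1)
  expect_equal(recon_loss(rv + 2, hr + 1, rv, hr), 5)
  m <- list(rv = rep(TRUE, 50), hr = rep(FALSE, 50))
  expect_equal(recon_loss(rv + 3, hr + 1, rv, hr, mask = m), 9)
  expect_error(recon_loss(rv, hr, rv, hr,
                          mask = rep(FALSE, 50)), "all frames masked")
})

test_that("recon_config validates hyperparameters", {
  expect_error(recon_config(dropout = 1), "dropout")
  expect_error(recon_config(lr_decay = 1.5), "lr_decay")
  expect_error(recon_config(patience = 0), "patience")
  cfg <- recon_config(hidden_size = 64)
  expect_s3_class(cfg, "recon_config")
  expect_equal(cfg$hidden_size, 64L)
})

test_that("analytic LSTM gradients agree with finite differences", {
  R <- 3; H <- 4; B <- 2; Tm <- 6
  lengths <- c(6L, 4L)
  X <- withr::with_seed(42, array(rnorm(R * B * Tm), c(R, B, Tm)))
  X[, 2, 5:6] <- 0
  rv <- withr::with_seed(43, matrix(rnorm(Tm * B), Tm, B))
  hr <- withr::with_seed(44, matrix(rnorm(Tm * B), Tm, B))
  mask <- matrix(0, Tm, B); mask[1:6, 1] <- 1; mask[1:4, 2] <- 1
  drop <- array(1, c(2 * H, B, Tm))
  ip <- withr::with_seed(45, physiorecon:::init_params(R, H))
  g <- function(p) physiorecon:::.cpp_bilstm_grad(
    X, lengths, rv, hr, mask, mask, drop, p$Wf, p$Uf, p$bf, p$Wb, p$Ub,
    p$bb, p$Wy, p$by)
  out <- g(ip)
  eps <- 1e-6
  for (nm in names(ip)) {
    idx <- withr::with_seed(46, sample(length(ip[[nm]]),
                                       min(6, length(ip[[nm]]))))
    for (i in idx) {
      p1 <- ip; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- ip; p2[[nm]][i] <- p2[[nm]][i] - eps
      gnum <- (g(p1)$loss - g(p2)$loss) / (2 * eps)
      expect_equal(out$grads[[nm]][i], gnum, tolerance = 1e-5,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("padded frames beyond a sequence's length never leak into the loss", {
  R <- 4; H <- 5
  x <- withr::with_seed(47, matrix(rnorm(R * 10), R, 10))
  rv <- rnorm(10); hr <- rnorm(10)
  solo <- physiorecon:::pack_batch(list(x), list(rv), list(hr))
  padded <- physiorecon:::pack_batch(
    list(x, matrix(rnorm(R * 20), R, 20)),
    list(rv, rnorm(20)), list(hr, rnorm(20)))
  ip <- withr::with_seed(48, physiorecon:::init_params(R, H))
  pred_solo <- physiorecon:::.cpp_bilstm_forward(
    solo$X, solo$lengths, ip$Wf, ip$Uf, ip$bf, ip$Wb, ip$Ub, ip$bb,
    ip$Wy, ip$by)
  pred_pad <- physiorecon:::.cpp_bilstm_forward(
    padded$X, padded$lengths, ip$Wf, ip$Uf, ip$bf, ip$Wb, ip$Ub, ip$bb,
    ip$Wy, ip$by)
  # scan 1's predictions are identical whether or not it is padded in a batch
  expect_equal(pred_pad$rv[1:10, 1], pred_solo$rv[, 1], tolerance = 1e-12)
  expect_equal(pred_pad$hr[1:10, 1], pred_solo$hr[, 1], tolerance = 1e-12)
})

test_that("forward_recon output length tracks input length", {
  ds <- make_tiny_dataset(n_scans = 8, n_rois = 6, n_frames = 80)
  cfg <- recon_config(hidden_size = 8, batch_size = 4, max_epochs = 2,
                      seed = 9)
  model <- train_recon(ds, cfg, train = ds$scan_id[1:6],
                       val = ds$scan_id[7:8])
  for (T_ in c(100, 300)) {
    ts <- withr::with_seed(T_, matrix(rnorm(6 * T_), 6, T_))
    pred <- forward_recon(model, ts)
    expect_equal(nrow(pred), T_)
  }
  # inference is bitwise deterministic
  ts <- withr::with_seed(1, matrix(rnorm(6 * 50), 6, 50))
  expect_identical(forward_recon(model, ts), forward_recon(model, ts))
  # channel mismatch is named
  expect_error(forward_recon(model, matrix(rnorm(4 * 50), 4, 50)),
               "channel mismatch")
})

test_that("training learns a small noiseless synthetic mapping", {
  ds <- simulate_dataset(sim_config(n_scans = 50, n_rois = 20,
                                    n_frames = 200, noise_sd = 0,
                                    zero_frac = 0, seed = 55))
  cfg <- recon_config(hidden_size = 64, batch_size = 16, dropout = 0,
                      max_epochs = 60, stall_epochs = 60, seed = 56)
  model <- train_recon(ds, cfg, train = ds$scan_id[1:40],
                       val = ds$scan_id[41:50])
  log <- tidy(model)
  expect_lt(log$val_loss[nrow(log)], 0.5 * log$val_loss[1])
  expect_equal(model$best_val_loss, min(log$val_loss))
  # held-out agreement on a fresh noiseless scan
  lat <- simulate_latent_physio(200, seed = 57)
  scan <- simulate_roi_scan(lat, sim_config(n_rois = 20, n_frames = 200,
                                            noise_sd = 0, zero_frac = 0,
                                            seed = 55), seed = 58)
  pred <- forward_recon(model, scan$roi)
  # noiseless recovery is still bounded by the ill-conditioned deconvolution
  # near the upper band edge (the response kernels pass almost nothing at
  # 0.15 Hz); at this scale the network plateaus just above 0.75
  expect_gt(evaluate_scan(pred$rv_hat, lat$rv), 0.75)
  expect_gt(evaluate_scan(pred$hr_hat, lat$hr), 0.75)
})

test_that("learning-rate schedule decays by 0.5 after `patience` stalls", {
  ds <- make_tiny_dataset(n_scans = 10, n_rois = 5, n_frames = 60)
  cfg <- recon_config(hidden_size = 6, batch_size = 4, lr = 1e-3,
                      lr_decay = 0.5, patience = 2, max_epochs = 15,
                      stall_epochs = 15, seed = 60)
  model <- train_recon(ds, cfg, train = ds$scan_id[1:8],
                       val = ds$scan_id[9:10])
  log <- tidy(model)
  # reconstruct the schedule from the validation-loss trace and compare
  lr <- cfg$lr; best <- Inf; stall <- 0L
  for (e in seq_len(nrow(log))) {
    expect_equal(log$lr[e], lr, tolerance = 1e-12,
                 label = paste("lr at epoch", e))
    if (log$val_loss[e] < best) {
      best <- log$val_loss[e]; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall %% cfg$patience == 0) lr <- lr * cfg$lr_decay
    }
  }
  expect_equal(model$best_val_loss, min(log$val_loss))
})

test_that("training validates its inputs", {
  ds <- make_tiny_dataset(n_scans = 6, n_rois = 4, n_frames = 40)
  cfg <- recon_config(hidden_size = 4, max_epochs = 1)
  expect_error(train_recon(ds, cfg, train = character(0),
                           val = ds$scan_id[1]), "empty or unknown")
  expect_error(train_recon(ds, cfg, train = ds$scan_id[1:3], val = "nope"),
               "empty or unknown")
})

test_that("input_rois restricts channels through configuration alone", {
  ds <- make_tiny_dataset(n_scans = 8, n_rois = 6, n_frames = 60)
  cfg <- recon_config(hidden_size = 6, batch_size = 4, max_epochs = 2,
                      input_rois = c("2", "5"), seed = 61)
  model <- train_recon(ds, cfg, train = ds$scan_id[1:6],
                       val = ds$scan_id[7:8])
  expect_equal(model$roi_ids, c("2", "5"))
  # a full-width scan is subset automatically at inference
  pred <- forward_recon(model, ds$x[[1]])
  expect_equal(nrow(pred), 60)
})

test_that("evaluate_scan endpoints and shuffled-pair baseline", {
  x <- sin((1:100) / 7)
  expect_equal(evaluate_scan(x, x), 1)
  expect_equal(evaluate_scan(-x, x), -1)
  expect_error(evaluate_scan(rep(1, 10), rnorm(10)), "undefined correlation")
  rs <- sapply(1:100, function(s) {
    a <- simulate_latent_physio(300, seed = 2 * s)$rv
    b <- simulate_latent_physio(300, seed = 2 * s + 1)$rv
    evaluate_scan(a, b)
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("model checkpoints round-trip with provenance intact", {
  ds <- make_tiny_dataset(n_scans = 6, n_rois = 4, n_frames = 40)
  cfg <- recon_config(hidden_size = 4, batch_size = 2, max_epochs = 2,
                      seed = 62)
  model <- train_recon(ds, cfg, train = ds$scan_id[1:4],
                       val = ds$scan_id[5:6])
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_recon_model(model, tmp)
  back <- load_recon_model(tmp)
  expect_identical(back$weights, model$weights)
  expect_identical(back$roi_ids, model$roi_ids)
  expect_identical(back$data_hash, model$data_hash)
  ts <- ds$x[[1]]
  expect_identical(forward_recon(back, ts), forward_recon(model, ts))
})

test_that("tidy, glance and autoplot expose the training record", {
  ds <- make_tiny_dataset(n_scans = 6, n_rois = 4, n_frames = 40)
  model <- train_recon(ds, recon_config(hidden_size = 4, max_epochs = 3,
                                        batch_size = 2, seed = 63),
                       train = ds$scan_id[1:4], val = ds$scan_id[5:6])
  log <- tidy(model)
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in% names(log)))
  gl <- glance(model)
  expect_equal(gl$n_rois, 4)
  expect_equal(gl$best_val_loss, min(log$val_loss))
  expect_s3_class(autoplot(model), "ggplot")
})
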
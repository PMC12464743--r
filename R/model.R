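#' Reconstruction model configuration
#'
#' Hyperparameters for the joint RV/HR reconstruction network: a single
#' bidirectional LSTM layer followed by dropout and two independent linear
#' heads. Defaults mirror the reference resting-state configuration (hidden
#' state 2000, batch 16, dropout 0.3, Adam with initial learning rate 1e-3
#' decayed by 0.5 after 2 epochs without validation improvement). Training
#' stops early after `stall_epochs` epochs without improvement (three decay
#' steps by default) or at `max_epochs`.
#'
#' @param hidden_size Hidden state size per direction.
#' @param batch_size Scans per training batch (variable-length scans are
#'   padded to the batch maximum and masked in the loss).
#' @param dropout Dropout rate on the concatenated LSTM output.
#' @param lr Initial Adam learning rate.
#' @param lr_decay Multiplicative decay factor.
#' @param patience Epochs without validation improvement before a decay.
#' @param max_epochs Epoch cap.
#' @param stall_epochs Epochs without improvement before early stop.
#' @param seed RNG seed governing initialization, batching and dropout.
#' @param input_rois Optional ROI-id subset restricting the input channels
#'   (one id reproduces an individual-ROI model; a ranked subset reproduces
#'   percent-ROI models; exclusion lists reproduce region-ablation models).
#' @return A `recon_config` list.
#' @export
recon_config <- function(hidden_size = 2000, batch_size = 16, dropout = 0.3,
                         lr = 1e-3, lr_decay = 0.5, patience = 2,
                         max_epochs = 100, stall_epochs = 6, seed = 1,
                         input_rois = NULL) {
  stopifnot(hidden_size >= 1, batch_size >= 1,
            dropout >= 0, dropout < 1,
            lr > 0, lr_decay > 0, lr_decay < 1,
            patience >= 1, max_epochs >= 1, stall_epochs >= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 lr = lr, lr_decay = lr_decay, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 stall_epochs = as.integer(stall_epochs),
                 seed = as.integer(seed), input_rois = input_rois),
            class = "recon_config")
}

#' Subject-wise cross-validation splits
#'
#' Partitions subjects into `k` disjoint test folds; within each fold the
#' remaining subjects are divided into training and validation so that the
#' overall fractions are 68\% train / 12\% validation / 20\% test. All scans
#' of a subject travel together, so no subject ever appears in more than one
#' of train/validation/test within a fold.
#'
#' @param subject_ids Character or factor vector of subject ids (one entry
#'   per subject, or per scan -- duplicates are collapsed).
#' @param k Number of folds.
#' @param seed RNG seed; identical seeds give identical folds.
#' @param val_frac Fraction of the non-test subjects held out for
#'   validation (0.12 / 0.80 by default).
#' @return A `cv_splits` tibble with columns `fold`, `subject`, `role`.
#' @export
make_cv_splits <- function(subject_ids, k = 5, seed = 1,
                           val_frac = 0.12 / 0.80) {
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < k) stop("fewer subjects than folds")
  shuffled <- with_seed(seed, sample(subjects))
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  out <- purrr::map_dfr(seq_len(k), function(f) {
    test <- shuffled[fold_of == f]
    rest <- shuffled[fold_of != f]
    n_val <- max(1L, round(val_frac * length(rest)))
    val <- rest[seq_len(n_val)]
    train <- setdiff(rest, val)
    tibble(fold = f,
           subject = c(train, val, test),
           role = rep(c("train", "val", "test"),
                      c(length(train), length(val), length(test))))
  })
  class(out) <- c("cv_splits", class(out))
  out
}

#' Subjects of one role in one fold
#'
#' @param splits A [make_cv_splits()] tibble.
#' @param fold Fold number.
#' @param role `"train"`, `"val"` or `"test"`.
#' @return Character vector of subject ids.
#' @export
cv_subjects <- function(splits, fold, role) {
  splits$subject[splits$fold == fold & splits$role == role]
}

#' Joint reconstruction loss
#'
#' Equal-weighted sum of the per-signal mean squared errors over valid
#' frames (targets are z-scored, so the two terms are commensurate). A mask
#' may exclude frames per signal; with one signal fully masked the loss
#' reduces to the other signal's MSE.
#'
#' @param rv_hat,hr_hat Predicted series.
#' @param rv,hr Target series (z-scored).
#' @param mask `NULL` (all frames valid), a logical vector applied to both
#'   signals, or `list(rv =, hr =)` of logical vectors.
#' @return Scalar loss.
#' @export
recon_loss <- function(rv_hat, hr_hat, rv, hr, mask = NULL) {
  n <- length(rv)
  stopifnot(length(rv_hat) == n, length(hr_hat) == n, length(hr) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!is.list(mask)) mask <- list(rv = mask, hr = mask)
  if (!any(mask$rv) && !any(mask$hr)) stop("all frames masked")
  mse <- function(a, b, m) if (!any(m)) 0 else mean((a[m] - b[m])^2)
  mse(rv_hat, rv, mask$rv) + mse(hr_hat, hr, mask$hr)
}

#' Pearson agreement between predicted and measured series
#'
#' @param pred,measured Equal-length non-constant series.
#' @return Pearson correlation in \[-1, 1\].
#' @export
evaluate_scan <- function(pred, measured) {
  stopifnot(length(pred) == length(measured))
  if (diff(range(pred)) == 0 || diff(range(measured)) == 0) {
    stop("undefined correlation for a constant series")
  }
  cor(pred, measured)
}

# ---- internal training machinery -----------------------------------------

init_params <- function(n_in, H) {
  kl <- 1 / sqrt(H)
  ky <- 1 / sqrt(2 * H)
  rmat <- function(r, c, k) matrix(runif(r * c, -k, k), r, c)
  list(Wf = rmat(4 * H, n_in, kl), Uf = rmat(4 * H, H, kl),
       bf = runif(4 * H, -kl, kl),
       Wb = rmat(4 * H, n_in, kl), Ub = rmat(4 * H, H, kl),
       bb = runif(4 * H, -kl, kl),
       Wy = rmat(2, 2 * H, ky), by = runif(2, -ky, ky))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Pack scans (list of R x T matrices + target vectors) into padded arrays.
pack_batch <- function(xs, rvs, hrs) {
  R <- nrow(xs[[1]])
  lens <- vapply(xs, ncol, integer(1))
  Tmax <- max(lens)
  B <- length(xs)
  X <- array(0, c(R, B, Tmax))
  rv <- matrix(0, Tmax, B)
  hr <- matrix(0, Tmax, B)
  mask <- matrix(0, Tmax, B)
  for (b in seq_len(B)) {
    X[, b, seq_len(lens[b])] <- xs[[b]]
    rv[seq_len(lens[b]), b] <- rvs[[b]]
    hr[seq_len(lens[b]), b] <- hrs[[b]]
    mask[seq_len(lens[b]), b] <- 1
  }
  list(X = X, rv = rv, hr = hr, mask = mask, lengths = lens)
}

batch_loss <- function(params, batch) {
  pred <- .cpp_bilstm_forward(batch$X, batch$lengths, params$Wf, params$Uf,
                              params$bf, params$Wb, params$Ub, params$bb,
                              params$Wy, params$by)
  n <- sum(batch$mask)
  sum(batch$mask * (pred$rv - batch$rv)^2) / n +
    sum(batch$mask * (pred$hr - batch$hr)^2) / n
}

scan_matrix <- function(x, input_rois = NULL) {
  mat <- if (inherits(x, "roi_timeseries")) x$data else as.matrix(x)
  if (!is.null(input_rois)) {
    ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
    miss <- setdiff(as.character(input_rois), ids)
    if (length(miss)) stop("input_rois not present: ",
                           paste(miss, collapse = ", "))
    mat <- mat[as.character(input_rois), , drop = FALSE]
  }
  mat
}

#' Train the joint RV/HR reconstruction network
#'
#' Trains the bidirectional LSTM with Adam on variable-length scans. The
#' learning rate is multiplied by `lr_decay` after `patience` epochs without
#' validation-loss improvement, training stops early after `stall_epochs`
#' epochs without improvement, and the returned weights are those of the
#' epoch with minimum validation loss. All randomness (initialization,
#' batch order, dropout) is governed by `config$seed`.
#'
#' @param dataset Tibble with columns `scan_id`, `subject`, `x` (list of
#'   R x T matrices or `roi_timeseries`), `rv`, `hr` (lists of length-T
#'   z-scored target vectors), e.g. from [simulate_dataset()].
#' @param config A [recon_config()].
#' @param train,val Vectors of `scan_id` selecting the training and
#'   validation scans.
#' @return A `recon_model`: best weights, config, ROI ids, per-epoch log
#'   tibble and provenance.
#' @export
train_recon <- function(dataset, config, train, val) {
  stopifnot(inherits(config, "recon_config"),
            all(c("scan_id", "x", "rv", "hr") %in% names(dataset)))
  tr <- match(train, dataset$scan_id)
  va <- match(val, dataset$scan_id)
  if (length(tr) == 0 || anyNA(tr)) stop("empty or unknown training set")
  if (length(va) == 0 || anyNA(va)) stop("empty or unknown validation set")

  xs <- lapply(dataset$x, scan_matrix, input_rois = config$input_rois)
  R <- unique(vapply(xs, nrow, integer(1)))
  if (length(R) != 1) stop("scans disagree on channel count")
  roi_ids <- rownames(xs[[1]]) %||% as.character(seq_len(R))

  H <- config$hidden_size
  p <- config$dropout
  val_batch <- pack_batch(xs[va], dataset$rv[va], dataset$hr[va])
  data_hash <- rlang::hash(list(dim = c(R, length(xs)), train = train,
                                val = val))

  with_seed(config$seed, {
    params <- init_params(R, H)
    state <- list(t = 0, m = lapply(params, function(x) x * 0),
                  v = lapply(params, function(x) x * 0))
    lr <- config$lr
    best_val <- Inf
    best_params <- params
    best_epoch <- 0L
    stall <- 0L
    stall_lr <- 0L
    log <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- tr[sample.int(length(tr))]
      nb <- ceiling(length(ord) / config$batch_size)
      tr_loss <- 0
      tr_n <- 0
      for (ib in seq_len(nb)) {
        sel <- ord[((ib - 1) * config$batch_size + 1):
                     min(ib * config$batch_size, length(ord))]
        batch <- pack_batch(xs[sel], dataset$rv[sel], dataset$hr[sel])
        dims <- c(2 * H, length(sel), dim(batch$X)[3])
        dropmask <- if (p > 0) {
          array((runif(prod(dims)) >= p) / (1 - p), dims)
        } else {
          array(1, dims)
        }
        out <- .cpp_bilstm_grad(batch$X, batch$lengths, batch$rv, batch$hr,
                                batch$mask, batch$mask, dropmask,
                                params$Wf, params$Uf, params$bf,
                                params$Wb, params$Ub, params$bb,
                                params$Wy, params$by)
        if (!is.finite(out$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        upd <- adam_step(params, out$grads, state, lr)
        params <- upd$params
        state <- upd$state
        tr_loss <- tr_loss + out$loss * length(sel)
        tr_n <- tr_n + length(sel)
      }
      val_loss <- batch_loss(params, val_batch)
      if (!is.finite(val_loss)) {
        stop("training diverged (non-finite validation loss) at epoch ",
             epoch)
      }
      log[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss / tr_n,
                             val_loss = val_loss, lr = lr)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
        stall_lr <- 0L
      } else {
        stall <- stall + 1L
        stall_lr <- stall_lr + 1L
        if (stall_lr >= config$patience) {
          lr <- lr * config$lr_decay
          stall_lr <- 0L
        }
        if (stall >= config$stall_epochs) break
      }
    }
    structure(list(weights = best_params, config = config,
                   roi_ids = roi_ids, hidden_size = H,
                   log = dplyr::bind_rows(log), best_epoch = best_epoch,
                   best_val_loss = best_val, data_hash = data_hash,
                   init = "uniform(-1/sqrt(h), 1/sqrt(h))"),
              class = "recon_model")
  })
}

#' Reconstruct RV and HR from a preprocessed scan
#'
#' Runs the trained network in inference mode (dropout inactive), producing
#' per-frame RV and HR estimates of the same length as the input. Inference
#' is deterministic: identical inputs and weights give identical outputs.
#'
#' @param model A [train_recon()] model.
#' @param ts A preprocessed [roi_timeseries()] or R x T matrix whose
#'   channels match the model's ROI ids.
#' @return Tibble with `frame`, `rv_hat`, `hr_hat`.
#' @export
forward_recon <- function(model, ts) {
  stopifnot(inherits(model, "recon_model"))
  mat <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  if (!identical(ids, model$roi_ids)) {
    if (all(model$roi_ids %in% ids)) {
      mat <- mat[model$roi_ids, , drop = FALSE]
    } else {
      stop("channel mismatch: model expects ROIs [",
           paste(utils::head(model$roi_ids, 5), collapse = ", "),
           if (length(model$roi_ids) > 5) ", ..." else "",
           "] but received [",
           paste(utils::head(ids, 5), collapse = ", "),
           if (length(ids) > 5) ", ..." else "", "]")
    }
  }
  T_ <- ncol(mat)
  X <- array(mat, c(nrow(mat), 1, T_))
  w <- model$weights
  pred <- .cpp_bilstm_forward(X, T_, w$Wf, w$Uf, w$bf, w$Wb, w$Ub, w$bb,
                              w$Wy, w$by)
  tibble(frame = seq_len(T_), rv_hat = as.numeric(pred$rv),
         hr_hat = as.numeric(pred$hr))
}

#' Evaluate a model on a set of scans
#'
#' @param model A [train_recon()] model.
#' @param dataset Dataset tibble (see [train_recon()]).
#' @param ids Scan ids to evaluate (default: all).
#' @param fold Optional fold label recorded in the output.
#' @return Tibble with `scan_id`, `subject`, `r_rv`, `r_hr` (and `fold`).
#' @export
evaluate_recon <- function(model, dataset, ids = NULL, fold = NA_integer_) {
  ids <- ids %||% dataset$scan_id
  sel <- match(ids, dataset$scan_id)
  stopifnot(!anyNA(sel))
  purrr::map_dfr(sel, function(i) {
    pred <- forward_recon(model, dataset$x[[i]])
    tibble(scan_id = dataset$scan_id[i],
           subject = if ("subject" %in% names(dataset))
             dataset$subject[i] else NA_character_,
           r_rv = evaluate_scan(pred$rv_hat, dataset$rv[[i]]),
           r_hr = evaluate_scan(pred$hr_hat, dataset$hr[[i]]),
           fold = fold)
  })
}

#' @export
print.recon_model <- function(x, ...) {
  cat(sprintf(paste0("<recon_model> bi-LSTM, %d input ROIs, hidden %d/dir; ",
                     "best epoch %d (val loss %.4g)\n"),
              length(x$roi_ids), x$hidden_size, x$best_epoch,
              x$best_val_loss))
  invisible(x)
}

#' @export
#' @method tidy recon_model
tidy.recon_model <- function(x, ...) x$log

#' @export
#' @method glance recon_model
glance.recon_model <- function(x, ...) {
  tibble(n_rois = length(x$roi_ids), hidden_size = x$hidden_size,
         n_params = sum(vapply(x$weights, length, numeric(1))),
         epochs_run = nrow(x$log), best_epoch = x$best_epoch,
         best_val_loss = x$best_val_loss)
}

#' @export
#' @method autoplot recon_model
autoplot.recon_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL)
}

#' Save / load a model checkpoint
#'
#' A single-file archive holding the weights, configuration, ROI-id list
#' and training-data hash, so inference can verify channel compatibility.
#'
#' @param model A `recon_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the `recon_model` (load).
#' @export
save_recon_model <- function(model, path) {
  stopifnot(inherits(model, "recon_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_recon_model
#' @export
load_recon_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "recon_model"))
  model
}
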
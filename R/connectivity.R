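#' Assemble a nuisance regressor set
#'
#' Column-binds physiological regressors (e.g. from
#' [physio_regressor_set()]) with six rigid-body head-motion parameters and
#' their backward first-difference derivatives (leading 0). All columns are
#' mean-centered.
#'
#' @param regressors Optional T x K matrix of physiological regressors.
#' @param motion Optional T x 6 matrix of motion parameters.
#' @return T x K' mean-centered nuisance matrix (0 columns if both `NULL`).
#' @export
make_nuisance <- function(regressors = NULL, motion = NULL) {
  parts <- list()
  if (!is.null(regressors)) parts$physio <- as.matrix(regressors)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(ncol(motion) == 6)
    colnames(motion) <- paste0("mot", 1:6)
    dmotion <- apply(motion, 2, function(x) c(0, diff(x)))
    colnames(dmotion) <- paste0("dmot", 1:6)
    parts$motion <- cbind(motion, dmotion)
  }
  if (length(parts) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  out <- do.call(cbind, parts)
  sweep(out, 2, colMeans(out))
}

#' Project a nuisance subspace out of ROI time series
#'
#' Per row, the OLS residual against an intercept plus the nuisance columns.
#' With an empty nuisance set this reduces to row-demeaning. Linearly
#' dependent nuisance columns are pruned with a warning. Residuals are
#' orthogonal to every retained column.
#'
#' @param ts A [roi_timeseries()] or R x T matrix.
#' @param nuisance T x K nuisance matrix (e.g. [make_nuisance()]), or `NULL`.
#' @return Residual object of the same type as `ts`.
#' @export
project_out_nuisance <- function(ts, nuisance = NULL) {
  is_obj <- inherits(ts, "roi_timeseries")
  mat <- if (is_obj) ts$data else as.matrix(ts)
  T_ <- ncol(mat)
  if (is.null(nuisance) || length(nuisance) == 0 || ncol(nuisance) == 0) {
    res <- mat - rowMeans(mat)
  } else {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == T_)
    if (ncol(nuisance) >= T_) stop("more nuisance columns than frames")
    A <- cbind(1, nuisance)
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) {
      warning("pruning ", ncol(A) - qrA$rank,
              " linearly dependent nuisance column(s)")
      A <- A[, qrA$pivot[seq_len(qrA$rank)], drop = FALSE]
      qrA <- qr(A)
    }
    res <- t(qr.resid(qrA, t(mat)))
  }
  if (is_obj) {
    roi_timeseries(res, dt = ts$dt, roi_ids = ts$roi_ids,
                   preprocessed = ts$preprocessed)
  } else {
    res
  }
}

#' ROI-to-ROI functional connectivity matrix
#'
#' Pairwise Pearson correlation of ROI time series: a symmetric matrix with
#' unit diagonal and entries in \[-1, 1\].
#'
#' @param ts A [roi_timeseries()] or R x T matrix.
#' @return An `fc_matrix` (R x R correlation matrix with `roi_ids`).
#' @export
fc_matrix <- function(ts) {
  is_obj <- inherits(ts, "roi_timeseries")
  mat <- if (is_obj) ts$data else as.matrix(ts)
  ids <- if (is_obj) ts$roi_ids else seq_len(nrow(mat))
  sds <- apply(mat, 1, function(x) diff(range(x)))
  if (any(sds == 0)) {
    stop("constant ROI time series: ", paste(ids[sds == 0], collapse = ", "))
  }
  fc <- cor(t(mat))
  dimnames(fc) <- list(ids, ids)
  structure(fc, roi_ids = ids, class = c("fc_matrix", "matrix", "array"))
}

#' @export
#' @method autoplot fc_matrix
autoplot.fc_matrix <- function(object, ...) {
  ids <- attr(object, "roi_ids")
  df <- tibble(
    roi_a = rep(seq_along(ids), times = length(ids)),
    roi_b = rep(seq_along(ids), each = length(ids)),
    r = as.numeric(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}

#' Seed-based correlation map
#'
#' Correlates the time course of a seed location (given in world/MNI mm
#' coordinates) with every voxel of a 4D volume. By default the seed series
#' is the single voxel nearest the coordinate; `radius > 0` averages voxels
#' within a sphere of that world-space radius. An optional nuisance set is
#' projected out of the seed and every voxel series before correlating.
#'
#' @param fmri 4D array or `RNifti` image.
#' @param seed_xyz Length-3 world coordinates (mm); the default
#'   `c(2, -58, 30)` is a standard default-mode-network seed in MNI152
#'   space.
#' @param affine 4 x 4 voxel-to-world affine; taken from the image header
#'   when `fmri` is a NIfTI image.
#' @param nuisance Optional T x K nuisance matrix.
#' @param radius Seed sphere radius (mm); 0 = nearest voxel only.
#' @return 3D array of correlations in \[-1, 1\].
#' @export
seed_correlation_map <- function(fmri, seed_xyz = c(2, -58, 30),
                                 affine = NULL, nuisance = NULL,
                                 radius = 0) {
  if (inherits(fmri, "niftiImage")) {
    if (is.null(affine)) affine <- structure(RNifti::xform(fmri),
                                             class = NULL)
    fmri <- as.array(fmri)
  }
  if (is.null(affine)) affine <- diag(4)
  dm <- dim(fmri)
  stopifnot(length(dm) == 4L, length(seed_xyz) == 3L)
  ijk1 <- solve(affine, c(seed_xyz, 1))[1:3] + 1  # 1-based voxel indices
  ijk <- round(ijk1)
  if (any(ijk < 1) || any(ijk > dm[1:3])) {
    stop("seed coordinate falls outside the image volume")
  }
  V <- prod(dm[1:3])
  flat <- matrix(fmri, V, dm[4])
  if (radius > 0) {
    grid <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                                  k = seq_len(dm[3])))
    world <- t(affine %*% rbind(t(grid) - 1, 1))[, 1:3]
    d2 <- rowSums(sweep(world, 2, seed_xyz)^2)
    sel <- which(d2 <= radius^2)
    seed_series <- colMeans(flat[sel, , drop = FALSE])
  } else {
    vidx <- ijk[1] + (ijk[2] - 1) * dm[1] + (ijk[3] - 1) * dm[1] * dm[2]
    seed_series <- flat[vidx, ]
  }
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0) {
    seed_series <- as.numeric(project_out_nuisance(matrix(seed_series, 1),
                                                   nuisance))
    flat <- project_out_nuisance(flat, nuisance)
  } else {
    seed_series <- seed_series - mean(seed_series)
    flat <- flat - rowMeans(flat)
  }
  seed_norm <- sqrt(sum(seed_series^2))
  if (seed_norm < 1e-10 * sqrt(dm[4])) {
    warning("seed series is degenerate (near-zero variance after projection)")
    return(array(0, dm[1:3]))
  }
  vox_norm <- sqrt(rowSums(flat^2))
  r <- as.numeric(flat %*% seed_series) / (vox_norm * seed_norm)
  r[vox_norm == 0] <- 0
  array(pmin(1, pmax(-1, r)), dm[1:3])
}

#' Read rigid-body motion parameters
#'
#' Six-column whitespace- or tab-separated text (translations + rotations,
#' one row per frame).
#'
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("expected 6 motion columns, got ", ncol(m))
  dimnames(m) <- NULL
  m
}

#' Write a functional connectivity matrix as TSV
#'
#' @param fc An [fc_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  write.table(unclass(fc), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
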
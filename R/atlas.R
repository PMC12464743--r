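#' A single atlas part
#'
#' One component of a composite parcellation: either an integer label volume
#' (3D array, 0 = background) or a probabilistic map (4D array, one volume
#' per region, values in \[0, 1\]) that is binarized at `threshold` before
#' labeling. A voxel covered by several probability volumes at or above the
#' threshold is assigned to the volume with the highest probability.
#'
#' @param data 3D integer array (`kind = "label"`) or 4D numeric array
#'   (`kind = "probability"`).
#' @param kind `"label"` or `"probability"`.
#' @param name Part name (e.g. `"cortical"`, `"wm"`).
#' @param threshold Probability threshold for probabilistic parts. The
#'   composite white-matter part is thresholded at 0.95 to exclude
#'   low-confidence voxels.
#' @param labels Optional character names for the part's regions.
#' @return An `atlas_part` object.
#' @export
atlas_part <- function(data, kind = c("label", "probability"), name,
                       threshold = 0.95, labels = NULL) {
  kind <- match.arg(kind)
  data <- unclass(data)
  if (kind == "label") {
    stopifnot(length(dim(data)) == 3L)
    n_lab <- max(data)
  } else {
    stopifnot(length(dim(data)) == 4L, threshold > 0, threshold <= 1)
    n_lab <- dim(data)[4]
  }
  if (!is.null(labels)) stopifnot(length(labels) == n_lab)
  structure(list(data = data, kind = kind, name = name,
                 threshold = threshold, n_labels = n_lab,
                 labels = labels %||% paste0(name, "_", seq_len(n_lab))),
            class = "atlas_part")
}

#' Compose a multi-atlas parcellation
#'
#' Merges atlas parts into a single label volume with contiguous global ROI
#' ids (1, 2, ...). Global ids follow the concatenation order of `parts`;
#' voxels claimed by several parts are resolved by `precedence` (lower rank
#' wins) and counted as overlaps. For the canonical four-part bundle
#' (cortical, white matter, subcortical, ascending arousal network) the
#' default precedence favors gray matter: cortical > subcortical > aan > wm.
#'
#' @param parts Named list of [atlas_part()] objects sharing one voxel grid.
#' @param precedence Integer rank per part (lower = higher precedence);
#'   `NULL` uses the gray-matter-first rule when the parts carry the
#'   canonical names, and list order otherwise.
#' @param space Template identifier stored with the bundle.
#' @return An `atlas_bundle`: label volume (`labels`), ROI index tibble
#'   (`roi_index` with `roi_id`, `part`, `local_label`, `name`, `n_voxels`),
#'   and the number of overlapping voxels (`overlap_voxels`).
#' @export
compose_atlas <- function(parts, precedence = NULL, space = "MNI152") {
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, logical(1),
                                           "atlas_part")))
  if (is.null(names(parts)) || any(names(parts) == "")) {
    names(parts) <- vapply(parts, `[[`, character(1), "name")
  }
  dims <- lapply(parts, function(p) dim(p$data)[1:3])
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("atlas parts do not share a voxel grid; resample upstream")
  }
  dm <- dims[[1]]
  canonical <- c("cortical", "wm", "subcortical", "aan")
  if (is.null(precedence)) {
    precedence <- if (all(names(parts) %in% canonical)) {
      match(names(parts), c("cortical", "subcortical", "aan", "wm"))
    } else {
      seq_along(parts)
    }
  }
  stopifnot(length(precedence) == length(parts))

  # global id offsets in concatenation (list) order
  offsets <- cumsum(c(0, head(vapply(parts, `[[`, numeric(1), "n_labels"),
                              -1)))
  global <- array(0L, dm)
  overlap <- 0L
  for (i in order(precedence)) {
    p <- parts[[i]]
    local <- part_local_labels(p)
    claimed <- local > 0L
    taken <- claimed & global > 0L
    overlap <- overlap + sum(taken)
    assign_to <- claimed & global == 0L
    global[assign_to] <- local[assign_to] + as.integer(offsets[i])
  }

  idx <- purrr::imap_dfr(parts, function(p, nm) {
    tibble(part = nm, local_label = seq_len(p$n_labels), name = p$labels)
  })
  idx$roi_id <- seq_len(nrow(idx))
  counts <- tabulate(global, nbins = nrow(idx))
  idx$n_voxels <- counts
  idx <- idx[, c("roi_id", "part", "local_label", "name", "n_voxels")]
  if (any(idx$n_voxels == 0)) {
    bad <- idx$name[idx$n_voxels == 0]
    stop("ROIs empty after composition: ", paste(bad, collapse = ", "))
  }
  structure(list(labels = global, roi_index = idx, overlap_voxels = overlap,
                 dim = dm, space = space,
                 precedence = stats::setNames(precedence, names(parts))),
            class = "atlas_bundle")
}

part_local_labels <- function(p) {
  if (p$kind == "label") return(array(as.integer(p$data), dim(p$data)[1:3]))
  dm <- dim(p$data)
  flat <- matrix(p$data, prod(dm[1:3]), dm[4])
  flat[flat < p$threshold] <- NA  # strictly below threshold excluded
  best <- max.col(replace(flat, is.na(flat), -Inf), ties.method = "first")
  best[!rowSums(!is.na(flat))] <- 0L
  array(as.integer(best), dm[1:3])
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> %d ROIs from %d parts on a %s grid (%s); %d overlapping voxels\n",
              nrow(x$roi_index), length(unique(x$roi_index$part)),
              paste(x$dim, collapse = "x"), x$space, x$overlap_voxels))
  invisible(x)
}

#' ROI-by-time matrix of parcel-mean BOLD signals
#'
#' @param data Numeric R x T matrix (one row per ROI).
#' @param dt Frame spacing (s).
#' @param roi_ids ROI identifiers (defaults to row numbers).
#' @param preprocessed Has [preprocess_timeseries()] been applied?
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(data, dt, roi_ids = NULL, preprocessed = FALSE) {
  data <- as.matrix(data)
  stopifnot(dt > 0)
  roi_ids <- roi_ids %||% seq_len(nrow(data))
  stopifnot(length(roi_ids) == nrow(data))
  rownames(data) <- as.character(roi_ids)
  structure(list(data = data, dt = dt, roi_ids = roi_ids,
                 preprocessed = preprocessed),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d ROIs x %d frames, dt = %g s%s\n",
              nrow(x$data), ncol(x$data), x$dt,
              if (x$preprocessed) " (preprocessed)" else ""))
  invisible(x)
}

#' @export
#' @method as_tibble roi_timeseries
as_tibble.roi_timeseries <- function(x, ...) {
  tibble(roi_id = rep(x$roi_ids, ncol(x$data)),
         frame = rep(seq_len(ncol(x$data)), each = nrow(x$data)),
         time = rep((seq_len(ncol(x$data)) - 1) * x$dt, each = nrow(x$data)),
         bold = as.numeric(x$data))
}

#' Extract parcel-mean time series from a 4D volume
#'
#' Each output row is the unweighted mean over the voxels of one ROI at each
#' frame. The fMRI grid must match the bundle grid. An ROI with no voxels
#' inside the image field of view yields a row of `NA` with a warning.
#'
#' @param fmri 4D numeric array or `RNifti` image (frame spacing read from
#'   the header when available).
#' @param bundle An [compose_atlas()] bundle.
#' @param dt Frame spacing (s); required for plain arrays.
#' @return A [roi_timeseries()] object.
#' @export
extract_roi_timeseries <- function(fmri, bundle, dt = NULL) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (inherits(fmri, "niftiImage")) {
    if (is.null(dt)) dt <- RNifti::pixdim(fmri)[4]
    fmri <- as.array(fmri)
  }
  if (is.null(dt) || !is.finite(dt) || dt <= 0) {
    stop("frame spacing dt not available; pass dt explicitly")
  }
  dm <- dim(fmri)
  if (length(dm) != 4L || !all(dm[1:3] == bundle$dim)) {
    stop(sprintf("fMRI grid (%s) does not match atlas grid (%s)",
                 paste(dm[1:3], collapse = "x"),
                 paste(bundle$dim, collapse = "x")))
  }
  V <- prod(dm[1:3])
  flat <- matrix(fmri, V, dm[4])
  lab <- as.integer(bundle$labels)
  R <- nrow(bundle$roi_index)
  keep <- lab > 0L
  sums <- rowsum(flat[keep, , drop = FALSE], lab[keep])
  counts <- tabulate(lab[keep], nbins = R)
  out <- matrix(NA_real_, R, dm[4])
  got <- as.integer(rownames(sums))
  out[got, ] <- sums / counts[got]
  if (any(counts == 0)) {
    warning("ROIs outside the image field of view: ",
            paste(bundle$roi_index$name[counts == 0], collapse = ", "))
  }
  roi_timeseries(out, dt = dt, roi_ids = bundle$roi_index$roi_id)
}

#' Preprocess parcel time series for model input
#'
#' Per row, in order: remove the OLS-best linear + quadratic trend, apply the
#' zero-phase Butterworth band-pass, decimate by `downsample` (keeping
#' frames 1, 1 + factor, ...), and z-normalize. The output frame spacing is
#' `dt * downsample`. Head-motion parameters are deliberately not regressed
#' out: apparent motion carries respiratory information that the
#' reconstruction model can exploit.
#'
#' @param ts A [roi_timeseries()] object (not yet preprocessed).
#' @param band Pass band (Hz).
#' @param downsample Integer decimation factor.
#' @return A preprocessed [roi_timeseries()].
#' @export
preprocess_timeseries <- function(ts, band = c(0.01, 0.15), downsample = 2L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ts$preprocessed) stop("time series already preprocessed")
  if (anyNA(ts$data)) stop("cannot preprocess rows with missing data")
  rows <- lapply(seq_len(nrow(ts$data)), function(r) {
    x <- detrend_poly2(ts$data[r, ])
    x <- bp_filtfilt(x, ts$dt, band)
    x <- decimate_keep(x, downsample)
    suppress_constant_warning <- diff(range(x)) == 0
    if (suppress_constant_warning) {
      warning("ROI ", ts$roi_ids[r], " is constant after filtering")
      rep(0, length(x))
    } else {
      znormalize(x)
    }
  })
  roi_timeseries(do.call(rbind, rows), dt = ts$dt * downsample,
                 roi_ids = ts$roi_ids, preprocessed = TRUE)
}

#' Write / read ROI time series as TSV + JSON sidecar
#'
#' Rows are ROIs, columns frames. The sidecar `<path>.json` records `dt`,
#' `roi_ids` and the preprocessing state.
#'
#' @param ts A [roi_timeseries()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  write.table(ts$data, path, sep = "\t", quote = FALSE, col.names = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(dt = ts$dt, roi_ids = ts$roi_ids,
                            preprocessed = ts$preprocessed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @export
read_roi_timeseries <- function(path) {
  dat <- as.matrix(read.table(path, header = FALSE, sep = "\t"))
  dimnames(dat) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  roi_timeseries(dat, dt = meta$dt, roi_ids = meta$roi_ids,
                 preprocessed = isTRUE(meta$preprocessed))
}

#' Read an atlas manifest and compose the bundle
#'
#' The manifest is a YAML list of parts, each with `file` (NIfTI volume),
#' `kind` (`label` or `probability`), optional `threshold`, `name` and
#' `precedence`. Paths are resolved relative to the manifest.
#'
#' @param path Manifest path.
#' @return An `atlas_bundle`.
#' @export
read_atlas_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  parts <- lapply(man$parts, function(p) {
    f <- p$file
    if (!file.exists(f)) f <- file.path(base, p$file)
    atlas_part(as.array(RNifti::readNifti(f)), kind = p$kind,
               name = p$name, threshold = p$threshold %||% 0.95)
  })
  names(parts) <- vapply(man$parts, `[[`, character(1), "name")
  prec <- vapply(man$parts, function(p) p$precedence %||% NA_integer_,
                 numeric(1))
  compose_atlas(parts,
                precedence = if (all(is.na(prec))) NULL else as.integer(prec))
}
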
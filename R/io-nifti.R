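#' Voxel mask: the node set of a voxel-wise network
#'
#' Maps a 3D voxel grid to flat node indices. In-mask voxels are enumerated
#' by a raster scan with the last (k) axis fastest and 0-based grid
#' coordinates internally converted to R's 1-based indexing; the ordering is
#' a pure function of the mask, so node indices are stable across platforms
#' and runs.
#'
#' @param include logical or 0/1 3D array marking in-mask voxels
#' @return an object of class `voxel_mask` with fields `dims` (grid shape),
#'   `voxel_index` (N x 3 integer matrix of 1-based (i,j,k) coordinates in
#'   scan order) and `N` (node count).
#' @export
voxel_mask <- function(include) {
  if (length(dim(include)) != 3L) stop("mask must be a 3D array")
  dims <- dim(include)
  inc <- array(as.logical(include), dims)
  if (anyNA(inc)) stop("mask contains missing values")
  coords <- which(inc, arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("mask selects no voxels; downstream analysis needs N >= 2")
  # raster order: i slowest, k fastest
  ord <- order(coords[, 1L], coords[, 2L], coords[, 3L])
  coords <- coords[ord, , drop = FALSE]
  colnames(coords) <- c("i", "j", "k")
  structure(list(dims = as.integer(dims),
                 voxel_index = coords,
                 N = nrow(coords)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %d voxels in a %s grid\n",
              x$N, paste(x$dims, collapse = " x ")))
  invisible(x)
}

#' Binarize a tissue-probability map into a voxel mask
#'
#' A voxel enters the mask iff its probability (or any scalar value) is
#' strictly greater than `threshold`. The default 0.2 is the conventional
#' gray-matter probability cutoff for voxel-wise network construction.
#'
#' @param prob_map 3D numeric array, or a path to a 3D NIfTI volume
#' @param threshold inclusion cutoff; strict `>`
#' @return a `voxel_mask`
#' @export
binarize_mask <- function(prob_map, threshold = 0.2) {
  if (is.character(prob_map)) prob_map <- as.array(RNifti::readNifti(prob_map))
  if (length(dim(prob_map)) != 3L) stop("probability map must be 3D")
  if (any(!is.finite(prob_map))) stop("probability map contains non-finite values")
  voxel_mask(prob_map > threshold)
}

#' Node-wise time series extracted from a 4D volume
#'
#' Constructs the L x N time-series container: rows are time points, columns
#' are nodes. Columns follow the mask's deterministic voxel ordering when a
#' mask is attached.
#'
#' @param data L x N numeric matrix
#' @param mask optional `voxel_mask`; if present its N must match `ncol(data)`
#' @param subject_id optional label
#' @return object of class `timeseries_set`
#' @export
timeseries_set <- function(data, mask = NULL, subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (anyNA(data)) stop("time-series data contains missing values")
  if (nrow(data) < 3L) stop("need at least 3 time points")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voxel_mask"))
    if (mask$N != ncol(data))
      stop(sprintf("mask has %d voxels but data has %d columns", mask$N, ncol(data)))
  }
  structure(list(data = data, mask = mask, subject_id = subject_id,
                 L = nrow(data), N = ncol(data)),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat(sprintf("timeseries_set: %d time points x %d nodes (subject: %s)\n",
              x$L, x$N, x$subject_id))
  invisible(x)
}

#' Read masked voxel time series from a 4D NIfTI volume
#'
#' @param path_4d path to a 4D NIfTI file (x, y, z, time)
#' @param mask a `voxel_mask` whose dims equal the volume's first three dims
#' @param subject_id optional label carried on the result
#' @return a `timeseries_set`; column j is the time course of mask voxel j
#' @export
read_timeseries <- function(path_4d, mask, subject_id = NA_character_) {
  stopifnot(inherits(mask, "voxel_mask"))
  vol <- as.array(RNifti::readNifti(path_4d))
  d <- dim(vol)
  if (length(d) != 4L) stop("input volume must be 4D (x, y, z, time)")
  if (!identical(as.integer(d[1:3]), mask$dims))
    stop(sprintf("volume grid %s does not match mask grid %s",
                 paste(d[1:3], collapse = "x"), paste(mask$dims, collapse = "x")))
  L <- d[4L]
  # flatten: voxel (i,j,k) at time t sits at linear index i + (j-1)*di + (k-1)*di*dj
  flat <- matrix(vol, prod(d[1:3]), L)
  lin <- mask$voxel_index[, 1L] +
    (mask$voxel_index[, 2L] - 1L) * d[1L] +
    (mask$voxel_index[, 3L] - 1L) * d[1L] * d[2L]
  timeseries_set(t(flat[lin, , drop = FALSE]), mask = mask, subject_id = subject_id)
}

#' Write per-node values back into a 3D NIfTI map
#'
#' In-mask voxels receive their node's value; out-of-mask voxels are 0.
#' Used for degree maps, hub masks and module label maps.
#'
#' @param values numeric vector of length `mask$N`
#' @param mask a `voxel_mask`
#' @param path output path (.nii or .nii.gz)
#' @return invisibly, the written 3D array
#' @export
write_voxel_map <- function(values, mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(values) != mask$N)
    stop(sprintf("expected %d values, got %d", mask$N, length(values)))
  vol <- array(0, dim = mask$dims)
  vol[mask$voxel_index] <- as.numeric(values)
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(vol)
}

#' Read a per-node map previously written with [write_voxel_map()]
#'
#' @param path NIfTI path
#' @param mask the `voxel_mask` the map was written with
#' @return numeric vector of length `mask$N`
#' @export
read_voxel_map <- function(path, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) != 3L) stop("voxel map must be 3D")
  if (!identical(as.integer(dim(vol)), mask$dims)) stop("grid mismatch with mask")
  as.numeric(vol[mask$voxel_index])
}

#' Write a 4D time-series volume for a masked node set
#'
#' Inverse of [read_timeseries()]: places column j of the series at mask
#' voxel j for every time point; out-of-mask voxels are 0.
#'
#' @param ts a `timeseries_set` with a mask attached
#' @param path output NIfTI path
#' @return invisibly, the path
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries_set"))
  if (is.null(ts$mask)) stop("timeseries_set has no voxel mask attached")
  d <- c(ts$mask$dims, ts$L)
  vol <- array(0, dim = d)
  lin0 <- ts$mask$voxel_index[, 1L] +
    (ts$mask$voxel_index[, 2L] - 1L) * d[1L] +
    (ts$mask$voxel_index[, 3L] - 1L) * d[1L] * d[2L]
  npervol <- prod(d[1:3])
  for (t in seq_len(ts$L)) {
    vol[lin0 + (t - 1L) * npervol] <- ts$data[t, ]
  }
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
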
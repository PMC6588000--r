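# Dataset container and map export.
#
# The dataset container is a versioned R-native (RDS) bundle holding the
# k-space samples, trajectory, coil maps, model parameters, optional B1
# map and optional ground truth; shapes and required fields are validated
# on load so that a malformed file fails with a descriptive error rather
# than deep inside the reconstruction.

DATASET_FORMAT_VERSION <- 1L

dataset_bundle <- function(data, traj, coils, model, b1 = NULL,
                           truth = NULL, attrs = list()) {
  list(version = DATASET_FORMAT_VERSION,
       kspace = data,
       trajectory = list(angles = traj$angles, n_samples = traj$n_samples,
                         n_spokes = traj$n_spokes,
                         n_encodings = traj$n_encodings,
                         continue_across = traj$continue_across,
                         start_index = traj$start_index),
       coils = coils,
       model = serialize_model(model),
       b1 = b1,
       ground_truth = truth,
       attrs = attrs)
}

serialize_model <- function(model) {
  if (model$type == "vfa") {
    list(type = "vfa", flip_angles_deg = model$flip_angles_deg,
         tr_ms = model$tr_ms)
  } else {
    list(type = "irll", params = unclass(model$params))
  }
}

deserialize_model <- function(m, b1 = NULL) {
  if (m$type == "vfa") {
    vfa_model(m$flip_angles_deg, m$tr_ms, b1 = b1)
  } else {
    p <- m$params
    irll_model(irll_params(p$flip_angle_deg, p$tau_ms, p$td_ms,
                           p$n_readouts, tr_ms = p$tr_ms,
                           spokes_per_frame = p$spokes_per_frame), b1 = b1)
  }
}

#' Write a dataset container
#'
#' Serializes k-space data, trajectory, coil maps, model parameters and
#' optional B1 map / ground truth into a single versioned file; the
#' round trip through [read_dataset()] is exact.
#'
#' @param path output file path (conventionally `.rds`).
#' @param data k-space array `(ns, nspokes, nz, nc, np)` or a
#'   [simulate_dataset()] result (in which case the remaining arguments
#'   are taken from it).
#' @param traj,coils,model,b1,truth dataset components.
#' @param attrs named list of additional attributes (e.g. `snr_db`,
#'   `seed`).
#' @return the path, invisibly.
#' @export
write_dataset <- function(path, data, traj = NULL, coils = NULL,
                          model = NULL, b1 = NULL, truth = NULL,
                          attrs = list()) {
  if (inherits(data, "t1_dataset")) {
    ds <- data
    attrs <- c(list(snr_db = ds$snr_db, seed = ds$seed), attrs)
    bundle <- dataset_bundle(ds$data, ds$traj, ds$coils, ds$model,
                             b1 = ds$b1, truth = ds$truth, attrs = attrs)
  } else {
    stopifnot(!is.null(traj), !is.null(coils), !is.null(model))
    bundle <- dataset_bundle(data, traj, coils, model, b1 = b1,
                             truth = truth, attrs = attrs)
  }
  saveRDS(bundle, path)
  invisible(path)
}

#' Read a dataset container
#'
#' Loads and validates a container written by [write_dataset()]: the
#' format version must match and all shapes must be mutually consistent.
#'
#' @param path file path.
#' @return list with `data`, `traj` (a `sos_trajectory`), `coils`,
#'   `model` (reconstructed signal model, with the stored B1 applied),
#'   `b1`, `truth`, `attrs`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  b <- readRDS(path)
  if (is.null(b$version) || b$version != DATASET_FORMAT_VERSION)
    stop(sprintf("dataset format version mismatch (found %s, expected %d)",
                 b$version %||% "none", DATASET_FORMAT_VERSION))
  if (is.null(b$coils)) stop("coil maps required but missing from container")
  if (is.null(b$kspace)) stop("k-space data missing from container")
  tr <- b$trajectory
  traj <- make_trajectory(tr$n_spokes, tr$n_samples, tr$n_encodings,
                          continue_across = tr$continue_across,
                          start_index = tr$start_index)
  if (!isTRUE(all.equal(traj$angles, tr$angles)))
    stop("stored trajectory angles are inconsistent with their parameters")
  dd <- dim(b$kspace); dc <- dim(b$coils)
  ok <- length(dd) == 5L && length(dc) == 4L &&
    dd[1] == tr$n_samples && dd[2] == tr$n_spokes && dd[3] == dc[3] &&
    dd[4] == dc[4] && dd[5] == tr$n_encodings
  if (!ok) stop("inconsistent array shapes in dataset container")
  model <- deserialize_model(b$model, b1 = b$b1)
  list(data = b$kspace, traj = traj, coils = b$coils, model = model,
       b1 = b$b1, truth = b$ground_truth, attrs = b$attrs)
}

#' Write parameter maps as NIfTI volumes
#'
#' Writes the T1 map (ms) and the M0 magnitude as two NIfTI files with the
#' voxel spacing recorded in the header.  Non-finite voxels are replaced
#' by 0 (with a message reporting the count).
#'
#' @param prefix output path prefix; files `<prefix>_T1.nii.gz` and
#'   `<prefix>_M0.nii.gz` are created.
#' @param fit a `t1_fit`, or a list with `T1` and `M0` volumes.
#' @param voxel_mm voxel size in mm (length 1 or 3); default 1 mm
#'   isotropic.
#' @return character vector of the two file paths, invisibly.
#' @export
write_maps <- function(prefix, fit, voxel_mm = 1) {
  T1 <- Re(fit$T1); M0 <- Mod(fit$M0)
  nbad <- sum(!is.finite(T1)) + sum(!is.finite(M0))
  if (nbad > 0) {
    message(sprintf("replacing %d non-finite voxels by 0", nbad))
    T1[!is.finite(T1)] <- 0
    M0[!is.finite(M0)] <- 0
  }
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  paths <- paste0(prefix, c("_T1.nii.gz", "_M0.nii.gz"))
  save1 <- function(vol, path) {
    im <- RNifti::asNifti(vol)
    RNifti::pixdim(im) <- voxel_mm
    RNifti::writeNifti(im, path)
  }
  save1(T1, paths[1])
  save1(M0, paths[2])
  invisible(paths)
}
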
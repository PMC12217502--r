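# NIfTI-1 I/O for image pairs and label maps (voxel size carried in the
# header pixdim).

#' Write an image pair (and optional label map) as NIfTI-1
#'
#' Writes `<prefix>_stir.nii.gz`, `<prefix>_flair.nii.gz`, and, when labels
#' are present, `<prefix>_labels.nii.gz` (integer-typed).
#'
#' @param pair an `ear_phantom` or a list with `stir`, `flair`, optional
#'   `labels`, and `voxel_size`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector of the paths written, invisibly.
#' @export
write_image_pair <- function(pair, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- pair$voxel_size
  as_nii <- function(a) {
    im <- RNifti::asNifti(a)
    RNifti::pixdim(im) <- c(v, v, v)
    im
  }
  paths <- c(stir = file.path(dir, paste0(prefix, "_stir.nii.gz")),
             flair = file.path(dir, paste0(prefix, "_flair.nii.gz")))
  RNifti::writeNifti(as_nii(pair$stir), paths[["stir"]])
  RNifti::writeNifti(as_nii(pair$flair), paths[["flair"]])
  if (!is.null(pair$labels)) {
    paths[["labels"]] <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
    RNifti::writeNifti(as_nii(array(as.integer(pair$labels), dim(pair$labels))),
                       paths[["labels"]], datatype = "int16")
  }
  invisible(paths)
}

#' Read an image pair from NIfTI files
#'
#' @param stir_path,flair_path paths to the two channels.
#' @param labels_path optional path to an integer label map.
#' @return list with `stir`, `flair`, optional `labels`, and `voxel_size`
#'   (mm, from the header; the two channels must agree in shape and
#'   spacing).
#' @export
read_image_pair <- function(stir_path, flair_path, labels_path = NULL) {
  stir <- RNifti::readNifti(stir_path)
  flair <- RNifti::readNifti(flair_path)
  if (!identical(dim(stir), dim(flair))) {
    stop("stir and flair grids differ in shape", call. = FALSE)
  }
  vs <- RNifti::pixdim(stir)[1]
  vf <- RNifti::pixdim(flair)[1]
  if (abs(vs - vf) > 1e-6) stop("stir and flair voxel sizes differ", call. = FALSE)
  out <- list(stir = array(as.numeric(stir), dim(stir)),
              flair = array(as.numeric(flair), dim(flair)),
              voxel_size = vs)
  if (!is.null(labels_path)) {
    lab <- RNifti::readNifti(labels_path)
    out$labels <- array(as.integer(lab), dim(lab))
  }
  out
}
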
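# NIfTI interchange for echo stacks, maps and label maps.

#' Write an echo series to NIfTI
#'
#' Stores the `H x W x n_echoes` stack as a NIfTI volume with the echo
#' spacing recorded in the temporal pixdim slot.
#'
#' @param series An [echo_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_echo_series <- function(series, path) {
  stopifnot(inherits(series, "echo_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(1, 1, series$protocol$echo_spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an echo series from NIfTI
#'
#' @param path NIfTI file holding an `H x W x n_echoes` stack.
#' @param protocol The acquisition protocol of the stored series.
#' @return An [echo_series()].
#' @export
read_echo_series <- function(path, protocol) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("expected a 3-D echo stack", call. = FALSE)
  arr <- array(as.numeric(arr), dim = dim(arr))   # drop NIfTI header attributes
  echo_series(arr, protocol)
}

#' Write a 2-D map or mask to NIfTI
#' @param img Numeric or logical matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(img, path) {
  RNifti::writeNifti(RNifti::asNifti(matrix(as.numeric(img), nrow(img))), path)
  invisible(path)
}

#' Read a 2-D map from NIfTI
#' @param path NIfTI file.
#' @return Numeric matrix.
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 2L) arr <- arr[, , 1L]
  matrix(as.numeric(arr), nrow(arr))
}
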
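#' Write / read volumes as NIfTI-1
#'
#' `write_volume()` accepts a `bold_run`, a 3-D/4-D array, or a logical
#' mask (written as 0/1) and stores voxel size (mm) and, for 4-D data, the
#' repetition time in the NIfTI pixdim. `read_volume()` returns a
#' `bold_run` for 4-D images and a plain array for 3-D images.
#'
#' @param x A `bold_run`, array, or logical mask.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size, taken from `x` when it is a `bold_run`.
#' @param tr_s Repetition time for 4-D arrays.
#' @return `write_volume()` returns `path` invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = c(3, 3, 3), tr_s = NULL) {
  if (inherits(x, "bold_run")) {
    voxel_size_mm <- x$voxel_size_mm
    tr_s <- x$tr_s
    x <- x$data
  }
  if (is.logical(x)) x <- array(as.numeric(x), dim = dim(x))
  nd <- length(dim(x))
  pd <- c(rep_len(voxel_size_mm, 3L), if (nd == 4L) tr_s %||% 1)
  im <- RNifti::asNifti(x)
  RNifti::pixdim(im) <- pd
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(im)
  arr <- array(as.numeric(im), dim = dim(im))
  if (length(dim(arr)) == 4L) {
    structure(list(data = arr, tr_s = pd[4], voxel_size_mm = pd[1:3],
                   mask = NULL), class = "bold_run")
  } else arr
}

#' Write a cluster table as CSV
#'
#' @param clusters A `cluster_table`.
#' @param path Output path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.csv(as.data.frame(clusters), path, row.names = FALSE)
  invisible(path)
}
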
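#' Write a 3D/4D array as NIfTI-1
#'
#' Volumes are written as float32 NIfTI-1 with the voxel size recorded in
#' the header; integer label volumes should be written with
#' `datatype = "int32"`.
#'
#' @param x 3D or 4D numeric array (or a vector with a `grid_dim`
#'   attribute).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_mm Isotropic voxel size in mm (default 1.5).
#' @param datatype NIfTI datatype (default `"float"`).
#' @export
write_volume <- function(x, path, voxel_mm = 1.5, datatype = "float") {
  if (!is.array(x)) {
    gd <- attr(x, "grid_dim")
    if (is.null(gd)) stop("x must be an array or carry a grid_dim attribute")
    x <- array(x, dim = gd)
  }
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- rep(voxel_mm, min(3, length(dim(x))))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path Path to a NIfTI file.
#' @return Numeric array.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write nuisance traces as TSV
#' @param nuisance Volumes x 17 matrix (e.g. `run$nuisance`).
#' @param path Output path.
#' @export
write_nuisance_tsv <- function(nuisance, path) {
  utils::write.table(as.data.frame(nuisance), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read nuisance traces from TSV
#' @param path Path written by [write_nuisance_tsv()].
#' @return Numeric matrix.
#' @export
read_nuisance_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
}
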
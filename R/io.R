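#' Read / write volumes as NIfTI
#'
#' Thin wrappers around the NIfTI-1 reader/writer: 3D label or statistic
#' volumes and 4D grids, with the TR recorded in the header's temporal
#' pixdim for 4D data.
#'
#' @param x 3D/4D numeric array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tr repetition time in seconds for 4D data (optional).
#' @param voxelMm isotropic voxel size, mm.
#' @return `writeVolume` returns `path` invisibly; `readVolume` a plain
#'   array with attributes `tr` and `voxelMm` when present.
#' @export
writeVolume <- function(x, path, tr = NULL, voxelMm = 3) {
  nd <- length(dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(rep(voxelMm, 3), if (nd == 4) tr %||% 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  attr(out, "voxelMm") <- pd[1]
  if (length(dim(out)) == 4 && length(pd) >= 4) attr(out, "tr") <- pd[4]
  out
}

#' Read / write tabular artifacts as TSV
#'
#' The pipeline's exchange format for series, matrices and tables: plain
#' tab-separated text, full precision, no row names (matrices keep their
#' column header).
#'
#' @param x data.frame or matrix.
#' @param path file path.
#' @return `writeTsv` returns `path` invisibly; `readTsv` a data.frame,
#'   `readMatrixTsv` a numeric matrix.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname writeTsv
#' @export
readMatrixTsv <- function(path) {
  as.matrix(readTsv(path))
}
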
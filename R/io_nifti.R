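#' Read and write histology blocks as NIfTI
#'
#' Blocks are stored as NIfTI-1 volumes with anisotropic voxel dimensions
#' (res, res, spacing) and an RAS affine placing the block at its world
#' origin, so that a write/read round trip preserves both the binary data
#' and the registration. Region label volumes use the same geometry.
#'
#' @param block a \code{\link{histology_block}}.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{read_histology_block}: a \code{histology_block};
#'   \code{write_histology_block}: \code{path}, invisibly.
#' @export
write_histology_block <- function(block, path) {
  stopifnot(inherits(block, "histology_block"))
  res <- block$in_plane_res_mm; sp <- block$slice_spacing_mm
  # voxel (1,1,1) center in world coords (NIfTI voxel (0,0,0))
  c0 <- block$origin_mm + c(0.5 * res, 0.5 * res, 0)
  aff <- rbind(cbind(diag(c(res, res, sp)), c0), c(0, 0, 0, 1))
  img <- RNifti::asNifti(block$data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_histology_block
#' @export
read_histology_block <- function(path) {
  if (!file.exists(path)) stop("read_histology_block: no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  res <- aff[1, 1]; sp <- aff[3, 3]
  if (abs(aff[2, 2] - res) > 1e-6)
    stop("read_histology_block: non-square in-plane pixels")
  c0 <- aff[1:3, 4]
  origin <- c(c0[1] - 0.5 * res, c0[2] - 0.5 * res, c0[3])
  histology_block(array(as.integer(img > 0), dim = dim(img)),
                  in_plane_res_mm = res, slice_spacing_mm = sp,
                  origin_mm = origin)
}
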
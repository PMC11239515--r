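# Dense-displacement bilinear warper. Convention: out(p) = img(p + u(p)),
# u in voxels, sampling positions clamped to the image border. The operator
# is differentiable in both arguments (analytic adjoints in C++), which is
# what lets the registration network train without supervision.

#' Warp a 2D slice by a dense displacement field
#'
#' Evaluates `out(p) = image(p + u(p))` with bilinear interpolation at
#' non-integer sampling positions; positions falling outside the grid are
#' clamped to the border (edge clamp, so no zeros are injected next to
#' cord tissue).
#'
#' @param image 2D numeric matrix (nx, ny)
#' @param field displacement field: numeric array (nx, ny, 2); component 1
#'   is the displacement along the first (x) axis, component 2 along the
#'   second (y) axis, both in voxels
#' @return the warped matrix, same shape as `image`
#' @export
warpSlice <- function(image, field) {
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  fd <- dim(field)
  if (length(fd) != 3L || fd[3] != 2L || any(fd[1:2] != dim(image)))
    stop("field must be an (nx, ny, 2) array matching the image shape")
  if (any(!is.finite(field))) stop("field contains non-finite values")
  img3 <- array(image, c(dim(image), 1L))
  f4 <- array(field, c(fd, 1L))
  out <- .warpFwd(img3, f4)
  matrix(out, dim(image)[1], dim(image)[2])
}

# Batched warp: img (H, W, N), field (H, W, 2, N).
warpBatch <- function(img, field) .warpFwd(img, field)

#' Gradients of a warp
#'
#' Backpropagates an upstream gradient through [warpSlice()]: returns the
#' gradient of the scalar objective with respect to the input image and to
#' the displacement field. Field gradients are zero wherever the sampling
#' position was border-clamped (the output there is insensitive to the
#' field).
#'
#' @param image,field as in [warpSlice()]
#' @param gout upstream gradient, same shape as the warped output
#' @return list with `gimage` (matrix) and `gfield` ((nx, ny, 2) array)
#' @export
warpSliceGrad <- function(image, field, gout) {
  img3 <- array(image, c(dim(image), 1L))
  f4 <- array(field, c(dim(field), 1L))
  g3 <- array(gout, c(dim(image), 1L))
  res <- .warpBwd(img3, f4, g3)
  list(gimage = matrix(res$gimg, nrow(image), ncol(image)),
       gfield = array(res$gfield, dim(field)))
}

warpBatchGrad <- function(img, field, gout) .warpBwd(img, field, gout)

#' Export a displacement field as a 2-channel NIfTI image
#' @param field (nx, ny, 2) array
#' @param path output path
#' @return invisibly, the path
#' @export
writeFieldNifti <- function(field, path) {
  arr <- array(field, c(dim(field)[1:2], 1L, 2L))
  writeVolumeSeries(volumeSeries(arr, voxelSize = c(1, 1, 1)), path)
}
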
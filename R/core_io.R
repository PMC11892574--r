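#' Voxel grid geometry
#'
#' A `voxel_grid` ties the array dimensions of a volume to scanner space:
#' the shape (voxels per axis), the voxel edge lengths in mm, and the 4x4
#' voxel-to-world affine. Voxel indices are 0-based triples in array axis
#' order internally to the affine ("voxel (0,0,0) maps to the affine's
#' translation column"); world coordinates are obtained only through the
#' affine.
#'
#' @param shape integer triple, voxels per axis (each >= 1).
#' @param voxel_size numeric triple, mm (each > 0). Ignored when `affine`
#'   is supplied (then derived from the affine columns).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be 3 positive integers")
  if (is.null(affine)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0))
      stop("voxel_size must be 3 positive lengths in mm")
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- unclass(affine)[1:4, 1:4]
    attributes(affine) <- list(dim = c(4L, 4L))
    if (any(!is.finite(affine))) stop("affine must be finite")
    if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d, voxel %.3gx%.3gx%.3g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

new_volume <- function(values, grid, class, extra = list()) {
  stopifnot(inherits(grid, "voxel_grid"))
  structure(c(list(values = values, grid = grid), extra), class = class)
}

#' Typed volumes on a voxel grid
#'
#' Constructors for the three volume types the pipeline consumes: binary
#' masks (tumor, white matter), scalar parametric maps (MD, FA, MK, ... in
#' map-dependent units) and diffusion-tensor fields. Tensor components are
#' stored lower-triangular-by-row: `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`, in
#' mm^2/s. Use `tensor_order = "diagonal_first"` in [read_volume()] for
#' files storing `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param values logical/numeric 3-D array matching `grid$shape`
#'   (`binary_mask`, `scalar_map`), or a 4-D array with 6 components on the
#'   fourth axis (`tensor_field`).
#' @param grid a [voxel_grid()].
#' @param name map label, e.g. one of MD, FA, MK, AK, RK, KA, AWF, AxEAD,
#'   AxIAD, RadEAD, RadIAD, TORT, or "other".
#' @return An object of class `binary_mask`, `scalar_map` or `tensor_field`.
#' @export
binary_mask <- function(values, grid) {
  values <- array(values != 0 & !is.na(values), dim = dim(values))
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("mask shape does not match grid")
  new_volume(values, grid, c("binary_mask", "volume"))
}

#' @rdname binary_mask
#' @export
scalar_map <- function(values, grid, name = "other") {
  values <- array(as.numeric(values), dim = dim(values))
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("map shape does not match grid")
  new_volume(values, grid, c("scalar_map", "volume"),
             extra = list(name = as.character(name)))
}

#' @rdname binary_mask
#' @export
tensor_field <- function(values, grid) {
  d <- dim(values)
  if (length(d) != 4L || d[4] != 6L)
    stop("tensor field must be a 4-D array with 6 components on axis 4")
  if (!identical(d[1:3], as.integer(grid$shape)))
    stop("tensor shape does not match grid")
  storage.mode(values) <- "double"
  new_volume(values, grid, c("tensor_field", "volume"))
}

#' @export
print.volume <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("<%s %s>\n", kind, paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

grid_from_nifti <- function(img) {
  d <- dim(img)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  voxel_grid(d[1:3], affine = aff)
}

#' Read a NIfTI volume as a typed object
#'
#' Reads a `.nii`/`.nii.gz` file and returns the matching typed volume.
#' Masks are binarized (any nonzero voxel becomes `TRUE`); tensor volumes
#' must carry 6 components on the fourth axis.
#'
#' @param path path to a NIfTI file.
#' @param expected_kind one of `"mask"`, `"scalar"`, `"tensor"`.
#' @param tensor_order component order on disk: `"lower"` for
#'   `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)` (the internal convention) or
#'   `"diagonal_first"` for `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @return A [binary_mask()], [scalar_map()] or [tensor_field()].
#' @export
read_volume <- function(path, expected_kind = c("mask", "scalar", "tensor"),
                        tensor_order = c("lower", "diagonal_first")) {
  expected_kind <- match.arg(expected_kind)
  tensor_order <- match.arg(tensor_order)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))  # drop NIfTI metadata attributes
  nd <- length(dim(vals))
  grid <- grid_from_nifti(img)
  if (expected_kind == "tensor") {
    if (nd != 4L || dim(vals)[4] != 6L)
      stop(path, ": expected a 4-D tensor volume with 6 components, got ",
           paste(dim(vals), collapse = "x"))
    if (tensor_order == "diagonal_first")
      vals <- vals[, , , c(1L, 4L, 5L, 2L, 6L, 3L), drop = FALSE]
    return(tensor_field(vals, grid))
  }
  if (nd == 4L && dim(vals)[4] == 1L) {
    vals <- array(vals, dim = dim(vals)[1:3])
    nd <- 3L
  }
  if (nd != 3L)
    stop(path, ": expected a 3-D volume, got ",
         paste(dim(vals), collapse = "x"))
  if (expected_kind == "mask") binary_mask(vals, grid)
  else scalar_map(vals, grid, name = sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Write a typed volume to NIfTI
#'
#' Masks are written as uint8 \{0,1\}; scalar maps as float32 with NaN
#' marking excluded voxels. A read/write round trip preserves values to
#' float32 precision and the affine exactly.
#'
#' @param volume a [binary_mask()] or [scalar_map()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (inherits(volume, "binary_mask")) {
    vals <- array(as.integer(volume$values), dim = dim(volume$values))
    dt <- "uint8"
  } else if (inherits(volume, "scalar_map")) {
    vals <- volume$values
    dt <- "float"
  } else stop("write_volume handles binary_mask and scalar_map volumes")
  img <- RNifti::asNifti(vals)
  img <- RNifti::`sform<-`(img, structure(volume$grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Check that volumes share one grid
#'
#' The pipeline assumes all inputs are co-registered on one DKI grid; this
#' verifies shapes match exactly and affines agree element-wise within a
#' tolerance, and returns the shared grid. A mismatch signals
#' non-co-registered inputs and aborts the run.
#'
#' @param volumes non-empty list of typed volumes.
#' @param tol affine agreement tolerance per element, mm (default 0.01).
#' @return The shared [voxel_grid()].
#' @export
validate_grids <- function(volumes, tol = 0.01) {
  if (length(volumes) == 0L) stop("no volumes to validate")
  grids <- lapply(volumes, function(v) {
    if (inherits(v, "voxel_grid")) v else v$grid
  })
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(g$shape, ref$shape))
      stop("grid shape mismatch: ", paste(ref$shape, collapse = "x"), " vs ",
           paste(g$shape, collapse = "x"), " (inputs not co-registered?)")
    if (max(abs(g$affine - ref$affine)) > tol)
      stop("affine mismatch beyond ", tol,
           " mm (inputs not co-registered?)")
  }
  ref
}
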
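#' Volumetric CT containers
#'
#' A `voxel_grid` is the unit of all imaging I/O in this package: a 3D array
#' of Hounsfield units (HU) with voxel spacing in mm and a world origin.
#' Axis order is fixed as (z, y, x): `values[z, y, x]`, spacing and origin are
#' length-3 vectors in the same order, and the world coordinate of the centre
#' of voxel (i, j, k) (1-based array index) is `origin + (index - 1) * spacing`.
#'
#' @param values 3D numeric array of HU, dimension (z, y, x).
#' @param spacing numeric length-3, mm per voxel along (z, y, x); all > 0.
#' @param origin numeric length-3, world mm of the centre of voxel (1, 1, 1).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(-850, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array (z, y, x)", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite HU", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @param mask 3D array coercible to logical, same shape as its grid.
#' @param grid optional `voxel_grid` the mask is aligned to; used to copy
#'   spacing/origin and to check shapes.
#' @rdname voxel_grid
#' @export
nodule_mask <- function(mask, grid = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array (z, y, x)", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "voxel_grid"))
    if (!identical(dim(mask), dim(grid$values)))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match grid shape ",
           paste(dim(grid$values), collapse = "x"), call. = FALSE)
    spacing <- grid$spacing
    origin <- grid$origin
  }
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "nodule_mask")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %s mm, HU [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.nodule_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<nodule_mask> %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

# world-mm centroid of mask foreground
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "nodule_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid", call. = FALSE)
  ctr_idx <- colMeans(idx) - 1
  mask$origin + ctr_idx * mask$spacing
}

check_aligned <- function(voi, mask) {
  if (!identical(dim(voi$values), dim(mask$mask)))
    stop("VOI shape ", paste(dim(voi$values), collapse = "x"),
         " does not match mask shape ",
         paste(dim(mask$mask), collapse = "x"), call. = FALSE)
  if (max(abs(voi$spacing - mask$spacing)) > 1e-8)
    stop("VOI and mask spacing differ", call. = FALSE)
  invisible(TRUE)
}
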
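#' Label volume container
#'
#' A minimal carrier for co-registered label images: an integer-valued
#' 2D or 3D array plus physical voxel dimensions in mm and an optional
#' grid-to-world affine. Masks are {0,1}-valued; lobe label volumes take
#' values 0 (background) to 9 (the lobes of [bullseye_lobes()]).
#'
#' @param grid 2D or 3D numeric array.
#' @param voxel_dims numeric, one positive entry per grid axis (mm).
#' @param affine optional 4x4 grid-to-world transform; defaults to a
#'   scaling by `voxel_dims`.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(grid, voxel_dims = rep(1, length(dim(grid))), affine = NULL) {
  if (is.null(dim(grid))) stop("grid must be a 2D or 3D array")
  nd <- length(dim(grid))
  if (!nd %in% 2:3) stop("grid must be 2D or 3D")
  if (length(voxel_dims) != nd || any(voxel_dims <= 0))
    stop("voxel_dims must have one positive entry per axis")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[seq_len(nd)] <- voxel_dims
  }
  structure(list(grid = grid, voxel_dims = as.numeric(voxel_dims), affine = affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$grid), collapse = " x "),
      " voxels, dims ", paste(x$voxel_dims, collapse = " x "), " mm, ",
      sum(x$grid != 0), " non-zero\n", sep = "")
  invisible(x)
}

voxel_volume_mm3 <- function(voxel_dims) prod(voxel_dims)

check_same_shape <- function(...) {
  vols <- list(...)
  nms <- names(vols)
  shp <- lapply(vols, function(v) dim(v$grid))
  for (i in seq_along(vols)[-1]) {
    if (!identical(shp[[i]], shp[[1]]))
      stop("volume shape mismatch: '", nms[1], "' is ",
           paste(shp[[1]], collapse = "x"), " but '", nms[i], "' is ",
           paste(shp[[i]], collapse = "x"))
  }
  invisible(TRUE)
}
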
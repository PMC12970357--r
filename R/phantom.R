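#' Generate a geometric bullseye phantom
#'
#' Builds the label volumes the bullseye mapper consumes from a simple
#' concentric geometry: a white-matter annulus (2D) or spherical shell
#' (3D) between `inner_radius` and `outer_radius`, an inner "ventricle"
#' core and outer "cortex/CSF" complement, 9 angular lobe sectors, and a
#' WMH mask assembled from spherical lesion blobs. All radii and lesion
#' coordinates are in physical mm; voxel dimensions are honoured.
#'
#' @param geometry list with `inner_radius`, `outer_radius` (mm),
#'   `grid_shape` (length 2 or 3), `voxel_dims` (mm per axis).
#' @param lesion_spec either the string `"full"` (lesion covers the whole
#'   white-matter domain) or a list of lesions, each a list with `radius`
#'   (distance from centre, mm), `angle` (radians, in (-pi, pi]), optional
#'   `z` (mm, 3D only) and `size` (blob radius, mm).
#' @return list of [label_volume()]s: `wm_mask`, `inner_mask`,
#'   `outer_mask`, `lobe_labels`, `wmh_mask`.
#' @export
generate_phantom <- function(geometry, lesion_spec = list()) {
  a <- geometry$inner_radius; b <- geometry$outer_radius
  shape <- geometry$grid_shape
  vd <- geometry$voxel_dims %||% rep(1, length(shape))
  if (!(a > 0 && a < b)) stop("need 0 < inner_radius < outer_radius")
  nd <- length(shape)
  if (!nd %in% 2:3) stop("grid_shape must have length 2 or 3")
  half_extent <- (shape - 1) / 2 * vd
  if (b > min(half_extent)) stop("outer_radius does not fit in the grid")

  centre <- (shape + 1) / 2
  coords <- lapply(seq_len(nd), function(i) (seq_len(shape[i]) - centre[i]) * vd[i])
  if (nd == 2) {
    X <- outer(coords[[1]], coords[[2]], function(x, y) x)
    Y <- outer(coords[[1]], coords[[2]], function(x, y) y)
    Z <- array(0, dim = shape)
  } else {
    X <- array(rep(coords[[1]], times = shape[2] * shape[3]), dim = shape)
    Y <- array(rep(rep(coords[[2]], each = shape[1]), times = shape[3]), dim = shape)
    Z <- array(rep(coords[[3]], each = shape[1] * shape[2]), dim = shape)
  }
  r <- sqrt(X^2 + Y^2 + Z^2)

  wm    <- (r >= a & r <= b) * 1L
  inner <- (r < a) * 1L
  outer <- (r > b) * 1L

  theta <- atan2(Y, X)                       # (-pi, pi]
  sector <- pmin(9L, as.integer(floor((theta + pi) / (2 * pi / 9))) + 1L)
  lobes <- array(ifelse(wm == 1L, sector, 0L), dim = shape)

  wmh <- array(0L, dim = shape)
  if (identical(lesion_spec, "full")) {
    wmh <- wm
  } else {
    for (les in lesion_spec) {
      cx <- les$radius * cos(les$angle)
      cy <- les$radius * sin(les$angle)
      cz <- les$z %||% 0
      d <- sqrt((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2)
      wmh[d <= les$size & wm == 1L] <- 1L
    }
  }

  list(wm_mask    = label_volume(wm, vd),
       inner_mask = label_volume(inner, vd),
       outer_mask = label_volume(outer, vd),
       lobe_labels = label_volume(lobes, vd),
       wmh_mask   = label_volume(wmh, vd))
}
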
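# Laplace-equation depth field over the white-matter domain.
#
# The depth coordinate used to define bullseye layers is the harmonic
# potential u solving  laplacian(u) = 0  on the white-matter voxels with
# Dirichlet conditions u = 0 on the inner (ventricular) boundary and
# u = 1 on the outer (cortical) boundary, discretised with the standard
# 4-neighbour (2D) / 6-neighbour (3D) stencil. The solver is red-black
# successive over-relaxation (Jacobi available as a mode); the contract
# is the fixed point, not the sweep order.

# linear indices of the face neighbours of `idx` (NA off-grid)
neighbour_matrix <- function(idx, shape) {
  nd <- length(shape)
  coords <- arrayInd(idx, shape)
  strides <- cumprod(c(1, shape[-nd]))
  nb <- matrix(NA_integer_, length(idx), 2 * nd)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      col <- 2L * (ax - 1L) + (s + 3L) / 2L
      ok <- coords[, ax] + s >= 1L & coords[, ax] + s <= shape[ax]
      nb[ok, col] <- idx[ok] + s * strides[ax]
    }
  }
  nb
}

#' Solve the Laplace depth field on a white-matter domain
#'
#' @param wm,inner,outer [label_volume()] masks of identical shape: the
#'   white-matter domain and the inner (depth 0) and outer (depth 1)
#'   Dirichlet boundaries. The boundaries must be disjoint; domain voxels
#'   also marked as boundary are treated as boundary.
#' @param tol stop when the largest per-voxel update of a sweep falls
#'   below `tol`; `Inf` returns the initial field (boundaries set,
#'   0 iterations).
#' @param max_iter sweep budget; reaching it without convergence warns
#'   and flags the result rather than failing.
#' @param method `"sor"` (red-black successive over-relaxation, default)
#'   or `"jacobi"`.
#' @param omega SOR relaxation factor; default `2 / (1 + sin(pi / L))`
#'   with `L` the largest grid extent.
#' @return object of class `depth_field`: `values` (array; NA outside
#'   domain and boundaries), `domain` (logical array), `voxel_dims`,
#'   `iterations`, `residual`, `converged`, `n_islands` (domain voxels
#'   unreachable from either boundary, filled from their nearest
#'   assigned voxel and excluded from convergence).
#' @export
solve_laplace_depth <- function(wm, inner, outer, tol = 1e-6, max_iter = 20000L,
                                method = c("sor", "jacobi"), omega = NULL) {
  method <- match.arg(method)
  check_same_shape(wm = wm, inner = inner, outer = outer)
  shape <- dim(wm$grid)
  g_in <- inner$grid != 0; g_out <- outer$grid != 0; g_wm <- wm$grid != 0
  if (any(g_in & g_out)) stop("inner and outer boundaries overlap")
  domain <- g_wm & !g_in & !g_out
  if (!any(domain)) stop("white-matter domain is empty")

  v <- rep(NA_real_, prod(shape))
  v[g_in] <- 0; v[g_out] <- 1
  dom_idx <- which(domain)
  v[dom_idx] <- 0.5

  nb <- neighbour_matrix(dom_idx, shape)
  assigned <- g_in | g_out | domain
  nb[!is.na(nb) & !assigned[ifelse(is.na(nb), 1L, nb)]] <- NA_integer_
  counts <- rowSums(!is.na(nb))

  # reachability from the boundaries through the domain graph
  in_domain_pos <- match(nb, dom_idx)                # domain-local neighbour ids
  touches_boundary <- rowSums(matrix(!is.na(nb) & is.na(in_domain_pos),
                                     nrow(nb)), na.rm = TRUE) > 0
  reach <- touches_boundary
  repeat {
    nbr_reach <- matrix(reach[in_domain_pos], nrow(nb))
    new_reach <- reach | rowSums(nbr_reach, na.rm = TRUE) > 0
    if (identical(new_reach, reach)) break
    reach <- new_reach
  }
  n_islands <- sum(!reach)

  iterations <- 0L; residual <- NA_real_; converged <- TRUE
  if (is.finite(tol)) {
    active <- which(reach & counts > 0)
    nb_a <- nb[active, , drop = FALSE]
    counts_a <- counts[active]
    idx_a <- dom_idx[active]
    if (method == "jacobi") {
      for (it in seq_len(max_iter)) {
        s <- rowSums(matrix(v[nb_a], nrow(nb_a)), na.rm = TRUE)
        newv <- s / counts_a
        residual <- max(abs(newv - v[idx_a]))
        v[idx_a] <- newv
        iterations <- it
        if (residual < tol) break
      }
    } else {
      if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(shape)))
      parity <- rowSums(arrayInd(idx_a, shape)) %% 2L
      halves <- list(which(parity == 0L), which(parity == 1L))
      for (it in seq_len(max_iter)) {
        residual <- 0
        for (h in halves) {
          if (!length(h)) next
          s <- rowSums(matrix(v[nb_a[h, , drop = FALSE]], length(h)), na.rm = TRUE)
          newv <- (1 - omega) * v[idx_a[h]] + omega * s / counts_a[h]
          residual <- max(residual, max(abs(newv - v[idx_a[h]])))
          v[idx_a[h]] <- newv
        }
        iterations <- it
        if (residual < tol) break
      }
    }
    converged <- is.na(residual) || residual < tol
    if (!converged)
      warning("Laplace solver did not reach tol=", tol, " in ", max_iter,
              " iterations (residual ", signif(residual, 3), ")")
    # over-relaxation can overshoot the [0,1] bounds transiently; the
    # fixed point is bounded, so clip residual-level excursions
    v[idx_a] <- pmin(1, pmax(0, v[idx_a]))
  }

  if (n_islands > 0) {
    isl <- dom_idx[!reach]
    src <- which(assigned & !is.na(v))
    src <- setdiff(src, isl)
    vd <- wm$voxel_dims
    ic <- sweep(arrayInd(isl, shape), 2, vd, `*`)
    sc <- sweep(arrayInd(src, shape), 2, vd, `*`)
    for (j in seq_along(isl)) {
      d2 <- colSums((t(sc) - ic[j, ])^2)
      v[isl[j]] <- v[src[which.min(d2)]]
    }
  }

  structure(list(values = array(v, dim = shape), domain = domain,
                 voxel_dims = wm$voxel_dims, iterations = iterations,
                 residual = residual, converged = converged,
                 n_islands = n_islands),
            class = "depth_field")
}

#' Bin a depth field into equidistant layers
#'
#' Layer `l` covers depth in `((l-1)/n, l/n]`; depth exactly 0 joins
#' layer 1 (half-open, upper-inclusive bins), so layer 1 is the most
#' periventricular and layer `n` the most juxtacortical.
#'
#' @param depth a [solve_laplace_depth()] result.
#' @param n_layers number of layers (default 4).
#' @return [label_volume()] with layer labels on the domain, 0 elsewhere.
#' @export
bin_layers <- function(depth, n_layers = 4L) {
  stopifnot(inherits(depth, "depth_field"))
  if (n_layers < 1) stop("n_layers must be >= 1")
  lay <- array(0L, dim = dim(depth$values))
  d <- depth$values[depth$domain]
  # small slack keeps the upper-inclusive edge rule stable when the solver
  # returns a bin edge up to ~1e-9 above its exact value
  l <- as.integer(ceiling(d * n_layers - 1e-9))
  l[l < 1L] <- 1L
  l[l > n_layers] <- n_layers
  lay[depth$domain] <- l
  label_volume(lay, voxel_dims = depth$voxel_dims)
}
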
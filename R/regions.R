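#' Bullseye region naming
#'
#' The bullseye representation summarises WMH load in 36 cells: 9 lobar
#' sectors (left/right frontal, parietal, occipital, temporal, plus the
#' combined basal ganglia / thalamus / infratentorial region, "bgit")
#' crossed with 4 depth layers numbered 1 (periventricular) to 4
#' (juxtacortical).
#'
#' @return `bullseye_lobes()`: character vector of the 9 lobe labels, in
#'   the order used for integer lobe labels 1..9 in label volumes.
#'   `bullseye_regions()`: the 36 region column names, lobe-major, named
#'   `<lobe>_<layer>`.
#' @export
bullseye_lobes <- function() {
  c("frontal_l", "frontal_r", "parietal_l", "parietal_r",
    "occipital_l", "occipital_r", "temporal_l", "temporal_r", "bgit")
}

#' @rdname bullseye_lobes
#' @param n_layers number of depth layers (default 4).
#' @export
bullseye_regions <- function(n_layers = 4L) {
  as.vector(vapply(bullseye_lobes(), function(l) paste(l, seq_len(n_layers), sep = "_"),
                   character(n_layers)))
}

# lobe and layer index of each of the 36 regions, aligned with bullseye_regions()
region_lobe_index <- function(n_layers = 4L) rep(seq_len(9L), each = n_layers)
region_layer_index <- function(n_layers = 4L) rep(seq_len(n_layers), times = 9L)
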
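#' Discretized spine geometry
#'
#' A dendritic spine is represented as a 1-D chain of cylindrical segments of
#' uniform length `h`, ordered from the synaptic end to the dendritic end:
#' head segments first, then neck, then dendrite.
#'
#' @param n_head,n_neck,n_dend Segment counts per region.
#' @param h Segment length (m).
#' @param radius_head,radius_neck,radius_dend Cylinder radii (m) per region,
#'   either scalars or vectors of the region length.
#' @return An object of class `spine_geometry` with fields `a` (per-segment
#'   radius, m), `region` (factor head/neck/dendrite), `h`, `n_seg`,
#'   `area` (cross-section pi a^2, m^2), `volume` (pi a^2 h, m^3) and
#'   `membrane_area` (2 pi a h, m^2).
#' @examples
#' g <- spine_geometry(5, 5, 4, h = 0.1e-6,
#'                     radius_head = 79.8e-9, radius_neck = 35e-9,
#'                     radius_dend = 0.25e-6)
#' sum(g$volume[g$region == "head"])  # ~0.01 um^3
#' @export
spine_geometry <- function(n_head, n_neck, n_dend, h,
                           radius_head, radius_neck, radius_dend) {
  stopifnot(n_head >= 1, n_neck >= 0, n_dend >= 1, h > 0,
            all(radius_head > 0), all(radius_neck > 0), all(radius_dend > 0))
  a <- c(rep_len(radius_head, n_head),
         rep_len(radius_neck, n_neck),
         rep_len(radius_dend, n_dend))
  region <- factor(rep(c("head", "neck", "dendrite"),
                       times = c(n_head, n_neck, n_dend)),
                   levels = c("head", "neck", "dendrite"))
  structure(
    list(
      n_head = n_head, n_neck = n_neck, n_dend = n_dend,
      h = h, a = a, region = region,
      n_seg = length(a),
      area = pi * a^2,
      volume = pi * a^2 * h,
      membrane_area = 2 * pi * a * h,
      total_length = length(a) * h
    ),
    class = "spine_geometry"
  )
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat(sprintf(
    "<spine_geometry> %d segments (%d head / %d neck / %d dendrite), h = %.3g um, length = %.3g um\n",
    x$n_seg, x$n_head, x$n_neck, x$n_dend, x$h * 1e6, x$total_length * 1e6))
  cat(sprintf("  radii (um): head %.4g, neck %.4g, dendrite %.4g\n",
              x$a[1] * 1e6,
              if (x$n_neck > 0) x$a[x$n_head + 1] * 1e6 else NA,
              x$a[x$n_seg] * 1e6))
  invisible(x)
}
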
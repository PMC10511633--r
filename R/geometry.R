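# Spherocylinder geometry: the proto-cell is an ideal cylinder with
# spherical caps. Area must be a single-valued function of volume, so one
# shape degree of freedom is fixed by the chosen mode.

#' Cell surface area and shape from cytoplasmic volume
#'
#' In `fixed_aspect` mode the cylinder length is `aspect_ratio * radius` and
#' the radius grows with volume, so `A = 2 pi (c + 2) r^2` with
#' `V = pi (c + 4/3) r^3`: area scales as `V^(2/3)` and the
#' surface-to-volume ratio vanishes for large cells. In `fixed_radius` mode
#' the radius is pinned at `radius_um`; the cylinder length absorbs all
#' growth, and below the minimal spherocylinder volume the shape degenerates
#' continuously to a sphere of smaller radius.
#'
#' @param volume_um3 Cytoplasmic volume (um^3), > 0.
#' @param geometry A [geometry_params()] object.
#' @return A list with `area_um2`, `radius_um`, `length_um` (cylindrical
#'   part) and `regime` (`"spherocylinder"` or `"sphere"`).
#' @examples
#' g <- geometry_params(shape_mode = "fixed_radius", radius_um = 0.5)
#' cell_dimensions(1, g)$area_um2   # ~5.047 um^2
#' @export
cell_dimensions <- function(volume_um3, geometry) {
  if (!is.numeric(volume_um3) || is.na(volume_um3) || volume_um3 <= 0)
    .stop_cond("protocell_domain_error",
               "volume must be positive (got %s)", format(volume_um3))
  if (geometry$shape_mode == "fixed_aspect") {
    c_asp <- geometry$aspect_ratio
    r <- (volume_um3 / (pi * (c_asp + 4 / 3)))^(1 / 3)
    list(area_um2 = 2 * pi * (c_asp + 2) * r^2,
         radius_um = r, length_um = c_asp * r,
         regime = if (c_asp > 0) "spherocylinder" else "sphere")
  } else {
    r <- geometry$radius_um
    v_min <- (4 / 3) * pi * r^3
    if (volume_um3 >= v_min) {
      len <- (volume_um3 - v_min) / (pi * r^2)
      list(area_um2 = 2 * pi * r * len + 4 * pi * r^2,
           radius_um = r, length_um = len, regime = "spherocylinder")
    } else {
      rs <- (3 * volume_um3 / (4 * pi))^(1 / 3)
      list(area_um2 = 4 * pi * rs^2, radius_um = rs, length_um = 0,
           regime = "sphere")
    }
  }
}
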
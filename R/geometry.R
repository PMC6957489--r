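#' v-SNARE surface density on a nanodisc
#'
#' Copies per disc-face area: `copies / (pi * (diameter/2)^2)`. The
#' convention uses one disc face (not both leaflets), which is the one that
#' reproduces the printed densities from the stated copy numbers and
#' diameters (e.g. 3 copies on a 13 nm disc give 0.022 copies/nm^2).
#'
#' @param copies total protein copies per disc (>= 0).
#' @param diameter_nm disc diameter, nm (> 0).
#' @return density in copies per nm^2.
#' @export
nd_surface_density <- function(copies, diameter_nm) {
  if (any(diameter_nm <= 0)) stop("diameter_nm must be > 0")
  if (any(copies < 0)) stop("copies must be >= 0")
  copies / (pi * (diameter_nm / 2)^2)
}

#' Fractional lipid contribution of fused vesicles to a planar membrane
#'
#' Percentage of the planar-membrane (BLM) area contributed by the membranes
#' of `vesicles` fused spheres of diameter `vesicle_diameter_nm`:
#' `100 * (count * 4 pi r_ves^2) / (pi r_aperture^2)` (the bilayer leaflet
#' factors cancel between sphere and disc).
#'
#' @param vesicles number of fused vesicles (>= 0).
#' @param vesicle_diameter_nm vesicle diameter, nm (default 50).
#' @param aperture_diameter_um BLM aperture diameter, um (default 150).
#' @return percentage of the BLM lipid contributed by vesicles.
#' @export
blm_lipid_fraction <- function(vesicles, vesicle_diameter_nm = 50,
                               aperture_diameter_um = 150) {
  if (any(vesicles < 0)) stop("vesicles must be >= 0")
  if (any(vesicle_diameter_nm <= 0) || any(aperture_diameter_um <= 0)) {
    stop("diameters must be > 0")
  }
  r_ves <- vesicle_diameter_nm / 2
  r_ap <- aperture_diameter_um * 1000 / 2    # nm
  100 * vesicles * 4 * pi * r_ves^2 / (pi * r_ap^2)
}
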
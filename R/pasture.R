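#' Lichen winter pasture
#'
#' State of the shared lichen resource: standing biomass (kg/ha) on a fixed
#' area of lichen-dominated winter pasture, with logistic regrowth between
#' winters.  All district-level quantities in the package are normalized to
#' 1000 ha of winter lichen pasture.
#'
#' @param biomass standing lichen biomass, kg/ha, in \[0, K\].
#' @param params model parameters (area, growth rate, carrying capacity).
#' @return Object of class `lichen_pasture`.
#' @export
lichen_pasture <- function(biomass, params = default_params()) {
  K <- params$pasture$K
  if (!is.finite(biomass) || biomass < 0 || biomass > K)
    stop("lichen biomass must lie in [0, K] = [0, ", K, "]", call. = FALSE)
  structure(list(biomass = biomass, area_ha = params$pasture$area_ha,
                 r_growth = params$pasture$r_growth, K = K),
            class = "lichen_pasture")
}

#' Winter grazing offtake
#'
#' Removes the herd's total winter lichen offtake (consumption plus wastage,
#' kg over the whole winter and district) from the pasture, floored at zero.
#'
#' @param pasture a [lichen_pasture()].
#' @param total_removal kg of lichen removed over the winter (>= 0).
#' @return The pasture with post-grazing biomass.
#' @export
#' @examples
#' p <- lichen_pasture(1000)
#' graze(p, total_removal = 2e5)$biomass   # 1000 - 200 kg/ha
graze <- function(pasture, total_removal) {
  stopifnot(inherits(pasture, "lichen_pasture"))
  if (!is.finite(total_removal) || total_removal < 0)
    stop("total removal must be non-negative", call. = FALSE)
  pasture$biomass <- max(0, pasture$biomass - total_removal / pasture$area_ha)
  pasture
}

#' Annual lichen regrowth
#'
#' Applies one year of logistic growth to the post-grazing biomass:
#' `x' = x + r * x * (1 - x / K)`.  Growth vanishes at zero biomass and at
#' the carrying capacity, with its maximum at `K/2`.
#'
#' @param pasture a [lichen_pasture()].
#' @return The pasture with next-year biomass.
#' @export
grow <- function(pasture) {
  stopifnot(inherits(pasture, "lichen_pasture"))
  x <- pasture$biomass
  pasture$biomass <- x + pasture$r_growth * x * (1 - x / pasture$K)
  pasture
}
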
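#' SeDeM parameter identifiers in canonical axis order
#'
#' The twelve parameters of the SeDeM diagram in the fixed axis order used
#' throughout the package: bulk density (Da), tapped density (Dc),
#' interparticle porosity (Ie), Carr index (IC), cohesion index (Icd),
#' Hausner ratio (IH), angle of repose (alpha), powder flow time (t_flow),
#' loss on drying (HR), hygroscopicity (H), fines fraction (Pf) and
#' particle-size homogeneity index (Itheta).
#'
#' @return Character vector of the 12 parameter ids.
#' @export
sedem_parameters <- function() {
  c("Da", "Dc", "Ie", "IC", "Icd", "IH",
    "alpha", "t_flow", "HR", "H", "Pf", "Itheta")
}

#' Incidence-factor grouping of the twelve parameters
#'
#' The five incidence factors partition the parameters as
#' Dimensions \{Da, Dc\}; Compressibility \{Ie, IC, Icd\};
#' Flowability/Powder flow \{IH, alpha, t_flow\};
#' Lubricity/Stability \{HR, H\}; Lubricity/Dosage \{Pf, Itheta\}.
#'
#' @return Named list mapping incidence-factor name to parameter ids.
#' @export
sedem_incidence_groups <- function() {
  list(
    dimensions        = c("Da", "Dc"),
    compressibility   = c("Ie", "IC", "Icd"),
    flowability       = c("IH", "alpha", "t_flow"),
    lubricity_stability = c("HR", "H"),
    lubricity_dosage  = c("Pf", "Itheta")
  )
}

# Transform table: acceptable v range (unfavorable -> favorable direction) and
# the affine map sending v to the standardized radius. Radii are clamped to
# [0, 10] after mapping; the favorable end of the range maps to 10.
.sedem_transform_table <- function() {
  list(
    Da     = list(unit = "g/mL", lo = 0,  hi = 1,    fav = "high", map = function(v) 10 * v,          inv = function(r) r / 10),
    Dc     = list(unit = "g/mL", lo = 0,  hi = 1,    fav = "high", map = function(v) 10 * v,          inv = function(r) r / 10),
    Ie     = list(unit = "",     lo = 0,  hi = 1.2,  fav = "high", map = function(v) 10 * v / 1.2,    inv = function(r) 1.2 * r / 10),
    IC     = list(unit = "%",    lo = 0,  hi = 50,   fav = "high", map = function(v) v / 5,           inv = function(r) 5 * r),
    Icd    = list(unit = "N",    lo = 0,  hi = 200,  fav = "high", map = function(v) v / 20,          inv = function(r) 20 * r),
    IH     = list(unit = "",     lo = 3,  hi = 1,    fav = "low",  map = function(v) (30 - 10 * v) / 2, inv = function(r) (30 - 2 * r) / 10),
    alpha  = list(unit = "deg",  lo = 50, hi = 0,    fav = "low",  map = function(v) 10 - v / 5,      inv = function(r) 5 * (10 - r)),
    t_flow = list(unit = "s",    lo = 20, hi = 0,    fav = "low",  map = function(v) 10 - v / 2,      inv = function(r) 2 * (10 - r)),
    HR     = list(unit = "%",    lo = 10, hi = 0,    fav = "low",  map = function(v) 10 - v,          inv = function(r) 10 - r),
    H      = list(unit = "%",    lo = 20, hi = 0,    fav = "low",  map = function(v) 10 - v / 2,      inv = function(r) 2 * (10 - r)),
    Pf     = list(unit = "%",    lo = 50, hi = 0,    fav = "low",  map = function(v) 10 - v / 5,      inv = function(r) 5 * (10 - r)),
    Itheta = list(unit = "",     lo = 0,  hi = 0.02, fav = "high", map = function(v) 500 * v,         inv = function(r) r / 500)
  )
}

#' Transform specifications for the twelve SeDeM parameters
#'
#' Returns the standardization rules that map each measured parameter value v
#' onto a radius in \[0, 10\]: the acceptable numeric range (listed from the
#' unfavorable to the favorable end), the measurement unit, and the direction
#' in which larger raw values are favorable. The mapping sends the favorable
#' end of the range to radius 10 and the unfavorable end to 0; values mapping
#' outside \[0, 10\] are clamped.
#'
#' @return A data.frame with one row per parameter: `parameter`, `unit`,
#'   `range_unfavorable`, `range_favorable`, `favorable`.
#' @examples
#' sedem_transforms()
#' @export
sedem_transforms <- function() {
  tab <- .sedem_transform_table()
  data.frame(
    parameter = names(tab),
    unit = vapply(tab, `[[`, character(1), "unit"),
    range_unfavorable = vapply(tab, `[[`, numeric(1), "lo"),
    range_favorable = vapply(tab, `[[`, numeric(1), "hi"),
    favorable = vapply(tab, `[[`, character(1), "fav"),
    row.names = NULL
  )
}

#' Convert a parameter value to its SeDeM radius
#'
#' Applies the standardization rule for one parameter and clamps the result
#' to \[0, 10\]. The maps are affine, e.g. radius = 10 v for the densities,
#' v/5 for the Carr index, (30 - 10 v)/2 for the Hausner ratio and 500 v for
#' the homogeneity index.
#'
#' @param parameter One of [sedem_parameters()].
#' @param v Numeric parameter value(s) in the parameter's measurement unit.
#' @return Radius value(s) in \[0, 10\].
#' @examples
#' to_radius("Da", 0.584)     # 5.84
#' to_radius("IH", 1.2021)    # 8.9895
#' to_radius("Itheta", 0.0025) # 1.25
#' @export
to_radius <- function(parameter, v) {
  spec <- .sedem_transform_table()[[match.arg(parameter, sedem_parameters())]]
  stopifnot(is.numeric(v), all(is.finite(v)))
  pmin(10, pmax(0, spec$map(v)))
}

#' Invert a SeDeM radius back to the parameter value
#'
#' Inverse of [to_radius()] on the unclamped branch: a radius strictly inside
#' (0, 10) identifies the parameter value uniquely; at the clamp boundaries
#' the range endpoint is returned.
#'
#' @param parameter One of [sedem_parameters()].
#' @param r Radius value(s) in \[0, 10\].
#' @return Parameter value(s) in measurement units.
#' @export
from_radius <- function(parameter, r) {
  spec <- .sedem_transform_table()[[match.arg(parameter, sedem_parameters())]]
  stopifnot(is.numeric(r), all(is.finite(r)), all(r >= 0), all(r <= 10))
  spec$inv(r)
}

#' Round half away from zero
#'
#' Display/comparison rounding used for all reported SeDeM values: ties are
#' rounded away from zero (5.725 -> 5.73), unlike base `round()`'s
#' round-half-even. Internal computation always carries full precision;
#' rounding applies only when a value is reported or compared.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' sedem_round(4.525)  # 4.53
#' round(4.525, 2)     # 4.52 (half-even)
#' @export
sedem_round <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
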
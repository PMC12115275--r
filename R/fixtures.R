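# Reference fixtures: the published SeDeM characterization of carbamazepine
# and four disintegrant excipients, the 16 reference blend compositions, the
# measured blend/tablet outcomes, and the standardized lubricant mixture.
# Shipped as plain JSON under extdata.

.fixture_files <- c(
  material_profiles    = "material_profiles.json",
  formulation_profiles = "formulation_profiles.json",
  compositions         = "reference_compositions.json",
  blend_outcomes       = "blend_outcomes.json",
  tablet_qc            = "tablet_qc.json",
  lubricants           = "lubricant_mixture.json"
)

#' Available reference fixtures
#'
#' @return Character vector of fixture names usable with [sedem_fixture()].
#' @export
sedem_fixtures <- function() names(.fixture_files)

#' Load a reference fixture
#'
#' Bundled reference data for validating the pipeline end to end:
#' \describe{
#'   \item{material_profiles}{Named list of [sedem_profile()]s for
#'     carbamazepine (API) and the disintegrants L-HPC LH11, L-HPC NBD022,
#'     PARTECK ODT and PROSOLV ODT, each with the externally reported
#'     incidence means and IGC attached (`reported_incidences`,
#'     `reported_igc`; PARTECK additionally carries
#'     `backsolved_compressibility_radius`).}
#'   \item{formulation_profiles}{[sedem_profile()]s of the optimized blends
#'     F13 and F14, same shape.}
#'   \item{compositions}{data.frame of the 16 reference blend compositions
#'     (formulation, target compressibility radius, excipient, component
#'     percentages).}
#'   \item{blend_outcomes}{data.frame of measured tablet weight, hardness and
#'     diameter for F1--F16.}
#'   \item{tablet_qc}{data.frame of measured QC attributes (Hausner ratio,
#'     hardness, friability, disintegration, diameter) for F13--F16.}
#'   \item{lubricants}{Named vector: the standardized lubricant mixture.}
#' }
#'
#' @param name One of [sedem_fixtures()].
#' @return See above; profiles as `sedem_profile` lists, tables as
#'   data.frames.
#' @examples
#' profs <- sedem_fixture("material_profiles")
#' profs[["carbamazepine"]]
#' @export
sedem_fixture <- function(name) {
  name <- match.arg(name, sedem_fixtures())
  path <- system.file("extdata", .fixture_files[[name]], package = "sedem",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (name %in% c("material_profiles", "formulation_profiles")) {
    out <- lapply(names(raw), function(nm) {
      rec <- raw[[nm]]
      p <- sedem_profile(unlist(rec$radii), name = nm,
                         reported_incidences = unlist(rec$reported_incidences))
      p$reported_igc <- rec$reported_igc
      p$role <- rec$role
      p$excipient <- rec$excipient
      if (!is.null(rec$backsolved_compressibility_radius)) {
        p$backsolved_compressibility_radius <-
          rec$backsolved_compressibility_radius
      }
      p
    })
    names(out) <- names(raw)
    return(out)
  }
  if (name == "lubricants") return(unlist(raw))
  as.data.frame(raw)
}

#' Material profile for blend design from a fixture profile
#'
#' Convenience wrapper: extracts the compressibility incidence mean of a
#' `sedem_profile` (rounded to the 2-decimal reporting precision, as the
#' design equation conventionally consumes reported incidences) into a
#' [material_profile()].
#'
#' @param p A `sedem_profile` with a `role` field, or one plus `role`.
#' @param role `"api"` or `"excipient"` (defaults to the profile's own role).
#' @param use_reported Use the externally reported compressibility incidence
#'   when present (default TRUE); otherwise the mean of the Ie, IC, Icd
#'   radii.
#' @return A [material_profile()].
#' @export
as_material_profile <- function(p, role = NULL, use_reported = TRUE) {
  stopifnot(inherits(p, "sedem_profile"))
  if (is.null(role)) role <- if (!is.null(p$role)) p$role else "excipient"
  rc <- if (use_reported && !is.null(p$reported_incidences)) {
    p$reported_incidences[["compressibility"]]
  } else {
    sedem_round(p$incidence_means[["compressibility"]])
  }
  material_profile(p$name, role, rc)
}
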
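# Corrective-excipient formulation design: given the compressibility
# incidence radius of a deficient API (RP) and of a corrective excipient
# (RE), the percentage of excipient bringing a binary blend to a target
# compressibility radius R is CP = 100 - 100 (RE - R)/(RE - RP). The fixed
# 3.5% lubricant trio is layered on afterwards: API% = 100 - CP - 3.5.

#' Standardized lubricant mixture
#'
#' The fixed lubricant trio added to every direct-compression blend:
#' talc 2.36\%, colloidal silicon dioxide 0.14\%, magnesium stearate 1.00\%
#' (3.50\% total).
#'
#' @return Named numeric vector of percentages.
#' @export
standard_lubricants <- function() {
  c(talc = 2.36, colloidal_silicon_dioxide = 0.14, magnesium_stearate = 1.00)
}

#' Material compressibility profile for blend design
#'
#' A named material with its compressibility incidence radius (the mean of
#' its Ie, IC and Icd radii) and its role in the blend.
#'
#' @param name Material name.
#' @param role `"api"` or `"excipient"`.
#' @param compressibility_radius Radius in \[0, 10\].
#' @return A `material_profile` object.
#' @examples
#' material_profile("carbamazepine", "api", 2.92)
#' @export
material_profile <- function(name, role = c("api", "excipient"),
                             compressibility_radius) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(compressibility_radius),
            length(compressibility_radius) == 1)
  if (compressibility_radius < 0 || compressibility_radius > 10) {
    stop("compressibility_radius must lie in [0, 10]")
  }
  structure(list(name = name, role = role,
                 compressibility_radius = compressibility_radius),
            class = "material_profile")
}

#' Corrective-excipient percentage for a target blend radius
#'
#' CP = 100 - 100 (RE - R)/(RE - RP): the percentage of corrective excipient
#' that brings the API/excipient pair to compressibility incidence radius R,
#' assuming the blend radius interpolates linearly in composition. Requires
#' RP < RE (the excipient must be the better-compressing component) and
#' RP <= R <= RE for a feasible design.
#'
#' @param re Excipient compressibility incidence radius (RE).
#' @param r Target blend compressibility radius (R).
#' @param rp API compressibility incidence radius (RP).
#' @return CP in \[0, 100\] (percent of the binary pair).
#' @examples
#' corrective_excipient_pct(re = 5.90, r = 5.0, rp = 2.92)  # 69.7987 -> 69.80
#' @export
corrective_excipient_pct <- function(re, r, rp) {
  stopifnot(is.numeric(re), is.numeric(r), is.numeric(rp),
            length(re) == 1, length(r) == 1, length(rp) == 1)
  if (abs(re - rp) < 1e-12) {
    stop("degenerate pair: RE equals RP, no corrective leverage")
  }
  if (rp > re) {
    stop("excipient radius RE must exceed API radius RP to correct the deficiency")
  }
  if (r > re + 1e-12) {
    stop(sprintf(
      "infeasible target: R = %.4g exceeds the excipient radius RE = %.4g; no blend of this pair can reach it",
      r, re))
  }
  if (r < rp - 1e-12) {
    stop(sprintf(
      "out-of-range target: R = %.4g is below the API radius RP = %.4g; the pure API already exceeds it",
      r, rp))
  }
  100 - (re - r) / (re - rp) * 100
}

#' Predicted blend compressibility radius from composition
#'
#' Algebraic inverse of [corrective_excipient_pct()]: the composition-weighted
#' mean R = (CP x RE + (100 - CP) x RP)/100. Round-trips with the dose
#' equation to machine precision.
#'
#' @param cp_pct Percent excipient in the binary pair, in \[0, 100\].
#' @param re,rp Excipient and API compressibility incidence radii.
#' @return Predicted blend radius.
#' @export
blend_radius_predict <- function(cp_pct, re, rp) {
  stopifnot(is.numeric(cp_pct), all(cp_pct >= 0), all(cp_pct <= 100))
  (cp_pct * re + (100 - cp_pct) * rp) / 100
}

#' Build a full composition row for one blend design
#'
#' Layers the fixed 3.5\% lubricant trio onto the binary design:
#' API\% = 100 - CP - 3.50, and computes the tablet weight carrying a fixed
#' API dose, weight = dose / (API\%/100).
#'
#' @param api,excipient [material_profile()]s (or names).
#' @param cp_pct Corrective-excipient percentage from
#'   [corrective_excipient_pct()].
#' @param dose_mg API dose per tablet in mg (default 50).
#' @param lubricants Named percentages of the lubricant components
#'   (default [standard_lubricants()]).
#' @return A one-row data.frame: component percentages (summing to 100),
#'   `tablet_weight_mg`.
#' @examples
#' build_composition("carbamazepine", "L-HPC LH11", cp_pct = 19.46)
#' @export
build_composition <- function(api, excipient, cp_pct, dose_mg = 50,
                              lubricants = standard_lubricants()) {
  api_name <- if (inherits(api, "material_profile")) api$name else api
  exc_name <- if (inherits(excipient, "material_profile")) excipient$name else excipient
  stopifnot(is.numeric(cp_pct), length(cp_pct) == 1,
            is.numeric(dose_mg), length(dose_mg) == 1, dose_mg > 0,
            is.numeric(lubricants), !is.null(names(lubricants)))
  lub_total <- sum(lubricants)
  if (cp_pct < 0) stop("cp_pct must be >= 0")
  if (cp_pct > 100 - lub_total) {
    stop(sprintf("cp_pct = %.4g leaves no room for API plus the %.2f%% lubricants",
                 cp_pct, lub_total))
  }
  api_pct <- 100 - cp_pct - lub_total
  out <- data.frame(api = api_name, excipient = exc_name,
                    api_pct = api_pct, excipient_pct = cp_pct,
                    t(lubricants),
                    dose_mg = dose_mg,
                    tablet_weight_mg = dose_mg / (api_pct / 100))
  stopifnot(abs(api_pct + cp_pct + lub_total - 100) < 1e-9)
  out
}

#' Sweep target compressibility radii for an API/excipient pair
#'
#' Evaluates the corrective-excipient dose equation over a decreasing series
#' of target radii (default 5.0, 4.5, 4.0, 3.5) and builds the full
#' composition for each feasible target. Infeasible targets (R above the
#' excipient radius, or below the API radius) are flagged in the result, not
#' dropped.
#'
#' @param api,excipient [material_profile()]s.
#' @param targets Target blend radii.
#' @param dose_mg API dose per tablet (default 50 mg).
#' @param lubricants Named lubricant percentages.
#' @return A data.frame with one row per target: `target_r`, `feasible`,
#'   `reason` (NA when feasible), `cp_pct`, `api_pct`, lubricant columns and
#'   `tablet_weight_mg`.
#' @examples
#' api <- material_profile("carbamazepine", "api", 2.92)
#' exc <- material_profile("L-HPC LH11", "excipient", 5.90)
#' r_sweep(api, exc)
#' @export
r_sweep <- function(api, excipient, targets = c(5.0, 4.5, 4.0, 3.5),
                    dose_mg = 50, lubricants = standard_lubricants()) {
  stopifnot(inherits(api, "material_profile"),
            inherits(excipient, "material_profile"),
            is.numeric(targets), length(targets) >= 1)
  rp <- api$compressibility_radius
  re <- excipient$compressibility_radius
  rows <- lapply(targets, function(r) {
    cp <- tryCatch(corrective_excipient_pct(re, r, rp), error = identity)
    if (inherits(cp, "error")) {
      return(data.frame(target_r = r, feasible = FALSE,
                        reason = conditionMessage(cp), cp_pct = NA_real_,
                        api_pct = NA_real_, tablet_weight_mg = NA_real_))
    }
    comp <- build_composition(api, excipient, cp, dose_mg, lubricants)
    data.frame(target_r = r, feasible = TRUE, reason = NA_character_,
               cp_pct = cp, api_pct = comp$api_pct,
               tablet_weight_mg = comp$tablet_weight_mg)
  })
  out <- do.call(rbind, rows)
  attr(out, "api") <- api$name
  attr(out, "excipient") <- excipient$name
  out
}
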
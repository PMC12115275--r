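# Raw powder-characterization records and the computations producing the
# twelve SeDeM parameter values. Each constructor validates the physical
# invariants of the measurement; the compute functions are pure.

#' Graduated-cylinder density measurement
#'
#' One bulk/tapped density run: sample mass, initial (untapped) apparent
#' volume and the tapped-volume series recorded after fixed tap counts
#' (10, 500, 1250, optionally 2500).
#'
#' @param mass_g Sample mass in grams.
#' @param volume_initial_ml Initial apparent volume V0 in mL.
#' @param tap_volumes_ml Named numeric vector of apparent volumes after
#'   tapping; names are tap counts, e.g. `c("10" = 98, "500" = 96, "1250" = 95)`.
#' @return A `density_measurement` object.
#' @examples
#' density_measurement(100, 171.2, c("10" = 168, "500" = 143.5, "1250" = 142.5))
#' @export
density_measurement <- function(mass_g, volume_initial_ml, tap_volumes_ml) {
  stopifnot(is.numeric(mass_g), length(mass_g) == 1,
            is.numeric(volume_initial_ml), length(volume_initial_ml) == 1,
            is.numeric(tap_volumes_ml), length(tap_volumes_ml) >= 1)
  if (!isTRUE(mass_g > 0)) stop("invalid measurement: mass must be positive")
  if (!isTRUE(volume_initial_ml > 0)) {
    stop("invalid measurement: initial volume must be positive")
  }
  if (is.null(names(tap_volumes_ml)) || anyNA(suppressWarnings(as.integer(names(tap_volumes_ml))))) {
    stop("tap_volumes_ml must be named by integer tap counts")
  }
  counts <- as.integer(names(tap_volumes_ml))
  tap_volumes_ml <- tap_volumes_ml[order(counts)]
  counts <- sort(counts)
  if (any(tap_volumes_ml > volume_initial_ml + 1e-9)) {
    stop("invalid measurement: tapped volumes cannot exceed the initial volume")
  }
  if (is.unsorted(-tap_volumes_ml, strictly = FALSE)) {
    stop("invalid measurement: tapped volumes must be non-increasing with tap count")
  }
  structure(
    list(mass_g = mass_g, volume_initial_ml = volume_initial_ml,
         tap_volumes_ml = tap_volumes_ml, tap_counts = counts),
    class = "density_measurement"
  )
}

#' Angle-of-repose cone measurement
#'
#' Height of the powder cone formed under a standardized funnel and the four
#' base radii measured along perpendicular directions.
#'
#' @param height_cm Cone height h in cm (0 allowed: flat pile).
#' @param base_radii_cm Exactly four base radii in cm, each positive.
#' @return A `cone_measurement` object.
#' @export
cone_measurement <- function(height_cm, base_radii_cm) {
  stopifnot(is.numeric(height_cm), length(height_cm) == 1,
            is.numeric(base_radii_cm))
  if (!isTRUE(height_cm >= 0)) stop("invalid measurement: cone height must be >= 0")
  if (length(base_radii_cm) != 4 || any(base_radii_cm <= 0)) {
    stop("invalid measurement: exactly four positive base radii are required")
  }
  structure(list(height_cm = height_cm, base_radii_cm = base_radii_cm),
            class = "cone_measurement")
}

#' Powder flow-time measurement
#'
#' Stopwatch times for 100 g of powder to discharge through a standardized
#' funnel, in triplicate. A powder that does not flow at all is recorded with
#' `nonflow = TRUE` and no times; its flow radius clamps to 0.
#'
#' @param times_s Three flow times in seconds (omit when `nonflow`).
#' @param nonflow Logical; the powder did not flow through the funnel.
#' @return A `flow_measurement` object.
#' @export
flow_measurement <- function(times_s = numeric(), nonflow = FALSE) {
  stopifnot(is.numeric(times_s), is.logical(nonflow), length(nonflow) == 1)
  if (!nonflow && length(times_s) != 3) {
    stop("invalid measurement: three flow times are required unless nonflow")
  }
  if (any(times_s < 0)) stop("invalid measurement: flow times must be >= 0")
  structure(list(times_s = times_s, nonflow = nonflow), class = "flow_measurement")
}

#' Loss-on-drying / hygroscopicity weight record
#'
#' Sample weight as received (`wet_g`), after drying at 105 degrees C to
#' constant weight (`dry_g`), and after 24 h at 76\% relative humidity
#' (`humid_g`).
#'
#' @param wet_g,dry_g,humid_g Weights in grams; `dry_g <= wet_g` required.
#' @return A `moisture_record` object.
#' @export
moisture_record <- function(wet_g, dry_g, humid_g) {
  stopifnot(is.numeric(wet_g), is.numeric(dry_g), is.numeric(humid_g),
            length(wet_g) == 1, length(dry_g) == 1, length(humid_g) == 1)
  if (any(c(wet_g, dry_g, humid_g) <= 0)) {
    stop("invalid measurement: weights must be positive")
  }
  if (dry_g > wet_g + 1e-12) {
    stop("measurement-order error: dry weight exceeds wet weight")
  }
  structure(list(wet_g = wet_g, dry_g = dry_g, humid_g = humid_g),
            class = "moisture_record")
}

#' Sieve-stack particle-size analysis
#'
#' Percent of a 100 g sample retained on each sieve of a descending stack,
#' plus the pan (particles passing the finest sieve). Fractions are labelled
#' by their bounding apertures; the coarsest fraction is bounded above by
#' `top_bound_mm`.
#'
#' @param retained_pct Percent retained, ordered coarsest sieve first, pan
#'   last; length must be `length(apertures_mm) + 1`; must sum to 100 (0.01
#'   tolerance).
#' @param apertures_mm Descending sieve apertures in mm.
#' @param top_bound_mm Upper diameter bound of the coarsest fraction in mm.
#' @return A `sieve_analysis` object with fraction mean diameters (midpoints
#'   of the bounding apertures, in micrometers; pan midpoint of 0 and the
#'   finest aperture).
#' @examples
#' sieve_analysis(c(10, 20, 40, 19, 11))
#' @export
sieve_analysis <- function(retained_pct,
                           apertures_mm = c(0.355, 0.212, 0.100, 0.05),
                           top_bound_mm = 0.500) {
  stopifnot(is.numeric(retained_pct), is.numeric(apertures_mm),
            is.numeric(top_bound_mm), length(top_bound_mm) == 1)
  if (is.unsorted(rev(apertures_mm), strictly = TRUE)) {
    stop("apertures_mm must be strictly descending")
  }
  if (top_bound_mm <= apertures_mm[1]) {
    stop("top_bound_mm must exceed the coarsest aperture")
  }
  if (length(retained_pct) != length(apertures_mm) + 1) {
    stop("retained_pct must have one entry per sieve plus the pan")
  }
  if (any(retained_pct < 0)) stop("retained percentages must be >= 0")
  if (abs(sum(retained_pct) - 100) > 0.01) {
    stop("normalization error: retained percentages must sum to 100 (+/- 0.01)")
  }
  # Fraction bounds coarsest -> pan, in micrometers.
  upper_um <- c(top_bound_mm, apertures_mm) * 1000
  lower_um <- c(apertures_mm, 0) * 1000
  structure(
    list(retained_pct = retained_pct, apertures_mm = apertures_mm,
         top_bound_mm = top_bound_mm,
         mean_diameter_um = (upper_um + lower_um) / 2),
    class = "sieve_analysis"
  )
}

#' Tablet breaking-force sample for the cohesion index
#'
#' Breaking forces of tablets compressed from the raw powder (or, when the
#' powder cannot be compressed alone, from the powder plus the standardized
#' 3.5\% lubricant mixture).
#'
#' @param breaking_forces_n Per-tablet breaking forces in newtons.
#' @param lubricated Logical; the standardized lubricant mixture was added.
#' @return A `hardness_sample` object.
#' @export
hardness_sample <- function(breaking_forces_n, lubricated = FALSE) {
  stopifnot(is.numeric(breaking_forces_n), is.logical(lubricated))
  if (length(breaking_forces_n) == 0) stop("no-data error: empty force list")
  if (any(breaking_forces_n < 0)) stop("breaking forces must be >= 0")
  structure(list(breaking_forces_n = breaking_forces_n, lubricated = lubricated),
            class = "hardness_sample")
}

#' Bulk (poured) density
#'
#' Da = m / V0: sample mass over the untapped apparent volume.
#'
#' @param d A [density_measurement()].
#' @return Bulk density in g/mL.
#' @examples
#' bulk_density(density_measurement(58.4, 100, c("1250" = 85)))  # 0.584
#' @export
bulk_density <- function(d) {
  stopifnot(inherits(d, "density_measurement"))
  d$mass_g / d$volume_initial_ml
}

#' Tapped (compacted) density
#'
#' Dc = m / V1250, or m / V2500 when the volume settled between 500 and 1250
#' taps by more than 2 mL (the series must then have been extended to 2500
#' taps). The volume actually used is attached as attribute `volume_used`.
#'
#' @param d A [density_measurement()] containing tap counts 500 and 1250 (and
#'   2500 when the 2 mL rule triggers).
#' @return Tapped density in g/mL with attribute `volume_used`
#'   (`"V1250"` or `"V2500"`).
#' @examples
#' m <- density_measurement(70.2, 110, c("10" = 107, "500" = 101, "1250" = 100))
#' tapped_density(m)  # 0.702, volume_used "V1250"
#' @export
tapped_density <- function(d) {
  stopifnot(inherits(d, "density_measurement"))
  v <- d$tap_volumes_ml
  counts <- d$tap_counts
  need <- c(500, 1250)
  if (!all(need %in% counts)) {
    stop("incomplete-series error: tap counts 500 and 1250 are required")
  }
  v500 <- v[match(500, counts)]
  v1250 <- v[match(1250, counts)]
  if (abs(v500 - v1250) > 2) {
    if (!2500 %in% counts) {
      stop("rule-violation error: |V500 - V1250| > 2 mL but no 2500-tap volume recorded")
    }
    dc <- d$mass_g / v[match(2500, counts)]
    attr(dc, "volume_used") <- "V2500"
  } else {
    dc <- d$mass_g / v1250
    attr(dc, "volume_used") <- "V1250"
  }
  dc
}

#' Density-derived compressibility and flow indices
#'
#' Interparticle porosity Ie = (Dc - Da) / (Dc * Da), Carr index
#' IC = 100 (Dc - Da) / Dc, Hausner ratio IH = Dc / Da.
#'
#' @param da Bulk density (g/mL), positive.
#' @param dc Tapped density (g/mL), `dc >= da`.
#' @return Named list with `Ie`, `IC` (percent), `IH`.
#' @examples
#' density_derived(0.584, 0.702)
#' @export
density_derived <- function(da, dc) {
  stopifnot(is.numeric(da), is.numeric(dc), length(da) == 1, length(dc) == 1)
  if (da <= 0 || dc <= 0) stop("densities must be positive")
  if (da > dc + 1e-12) {
    stop("inconsistent-densities error: bulk density exceeds tapped density")
  }
  list(Ie = (dc - da) / (dc * da),
       IC = 100 * (dc - da) / dc,
       IH = dc / da)
}

#' Angle of repose
#'
#' alpha = atan(h / r) in degrees, with r the mean of the four base radii.
#'
#' @param c A [cone_measurement()].
#' @return Angle in degrees.
#' @examples
#' angle_of_repose(cone_measurement(3, c(5, 5, 5, 5)))  # 30.96
#' @export
angle_of_repose <- function(c) {
  stopifnot(inherits(c, "cone_measurement"))
  r <- mean(c$base_radii_cm)
  if (r <= 0) stop("degenerate-cone error: zero mean base radius")
  atan(c$height_cm / r) * 180 / pi
}

#' Powder flow time
#'
#' Mean of the three stopwatch times (seconds per 100 g). A non-flowing
#' powder returns `Inf`, which clamps to flow radius 0.
#'
#' @param f A [flow_measurement()].
#' @return Mean flow time in seconds (`Inf` when the powder did not flow).
#' @export
flow_time <- function(f) {
  stopifnot(inherits(f, "flow_measurement"))
  if (f$nonflow) return(Inf)
  mean(f$times_s)
}

#' Relative homogeneity index from a sieve analysis
#'
#' Identifies the majority fraction Fm and evaluates
#' Itheta = Fm / (100 + sum over all other fractions of |dm - d_i| F_i),
#' with fraction mean diameters d in micrometers (midpoints of the bounding
#' apertures; pan midpoint of 0 and the finest aperture). A tie for the
#' majority fraction is resolved to the coarser fraction with a warning.
#'
#' @param s A [sieve_analysis()].
#' @return Homogeneity index in (0, 1], with attribute `majority_fraction`
#'   (index into the fractions, coarsest first).
#' @examples
#' homogeneity_index(sieve_analysis(c(0, 0, 100, 0, 0)))  # 1
#' @export
homogeneity_index <- function(s) {
  stopifnot(inherits(s, "sieve_analysis"))
  f <- s$retained_pct
  d <- s$mean_diameter_um
  mx <- max(f)
  ties <- which(abs(f - mx) < 1e-12)
  if (length(ties) > 1) {
    warning("tie for the majority sieve fraction; using the coarser fraction")
  }
  m <- ties[1]  # fractions ordered coarsest first
  denom <- 100 + sum(abs(d[m] - d[-m]) * f[-m])
  structure(f[m] / denom, majority_fraction = m)
}

#' Loss on drying and hygroscopicity
#'
#' HR = 100 (wet - dry) / wet (percent weight lost at 105 degrees C);
#' H = 100 (humid - wet) / wet (percent weight gained at 76\% RH / 24 h).
#' A net weight loss under humidification is floored to H = 0 with a warning,
#' since the standardization range presumes non-negative uptake.
#'
#' @param m A [moisture_record()].
#' @return Named list with `HR` and `H`, both in percent.
#' @export
moisture_params <- function(m) {
  stopifnot(inherits(m, "moisture_record"))
  hr <- 100 * (m$wet_g - m$dry_g) / m$wet_g
  h <- 100 * (m$humid_g - m$wet_g) / m$wet_g
  if (h < 0) {
    warning("negative hygroscopicity (weight loss at 76% RH); floored to 0")
    h <- 0
  }
  list(HR = hr, H = h)
}

#' Cohesion index
#'
#' Mean tablet breaking force in newtons; the lubrication flag is carried as
#' attribute `lubricated`.
#'
#' @param h A [hardness_sample()].
#' @return Mean breaking force (N) with attribute `lubricated`.
#' @export
cohesion_index <- function(h) {
  stopifnot(inherits(h, "hardness_sample"))
  structure(mean(h$breaking_forces_n), lubricated = h$lubricated)
}

#' Fines fraction (particles below 50 micrometers)
#'
#' The pan percentage of the sieve analysis: particles passing the 0.05 mm
#' sieve.
#'
#' @param s A [sieve_analysis()].
#' @return Percent of sample below the finest sieve.
#' @export
fines_fraction <- function(s) {
  stopifnot(inherits(s, "sieve_analysis"))
  s$retained_pct[length(s$retained_pct)]
}
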
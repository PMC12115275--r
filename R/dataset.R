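# PowderDataset: the bundle of raw records for one material, and the
# ParameterSet it yields.

#' Bundle raw measurement records for one material
#'
#' Collects one of each record kind needed to characterize a powder. All six
#' records are required to compute a complete parameter set; a dataset with
#' some records missing is valid but yields NA for the affected parameters.
#'
#' @param name Material name.
#' @param density A [density_measurement()].
#' @param cone A [cone_measurement()].
#' @param flow A [flow_measurement()].
#' @param moisture A [moisture_record()].
#' @param sieve A [sieve_analysis()].
#' @param hardness A [hardness_sample()].
#' @return A `powder_dataset` object.
#' @export
powder_dataset <- function(name, density = NULL, cone = NULL, flow = NULL,
                           moisture = NULL, sieve = NULL, hardness = NULL) {
  chk <- function(x, cls) is.null(x) || inherits(x, cls)
  stopifnot(is.character(name), length(name) == 1,
            chk(density, "density_measurement"), chk(cone, "cone_measurement"),
            chk(flow, "flow_measurement"), chk(moisture, "moisture_record"),
            chk(sieve, "sieve_analysis"), chk(hardness, "hardness_sample"))
  structure(list(name = name, density = density, cone = cone, flow = flow,
                 moisture = moisture, sieve = sieve, hardness = hardness),
            class = "powder_dataset")
}

#' @export
print.powder_dataset <- function(x, ...) {
  kinds <- c("density", "cone", "flow", "moisture", "sieve", "hardness")
  have <- kinds[!vapply(x[kinds], is.null, logical(1))]
  cat("powder_dataset:", x$name, "\n  records:",
      if (length(have)) paste(have, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' The twelve experimental SeDeM parameter values
#'
#' Container for the measured parameter values v, in measurement units, in the
#' canonical order of [sedem_parameters()]. Values may be NA where a record
#' was unavailable. Validates `Da <= Dc` and `IH >= 1` when both densities
#' are present.
#'
#' @param values Named numeric vector (or list) covering
#'   [sedem_parameters()].
#' @param provenance Optional named list of bookkeeping (which tapped volume
#'   was used, lubrication flag, ...).
#' @return A `parameter_set` object: named numeric vector of length 12 with
#'   attribute `provenance`.
#' @export
parameter_set <- function(values, provenance = list()) {
  values <- unlist(values)
  ids <- sedem_parameters()
  if (!all(ids %in% names(values))) {
    stop("parameter_set requires values named by all of: ",
         paste(ids, collapse = ", "))
  }
  v <- as.numeric(values[ids])
  names(v) <- ids
  if (any(v < 0, na.rm = TRUE)) stop("parameter values must be >= 0")
  if (!anyNA(v[c("Da", "Dc")]) && v["Da"] > v["Dc"] + 1e-12) {
    stop("inconsistent-densities error: Da exceeds Dc")
  }
  if (!is.na(v["IH"]) && v["IH"] < 1 - 1e-12) {
    stop("Hausner ratio below 1 is inconsistent with Da <= Dc")
  }
  structure(v, provenance = provenance, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  tab <- sedem_transforms()
  cat("SeDeM parameter set\n")
  df <- data.frame(parameter = tab$parameter, unit = tab$unit,
                   value = sedem_round(unclass(x), 4), row.names = NULL)
  print(df)
  invisible(x)
}

#' Compute the SeDeM parameter set from raw measurements
#'
#' Runs all per-record computations on one [powder_dataset()]: densities and
#' the derived Carr index, Hausner ratio and interparticle porosity, angle of
#' repose, mean flow time, loss on drying, hygroscopicity, cohesion index,
#' fines fraction and homogeneity index.
#'
#' Given several replicate datasets (a list), parameters are computed per
#' replicate and averaged before any radius transformation.
#'
#' @param x A `powder_dataset` or a list of replicate `powder_dataset`s.
#' @return A [parameter_set()] with provenance recording the tapped-volume
#'   rule and lubrication flag.
#' @examples
#' d <- powder_dataset("demo",
#'   density = density_measurement(100, 171.2,
#'     c("10" = 168, "500" = 143.5, "1250" = 142.5)),
#'   cone = cone_measurement(2.5, c(5, 5, 5, 5)),
#'   flow = flow_measurement(c(3.6, 3.7, 3.7)),
#'   moisture = moisture_record(100, 99.67, 100.10),
#'   sieve = sieve_analysis(c(15, 25, 30, 19, 11)),
#'   hardness = hardness_sample(c(58, 60, 62)))
#' compute_parameters(d)
#' @export
compute_parameters <- function(x) {
  if (is.list(x) && !inherits(x, "powder_dataset")) {
    stopifnot(length(x) >= 1,
              all(vapply(x, inherits, logical(1), "powder_dataset")))
    sets <- lapply(x, compute_parameters)
    m <- do.call(rbind, lapply(sets, unclass))
    return(parameter_set(colMeans(m),
                         provenance = list(replicates = length(sets))))
  }
  stopifnot(inherits(x, "powder_dataset"))
  v <- stats::setNames(rep(NA_real_, 12), sedem_parameters())
  prov <- list()
  if (!is.null(x$density)) {
    v["Da"] <- bulk_density(x$density)
    dc <- tapped_density(x$density)
    v["Dc"] <- as.numeric(dc)
    prov$tapped_volume_used <- attr(dc, "volume_used")
    der <- density_derived(v[["Da"]], v[["Dc"]])
    v["Ie"] <- der$Ie; v["IC"] <- der$IC; v["IH"] <- der$IH
  }
  if (!is.null(x$cone)) v["alpha"] <- angle_of_repose(x$cone)
  if (!is.null(x$flow)) v["t_flow"] <- flow_time(x$flow)
  if (!is.null(x$moisture)) {
    mo <- moisture_params(x$moisture)
    v["HR"] <- mo$HR; v["H"] <- mo$H
  }
  if (!is.null(x$sieve)) {
    v["Pf"] <- fines_fraction(x$sieve)
    v["Itheta"] <- as.numeric(homogeneity_index(x$sieve))
  }
  if (!is.null(x$hardness)) {
    icd <- cohesion_index(x$hardness)
    v["Icd"] <- as.numeric(icd)
    prov$lubricated <- attr(icd, "lubricated")
  }
  # Inf mean flow time (nonflow) is carried as the unfavorable range end so
  # the parameter_set stays finite; the radius clamps to 0 either way.
  if (is.infinite(v["t_flow"])) {
    v["t_flow"] <- 20
    prov$nonflow <- TRUE
  }
  parameter_set(v, provenance = prov)
}
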
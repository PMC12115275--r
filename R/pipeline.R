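# Measurement-file parsing, JSON serialization and the end-to-end pipeline:
# characterize -> profile -> design -> report.
#
# Measurement CSV dialect (UTF-8, comma-separated, header row mandatory):
# long format with columns `record_kind`, `field`, `value` and optionally
# `material`. Recognized kinds/fields:
#   density : mass_g, volume_initial_ml, tap10, tap500, tap1250 [, tap2500]
#   cone    : height_cm, radius1..radius4
#   flow    : time1, time2, time3 | nonflow (0/1)
#   moisture: wet_g, dry_g, humid_g
#   sieve   : retained_<aperture-mm> (descending), retained_pan
#             [, top_bound_mm]
#   hardness: force1..forceN [, lubricated (0/1)]

#' Parse a measurement CSV into a powder dataset
#'
#' Reads the long-format measurement dialect documented in this package (see
#' the package vignette): one row per measured field, typed by
#' `record_kind`. Malformed rows are reported with their line numbers;
#' unknown record kinds are rejected.
#'
#' @param file Path to the CSV file.
#' @return A [powder_dataset()].
#' @export
parse_measurements <- function(file) {
  if (!file.exists(file)) stop("measurement file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("record_kind", "field", "value")
  if (!all(need %in% names(df))) {
    stop("measurement CSV must have columns: ", paste(need, collapse = ", "))
  }
  kinds <- c("density", "cone", "flow", "moisture", "sieve", "hardness")
  bad <- which(!df$record_kind %in% kinds)
  if (length(bad)) {
    stop("unknown record_kind at line(s) ",
         paste(bad + 1, collapse = ", "), ": ",
         paste(unique(df$record_kind[bad]), collapse = ", "))
  }
  df$value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(df$value)) {
    stop("non-numeric value at line(s) ",
         paste(which(is.na(df$value)) + 1, collapse = ", "))
  }
  name <- if ("material" %in% names(df) && any(nzchar(df$material))) {
    df$material[nzchar(df$material)][1]
  } else sub("\\.[^.]*$", "", basename(file))
  fields <- function(kind) {
    sub <- df[df$record_kind == kind, ]
    stats::setNames(sub$value, sub$field)
  }
  get1 <- function(f, kind, nm) {
    if (!nm %in% names(f)) stop(sprintf("%s record missing field '%s'", kind, nm))
    f[[nm]]
  }
  density <- cone <- flow <- moisture <- sieve <- hardness <- NULL
  if (any(df$record_kind == "density")) {
    f <- fields("density")
    taps <- f[grep("^tap[0-9]+$", names(f))]
    names(taps) <- sub("^tap", "", names(taps))
    density <- density_measurement(get1(f, "density", "mass_g"),
                                   get1(f, "density", "volume_initial_ml"),
                                   taps)
  }
  if (any(df$record_kind == "cone")) {
    f <- fields("cone")
    cone <- cone_measurement(get1(f, "cone", "height_cm"),
                             unname(f[paste0("radius", 1:4)]))
  }
  if (any(df$record_kind == "flow")) {
    f <- fields("flow")
    if ("nonflow" %in% names(f) && f[["nonflow"]] > 0) {
      flow <- flow_measurement(nonflow = TRUE)
    }
    else flow <- flow_measurement(unname(f[paste0("time", 1:3)]))
  }
  if (any(df$record_kind == "moisture")) {
    f <- fields("moisture")
    moisture <- moisture_record(get1(f, "moisture", "wet_g"),
                                get1(f, "moisture", "dry_g"),
                                get1(f, "moisture", "humid_g"))
  }
  if (any(df$record_kind == "sieve")) {
    f <- fields("sieve")
    ret <- f[grep("^retained_[0-9.]+$", names(f))]
    ap <- as.numeric(sub("^retained_", "", names(ret)))
    o <- order(-ap)
    tb <- if ("top_bound_mm" %in% names(f)) f[["top_bound_mm"]] else 0.500
    sieve <- sieve_analysis(c(unname(ret[o]), get1(f, "sieve", "retained_pan")),
                            apertures_mm = ap[o], top_bound_mm = tb)
  }
  if (any(df$record_kind == "hardness")) {
    f <- fields("hardness")
    forces <- unname(f[grep("^force[0-9]+$", names(f))])
    lub <- "lubricated" %in% names(f) && f[["lubricated"]] > 0
    hardness <- hardness_sample(forces, lubricated = lub)
  }
  powder_dataset(name, density = density, cone = cone, flow = flow,
                 moisture = moisture, sieve = sieve, hardness = hardness)
}

#' Write a powder dataset as a measurement CSV
#'
#' Inverse of [parse_measurements()]; writing then parsing reproduces the
#' dataset.
#'
#' @param d A [powder_dataset()].
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_measurements <- function(d, file) {
  stopifnot(inherits(d, "powder_dataset"))
  rows <- list()
  add <- function(kind, field, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      material = d$name, record_kind = kind, field = field, value = value)
  }
  if (!is.null(d$density)) {
    add("density", "mass_g", d$density$mass_g)
    add("density", "volume_initial_ml", d$density$volume_initial_ml)
    for (i in seq_along(d$density$tap_counts)) {
      add("density", paste0("tap", d$density$tap_counts[i]),
          unname(d$density$tap_volumes_ml[i]))
    }
  }
  if (!is.null(d$cone)) {
    add("cone", "height_cm", d$cone$height_cm)
    for (i in 1:4) add("cone", paste0("radius", i), d$cone$base_radii_cm[i])
  }
  if (!is.null(d$flow)) {
    if (d$flow$nonflow) add("flow", "nonflow", 1)
    else for (i in 1:3) add("flow", paste0("time", i), d$flow$times_s[i])
  }
  if (!is.null(d$moisture)) {
    add("moisture", "wet_g", d$moisture$wet_g)
    add("moisture", "dry_g", d$moisture$dry_g)
    add("moisture", "humid_g", d$moisture$humid_g)
  }
  if (!is.null(d$sieve)) {
    k <- length(d$sieve$apertures_mm)
    for (i in seq_len(k)) {
      add("sieve", paste0("retained_", format(d$sieve$apertures_mm[i])),
          d$sieve$retained_pct[i])
    }
    add("sieve", "retained_pan", d$sieve$retained_pct[k + 1])
    add("sieve", "top_bound_mm", d$sieve$top_bound_mm)
  }
  if (!is.null(d$hardness)) {
    for (i in seq_along(d$hardness$breaking_forces_n)) {
      add("hardness", paste0("force", i), d$hardness$breaking_forces_n[i])
    }
    add("hardness", "lubricated", as.numeric(d$hardness$lubricated))
  }
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Serialize a parameter set or profile to JSON
#'
#' Parameter sets are written with units and provenance (which tapped volume
#' fired, lubrication flag); profiles with radii, incidence means, IPP, f
#' and IGC.
#'
#' @param x A [parameter_set()] or `sedem_profile`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_sedem_json <- function(x, path) {
  obj <- if (inherits(x, "parameter_set")) {
    tab <- sedem_transforms()
    list(type = "parameter_set",
         values = as.list(unclass(x)),
         units = as.list(stats::setNames(tab$unit, tab$parameter)),
         provenance = attr(x, "provenance"))
  } else if (inherits(x, "sedem_profile")) {
    list(type = "sedem_profile", name = x$name,
         radii = as.list(x$radii),
         incidence_means = as.list(x$incidence_means),
         ipp = x$ipp, f = x$f, igc = x$igc)
  } else stop("unsupported object for JSON serialization")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a profile written by [write_sedem_json()]
#'
#' @param path JSON path.
#' @return A `sedem_profile`.
#' @export
read_sedem_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "sedem_profile")) stop("not a sedem_profile JSON")
  sedem_profile(unlist(obj$radii), name = obj$name, f = obj$f)
}

#' Run the end-to-end preformulation pipeline
#'
#' Characterizes an API and one or more corrective excipients (from raw
#' measurement CSVs, or from the bundled reference profiles when no inputs
#' are given), writes parameter/profile JSONs and SVG diagrams, sweeps the
#' target compressibility radii to design compositions, and writes a
#' composition CSV plus a machine-readable summary JSON.
#'
#' @param api_file,excipient_files Measurement CSV paths (`excipient_files`
#'   may name several files). When both are NULL the bundled reference
#'   profiles are used (carbamazepine as API, the four disintegrants as
#'   excipients).
#' @param out_dir Output directory (created if needed).
#' @param targets Target compressibility radii for the design sweep.
#' @param dose_mg API dose per tablet.
#' @param f_mode Reliability-factor mode, `"printed"` or `"geometric"`.
#' @param seed Optional integer seed (forwarded to any simulation step;
#'   recorded in the summary for reproducibility).
#' @return Invisibly, the summary list (also written to
#'   `summary.json`): per-material profile statistics and the design table.
#' @export
run_pipeline <- function(api_file = NULL, excipient_files = NULL,
                         out_dir = tempfile("sedem_run_"),
                         targets = c(5.0, 4.5, 4.0, 3.5), dose_mg = 50,
                         f_mode = c("printed", "geometric"), seed = NULL) {
  f_mode <- match.arg(f_mode)
  f <- reliability_factor(12, mode = f_mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(api_file) != is.null(excipient_files)) {
    stop("supply both api_file and excipient_files, or neither (fixtures run)")
  }
  if (!is.null(api_file)) {
    missing <- c(api_file, excipient_files)[!file.exists(c(api_file, excipient_files))]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
    api_prof <- local({
      d <- parse_measurements(api_file)
      sedem_profile(compute_parameters(d), name = d$name, f = f)
    })
    exc_profs <- lapply(excipient_files, function(fp) {
      d <- parse_measurements(fp)
      sedem_profile(compute_parameters(d), name = d$name, f = f)
    })
    api_mat <- as_material_profile(api_prof, role = "api", use_reported = FALSE)
    exc_mats <- lapply(exc_profs, as_material_profile, role = "excipient",
                       use_reported = FALSE)
  } else {
    profs <- sedem_fixture("material_profiles")
    roles <- vapply(profs, function(p) p$role, character(1))
    api_prof <- profs[[which(roles == "api")[1]]]
    exc_profs <- profs[roles == "excipient"]
    api_mat <- as_material_profile(api_prof)
    exc_mats <- lapply(exc_profs, as_material_profile)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_profs <- c(list(api_prof), exc_profs)
  for (p in all_profs) {
    slug <- gsub("[^A-Za-z0-9]+", "_", p$name)
    write_sedem_json(p, file.path(out_dir, paste0(slug, "_profile.json")))
    write_sedem_svg(p, file.path(out_dir, paste0(slug, "_diagram.svg")))
  }
  designs <- do.call(rbind, lapply(exc_mats, function(em) {
    sw <- r_sweep(api_mat, em, targets = targets, dose_mg = dose_mg)
    cbind(api = api_mat$name, excipient = em$name, sw)
  }))
  utils::write.csv(designs, file.path(out_dir, "compositions.csv"),
                   row.names = FALSE)
  summary <- list(
    f_mode = f_mode, f = f, dose_mg = dose_mg, targets = targets, seed = seed,
    materials = lapply(all_profs, function(p) list(
      name = p$name, ipp = p$ipp, igc = p$igc,
      incidence_means = as.list(p$incidence_means))),
    designs = designs
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
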
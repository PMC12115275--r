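# The SeDeM radius profile: the 12 standardized radii, the five incidence
# factors, the parametric profile index (IPP), the reliability factor f and
# the Good Compression Index (IGC), plus the radar-polygon geometry.

#' Reliability factor f of the SeDeM diagram
#'
#' Ratio of the area of the regular polygon inscribed on the diagram axes to
#' the area of the circumscribing circle. The conventional printed value for
#' 12 parameters is 0.952, which is the default; `mode = "geometric"` instead
#' returns the exact regular-polygon ratio (n / 2 pi) sin(2 pi / n), 0.9549
#' for n = 12. The printed value is the default because it is the constant
#' used by the expert system's validated worksheets, and only it reproduces
#' the conventional reported IGC values.
#'
#' @param n_params Number of diagram axes (>= 3).
#' @param mode `"printed"` (default) or `"geometric"`.
#' @return The reliability factor.
#' @examples
#' reliability_factor(12)                      # 0.952
#' reliability_factor(12, mode = "geometric")  # 0.9549297
#' @export
reliability_factor <- function(n_params = 12, mode = c("printed", "geometric")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n_params), length(n_params) == 1, n_params >= 3)
  if (mode == "printed") {
    if (n_params != 12) {
      stop("printed reliability factor is tabulated only for 12 parameters; ",
           "use mode = \"geometric\"")
    }
    return(0.952)
  }
  (n_params / (2 * pi)) * sin(2 * pi / n_params)
}

#' Incidence-factor means of a 12-radius profile
#'
#' Means of the radii within each of the five incidence groups:
#' Dimensions (Da, Dc); Compressibility (Ie, IC, Icd); Flowability/Powder
#' flow (IH, alpha, t_flow); Lubricity/Stability (HR, H); Lubricity/Dosage
#' (Pf, Itheta).
#'
#' @param radii Named numeric vector of the 12 radii (names from
#'   [sedem_parameters()]) or a `sedem_profile`.
#' @return Named numeric vector of the five incidence means.
#' @export
incidence_means <- function(radii) {
  if (inherits(radii, "sedem_profile")) radii <- radii$radii
  ids <- sedem_parameters()
  stopifnot(is.numeric(radii), all(ids %in% names(radii)))
  vapply(sedem_incidence_groups(), function(g) mean(radii[g]), numeric(1))
}

#' Build a SeDeM radius profile
#'
#' From a [parameter_set()] (applying the twelve standardization rules of
#' [sedem_transforms()]) or directly from a named 12-radius vector (e.g. a
#' published characterization). The profile carries the radii at full
#' precision, the five incidence-factor means, the parametric profile index
#' IPP (mean of the 12 radii), the reliability factor f and the Good
#' Compression Index IGC = IPP x f.
#'
#' @param x A `parameter_set` or named numeric vector of 12 radii in
#'   \[0, 10\].
#' @param name Material name for display.
#' @param f Reliability factor; default [reliability_factor()] for 12 axes.
#' @param reported_incidences Optional named 5-vector of externally reported
#'   incidence means (see [good_compression_index()]'s `from =
#'   "incidences"` path); stored as-is.
#' @return A `sedem_profile` object.
#' @examples
#' r <- c(Da = 5.84, Dc = 7.02, Ie = 2.39, IC = 3.36, Icd = 3.00, IH = 8.99,
#'        alpha = 4.69, t_flow = 8.17, HR = 9.67, H = 9.95, Pf = 7.80,
#'        Itheta = 1.25)
#' sedem_profile(r, name = "carbamazepine")
#' @export
sedem_profile <- function(x, name = "material", f = reliability_factor(12),
                          reported_incidences = NULL) {
  ids <- sedem_parameters()
  if (inherits(x, "parameter_set")) {
    if (anyNA(x)) stop("missing-radius error: parameter set is incomplete")
    radii <- vapply(ids, function(p) to_radius(p, unclass(x)[[p]]), numeric(1))
  } else {
    stopifnot(is.numeric(x), all(ids %in% names(x)))
    radii <- as.numeric(x[ids])
    names(radii) <- ids
    if (anyNA(radii)) stop("missing-radius error: profile is incomplete")
    if (any(radii < 0 | radii > 10)) stop("radii must lie in [0, 10]")
  }
  if (!is.null(reported_incidences)) {
    grp <- names(sedem_incidence_groups())
    stopifnot(is.numeric(reported_incidences),
              all(grp %in% names(reported_incidences)))
    reported_incidences <- reported_incidences[grp]
  }
  ipp <- mean(radii)
  structure(
    list(name = name, radii = radii, incidence_means = incidence_means(radii),
         reported_incidences = reported_incidences,
         ipp = ipp, f = f, igc = ipp * f),
    class = "sedem_profile"
  )
}

#' Good Compression Index
#'
#' IGC = IPP x f, where IPP is the parametric profile index (mean of the 12
#' radii) and f the reliability factor. An IGC above 5 indicates the powder
#' is suitable for direct compression.
#'
#' Two aggregation paths are provided. `from = "radii"` (default) averages
#' the 12 radii directly. `from = "incidences"` takes the count-weighted mean
#' of the five incidence-factor means (weights 2, 3, 3, 2, 2), using the
#' profile's `reported_incidences` when present: this is the path that
#' reproduces externally reported IGC values when a published incidence mean
#' disagrees with the published per-parameter radii.
#'
#' @param p A `sedem_profile`.
#' @param from `"radii"` or `"incidences"`.
#' @return List with `ipp`, `f`, `igc` and logical `suitable` (igc > 5).
#' @examples
#' r <- c(Da = 5.84, Dc = 7.02, Ie = 2.39, IC = 3.36, Icd = 3.00, IH = 8.99,
#'        alpha = 4.69, t_flow = 8.17, HR = 9.67, H = 9.95, Pf = 7.80,
#'        Itheta = 1.25)
#' good_compression_index(sedem_profile(r))  # igc 5.72
#' @export
good_compression_index <- function(p, from = c("radii", "incidences")) {
  stopifnot(inherits(p, "sedem_profile"))
  from <- match.arg(from)
  if (from == "radii") {
    ipp <- mean(p$radii)
  } else {
    inc <- if (!is.null(p$reported_incidences)) p$reported_incidences else p$incidence_means
    w <- lengths(sedem_incidence_groups())
    ipp <- sum(inc * w) / sum(w)
  }
  igc <- ipp * p$f
  list(ipp = ipp, f = p$f, igc = igc, suitable = igc > 5)
}

#' Radar-polygon geometry of a SeDeM profile
#'
#' Places the 12 radii on equally spaced axes (first axis at 12 o'clock,
#' clockwise, in the canonical parameter order), and computes the polygon
#' vertices, the polygon area by the shoelace rule, and the area of the
#' radius-10 circumscribing circle. For radii r_i the polygon area equals the
#' sum of triangle areas (1/2) r_i r_(i+1) sin(2 pi / 12).
#'
#' @param p A `sedem_profile` or named 12-radius vector.
#' @return List with `angles` (radians), `vertices` (two-column matrix),
#'   `polygon_area`, `circle_area`.
#' @export
diagram_geometry <- function(p) {
  radii <- if (inherits(p, "sedem_profile")) p$radii else p
  ids <- sedem_parameters()
  stopifnot(is.numeric(radii), all(ids %in% names(radii)))
  radii <- radii[ids]
  n <- length(radii)
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n  # start at top, clockwise
  xy <- cbind(x = radii * cos(ang), y = radii * sin(ang))
  # shoelace
  xs <- xy[, 1]; ys <- xy[, 2]
  j <- c(2:n, 1)
  area <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
  list(angles = ang, vertices = xy, polygon_area = area,
       circle_area = pi * 10^2)
}

#' @export
print.sedem_profile <- function(x, ...) {
  cat("SeDeM profile:", x$name, "\n")
  cat("  radii: ",
      paste(sprintf("%s=%.2f", names(x$radii), sedem_round(x$radii)),
            collapse = " "), "\n", sep = "")
  inc <- sedem_round(x$incidence_means)
  cat("  incidence means: ",
      paste(sprintf("%s=%.2f", names(inc), inc), collapse = " "), "\n", sep = "")
  cat(sprintf("  IPP = %.2f, f = %.3f, IGC = %.2f (%s)\n",
              sedem_round(x$ipp), x$f, sedem_round(x$igc),
              if (x$igc > 5) "suitable for direct compression" else
                "not suitable for direct compression"))
  invisible(x)
}

#' Plot a SeDeM diagram
#'
#' Base-graphics radar plot of the 12-axis profile: reference circles, the
#' labelled axes in canonical order and the shaded radius polygon.
#'
#' @param x A `sedem_profile`.
#' @param ... Ignored.
#' @return Invisibly, the [diagram_geometry()] of the profile.
#' @export
plot.sedem_profile <- function(x, ...) {
  geo <- diagram_geometry(x)
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-12, 12), ylim = c(-12, 12), axes = FALSE,
                 xlab = "", ylab = "", main = x$name, asp = 1)
  th <- seq(0, 2 * pi, length.out = 181)
  for (rr in c(5, 10)) {
    graphics::lines(rr * cos(th), rr * sin(th), col = "grey70",
                    lty = if (rr == 5) 2 else 1)
  }
  for (i in seq_along(geo$angles)) {
    a <- geo$angles[i]
    graphics::segments(0, 0, 10 * cos(a), 10 * sin(a), col = "grey85")
    graphics::text(11.2 * cos(a), 11.2 * sin(a), names(x$radii)[i], cex = 0.8)
  }
  graphics::polygon(geo$vertices, col = grDevices::adjustcolor("steelblue", 0.4),
                    border = "steelblue4", lwd = 2)
  invisible(geo)
}

#' Write a SeDeM diagram as an SVG document
#'
#' Standalone vector rendering of the diagram: radius-10 circle, the r = 5
#' acceptability circle, labelled axes and the radius polygon.
#'
#' @param p A `sedem_profile`.
#' @param path Output file path (`.svg`).
#' @return Invisibly, `path`.
#' @export
write_sedem_svg <- function(p, path) {
  stopifnot(inherits(p, "sedem_profile"))
  geo <- diagram_geometry(p)
  s <- 20                                  # px per radius unit
  cx <- 260; cy <- 270
  px <- function(x) cx + s * x
  py <- function(y) cy - s * y
  pts <- paste(sprintf("%.2f,%.2f", px(geo$vertices[, 1]), py(geo$vertices[, 2])),
               collapse = " ")
  axes <- vapply(seq_along(geo$angles), function(i) {
    a <- geo$angles[i]
    sprintf(paste0('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#ccc"/>',
                   '<text x="%.2f" y="%.2f" font-size="12" text-anchor="middle">%s</text>'),
            px(0), py(0), px(10 * cos(a)), py(10 * sin(a)),
            px(11.3 * cos(a)), py(11.3 * sin(a)) + 4, names(p$radii)[i])
  }, character(1))
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="520" height="560" viewBox="0 0 520 560">',
    sprintf('<title>SeDeM diagram: %s</title>', p$name),
    sprintf('<text x="%d" y="28" font-size="16" text-anchor="middle">%s</text>', cx, p$name),
    sprintf('<circle cx="%d" cy="%d" r="%.1f" fill="none" stroke="#888"/>', cx, cy, 10 * s),
    sprintf('<circle cx="%d" cy="%d" r="%.1f" fill="none" stroke="#bbb" stroke-dasharray="4 3"/>',
            cx, cy, 5 * s),
    axes,
    sprintf('<polygon points="%s" fill="#4682b4" fill-opacity="0.4" stroke="#27506e" stroke-width="2"/>', pts),
    sprintf('<text x="%d" y="545" font-size="13" text-anchor="middle">IPP = %.2f, f = %.3f, IGC = %.2f</text>',
            cx, sedem_round(p$ipp), p$f, sedem_round(p$igc)),
    '</svg>'
  )
  writeLines(doc, path)
  invisible(path)
}
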
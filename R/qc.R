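# Tablet batch quality control: friability, compendial weight variation,
# and evaluation against the QTPP / CQA rule set for orally disintegrating
# mini-tablets.

#' Tablet friability
#'
#' Percent weight lost by a tablet sample under standardized tumbling:
#' 100 (W1 - W2) / W1, with W1 and W2 the sample weights before and after
#' the test.
#'
#' @param w1_g Weight before the test (g).
#' @param w2_g Weight after dedusting and reweighing (g); `w2_g <= w1_g`.
#' @return Friability in percent, in \[0, 100).
#' @examples
#' friability(6.50, 6.44)  # 0.923
#' @export
friability <- function(w1_g, w2_g) {
  stopifnot(is.numeric(w1_g), is.numeric(w2_g),
            length(w1_g) == 1, length(w2_g) == 1)
  if (w1_g <= 0 || w2_g <= 0) stop("weights must be positive")
  if (w2_g > w1_g + 1e-12) {
    stop("impossible-gain error: weight after the test exceeds weight before")
  }
  100 * (w1_g - w2_g) / w1_g
}

#' Compendial weight variation test
#'
#' Compares individual tablet weights against their mean, using the
#' uncoated-tablet deviation band for the mean weight class: 10\% below
#' 80 mg, 7.5\% from 80 to 250 mg, 5\% above 250 mg. The batch passes when
#' at most two units deviate beyond the band and none beyond twice the band.
#'
#' @param weights_mg At least 20 individual tablet weights (mg).
#' @param bands Named numeric: deviation bands (percent) for the three mean
#'   weight classes, in increasing weight order.
#' @return List with `mean_mg`, `band_pct`, `deviation_pct` (per tablet,
#'   signed), `n_outside`, `n_outside_double`, `pass`.
#' @export
weight_variation <- function(weights_mg,
                             bands = c(under_80mg = 10, mg_80_250 = 7.5,
                                       over_250mg = 5)) {
  stopifnot(is.numeric(weights_mg), length(bands) == 3)
  if (length(weights_mg) < 20) {
    stop("insufficient-sample error: at least 20 tablet weights are required")
  }
  if (any(weights_mg <= 0)) stop("weights must be positive")
  m <- mean(weights_mg)
  band <- if (m < 80) bands[[1]] else if (m <= 250) bands[[2]] else bands[[3]]
  dev <- 100 * (weights_mg - m) / m
  n_out <- sum(abs(dev) > band)
  n_out2 <- sum(abs(dev) > 2 * band)
  list(mean_mg = m, band_pct = band, deviation_pct = dev,
       n_outside = n_out, n_outside_double = n_out2,
       pass = n_out <= 2 && n_out2 == 0)
}

#' QTPP / CQA rule set for orally disintegrating mini-tablets
#'
#' Machine-readable limits: tablet diameter strictly below 7 mm,
#' disintegration not more than 180 s, friability not more than 1.0\%
#' (pass-at-limit), and a hardness window (default 25--60 N) treated as a
#' flag band rather than a hard failure, since moderately harder tablets can
#' remain acceptable when the other attributes hold.
#'
#' @param max_diameter_mm Diameter limit (strict), default 7.
#' @param max_disintegration_s Disintegration limit in seconds, default 180.
#' @param max_friability_pct Friability limit in percent, default 1.0.
#' @param hardness_window_n Two-element hardness window in newtons,
#'   default c(25, 60).
#' @param dose_mg Label dose, default 50.
#' @return A `qtpp_rules` object.
#' @export
qtpp_rules <- function(max_diameter_mm = 7, max_disintegration_s = 180,
                       max_friability_pct = 1.0,
                       hardness_window_n = c(25, 60), dose_mg = 50) {
  stopifnot(max_diameter_mm > 0, max_disintegration_s > 0,
            max_friability_pct > 0, length(hardness_window_n) == 2,
            all(hardness_window_n > 0),
            hardness_window_n[1] < hardness_window_n[2], dose_mg > 0)
  structure(list(max_diameter_mm = max_diameter_mm,
                 max_disintegration_s = max_disintegration_s,
                 max_friability_pct = max_friability_pct,
                 hardness_window_n = hardness_window_n,
                 dose_mg = dose_mg),
            class = "qtpp_rules")
}

#' Measured quality attributes of one tablet batch
#'
#' Container for the batch-level QC measurements. Any attribute may be
#' omitted (NULL); it is then reported as not assessed. When raw per-tablet
#' weights are given they must number at least 20; hardness lists at least
#' 10 are conventional but shorter lists are accepted with the summary mean.
#'
#' @param name Batch / formulation label.
#' @param weights_mg Individual tablet weights (>= 20) or NULL.
#' @param hardness_n Per-tablet breaking forces (N), or a single mean value.
#' @param friability_pct Measured friability (percent), or NULL; may instead
#'   be supplied as `friability_w1_g`/`friability_w2_g`.
#' @param friability_w1_g,friability_w2_g Sample weights before/after the
#'   friability test (used when `friability_pct` is NULL).
#' @param disintegration_s Per-tablet disintegration times (s).
#' @param diameter_mm Tablet diameter.
#' @return A `tablet_batch` object.
#' @export
tablet_batch <- function(name, weights_mg = NULL, hardness_n = NULL,
                         friability_pct = NULL, friability_w1_g = NULL,
                         friability_w2_g = NULL, disintegration_s = NULL,
                         diameter_mm = NULL) {
  if (!is.null(weights_mg)) {
    stopifnot(is.numeric(weights_mg))
    if (any(weights_mg <= 0)) stop("weights must be positive")
  }
  if (!is.null(hardness_n) && any(hardness_n < 0)) {
    stop("breaking forces must be >= 0")
  }
  if (is.null(friability_pct) && !is.null(friability_w1_g)) {
    friability_pct <- friability(friability_w1_g, friability_w2_g)
  }
  if (!is.null(disintegration_s) && any(disintegration_s < 0)) {
    stop("disintegration times must be >= 0")
  }
  if (!is.null(diameter_mm) && diameter_mm <= 0) {
    stop("diameter must be positive")
  }
  structure(list(name = name, weights_mg = weights_mg,
                 hardness_n = hardness_n, friability_pct = friability_pct,
                 disintegration_s = disintegration_s,
                 diameter_mm = diameter_mm),
            class = "tablet_batch")
}

#' Evaluate a tablet batch against the QTPP / CQA rules
#'
#' Per-attribute verdicts: `"pass"`, `"fail"`, `"flag"` (hardness outside its
#' window) or `"not_assessed"` (attribute missing). Friability exactly at
#' the limit passes at-limit with a warning. The overall verdict is the
#' conjunction: `"fail"` if any attribute fails, `"indeterminate"` if none
#' fail but some are not assessed, otherwise `"pass"` (hardness flags are
#' reported alongside, not as failures).
#'
#' @param batch A [tablet_batch()].
#' @param rules A [qtpp_rules()] (defaults to the standard rule set).
#' @return A `cqa_verdict`: list with `batch`, a data.frame `attributes`
#'   (attribute, measured value, limit, status) and `overall`.
#' @export
evaluate_cqa <- function(batch, rules = qtpp_rules()) {
  stopifnot(inherits(batch, "tablet_batch"), inherits(rules, "qtpp_rules"))
  rows <- list()
  add <- function(attribute, value, limit, status) {
    rows[[length(rows) + 1]] <<- data.frame(
      attribute = attribute, value = value, limit = limit, status = status)
  }
  if (!is.null(batch$diameter_mm)) {
    add("diameter_mm", batch$diameter_mm,
        sprintf("< %g", rules$max_diameter_mm),
        if (batch$diameter_mm < rules$max_diameter_mm) "pass" else "fail")
  } else add("diameter_mm", NA_real_, sprintf("< %g", rules$max_diameter_mm),
             "not_assessed")
  if (!is.null(batch$disintegration_s)) {
    d <- max(batch$disintegration_s)
    add("disintegration_s", d, sprintf("<= %g", rules$max_disintegration_s),
        if (d <= rules$max_disintegration_s) "pass" else "fail")
  } else add("disintegration_s", NA_real_,
             sprintf("<= %g", rules$max_disintegration_s), "not_assessed")
  if (!is.null(batch$friability_pct)) {
    fr <- batch$friability_pct
    lim <- rules$max_friability_pct
    if (abs(fr - lim) < 1e-9) {
      warning(sprintf("friability of %s at the %.2f%% limit: pass-at-limit",
                      batch$name, lim))
      st <- "pass"
    } else st <- if (fr < lim) "pass" else "fail"
    add("friability_pct", fr, sprintf("<= %g", lim), st)
  } else add("friability_pct", NA_real_,
             sprintf("<= %g", rules$max_friability_pct), "not_assessed")
  if (!is.null(batch$hardness_n)) {
    hmean <- mean(batch$hardness_n)
    w <- rules$hardness_window_n
    add("hardness_n", hmean, sprintf("%g-%g", w[1], w[2]),
        if (hmean >= w[1] && hmean <= w[2]) "pass" else "flag")
  } else add("hardness_n", NA_real_,
             sprintf("%g-%g", rules$hardness_window_n[1],
                     rules$hardness_window_n[2]), "not_assessed")
  if (!is.null(batch$weights_mg)) {
    wv <- weight_variation(batch$weights_mg)
    add("weight_variation", wv$mean_mg,
        sprintf("<= 2 units beyond %.1f%%", wv$band_pct),
        if (wv$pass) "pass" else "fail")
  } else add("weight_variation", NA_real_, "compendial bands", "not_assessed")
  tab <- do.call(rbind, rows)
  overall <- if (any(tab$status == "fail")) "fail"
             else if (any(tab$status == "not_assessed")) "indeterminate"
             else "pass"
  structure(list(batch = batch$name, attributes = tab, overall = overall),
            class = "cqa_verdict")
}

#' @export
print.cqa_verdict <- function(x, ...) {
  cat("CQA verdict for batch:", x$batch, "\n")
  print(x$attributes, row.names = FALSE)
  cat("overall:", x$overall, "\n")
  invisible(x)
}
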
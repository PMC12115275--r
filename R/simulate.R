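# Synthetic measurement generator: builds raw powder-characterization
# records whose recomputed SeDeM parameters hit a known ground truth, with
# optional per-instrument multiplicative Gaussian noise. Lets every pipeline
# stage be validated without any external data.

#' Ground truth for the synthetic measurement generator
#'
#' The target parameter values a simulated dataset should reproduce. The
#' density-derived indices (Ie, IC, IH) are determined by Da and Dc and are
#' recomputed here; supplying inconsistent values is an error.
#'
#' @param params Named numeric vector with at least `Da`, `Dc`, `Icd`,
#'   `alpha`, `t_flow`, `HR`, `H`, `Pf`, `Itheta` (units as in
#'   [sedem_transforms()]). `Ie`, `IC`, `IH` entries, if present, must agree
#'   with the densities to 1e-6.
#' @param noise Per-instrument relative standard deviations: a scalar applied
#'   to every instrument, or a named vector with any of `volume`, `weight`,
#'   `force`, `time`, `length`, `sieve` (missing entries default 0).
#' @param replicates Number of replicate datasets to generate.
#' @param seed Integer seed fixing all randomness.
#' @param name Material name for the simulated datasets.
#' @return A `ground_truth` object containing the completed
#'   [parameter_set()].
#' @examples
#' ground_truth(c(Da = 0.584, Dc = 0.702, Icd = 60, alpha = 26.55,
#'                t_flow = 3.66, HR = 0.33, H = 0.10, Pf = 11,
#'                Itheta = 0.0025))
#' @export
ground_truth <- function(params, noise = 0, replicates = 1, seed = 1L,
                         name = "simulated") {
  params <- unlist(params)
  free <- c("Da", "Dc", "Icd", "alpha", "t_flow", "HR", "H", "Pf", "Itheta")
  if (!all(free %in% names(params))) {
    stop("ground truth requires values for: ", paste(free, collapse = ", "))
  }
  if (params[["Da"]] > params[["Dc"]] + 1e-12) {
    stop("infeasible-truth error: Da exceeds Dc")
  }
  der <- density_derived(params[["Da"]], params[["Dc"]])
  for (p in c("Ie", "IC", "IH")) {
    if (p %in% names(params) && abs(params[[p]] - der[[p]]) > 1e-6) {
      stop(sprintf("infeasible-truth error: %s = %g inconsistent with densities (implied %g)",
                   p, params[[p]], der[[p]]))
    }
  }
  full <- c(params[free], Ie = der$Ie, IC = der$IC, IH = der$IH)
  ps <- parameter_set(full)
  noise <- .expand_noise(noise)
  stopifnot(is.numeric(replicates), replicates >= 1)
  structure(list(params = ps, noise = noise, replicates = as.integer(replicates),
                 seed = as.integer(seed), name = name),
            class = "ground_truth")
}

.noise_instruments <- c("volume", "weight", "force", "time", "length", "sieve")

.expand_noise <- function(noise) {
  stopifnot(is.numeric(noise), all(noise >= 0))
  if (is.null(names(noise))) {
    stopifnot(length(noise) == 1)
    return(stats::setNames(rep(noise, length(.noise_instruments)),
                           .noise_instruments))
  }
  if (!all(names(noise) %in% .noise_instruments)) {
    stop("unknown noise instrument(s): ",
         paste(setdiff(names(noise), .noise_instruments), collapse = ", "))
  }
  out <- stats::setNames(rep(0, length(.noise_instruments)), .noise_instruments)
  out[names(noise)] <- noise
  out
}

#' Ground truth matching a published 12-radius profile
#'
#' Inverts the standardization rules of a radius profile to recover the raw
#' parameter values (densities, cohesion index, angle, flow time, moisture
#' percentages, fines fraction and homogeneity index), from which a
#' simulated dataset can be generated. Radii at the clamp boundaries invert
#' to the range endpoints. The density-derived radii (Ie, IC, IH) are then
#' implied by the recovered Da and Dc and may differ from the profile's
#' printed radii in the second decimal.
#'
#' @param profile A `sedem_profile` (or named 12-radius vector).
#' @param ... Passed to [ground_truth()] (`noise`, `replicates`, `seed`).
#' @return A `ground_truth` object.
#' @export
ground_truth_from_profile <- function(profile, ...) {
  radii <- if (inherits(profile, "sedem_profile")) profile$radii else profile
  nm <- if (inherits(profile, "sedem_profile")) profile$name else "simulated"
  free <- c("Da", "Dc", "Icd", "alpha", "t_flow", "HR", "H", "Pf", "Itheta")
  v <- vapply(free, function(p) from_radius(p, radii[[p]]), numeric(1))
  ground_truth(v, name = nm, ...)
}

# Deterministic sieve-composition solver: find retained percentages (pan
# fixed at the target fines fraction) whose homogeneity index matches the
# target exactly. Searches candidate majority fractions; within a candidate,
# the non-majority mass is spread with distance-decay weights
# w_i ~ exp(-lambda |d_m - d_i|); lambda is found in closed form or by
# bisection (the weighted mean distance is monotone in lambda).
.solve_sieve_composition <- function(itheta, pf,
                                     apertures_mm = c(0.355, 0.212, 0.100, 0.05),
                                     top_bound_mm = 0.500) {
  stopifnot(itheta > 0, itheta <= 1, pf >= 0, pf < 100)
  k <- length(apertures_mm) + 1
  proto <- sieve_analysis(c(rep((100 - pf) / (k - 1), k - 1), pf),
                          apertures_mm, top_bound_mm)
  d <- proto$mean_diameter_um
  pan <- k
  wts <- function(lambda, dist) {
    t <- -lambda * dist
    w <- exp(t - max(t))
    w / sum(w)
  }
  check <- function(f, m) {
    s <- sieve_analysis(f, apertures_mm, top_bound_mm)
    it <- suppressWarnings(homogeneity_index(s))
    if (attr(it, "majority_fraction") != m) return(NULL)
    if (abs(as.numeric(it) - itheta) > 1e-9) return(NULL)
    f
  }
  for (m in seq_len(k)) {
    others <- setdiff(seq_len(k), m)
    dist <- abs(d[m] - d[others])
    if (m == pan) {
      fm <- pf
      if (fm <= 0) next
      rem <- 100 - pf
      if (rem <= 0) next
      # need: itheta = fm / (100 + wbar * rem)
      wbar_req <- (fm / itheta - 100) / rem
      if (wbar_req < min(dist) - 1e-9 || wbar_req > max(dist) + 1e-9) next
      g <- function(l) sum(dist * wts(l, dist)) - wbar_req
      lo <- -0.5; hi <- 0.5
      if (g(lo) < 0 || g(hi) > 0) next   # wbar(lo)=max(dist), wbar(hi)=min(dist)
      lambda <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
      f <- numeric(k)
      f[m] <- fm
      f[others] <- rem * wts(lambda, dist)
      f <- check(f, m)
      if (!is.null(f)) return(f)
    } else {
      nonpan <- setdiff(others, pan)
      dist_np <- abs(d[m] - d[nonpan])
      c_pan <- abs(d[m] - d[pan])
      for (lambda in c(0, seq(-0.05, 0.05, by = 0.001))) {
        w <- wts(lambda, dist_np)
        wbar <- sum(dist_np * w)
        # denom = 100 + c_pan*pf + wbar*(100 - pf - fm); itheta = fm/denom
        fm <- itheta * (100 + c_pan * pf + wbar * (100 - pf)) /
          (1 + itheta * wbar)
        if (fm < 0 || fm > 100 - pf + 1e-9) next
        rest <- (100 - pf - fm) * w
        if (any(rest > fm + 1e-9) || pf > fm + 1e-9) next
        f <- numeric(k)
        f[m] <- fm; f[pan] <- pf; f[nonpan] <- rest
        f <- check(f, m)
        if (!is.null(f)) return(f)
      }
    }
  }
  stop(sprintf(
    "infeasible-truth error: no sieve composition with fines %.4g%% attains homogeneity index %.6g",
    pf, itheta))
}

.noisy <- function(x, sd_rel) {
  if (sd_rel <= 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, sd_rel))
}

.simulate_one <- function(gt) {
  v <- unclass(gt$params)
  ns <- gt$noise
  # density: fixed 100 g charge; volumes back-computed from target densities.
  m <- 100
  v0 <- m / v[["Da"]]
  v1250 <- m / v[["Dc"]]
  v500 <- v1250 + min(1.5, (v0 - v1250) / 2)
  v10 <- v1250 + 0.8 * (v0 - v1250)
  vol <- .noisy(c(v0, v10, v500, v1250), ns[["volume"]])
  # truncation preserving the record invariants: volumes non-increasing along
  # the tap series and the 2 mL rule on the V500/V1250 gap.
  vol <- cummin(pmax(vol, 1e-6))
  vol[3] <- min(vol[3], vol[4] + 2)
  vol[3] <- max(vol[3], vol[4])
  density <- density_measurement(m, vol[1],
                                 c("10" = vol[2], "500" = vol[3], "1250" = vol[4]))
  # cone: base radii 5 cm, height from the target angle
  base_r <- .noisy(rep(5, 4), ns[["length"]])
  h <- max(0, .noisy(5 * tan(v[["alpha"]] * pi / 180), ns[["length"]]))
  cone <- cone_measurement(h, base_r)
  # flow: triplicate stopwatch times
  times <- pmax(0, .noisy(rep(v[["t_flow"]], 3), ns[["time"]]))
  flow <- flow_measurement(times)
  # moisture: 100 g wet charge
  wet <- 100
  dry <- min(wet, .noisy(wet * (1 - v[["HR"]] / 100), ns[["weight"]]))
  humid <- max(0.001, .noisy(wet * (1 + v[["H"]] / 100), ns[["weight"]]))
  moisture <- moisture_record(wet, dry, humid)
  # hardness: ten tablets at the target mean breaking force
  forces <- pmax(0, .noisy(rep(v[["Icd"]], 10), ns[["force"]]))
  hardness <- hardness_sample(forces, lubricated = FALSE)
  # sieve: composition solved to hit (Itheta, Pf) exactly, then perturbed
  f <- .solve_sieve_composition(v[["Itheta"]], v[["Pf"]])
  if (ns[["sieve"]] > 0) {
    f <- pmax(0, .noisy(f, ns[["sieve"]]))
    f <- 100 * f / sum(f)
  }
  sieve <- sieve_analysis(f)
  powder_dataset(gt$name, density = density, cone = cone, flow = flow,
                 moisture = moisture, sieve = sieve, hardness = hardness)
}

#' Simulate raw powder measurements from a ground truth
#'
#' Generates complete measurement records (density tap series, cone
#' geometry, flow times, drying/humidification weights, sieve composition,
#' breaking forces) whose recomputed parameters equal the ground truth: with
#' zero noise, [compute_parameters()] on the result recovers every target to
#' 1e-6. Noise is multiplicative Gaussian on the raw instrument readings,
#' truncated where needed to preserve record invariants. The generator is
#' fully deterministic given the seed.
#'
#' @param gt A [ground_truth()].
#' @return A single [powder_dataset()] when `gt$replicates == 1`, else a
#'   list of replicate datasets (which [compute_parameters()] averages).
#' @examples
#' gt <- ground_truth(c(Da = 0.584, Dc = 0.702, Icd = 60, alpha = 26.55,
#'                      t_flow = 3.66, HR = 0.33, H = 0.10, Pf = 11,
#'                      Itheta = 0.0025))
#' d <- simulate_powder_dataset(gt)
#' compute_parameters(d)
#' @export
simulate_powder_dataset <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(gt$seed)
  sims <- lapply(seq_len(gt$replicates), function(i) .simulate_one(gt))
  if (gt$replicates == 1) sims[[1]] else sims
}

#' Monte-Carlo parameter-recovery report
#'
#' Simulates `n_replicates` noisy datasets from a ground truth, recomputes
#' the parameter set for each, and summarizes recovery per parameter and for
#' the Good Compression Index: truth, mean estimate, bias and RMSE. With
#' zero noise all biases and RMSEs are zero.
#'
#' @param gt A [ground_truth()] (its `noise`/`replicates`/`seed` are
#'   overridden by the arguments below when supplied).
#' @param n_replicates Number of Monte-Carlo datasets (>= 2).
#' @param noise Noise specification as in [ground_truth()].
#' @param seed Integer seed.
#' @return A data.frame with rows for the 12 parameters and `IGC`:
#'   `quantity`, `truth`, `mean_estimate`, `bias`, `rmse`.
#' @export
recovery_report <- function(gt, n_replicates = 100, noise = gt$noise,
                            seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"), n_replicates >= 2)
  gt2 <- gt
  gt2$noise <- .expand_noise(noise)
  gt2$replicates <- as.integer(n_replicates)
  gt2$seed <- as.integer(seed)
  sims <- simulate_powder_dataset(gt2)
  est <- do.call(rbind, lapply(sims, function(d) unclass(compute_parameters(d))))
  igc_est <- vapply(seq_len(nrow(est)), function(i) {
    sedem_profile(parameter_set(est[i, ]))$igc
  }, numeric(1))
  truth <- c(unclass(gt$params), IGC = sedem_profile(gt$params)$igc)
  est <- cbind(est, IGC = igc_est)
  data.frame(
    quantity = names(truth),
    truth = as.numeric(truth),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - as.numeric(truth),
    rmse = sqrt(colMeans((t(t(est) - as.numeric(truth)))^2)),
    row.names = NULL
  )
}
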
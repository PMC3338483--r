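# Condition parameters and population sampling for the synthetic-microscopy
# generator. Populations are truncated Normals whose parent (mu, sigma) are
# calibrated so the *post-truncation* mean hits the configured target exactly
# and the sd comes as close as the truncation allows; interface conditions are
# two-component mixtures (spindle + rounded) whose pooled moments equal the
# configured ones.

# closed-form moments of a Normal(mu, sigma) truncated to [lower, Inf)
.truncnorm_moments <- function(mu, sigma, lower) {
  a <- (lower - mu) / sigma
  # inverse Mills ratio in log space (stable far into either tail)
  lam <- exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# calibrate parent (mu, sigma) so the truncated mean equals `mean` exactly and
# the truncated sd is as close to `sd` as attainable. For a lower-truncated
# Normal sd/(mean - lower) is bounded (~< 1), so some targets are infeasible;
# the closest attainable sd is returned in `sd_attained`.
match_truncnorm <- function(mean, sd, lower = 0) {
  stopifnot(mean > lower, sd >= 0)
  if (sd == 0) {
    return(list(mu = mean, sigma = 0, lower = lower, sd_attained = 0))
  }
  mu_for <- function(sigma) {
    # truncated mean is increasing in mu; bracket generously
    # far-left asymptote: truncated mean ~ lower + sigma^2/(lower - mu), so
    # this bracket always straddles the target
    mu_lo <- lower - max(20 * sigma, 5 * sigma^2 / (mean - lower))
    uniroot(function(mu) .truncnorm_moments(mu, sigma, lower)[1] - mean,
            lower = mu_lo, upper = mean + 5 * sigma, tol = 1e-10)$root
  }
  obj <- function(log_sigma) {
    sigma <- exp(log_sigma)
    mu <- mu_for(sigma)
    (.truncnorm_moments(mu, sigma, lower)[2] - sd)^2
  }
  opt <- optimize(obj, interval = log(c(sd / 10, sd * 20)), tol = 1e-9)
  sigma <- exp(opt$minimum)
  mu <- mu_for(sigma)
  list(mu = mu, sigma = sigma, lower = lower,
       sd_attained = unname(.truncnorm_moments(mu, sigma, lower)[2]))
}

# deterministic inverse-CDF sampler for the calibrated truncated Normal,
# parameterized through the upper tail so extreme truncation stays finite
rtrunc <- function(n, tn) {
  if (tn$sigma == 0) return(rep(tn$mu, n))
  a <- (tn$lower - tn$mu) / tn$sigma
  q <- pnorm(a, lower.tail = FALSE)
  x <- if (q > 1e-12) {
    qnorm(runif(n) * q, lower.tail = FALSE)
  } else {
    a + stats::rexp(n) / a   # far-tail limit: exponential with rate a
  }
  tn$mu + tn$sigma * x
}

#' Cell-population parameters for one experimental condition
#'
#' Pooled population statistics (mean and sd of cell area, moment-ellipse
#' aspect ratio, and path-length migration speed) plus the fraction of
#' spindle-shaped cells. Near the rigid interface two populations coexist
#' (elongated spindle cells and rounded cells); in the bulk only the rounded
#' population remains, so `spindle_fraction = 0` there.
#'
#' @param label Condition label, e.g. `"matrigel40_low"`.
#' @param area_mean,area_sd Cell area statistics (um^2).
#' @param ar_mean,ar_sd Aspect-ratio statistics (>= 1).
#' @param speed_mean,speed_sd Migration-speed statistics (um/hr).
#' @param spindle_fraction Probability a cell belongs to the spindle
#'   component, in `[0, 1]`.
#' @return A `condition_params` list.
#' @export
condition_params <- function(label, area_mean, area_sd, ar_mean, ar_sd,
                             speed_mean, speed_sd, spindle_fraction = 0) {
  stopifnot(area_mean > 0, ar_mean >= 1, speed_mean > 0,
            area_sd >= 0, ar_sd >= 0, speed_sd >= 0,
            spindle_fraction >= 0, spindle_fraction <= 1)
  structure(list(label = label, area_mean = area_mean, area_sd = area_sd,
                 ar_mean = ar_mean, ar_sd = ar_sd, speed_mean = speed_mean,
                 speed_sd = speed_sd, spindle_fraction = spindle_fraction),
            class = "condition_params")
}

#' Built-in condition presets
#'
#' Pooled statistics of the three reference conditions of the study system:
#' the lowest observation plane in 40% v/v Matrigel (interface, mixed
#' spindle/rounded population), the highest plane (bulk, rounded), and cells
#' plated on bare glass.
#'
#' @param label One of `"matrigel40_low"`, `"matrigel40_high"`, `"glass"`;
#'   omit to get the full named list.
#' @return A `condition_params` object, or a named list of all presets.
#' @export
preset_conditions <- function(label = NULL) {
  presets <- list(
    matrigel40_low = condition_params("matrigel40_low",
      area_mean = 1340, area_sd = 470, ar_mean = 10.4, ar_sd = 7.3,
      speed_mean = 29.5, speed_sd = 11.3, spindle_fraction = 0.9),
    matrigel40_high = condition_params("matrigel40_high",
      area_mean = 400, area_sd = 270, ar_mean = 1.6, ar_sd = 0.8,
      speed_mean = 7.6, speed_sd = 3.1, spindle_fraction = 0),
    glass = condition_params("glass",
      area_mean = 2309, area_sd = 1232, ar_mean = 2.2, ar_sd = 1.5,
      speed_mean = 28.2, speed_sd = 9.7, spindle_fraction = 0)
  )
  if (is.null(label)) return(presets)
  if (!label %in% names(presets)) {
    stop("unknown preset '", label, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[label]]
}

# Solve mixture components from pooled targets: rounded component moments are
# fixed (reference rounded population), the spindle component is solved so the
# pooled mean/sd equal the configured ones. Errors if the pooled sd is too
# small to accommodate the component separation.
.mixture_components <- function(mean, sd, p, rounded_mean, rounded_sd, lower,
                                spindle_lower = lower) {
  if (p <= 0) {
    return(list(spindle = NULL, rounded = match_truncnorm(mean, sd, lower), p = 0))
  }
  if (p >= 1) {
    return(list(spindle = match_truncnorm(mean, sd, spindle_lower),
                rounded = NULL, p = 1))
  }
  m_s <- (mean - (1 - p) * rounded_mean) / p
  if (m_s <= spindle_lower) {
    stop("infeasible mixture: spindle component mean below truncation bound")
  }
  delta <- m_s - rounded_mean
  var_s <- (sd^2 - p * (1 - p) * delta^2 - (1 - p) * rounded_sd^2) / p
  if (var_s <= 0) {
    stop("infeasible mixture: pooled sd ", sd, " too small for component ",
         "separation ", round(delta, 2), " at spindle fraction ", p)
  }
  list(spindle = match_truncnorm(m_s, sqrt(var_s), spindle_lower),
       rounded = match_truncnorm(rounded_mean, rounded_sd, lower),
       p = p)
}

#' Sample per-cell areas and aspect ratios for a condition
#'
#' Draws from the spindle/rounded mixture implied by the condition's pooled
#' statistics: with probability `spindle_fraction` a cell comes from the
#' elongated spindle component, otherwise from the rounded component. The
#' components are solved so the pooled mean and sd reproduce the configured
#' values; areas are truncated at > 0 and aspect ratios at >= 1 (>= 2 for the
#' spindle component).
#'
#' @param params A [condition_params()].
#' @param n Number of cells (>= 1).
#' @param seed Integer seed; identical seeds give identical samples.
#' @param rounded_ref Pooled statistics of the reference rounded population
#'   used as the rounded mixture component (defaults to the bulk preset).
#' @param area_floor Lower bound (um^2) of the observable cell-area
#'   population. The reported population statistics describe objects the
#'   image analysis counts as cells, so the generated support matches the
#'   segmentation inclusion floor (default 50 um^2, the [segment_plane()]
#'   `min_area` default).
#' @return A tibble: `cell_id`, `component` ("spindle"/"rounded"),
#'   `area` (um^2), `aspect_ratio`.
#' @export
sample_cell_shapes <- function(params, n, seed,
                               rounded_ref = preset_conditions("matrigel40_high"),
                               area_floor = 50) {
  stopifnot(inherits(params, "condition_params"), n >= 1)
  p <- params$spindle_fraction
  area_cmp <- .mixture_components(params$area_mean, params$area_sd, p,
                                  rounded_ref$area_mean, rounded_ref$area_sd,
                                  area_floor)
  ar_cmp <- .mixture_components(params$ar_mean, params$ar_sd, p,
                                rounded_ref$ar_mean, rounded_ref$ar_sd, 1,
                                spindle_lower = 2)   # elongated cells: AR >= 2
  set.seed(seed)
  spindle <- runif(n) < p
  area <- numeric(n)
  ar <- numeric(n)
  ns <- sum(spindle)
  if (ns > 0) {
    area[spindle] <- rtrunc(ns, area_cmp$spindle)
    ar[spindle] <- rtrunc(ns, ar_cmp$spindle)
  }
  if (ns < n) {
    area[!spindle] <- rtrunc(n - ns, area_cmp$rounded)
    ar[!spindle] <- rtrunc(n - ns, ar_cmp$rounded)
  }
  tibble::tibble(cell_id = seq_len(n),
                 component = ifelse(spindle, "spindle", "rounded"),
                 area = area, aspect_ratio = ar)
}

#' Exponential depth profile of a morphological metric
#'
#' Interfacial properties decay exponentially with distance from the rigid
#' support: `m(z) = m_bulk + (m_interface - m_bulk) * exp(-z / lambda)`.
#'
#' @param interface_value Metric value at the interface (z = 0).
#' @param bulk_value Metric value far from the support.
#' @param decay_length Decay length lambda (um), > 0.
#' @return A `depth_profile` object; evaluate it with [profile_value()].
#' @export
depth_profile_params <- function(interface_value, bulk_value, decay_length = 100) {
  stopifnot(decay_length > 0)
  structure(list(interface_value = interface_value, bulk_value = bulk_value,
                 decay_length = decay_length), class = "depth_profile")
}

#' Evaluate a depth profile at heights z
#'
#' @param profile A [depth_profile_params()] object.
#' @param z Heights above the first cell plane (um).
#' @return Metric values at `z`.
#' @export
profile_value <- function(profile, z) {
  stopifnot(inherits(profile, "depth_profile"))
  profile$bulk_value +
    (profile$interface_value - profile$bulk_value) * exp(-z / profile$decay_length)
}

#' Interpolate condition parameters at depth z
#'
#' Blends interface and bulk condition parameters with the exponential depth
#' profile (same decay length for every metric), yielding the effective
#' population statistics at a given height above the first cell plane.
#'
#' @param interface_params,bulk_params [condition_params()] at z = 0 and in
#'   the bulk.
#' @param z Height (um).
#' @param decay_length Decay length lambda (um), default 100 so profiles
#'   flatten well before 500 um.
#' @return A [condition_params()] for height `z`.
#' @export
condition_at_depth <- function(interface_params, bulk_params, z,
                               decay_length = 100) {
  mix <- function(a, b) {
    profile_value(depth_profile_params(a, b, decay_length), z)
  }
  condition_params(
    label = paste0(interface_params$label, "_z", z),
    area_mean = mix(interface_params$area_mean, bulk_params$area_mean),
    area_sd = mix(interface_params$area_sd, bulk_params$area_sd),
    ar_mean = mix(interface_params$ar_mean, bulk_params$ar_mean),
    ar_sd = mix(interface_params$ar_sd, bulk_params$ar_sd),
    speed_mean = mix(interface_params$speed_mean, bulk_params$speed_mean),
    speed_sd = mix(interface_params$speed_sd, bulk_params$speed_sd),
    spindle_fraction = mix(interface_params$spindle_fraction,
                           bulk_params$spindle_fraction)
  )
}

#' Imaging configuration for the synthetic generator
#'
#' @param pixel_size Pixel size (um/px), default 1.
#' @param frame_interval Time-lapse frame interval (minutes), default 20.
#' @param duration Time-lapse duration (hours), default 12 (37 frames).
#' @param image_shape Image size in pixels `c(ny, nx)`.
#' @param z_planes Heights of morphology planes (um).
#' @param noise_sd Additive Gaussian background noise (intensity units on the
#'   [0, 1] scale).
#' @param seed Integer seed for image realization.
#' @return An `imaging_config` list.
#' @export
imaging_config <- function(pixel_size = 1, frame_interval = 20, duration = 12,
                           image_shape = c(512, 512),
                           z_planes = c(0, 25, 50, 100, 200, 500, 700),
                           noise_sd = 0.03, seed = 1) {
  stopifnot(pixel_size > 0, frame_interval > 0, duration > 0,
            length(image_shape) == 2, all(image_shape >= 16), noise_sd >= 0)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 duration = duration, image_shape = as.integer(image_shape),
                 z_planes = z_planes, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "imaging_config")
}

n_frames <- function(config) {
  as.integer(round(config$duration * 60 / config$frame_interval)) + 1L
}
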
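#' Radionuclide physical constants
#'
#' Constructs a radionuclide descriptor holding the physical half-life and
#' the derived decay constant. Two nuclides are used throughout the
#' package: \code{"Zr-89"} (half-life 3.3 d = 79.2 h by default, the value
#' used in all downstream decay arithmetic; the physical 78.41 h is
#' available by passing it explicitly) and \code{"O-15"} (122.24 s).
#'
#' @param name Nuclide label, e.g. \code{"Zr-89"}.
#' @param half_life_h Physical half-life in hours (> 0).
#' @return An object of class \code{radionuclide} with fields \code{name},
#'   \code{half_life_h} and \code{lambda_per_h} (= ln 2 / half-life).
#' @examples
#' zr <- radionuclide("Zr-89", 79.2)
#' zr$lambda_per_h
#' @export
radionuclide <- function(name, half_life_h) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0) {
    stop("half_life_h must be a single finite positive number", call. = FALSE)
  }
  structure(
    list(name = name, half_life_h = half_life_h,
         lambda_per_h = log(2) / half_life_h),
    class = "radionuclide"
  )
}

#' @rdname radionuclide
#' @export
zr89 <- function(half_life_h = 79.2) radionuclide("Zr-89", half_life_h)

#' @rdname radionuclide
#' @export
o15 <- function() radionuclide("O-15", 122.24 / 3600)

#' PET frame schedule
#'
#' An ordered set of acquisition frames, each defined by its start time and
#' duration in seconds. Frames must be sorted, non-overlapping and of
#' positive duration. Two schedules from the study protocol are provided as
#' constructors: the 6-min oxygen-15 water schedule
#' (15 x 4 s, 4 x 10 s, 4 x 20 s, 3 x 60 s) and the 30-min dynamic
#' zirconium-89 schedule (4 x 30 s, 4 x 60 s, 2 x 120 s, 2 x 600 s).
#'
#' @param start_s Numeric vector of frame start times (seconds, >= 0).
#' @param duration_s Numeric vector of frame durations (seconds, > 0).
#' @return A \code{frame_schedule} object: a data frame with columns
#'   \code{start_s}, \code{duration_s}, \code{mid_s}.
#' @examples
#' sched <- o15_schedule()
#' nrow(sched)      # 26 frames
#' sched$mid_s[1]   # 2 s
#' @export
frame_schedule <- function(start_s, duration_s) {
  stopifnot(is.numeric(start_s), is.numeric(duration_s),
            length(start_s) == length(duration_s), length(start_s) >= 1L)
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s)))
    stop("frame times must be finite", call. = FALSE)
  if (any(start_s < 0)) stop("frame starts must be >= 0", call. = FALSE)
  if (any(duration_s <= 0)) stop("frame durations must be > 0", call. = FALSE)
  if (is.unsorted(start_s, strictly = TRUE))
    stop("frames must be sorted by strictly increasing start time", call. = FALSE)
  ends <- start_s + duration_s
  if (any(ends[-length(ends)] > start_s[-1] + 1e-9))
    stop("frames must not overlap", call. = FALSE)
  out <- data.frame(start_s = start_s, duration_s = duration_s,
                    mid_s = start_s + duration_s / 2)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' @rdname frame_schedule
#' @export
o15_schedule <- function() {
  dur <- c(rep(4, 15), rep(10, 4), rep(20, 4), rep(60, 3))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' @rdname frame_schedule
#' @export
zr89_dynamic_schedule <- function() {
  dur <- c(rep(30, 4), rep(60, 4), rep(120, 2), rep(600, 2))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Framed time-activity curve
#'
#' A regional radioactivity concentration series sampled on a PET frame
#' schedule, carrying an explicit decay-correction flag and the nuclide the
#' correction refers to. Mixing decay-corrected and uncorrected curves in
#' one computation is always an explicit error downstream, never silent.
#'
#' @param region Region label.
#' @param schedule A \code{\link{frame_schedule}}.
#' @param conc_kBq_per_mL Per-frame concentrations (kBq/mL, finite, >= 0).
#' @param decay_corrected Logical: are values referred back to injection
#'   time?
#' @param nuclide A \code{\link{radionuclide}}.
#' @return A \code{tac} object.
#' @export
tac <- function(region, schedule, conc_kBq_per_mL, decay_corrected, nuclide) {
  stopifnot(inherits(schedule, "frame_schedule"),
            inherits(nuclide, "radionuclide"),
            is.logical(decay_corrected), length(decay_corrected) == 1L)
  if (length(conc_kBq_per_mL) != nrow(schedule))
    stop("need exactly one concentration per frame", call. = FALSE)
  if (any(!is.finite(conc_kBq_per_mL)) || any(conc_kBq_per_mL < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(
    list(region = as.character(region), schedule = schedule,
         conc_kBq_per_mL = as.numeric(conc_kBq_per_mL),
         decay_corrected = decay_corrected, nuclide = nuclide),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %s (%s, %s)\n", x$region, x$nuclide$name,
              if (x$decay_corrected) "decay-corrected" else "not decay-corrected"))
  cat(sprintf("  %d frames, %.0f-%.0f s, peak %.3g kBq/mL\n",
              nrow(x$schedule), min(x$schedule$start_s),
              max(x$schedule$start_s + x$schedule$duration_s),
              max(x$conc_kBq_per_mL)))
  invisible(x)
}

#' Subject metadata
#'
#' Injection-level metadata: species, disease group, body weight and
#' injected activity, defining the normalization used for SUV.
#'
#' @param subject_id Identifier.
#' @param species \code{"rabbit"} or \code{"human"}.
#' @param group \code{"UUO"} (unilateral ureteric obstruction) or
#'   \code{"healthy"}.
#' @param body_weight_kg Body weight in kg (> 0).
#' @param injected_activity_MBq Injected activity in MBq (> 0).
#' @return A \code{subject_info} object.
#' @examples
#' subject_info("R1", "rabbit", "UUO", 2.12, 7.2)
#' @export
subject_info <- function(subject_id, species = c("rabbit", "human"),
                         group = c("healthy", "UUO"),
                         body_weight_kg, injected_activity_MBq) {
  species <- match.arg(species)
  group <- match.arg(group)
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be > 0", call. = FALSE)
  if (!is.numeric(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("injected_activity_MBq must be > 0", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), species = species,
         group = group, body_weight_kg = body_weight_kg,
         injected_activity_MBq = injected_activity_MBq),
    class = "subject_info"
  )
}

#' Decay-correction factor
#'
#' Factor referring a concentration measured \code{elapsed_h} hours after
#' injection back to injection time: \code{2^(elapsed_h / half_life_h)}.
#' Multiplying the measured value by this factor undoes physical decay.
#'
#' @param nuclide A \code{\link{radionuclide}}.
#' @param elapsed_h Hours since injection (>= 0; vectorized).
#' @return Dimensionless factor(s) >= 1.
#' @examples
#' decay_correction_factor(zr89(), 79.2)  # 2: one half-life
#' @export
decay_correction_factor <- function(nuclide, elapsed_h) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (any(!is.finite(elapsed_h)) || any(elapsed_h < 0))
    stop("elapsed_h must be finite and >= 0", call. = FALSE)
  2^(elapsed_h / nuclide$half_life_h)
}

#' Standardized uptake value
#'
#' SUV = C / (A0 / W) with the tissue concentration C in kBq/mL (assumed
#' 1 g/mL tissue density, so numerically kBq/g), injected activity A0 in
#' kBq and body weight W in g. The concentration must already be
#' decay-corrected to injection time.
#'
#' @param conc_kBq_per_mL Decay-corrected concentration(s), kBq/mL.
#' @param subject A \code{\link{subject_info}}.
#' @param decay_corrected Set \code{FALSE} to state the input is not
#'   corrected; this is rejected rather than silently accepted.
#' @param density_g_per_mL Tissue density converting mL to g (default 1).
#' @return Dimensionless SUV(s).
#' @examples
#' s <- subject_info("R1", "rabbit", "UUO", 2.12, 7.2)
#' suv(3.396, s)  # ~1.0: concentration equal to A0/W
#' @export
suv <- function(conc_kBq_per_mL, subject, decay_corrected = TRUE,
                density_g_per_mL = 1) {
  stopifnot(inherits(subject, "subject_info"))
  if (!isTRUE(decay_corrected))
    stop("suv() requires decay-corrected concentrations; correct first",
         call. = FALSE)
  if (any(!is.finite(conc_kBq_per_mL)) || any(conc_kBq_per_mL < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  a0_kBq <- subject$injected_activity_MBq * 1000
  w_g <- subject$body_weight_kg * 1000
  (conc_kBq_per_mL / density_g_per_mL) / (a0_kBq / w_g)
}

#' Reduce a framed TAC to fitting points
#'
#' Returns one representative time per frame (the frame midpoint by
#' default, or the decay-weighted mean time within the frame) in minutes,
#' together with the frame concentrations. This is the frame-to-point
#' reduction used by the kinetic fitter.
#'
#' @param x A \code{\link{tac}}.
#' @param representative \code{"midpoint"} (default) or
#'   \code{"decay_weighted"}, which uses the activity-weighted mean time of
#'   a frame under pure physical decay of the curve's nuclide.
#' @return A list with \code{time_min} and \code{conc_kBq_per_mL}.
#' @export
tac_resample_midpoints <- function(x, representative = c("midpoint", "decay_weighted")) {
  stopifnot(inherits(x, "tac"))
  representative <- match.arg(representative)
  if (nrow(x$schedule) == 0L) stop("empty TAC", call. = FALSE)
  if (representative == "midpoint") {
    t_s <- x$schedule$mid_s
  } else {
    lam_s <- x$nuclide$lambda_per_h / 3600
    t0 <- x$schedule$start_s; d <- x$schedule$duration_s
    # mean of t weighted by exp(-lambda t) over [t0, t0+d]
    t_s <- t0 + 1 / lam_s - d * exp(-lam_s * d) / (1 - exp(-lam_s * d))
  }
  list(time_min = t_s / 60, conc_kBq_per_mL = x$conc_kBq_per_mL)
}

#' Decay-correct a TAC to injection time
#'
#' Applies \code{\link{decay_correction_factor}} at each frame's
#' representative midpoint time. A no-op (with a message) if the curve is
#' already corrected.
#'
#' @param x A \code{\link{tac}}.
#' @return The corrected \code{tac} with \code{decay_corrected = TRUE}.
#' @export
tac_decay_correct <- function(x) {
  stopifnot(inherits(x, "tac"))
  if (x$decay_corrected) {
    message("TAC already decay-corrected; returning unchanged")
    return(x)
  }
  f <- decay_correction_factor(x$nuclide, x$schedule$mid_s / 3600)
  tac(x$region, x$schedule, x$conc_kBq_per_mL * f, TRUE, x$nuclide)
}
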
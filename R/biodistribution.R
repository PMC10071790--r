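# Ex vivo gamma-counting quantification, phosphor-plate autoradiograph
# normalization, and the two-group statistics used for all group
# comparisons.

#' SUV of a dissected tissue sample
#'
#' Decay-corrects the measured sample activity back to injection time
#' (Zr-89, half-life 79.2 h by default), converts to concentration per
#' gram of wet tissue, and normalizes by injected activity per gram of
#' body weight. Vectorized over samples.
#'
#' @param measured_activity_kBq Assayed activity at measurement time
#'   (>= 0).
#' @param wet_weight_g Sample wet weight, grams (> 0).
#' @param measurement_time_h Hours between injection and assay (>= 0).
#' @param subject A \code{\link{subject_info}}.
#' @param nuclide Decay constants; default \code{\link{zr89}()}.
#' @return Dimensionless SUV(s).
#' @examples
#' s <- subject_info("R1", "rabbit", "healthy", 2.5, 7.2)
#' exvivo_suv(7200 / 2 / 2500 * 5, 5, 79.2, s)  # one half-life: SUV = 1
#' @export
exvivo_suv <- function(measured_activity_kBq, wet_weight_g,
                       measurement_time_h, subject, nuclide = zr89()) {
  stopifnot(inherits(subject, "subject_info"))
  if (any(wet_weight_g <= 0)) stop("wet weight must be > 0", call. = FALSE)
  if (any(measured_activity_kBq < 0))
    stop("activity must be >= 0", call. = FALSE)
  corr <- measured_activity_kBq *
    decay_correction_factor(nuclide, measurement_time_h)
  suv(corr / wet_weight_g, subject)
}

#' Percent injected dose per gram of tissue
#'
#' Decay-corrected activity as a percentage of the injected activity,
#' per gram of wet tissue.
#'
#' @inheritParams exvivo_suv
#' @return Percent injected dose per gram.
#' @export
exvivo_pid_per_g <- function(measured_activity_kBq, wet_weight_g,
                             measurement_time_h, subject, nuclide = zr89()) {
  stopifnot(inherits(subject, "subject_info"))
  if (any(wet_weight_g <= 0)) stop("wet weight must be > 0", call. = FALSE)
  corr <- measured_activity_kBq *
    decay_correction_factor(nuclide, measurement_time_h)
  100 * corr / wet_weight_g / (subject$injected_activity_MBq * 1000)
}

#' Normalized autoradiograph signal
#'
#' Background-subtracts a phosphor-plate region reading, corrects for
#' radioactive decay both from injection to the start of exposure and for
#' decay during the exposure window (time-averaged decay factor
#' \eqn{2^{-t_0/T_{1/2}} (1 - e^{-\lambda T})/(\lambda T)}), and
#' normalizes to the injected activity. The result is photostimulated
#' luminescence per square millimetre per MBq injected.
#'
#' @param psl_per_mm2 Region signal, PSL/mm^2 (>= 0).
#' @param background_psl_per_mm2 Plate background, PSL/mm^2 (>= 0).
#' @param exposure_start_h Hours post-injection at exposure start.
#' @param exposure_duration_h Exposure length, hours (> 0).
#' @param subject A \code{\link{subject_info}}.
#' @param nuclide Default \code{\link{zr89}()}.
#' @return Corrected PSL/mm^2 per MBq injected.
#' @export
normalize_autoradiograph <- function(psl_per_mm2, background_psl_per_mm2,
                                     exposure_start_h, exposure_duration_h,
                                     subject, nuclide = zr89()) {
  stopifnot(inherits(subject, "subject_info"))
  if (any(exposure_duration_h <= 0))
    stop("exposure duration must be > 0", call. = FALSE)
  net <- psl_per_mm2 - background_psl_per_mm2
  if (any(net < 0)) {
    warning("background exceeds signal; clamping net PSL to 0", call. = FALSE)
    net <- pmax(net, 0)
  }
  lam <- nuclide$lambda_per_h
  decay_factor <- 2^(-exposure_start_h / nuclide$half_life_h) *
    (1 - exp(-lam * exposure_duration_h)) / (lam * exposure_duration_h)
  net / decay_factor / subject$injected_activity_MBq
}

#' Independent two-sample t test
#'
#' The two-group comparison used throughout: Student's pooled-variance t
#' test by default (Welch available), two-sided, with p < 0.05 flagged
#' significant.
#'
#' @param group_a,group_b Numeric vectors, n >= 2 each.
#' @param variant \code{"student"} (pooled, default) or \code{"welch"}.
#' @return List with \code{t}, \code{df}, \code{p_value},
#'   \code{significant}, \code{mean_a}, \code{mean_b}.
#' @export
group_ttest <- function(group_a, group_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need n >= 2 per group", call. = FALSE)
  tt <- stats::t.test(group_a, group_b, var.equal = variant == "student")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < 0.05,
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Two-sample t test from group summaries
#'
#' Pooled (or Welch) t test computed from reported means, SDs and group
#' sizes, for comparisons against published summary statistics.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @param variant \code{"student"} (default) or \code{"welch"}.
#' @return List with \code{t}, \code{df}, \code{p_value},
#'   \code{significant}.
#' @examples
#' group_ttest_summary(10.4, 2.1, 3, 17, 2.1, 3)  # |t| ~ 3.85, df 4
#' @export
group_ttest_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (n_a < 2L || n_b < 2L) stop("need n >= 2 per group", call. = FALSE)
  if (variant == "student") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_value = p, significant = p < 0.05)
}
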
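# Noncompartmental plasma pharmacokinetics of the Zr-89 antibody, plus
# small radiochemistry QC quotients. Concentrations are decay-corrected
# totals; percent values are carried on the 0-100 scale throughout.

#' Blood-to-plasma radioactivity ratio
#'
#' Per-time ratio of whole-blood to plasma activity concentration and its
#' mean over the sampling series. Samples with zero plasma activity are
#' excluded with a warning rather than producing infinities.
#'
#' @param time_h Sampling times, hours (strictly increasing).
#' @param blood_kBq_per_mL Whole-blood concentrations (>= 0).
#' @param plasma_kBq_per_mL Plasma concentrations (>= 0).
#' @return List with \code{per_time} (data frame time_h, ratio) and
#'   \code{mean_ratio}.
#' @examples
#' blood_plasma_ratio(c(1, 24), c(60, 6), c(100, 10))  # 0.6 throughout
#' @export
blood_plasma_ratio <- function(time_h, blood_kBq_per_mL, plasma_kBq_per_mL) {
  stopifnot(length(time_h) == length(blood_kBq_per_mL),
            length(time_h) == length(plasma_kBq_per_mL))
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(blood_kBq_per_mL < 0) || any(plasma_kBq_per_mL < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  keep <- plasma_kBq_per_mL > 0
  if (any(!keep))
    warning(sum(!keep), " sample(s) with zero plasma activity excluded",
            call. = FALSE)
  ratio <- blood_kBq_per_mL[keep] / plasma_kBq_per_mL[keep]
  list(per_time = data.frame(time_h = time_h[keep], ratio = ratio),
       mean_ratio = mean(ratio))
}

#' Monoexponential intact-fraction model fit
#'
#' Fits \eqn{f(t) = f_0 e^{-r t}} (rate in 1/day, times in hours) to
#' SDS-PAGE intact percentages by least squares on the log scale, which is
#' exact for noise-free monoexponential data and leaves the rate invariant
#' under rescaling of the percentages.
#'
#' @param times_h Sampling times, hours (>= 2 points).
#' @param intact_pct Intact percentages (> 0, 0-100 scale).
#' @return List with \code{f0_pct}, \code{rate_per_d}, and
#'   \code{fitted_pct} at the input times.
#' @examples
#' fit_intact_fraction(c(0, 24), c(100, 50))$rate_per_d  # ln 2 per day
#' @export
fit_intact_fraction <- function(times_h, intact_pct) {
  if (length(times_h) < 2L) stop("need at least 2 time points", call. = FALSE)
  stopifnot(length(times_h) == length(intact_pct))
  if (any(intact_pct <= 0))
    stop("intact percentages must be positive", call. = FALSE)
  t_d <- times_h / 24
  fit <- stats::lm(log(intact_pct) ~ t_d)
  f0 <- exp(stats::coef(fit)[[1]])
  r <- -stats::coef(fit)[[2]]
  list(f0_pct = f0, rate_per_d = r,
       fitted_pct = f0 * exp(-r * t_d))
}

# Linear-up/log-down trapezoid over one interval; log rule only when both
# endpoints are positive and the curve declines.
.nca_interval_auc <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c1 > c2 && c2 > 0) (c1 - c2) / log(c1 / c2) * dt
  else (c1 + c2) / 2 * dt
}

#' Linear-up/log-down trapezoidal AUC over the sampled range
#'
#' Area under a concentration-time series from the first to the last
#' sample, using linear interpolation on rising segments and logarithmic
#' interpolation on declining segments (exact for exponential decline).
#' Additive over any interior sample point.
#'
#' @param time_h Strictly increasing times, hours.
#' @param conc Concentrations (>= 0).
#' @return AUC in concentration x hours.
#' @export
auc_linlog <- function(time_h, conc) {
  stopifnot(length(time_h) == length(conc), length(time_h) >= 2L)
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  s <- 0
  for (i in seq_len(length(time_h) - 1L))
    s <- s + .nca_interval_auc(time_h[i], time_h[i + 1], conc[i], conc[i + 1])
  s
}

#' Noncompartmental AUC and total clearance
#'
#' Computes \eqn{AUC_{0\to last}} by the linear-up/log-down trapezoid rule
#' (exact on exponentially declining segments), estimates the terminal
#' rate constant by log-linear regression of the last \code{n_terminal}
#' points, extrapolates \eqn{AUC_{0\to\infty} = AUC_{0\to last} +
#' C_{last}/\lambda_z}, and reports total clearance
#' \eqn{CL = A_0 / AUC_{0\to\infty}} in mL/h (activity units cancel). If
#' the terminal phase is not declining, extrapolation is refused and only
#' \eqn{AUC_{0\to last}} is reported, flagged. When intact percentages are
#' supplied, an intact-corrected clearance (on plasma activity times the
#' intact fraction) is reported alongside the total.
#'
#' @param time_h Sampling times, hours, strictly increasing.
#' @param plasma_kBq_per_mL Decay-corrected plasma concentrations.
#' @param subject A \code{\link{subject_info}} supplying the injected
#'   activity.
#' @param blood_kBq_per_mL Optional whole-blood series for the
#'   blood-to-plasma ratio.
#' @param intact_pct Optional intact percentages at the same times.
#' @param n_terminal Number of final points in the terminal fit
#'   (default 3).
#' @return A \code{plasma_pk_result}: \code{auc_0_last}, \code{auc_0_inf}
#'   (kBq.h/mL), \code{terminal_lambda_per_h}, \code{terminal_half_life_h},
#'   \code{CL_total_mL_per_h}, \code{CL_intact_mL_per_h} (NA when no
#'   intact data), \code{blood_to_plasma_ratio} (NA when no blood data),
#'   \code{intact_fit}, \code{extrapolated} flag.
#' @export
auc_and_clearance <- function(time_h, plasma_kBq_per_mL, subject,
                              blood_kBq_per_mL = NULL, intact_pct = NULL,
                              n_terminal = 3) {
  stopifnot(inherits(subject, "subject_info"),
            length(time_h) == length(plasma_kBq_per_mL))
  if (length(time_h) < 3L)
    stop("need at least 3 points for the terminal fit", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(plasma_kBq_per_mL < 0))
    stop("concentrations must be >= 0", call. = FALSE)

  a0_kBq <- subject$injected_activity_MBq * 1000

  nca <- function(tt, cc) {
    n <- length(tt)
    # leading segment from injection: linear from C(0)=C(first observed)
    # is avoided; integrate from the first sample only, plus a back-
    # extrapolated triangle assuming C(0) = first concentration would
    # overstate early AUC for a bolus; the first sample at 1 min makes
    # the omitted sliver negligible. Start the integral at t = 0 with
    # the first observed concentration held constant back to zero time.
    auc_last <- tt[1] * cc[1] + auc_linlog(tt, cc)
    idx <- seq.int(n - n_terminal + 1L, n)
    cterm <- cc[idx]
    extrap <- all(cterm > 0)
    lambda <- NA_real_
    auc_inf <- NA_real_
    if (extrap) {
      fit <- stats::lm(log(cterm) ~ tt[idx])
      lambda <- -stats::coef(fit)[[2]]
      if (!is.finite(lambda) || lambda <= 0) extrap <- FALSE
    }
    if (extrap) auc_inf <- auc_last + cc[n] / lambda
    list(auc_last = auc_last, auc_inf = auc_inf, lambda = lambda,
         extrapolated = extrap)
  }

  tot <- nca(time_h, plasma_kBq_per_mL)
  if (!tot$extrapolated)
    warning("terminal phase not declining; AUC extrapolation refused",
            call. = FALSE)

  cl_int <- NA_real_
  intact_fit <- NULL
  if (!is.null(intact_pct)) {
    intact_fit <- fit_intact_fraction(time_h, intact_pct)
    ci <- plasma_kBq_per_mL * intact_pct / 100
    ni <- nca(time_h, ci)
    if (ni$extrapolated) cl_int <- a0_kBq / ni$auc_inf
  }

  b2p <- NA_real_
  if (!is.null(blood_kBq_per_mL))
    b2p <- blood_plasma_ratio(time_h, blood_kBq_per_mL,
                              plasma_kBq_per_mL)$mean_ratio

  structure(list(
    auc_0_last = tot$auc_last,
    auc_0_inf = tot$auc_inf,
    terminal_lambda_per_h = tot$lambda,
    terminal_half_life_h = if (is.finite(tot$lambda)) log(2) / tot$lambda else NA_real_,
    CL_total_mL_per_h = if (tot$extrapolated) a0_kBq / tot$auc_inf else NA_real_,
    CL_intact_mL_per_h = cl_int,
    blood_to_plasma_ratio = b2p,
    intact_fit = intact_fit,
    extrapolated = tot$extrapolated,
    n_points = length(time_h)), class = "plasma_pk_result")
}

#' @export
print.plasma_pk_result <- function(x, ...) {
  cat(sprintf("Plasma NCA (%d points): AUC(0-inf) = %.4g kBq.h/mL, CL = %.3g mL/h\n",
              x$n_points, x$auc_0_inf, x$CL_total_mL_per_h))
  if (is.finite(x$blood_to_plasma_ratio))
    cat(sprintf("  blood-to-plasma ratio %.2f\n", x$blood_to_plasma_ratio))
  invisible(x)
}

#' Radiochemical purity by ultrafiltration
#'
#' Percentage of radioactivity retained on the filter relative to the
#' total (filter plus filtrate).
#'
#' @param filter_counts Activity on the filter (>= 0).
#' @param filtrate_counts Activity in the filtrate (>= 0).
#' @return Purity in percent.
#' @examples
#' radiochemical_purity(991, 9)  # 99.1
#' @export
radiochemical_purity <- function(filter_counts, filtrate_counts) {
  if (filter_counts < 0 || filtrate_counts < 0)
    stop("counts must be >= 0", call. = FALSE)
  total <- filter_counts + filtrate_counts
  if (total <= 0) stop("total counts must be positive", call. = FALSE)
  100 * filter_counts / total
}
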
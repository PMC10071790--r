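# One-tissue compartment model: C_t'(t) = K1*C_a(t - delay) - k2*C_t(t).
# The tissue curve is the convolution C_t(t) = K1 * int_0^t C_a(s-delay)
# exp(-k2 (t-s)) ds. For a piecewise-linear input the convolution has a
# closed form on each interval, so the model is evaluated exactly on a fine
# uniform grid by a first-order linear recurrence (stats::filter,
# method = "recursive"), then reduced to frame values.

# Piecewise-linear input sampled onto a uniform grid (minutes). Zero is
# prepended before the first input node; the last value is held constant
# beyond the final node.
.interp_input <- function(t_in_min, c_in, t_grid_min) {
  xs <- t_in_min
  ys <- c_in
  if (xs[1] > 0) { xs <- c(0, xs); ys <- c(0, ys) }
  stats::approx(xs, ys, xout = t_grid_min, rule = 2)$y
}

# Exact convolution of a piecewise-linear input with exp(-k2 t) on a
# uniform grid. Returns K1 * int_0^t ca(s) exp(-k2 (t - s)) ds at grid
# nodes. k2 = 0 reduces to pure integration.
.conv_1tcm_grid <- function(k1, k2, ca_grid, dt_min) {
  n <- length(ca_grid)
  if (n < 2L) return(numeric(n))
  E <- exp(-k2 * dt_min)
  if (k2 > 0) {
    phi1 <- (1 - E) / k2
    phi2 <- (dt_min - phi1) / k2
  } else {
    phi1 <- dt_min
    phi2 <- dt_min^2 / 2
  }
  a <- ca_grid[-n]
  b <- ca_grid[-1L]
  inc <- a * phi1 + (b - a) / dt_min * phi2
  y <- stats::filter(inc, E, method = "recursive")
  k1 * c(0, as.numeric(y))
}

# Cumulative trapezoid used to frame-average a gridded model curve.
.cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Predicted one-tissue-compartment tissue curve
#'
#' Evaluates the single-tissue compartment model
#' \deqn{C_t(t) = K_1 \int_0^t C_a(s - \Delta)\, e^{-k_2 (t - s)}\, ds}
#' for an arterial input curve \code{input} (piecewise-linear between its
#' frame points), and reduces the continuous model to frame values, either
#' as the duration-average over each frame window (default, matching what
#' framed PET data measure) or as the value at the frame midpoint.
#'
#' @param K1 Delivery/perfusion rate constant, mL blood / mL tissue / min
#'   (>= 0). For freely diffusible water this is the reported perfusion.
#' @param k2 Tissue efflux rate constant, 1/min (>= 0).
#' @param input Arterial input \code{\link{tac}}.
#' @param schedule \code{\link{frame_schedule}} on which to return values.
#' @param delay_s Time shift of the input relative to the tissue curve,
#'   seconds (input arrives \code{delay_s} later); default 0.
#' @param frame_value \code{"average"} (duration-weighted frame mean,
#'   default) or \code{"midpoint"}.
#' @param dt_s Internal integration grid step in seconds (default 0.1).
#' @return Numeric vector of predicted concentrations (kBq/mL), one per
#'   frame.
#' @examples
#' inp <- sim_input_function(sim_config())
#' m <- model_curve(2, 2.13, inp, o15_schedule())
#' @export
model_curve <- function(K1, k2, input, schedule, delay_s = 0,
                        frame_value = c("average", "midpoint"), dt_s = 0.1) {
  stopifnot(inherits(input, "tac"), inherits(schedule, "frame_schedule"))
  frame_value <- match.arg(frame_value)
  if (!is.finite(K1) || !is.finite(k2) || K1 < 0 || k2 < 0)
    stop("K1 and k2 must be finite and >= 0", call. = FALSE)
  t_end_min <- max(schedule$start_s + schedule$duration_s) / 60
  dt_min <- dt_s / 60
  t_grid <- seq(0, t_end_min, by = dt_min)
  if (t_grid[length(t_grid)] < t_end_min) t_grid <- c(t_grid, t_end_min)
  ip <- tac_resample_midpoints(input)
  ca <- .interp_input(ip$time_min + delay_s / 60, ip$conc_kBq_per_mL, t_grid)
  ct <- .conv_1tcm_grid(K1, k2, ca, dt_min)
  if (frame_value == "midpoint") {
    stats::approx(t_grid, ct, xout = schedule$mid_s / 60)$y
  } else {
    cum <- .cumtrapz(t_grid, ct)
    cum_at <- function(tt) stats::approx(t_grid, cum, xout = tt)$y
    (cum_at((schedule$start_s + schedule$duration_s) / 60) -
       cum_at(schedule$start_s / 60)) / (schedule$duration_s / 60)
  }
}

.resid_1tcm <- function(par, obs, sw, input, schedule, delay_s, frame_value, dt_s) {
  pred <- model_curve(par[1], par[2], input, schedule, delay_s = delay_s,
                      frame_value = frame_value, dt_s = dt_s)
  sw * (obs - pred)
}

#' Fit the one-tissue compartment model to a tissue TAC
#'
#' Weighted nonlinear least squares estimation of (K1, k2) given a tissue
#' curve and an image-derived arterial input curve. Weights are
#' proportional to frame duration by default (longer frames carry more
#' counts). Five log-spaced multi-start initializations are run and the
#' best optimum by weighted residual sum of squares is reported (ties
#' broken by lower k2), so the result does not depend on a lucky starting
#' point. Optionally the input delay is grid-searched over +/- 10 s in 1-s
#' steps.
#'
#' @param tissue Tissue \code{\link{tac}}.
#' @param input Arterial input \code{\link{tac}} on a compatible time base.
#' @param weights \code{"duration"} (default) or \code{"uniform"}.
#' @param frame_value Model frame representation passed to
#'   \code{\link{model_curve}}: \code{"average"} (default) or
#'   \code{"midpoint"}.
#' @param fit_delay If \code{TRUE}, grid-search the input delay over
#'   \code{delay_grid_s}; default \code{FALSE} (delay 0).
#' @param delay_grid_s Candidate delays in seconds.
#' @param bounds Upper bound for both parameters (lower bound is 0);
#'   default 20.
#' @param n_starts Number of log-spaced multi-start initializations.
#' @param dt_s Integration step for the model grid, seconds.
#' @return A \code{one_tissue_fit}: list with \code{region}, \code{K1},
#'   \code{k2}, \code{delay_s}, \code{wrss}, \code{converged},
#'   \code{degenerate}, \code{n_frames} and the partition coefficient
#'   \code{K1_over_k2}.
#' @export
fit_1tcm <- function(tissue, input, weights = c("duration", "uniform"),
                     frame_value = c("average", "midpoint"),
                     fit_delay = FALSE, delay_grid_s = -10:10,
                     bounds = 20, n_starts = 5, dt_s = 0.1) {
  stopifnot(inherits(tissue, "tac"), inherits(input, "tac"))
  weights <- match.arg(weights)
  frame_value <- match.arg(frame_value)
  sched <- tissue$schedule
  if (nrow(sched) < 4L) stop("need at least 4 frames to fit", call. = FALSE)
  obs <- tissue$conc_kBq_per_mL
  w <- if (weights == "duration") sched$duration_s / sum(sched$duration_s)
       else rep(1 / nrow(sched), nrow(sched))

  res <- list(region = tissue$region, K1 = 0, k2 = 0, delay_s = 0,
              wrss = 0, converged = TRUE, degenerate = FALSE,
              n_frames = nrow(sched), K1_over_k2 = NA_real_)
  if (all(obs == 0)) {
    res$degenerate <- TRUE
    class(res) <- "one_tissue_fit"
    return(res)
  }

  starts <- exp(seq(log(0.2), log(8), length.out = n_starts))
  delays <- if (fit_delay) delay_grid_s else 0
  sw <- sqrt(w)
  best <- NULL
  for (d in delays) {
    for (s in starts) {
      opt <- minpack.lm::nls.lm(
        par = c(s, s), lower = c(0, 0), upper = c(bounds, bounds),
        fn = .resid_1tcm, obs = obs, sw = sw, input = input, schedule = sched,
        delay_s = d, frame_value = frame_value, dt_s = dt_s,
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 200))
      cand <- list(par = unname(opt$par), wrss = sum(opt$fvec^2),
                   conv = opt$info %in% 1:4, delay = d)
      if (is.null(best) ||
          cand$wrss < best$wrss - 1e-12 ||
          (abs(cand$wrss - best$wrss) <= 1e-12 && cand$par[2] < best$par[2])) {
        best <- cand
      }
    }
  }
  res$K1 <- best$par[1]
  res$k2 <- best$par[2]
  res$delay_s <- best$delay
  res$wrss <- best$wrss
  res$converged <- best$conv && all(is.finite(best$par))
  if (!res$converged) warning("1TCM fit did not converge for region ",
                              tissue$region, call. = FALSE)
  res$K1_over_k2 <- if (res$k2 > 0) res$K1 / res$k2 else NA_real_
  class(res) <- "one_tissue_fit"
  res
}

#' @export
print.one_tissue_fit <- function(x, ...) {
  cat(sprintf("1TCM fit [%s]: K1 = %.4g mL/mL/min, k2 = %.4g /min (%s%s)\n",
              x$region, x$K1, x$k2,
              if (x$converged) "converged" else "NOT converged",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Group summary of perfusion fits
#'
#' Per-region, per-group mean, SD and n of fitted K1 (the reported
#' perfusion), optionally with pairwise pooled-t comparisons between
#' groups via \code{\link{group_ttest}}.
#'
#' @param fits List of \code{one_tissue_fit} objects.
#' @param groups Character vector, one group label per fit.
#' @param pairwise_tests Run t tests between every pair of groups sharing a
#'   region? Default \code{TRUE} when every group has n >= 2.
#' @return A list with \code{summary} (data frame: region, group, n,
#'   mean_K1, sd_K1) and \code{tests} (data frame of pairwise comparisons,
#'   possibly empty).
#' @export
perfusion_report <- function(fits, groups, pairwise_tests = TRUE) {
  stopifnot(length(fits) == length(groups), length(fits) >= 1L)
  k1 <- vapply(fits, function(f) f$K1, numeric(1))
  region <- vapply(fits, function(f) f$region, character(1))
  df <- data.frame(region = region, group = as.character(groups), K1 = k1)
  agg <- do.call(rbind, lapply(split(df, list(df$region, df$group), drop = TRUE),
    function(d) data.frame(region = d$region[1], group = d$group[1],
                           n = nrow(d), mean_K1 = mean(d$K1),
                           sd_K1 = if (nrow(d) > 1) stats::sd(d$K1) else NA_real_)))
  rownames(agg) <- NULL
  tests <- data.frame()
  if (pairwise_tests) {
    for (r in unique(agg$region)) {
      gs <- agg$group[agg$region == r & agg$n >= 2]
      if (length(gs) >= 2) {
        prs <- utils::combn(sort(gs), 2, simplify = FALSE)
        for (p in prs) {
          a <- df$K1[df$region == r & df$group == p[1]]
          b <- df$K1[df$region == r & df$group == p[2]]
          tt <- group_ttest(a, b)
          tests <- rbind(tests, data.frame(
            region = r, group_a = p[1], group_b = p[2],
            t = tt$t, df = tt$df, p_value = tt$p_value))
        }
      }
    }
  }
  list(summary = agg, tests = tests)
}
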
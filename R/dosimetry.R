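# MIRD-style internal dosimetry: residence times (normalized numbers of
# disintegrations) from organ biokinetics, rabbit-to-human extrapolation
# by relative organ mass, organ absorbed doses from a user-supplied
# S-value matrix, and ICRP-103 effective dose. S values are input data:
# this module implements the formalism, not a phantom library.

#' Organ biokinetics container
#'
#' A long-format table of per-organ fraction-of-injected-activity time
#' series. Dosimetry requires the series to include physical decay (i.e.
#' NOT decay-corrected); the flag is carried explicitly and checked.
#'
#' @param data Data frame with columns \code{organ}, \code{time_h},
#'   \code{fraction_of_injected}.
#' @param decay_corrected Logical flag; must be \code{FALSE} for use in
#'   residence-time integration.
#' @param nuclide The physical-decay nuclide; default \code{\link{zr89}()}.
#' @return An \code{organ_biokinetics} data frame.
#' @export
organ_biokinetics <- function(data, decay_corrected = FALSE, nuclide = zr89()) {
  stopifnot(is.data.frame(data),
            all(c("organ", "time_h", "fraction_of_injected") %in% names(data)))
  if (any(data$fraction_of_injected < 0) || any(data$fraction_of_injected > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  for (o in unique(data$organ)) {
    tt <- data$time_h[data$organ == o]
    if (is.unsorted(tt, strictly = TRUE))
      stop("times must be strictly increasing within organ '", o, "'",
           call. = FALSE)
  }
  tot <- stats::aggregate(fraction_of_injected ~ time_h, data, sum)
  if (any(tot$fraction_of_injected > 1 + 1e-9))
    stop("per-time sum of organ fractions exceeds 1", call. = FALSE)
  structure(data, decay_corrected = decay_corrected, nuclide = nuclide,
            class = c("organ_biokinetics", "data.frame"))
}

#' Residence time of one organ
#'
#' The normalized number of disintegrations \eqn{\tau = \int_0^\infty
#' f(t)\,dt} (hours) of a fraction-of-injected-activity series that
#' includes physical decay. The observed range is integrated by the
#' linear-up/log-down trapezoid (exact on exponentially declining
#' segments); beyond the last sample the series is assumed to decay
#' physically only (no further biological loss, conservative), adding
#' \eqn{f_{last}/\lambda_{phys}}.
#'
#' @param times_h Strictly increasing times, hours.
#' @param fraction_of_injected Fractions in [0, 1], physical decay
#'   included.
#' @param nuclide Physical decay used for the tail; default
#'   \code{\link{zr89}()}.
#' @param decay_corrected Must be \code{FALSE}; a decay-corrected series
#'   is rejected.
#' @return Residence time in hours.
#' @examples
#' t <- c(0, 4, 24, 72, 168)
#' residence_time(t, exp(-log(2) / 79.2 * t))  # 79.2 / ln 2 = 114.3 h
#' @export
residence_time <- function(times_h, fraction_of_injected, nuclide = zr89(),
                           decay_corrected = FALSE) {
  if (isTRUE(decay_corrected))
    stop("residence_time requires a NOT decay-corrected series", call. = FALSE)
  stopifnot(length(times_h) == length(fraction_of_injected))
  if (any(fraction_of_injected < 0))
    stop("fractions must be >= 0", call. = FALSE)
  if (length(times_h) < 2L)
    stop("need at least 2 time points", call. = FALSE)
  if (is.unsorted(times_h, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  head_auc <- if (times_h[1] > 0) times_h[1] * fraction_of_injected[1] else 0
  body_auc <- auc_linlog(times_h, fraction_of_injected)
  n <- length(times_h)
  tail_auc <- fraction_of_injected[n] / nuclide$lambda_per_h
  head_auc + body_auc + tail_auc
}

#' Residence times for every organ of a biokinetics table
#'
#' @param bio An \code{\link{organ_biokinetics}}.
#' @return Named numeric vector of residence times (hours).
#' @export
residence_times <- function(bio) {
  stopifnot(inherits(bio, "organ_biokinetics"))
  if (isTRUE(attr(bio, "decay_corrected")))
    stop("biokinetics must not be decay-corrected", call. = FALSE)
  nuc <- attr(bio, "nuclide")
  organs <- unique(bio$organ)
  out <- vapply(organs, function(o) {
    d <- bio[bio$organ == o, ]
    residence_time(d$time_h, d$fraction_of_injected, nuclide = nuc)
  }, numeric(1))
  names(out) <- organs
  out
}

#' Phantom organ-mass table
#'
#' @param species \code{"rabbit"} or \code{"human"}.
#' @param organ_masses_kg Named vector of organ masses, kg (> 0, each
#'   less than the total).
#' @param total_body_kg Total body mass, kg; human default 70.
#' @return A \code{phantom_masses} object.
#' @export
phantom_masses <- function(species = c("rabbit", "human"), organ_masses_kg,
                           total_body_kg) {
  species <- match.arg(species)
  if (any(organ_masses_kg <= 0) || total_body_kg <= 0)
    stop("masses must be > 0", call. = FALSE)
  if (any(organ_masses_kg >= total_body_kg))
    stop("each organ mass must be below total body mass", call. = FALSE)
  structure(list(species = species,
                 organ_masses_kg = organ_masses_kg,
                 total_body_kg = total_body_kg),
            class = "phantom_masses")
}

#' Extrapolate rabbit biokinetics to a human phantom
#'
#' Relative-organ-mass scaling: the human fraction of injected activity
#' in an organ is the rabbit fraction times the ratio of the organ's
#' share of total body mass in human versus rabbit,
#' \deqn{f_h(t) = f_r(t)\,\frac{m_{o,h}/m_{TB,h}}{m_{o,r}/m_{TB,r}}.}
#' If scaling pushes the per-time sum over organs above 1, all organ
#' fractions at that time are renormalized proportionally (preserving
#' ratios) and a message is emitted. An alternative per-kilogram
#' (activity-concentration) scaling is available.
#'
#' @param bio_rabbit Rabbit \code{\link{organ_biokinetics}}.
#' @param masses_rabbit,masses_human \code{\link{phantom_masses}} tables
#'   covering every organ in \code{bio_rabbit}.
#' @param method \code{"relative_mass"} (default) or \code{"per_kg"}
#'   (scales by total-body mass ratio only, i.e. equal activity
#'   concentration per unit body mass).
#' @return Human \code{organ_biokinetics}.
#' @export
scale_rabbit_to_human <- function(bio_rabbit, masses_rabbit, masses_human,
                                  method = c("relative_mass", "per_kg")) {
  stopifnot(inherits(bio_rabbit, "organ_biokinetics"),
            inherits(masses_rabbit, "phantom_masses"),
            inherits(masses_human, "phantom_masses"))
  method <- match.arg(method)
  organs <- unique(bio_rabbit$organ)
  missing_r <- setdiff(organs, names(masses_rabbit$organ_masses_kg))
  missing_h <- setdiff(organs, names(masses_human$organ_masses_kg))
  if (length(missing_r) || length(missing_h))
    stop("missing organ masses: ",
         paste(unique(c(missing_r, missing_h)), collapse = ", "),
         call. = FALSE)
  d <- as.data.frame(bio_rabbit)
  ratio <- vapply(d$organ, function(o) {
    if (method == "relative_mass") {
      (masses_human$organ_masses_kg[[o]] / masses_human$total_body_kg) /
        (masses_rabbit$organ_masses_kg[[o]] / masses_rabbit$total_body_kg)
    } else {
      1  # per-kg: fraction of injected per kg body mass is conserved
    }
  }, numeric(1))
  d$fraction_of_injected <- d$fraction_of_injected * ratio
  # proportional renormalization wherever the organ sum exceeds unity
  tot <- tapply(d$fraction_of_injected, d$time_h, sum)
  bad <- as.numeric(names(tot))[tot > 1]
  if (length(bad)) {
    message("renormalizing organ fractions at ", length(bad),
            " time point(s) where scaled sum exceeded 1")
    for (tb in bad) {
      sel <- d$time_h == tb
      d$fraction_of_injected[sel] <-
        d$fraction_of_injected[sel] / sum(d$fraction_of_injected[sel])
    }
  }
  organ_biokinetics(d, decay_corrected = attr(bio_rabbit, "decay_corrected"),
                    nuclide = attr(bio_rabbit, "nuclide"))
}

#' Residence-time table with remainder of body
#'
#' Completes a set of source-organ residence times with the remainder of
#' the body. The total-body residence time defaults to the no-excretion
#' physical bound \eqn{T_{1/2}/\ln 2} (114.3 h for the 79.2-h half-life);
#' a measured whole-body total can be supplied instead. The remainder is
#' total minus the organ sum and must be non-negative.
#'
#' @param taus_h Named vector of organ residence times, hours (>= 0).
#' @param nuclide Default \code{\link{zr89}()}.
#' @param total_h Total-body residence time; default \eqn{T_{1/2}/\ln 2}.
#' @return A \code{residence_time_table}: list with \code{organ_tau_h}
#'   (named), \code{remainder_h}, \code{total_h}.
#' @examples
#' remainder_and_total(c(liver = 30, spleen = 40))  # remainder 44.3 h
#' @export
remainder_and_total <- function(taus_h, nuclide = zr89(), total_h = NULL) {
  if (length(taus_h) && any(taus_h < 0))
    stop("residence times must be >= 0", call. = FALSE)
  if (is.null(total_h)) total_h <- nuclide$half_life_h / log(2)
  s <- if (length(taus_h)) sum(taus_h) else 0
  if (s > total_h * (1 + 1e-12))
    stop(sprintf("organ residence times sum to %.4g h, above the total %.4g h",
                 s, total_h), call. = FALSE)
  structure(list(organ_tau_h = taus_h, remainder_h = total_h - s,
                 total_h = total_h), class = "residence_time_table")
}

#' @export
print.residence_time_table <- function(x, ...) {
  cat("Residence times (h):\n")
  for (o in names(x$organ_tau_h))
    cat(sprintf("  %-14s %8.3f\n", o, x$organ_tau_h[[o]]))
  cat(sprintf("  %-14s %8.3f\n  %-14s %8.3f\n", "remainder",
              x$remainder_h, "total", x$total_h))
  invisible(x)
}

#' S-value matrix
#'
#' Absorbed dose to a target organ per unit cumulated activity in a
#' source organ, mGy/(MBq.h), for one phantom. Built from a long-format
#' table (source, target, value). Self-dose entries are expected to
#' dominate cross-irradiation of the same target; violations only warn,
#' since thin-walled targets can break the pattern.
#'
#' @param data Data frame with columns \code{source}, \code{target},
#'   \code{mGy_per_MBq_h} (>= 0).
#' @param phantom Phantom label, e.g. \code{"adult-70kg"}.
#' @return An \code{s_matrix} object: target x source matrix plus label.
#' @export
s_matrix <- function(data, phantom = "unspecified") {
  stopifnot(is.data.frame(data),
            all(c("source", "target", "mGy_per_MBq_h") %in% names(data)))
  if (any(data$mGy_per_MBq_h < 0))
    stop("S values must be >= 0", call. = FALSE)
  sources <- unique(data$source)
  targets <- unique(data$target)
  m <- matrix(0, length(targets), length(sources),
              dimnames = list(targets, sources))
  m[cbind(match(data$target, targets), match(data$source, sources))] <-
    data$mGy_per_MBq_h
  for (o in intersect(sources, targets)) {
    cross <- m[o, setdiff(sources, o)]
    if (length(cross) && any(cross > m[o, o]))
      warning("S(", o, "<-", o, ") is not the largest contribution to ", o,
              call. = FALSE)
  }
  structure(list(S = m, phantom = phantom), class = "s_matrix")
}

#' Organ absorbed doses from residence times and S values
#'
#' MIRD sum \eqn{D(target) = \sum_{source} \tau_{source}\,
#' S(target \leftarrow source)}, with the remainder of the body treated
#' as a source with its own S row (named \code{"remainder"}).
#'
#' @param table A \code{\link{remainder_and_total}} result.
#' @param s An \code{\link{s_matrix}} providing every source in the
#'   table (missing sources are an explicit error listing the names).
#' @return Named vector of organ doses, mGy/MBq, one per S-matrix target.
#' @export
organ_doses <- function(table, s) {
  stopifnot(inherits(table, "residence_time_table"), inherits(s, "s_matrix"))
  tau <- c(table$organ_tau_h, remainder = table$remainder_h)
  missing <- setdiff(names(tau), colnames(s$S))
  if (length(missing))
    stop("S matrix lacks source organ(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  drop(s$S[, names(tau), drop = FALSE] %*% tau)
}

#' ICRP-103 tissue weighting factors
#'
#' The tissue weighting factors of ICRP Publication 103: 0.12 for red
#' marrow, colon, lung, stomach, breast and the remainder tissues; 0.08
#' for gonads; 0.04 for bladder, oesophagus, liver and thyroid; 0.01 for
#' bone surface, brain, salivary glands and skin. They sum to 1.
#'
#' @return Named numeric vector of weights (including
#'   \code{"remainder"}).
#' @export
icrp103_weights <- function() {
  c(red_marrow = 0.12, colon = 0.12, lung = 0.12, stomach = 0.12,
    breast = 0.12, remainder = 0.12,
    gonads = 0.08,
    bladder = 0.04, oesophagus = 0.04, liver = 0.04, thyroid = 0.04,
    bone_surface = 0.01, brain = 0.01, salivary_glands = 0.01, skin = 0.01)
}

#' ICRP-103 effective dose
#'
#' Weighted sum \eqn{E = \sum_T w_T H_T} of organ equivalent doses with
#' the ICRP-103 tissue weighting factors. For photon/electron/positron
#' emitters the radiation weighting factor is 1, so organ absorbed doses
#' in mGy/MBq equal equivalent doses in mSv/MBq numerically. Organ doses
#' are matched to the weighted tissues by name; doses provided for organs
#' outside the named list form the remainder pool, whose arithmetic mean
#' is used for the remainder weight and as the fallback for any named
#' tissue without an assessed dose.
#'
#' @param organ_doses_mGy_per_MBq Named vector of organ doses.
#' @param remainder_dose Optional explicit remainder equivalent dose;
#'   default the mean of the unmatched (else all) organ doses.
#' @return Effective dose coefficient, mSv/MBq.
#' @examples
#' d <- rep(1, 15); names(d) <- names(icrp103_weights())
#' effective_dose(d)  # exactly 1: the weights sum to 1
#' @export
effective_dose <- function(organ_doses_mGy_per_MBq, remainder_dose = NULL) {
  w <- icrp103_weights()
  if (abs(sum(w) - 1) > 1e-9)
    stop("tissue weights must sum to 1", call. = FALSE)
  doses <- organ_doses_mGy_per_MBq
  if (is.null(names(doses)) || any(!nzchar(names(doses))))
    stop("organ doses must be a fully named vector", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  named <- setdiff(names(w), "remainder")
  pool <- doses[setdiff(names(doses), named)]
  if (is.null(remainder_dose)) {
    remainder_dose <- if (length(pool)) mean(pool) else mean(doses)
  }
  h <- vapply(named, function(tn) {
    if (tn %in% names(doses)) doses[[tn]] else remainder_dose
  }, numeric(1))
  sum(w[named] * h) + w[["remainder"]] * remainder_dose
}

#' Effective dose of an administered activity
#'
#' Product of an effective-dose coefficient (mSv/MBq) and an administered
#' activity (MBq), rounded to 2 significant figures by default for
#' reporting.
#'
#' @param effective_coeff_mSv_per_MBq Coefficient (> 0).
#' @param activity_MBq Administered activity (> 0).
#' @param signif_digits Significant digits for the reported value
#'   (default 2); \code{NULL} for no rounding.
#' @return Effective dose in mSv.
#' @examples
#' administered_dose(0.702, 37)  # 26 mSv
#' @export
administered_dose <- function(effective_coeff_mSv_per_MBq, activity_MBq,
                              signif_digits = 2) {
  if (effective_coeff_mSv_per_MBq <= 0 || activity_MBq <= 0)
    stop("coefficient and activity must be > 0", call. = FALSE)
  out <- effective_coeff_mSv_per_MBq * activity_MBq
  if (!is.null(signif_digits)) out <- signif(out, signif_digits)
  out
}
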
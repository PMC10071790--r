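# CSV/YAML/JSON readers and writers binding the stages together. Column
# names carry units; readers validate headers and report offending rows.

.tac_csv_cols <- c("region", "frame_start_s", "frame_duration_s",
                   "conc_kBq_per_mL", "decay_corrected", "nuclide",
                   "half_life_h")

.check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("malformed file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "),
         " (unit-bearing headers are mandatory)", call. = FALSE)
}

#' Read and write time-activity curve CSVs
#'
#' One row per frame with unit-bearing headers: \code{region},
#' \code{frame_start_s}, \code{frame_duration_s}, \code{conc_kBq_per_mL},
#' \code{decay_corrected} (0/1), \code{nuclide}, \code{half_life_h}. A
#' file may hold several regions; the reader returns a named list of
#' \code{\link{tac}} objects (or a single \code{tac} when only one region
#' is present and \code{simplify = TRUE}). Round-trips are lossless.
#'
#' @param path File path.
#' @param simplify Return a bare \code{tac} when only one region?
#' @return \code{read_tac_csv}: a \code{tac} or named list of them;
#'   \code{write_tac_csv}: \code{path}, invisibly.
#' @export
read_tac_csv <- function(path, simplify = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .check_header(df, .tac_csv_cols, path)
  bad <- which(!is.finite(df$conc_kBq_per_mL) | df$conc_kBq_per_mL < 0 |
                 !is.finite(df$frame_start_s) | !is.finite(df$frame_duration_s))
  if (length(bad))
    stop("malformed rows in ", path, " (after header): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$frame_start_s), ]
    tac(d$region[1],
        frame_schedule(d$frame_start_s, d$frame_duration_s),
        d$conc_kBq_per_mL,
        decay_corrected = as.logical(d$decay_corrected[1]),
        nuclide = radionuclide(d$nuclide[1], d$half_life_h[1]))
  })
  if (simplify && length(out) == 1L) out[[1]] else out
}

#' @rdname read_tac_csv
#' @param x A \code{tac} or list of \code{tac} objects.
#' @export
write_tac_csv <- function(x, path) {
  if (inherits(x, "tac")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(tc) {
    data.frame(region = tc$region,
               frame_start_s = tc$schedule$start_s,
               frame_duration_s = tc$schedule$duration_s,
               conc_kBq_per_mL = tc$conc_kBq_per_mL,
               decay_corrected = as.integer(tc$decay_corrected),
               nuclide = tc$nuclide$name,
               half_life_h = tc$nuclide$half_life_h)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plasma sampling table
#'
#' Columns: \code{time_h}, \code{blood_kBq_per_mL},
#' \code{plasma_kBq_per_mL}, optional \code{intact_pct}.
#'
#' @param path File path.
#' @return Data frame sorted by time.
#' @export
read_plasma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .check_header(df, c("time_h", "blood_kBq_per_mL", "plasma_kBq_per_mL"), path)
  df[order(df$time_h), , drop = FALSE]
}

#' Read an organ-biokinetics table
#'
#' Columns: \code{organ}, \code{time_h}, \code{fraction_id} (fraction of
#' injected activity, physical decay included).
#'
#' @param path File path.
#' @param nuclide Physical-decay nuclide; default \code{\link{zr89}()}.
#' @return An \code{\link{organ_biokinetics}}.
#' @export
read_biokinetics_csv <- function(path, nuclide = zr89()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .check_header(df, c("organ", "time_h", "fraction_id"), path)
  organ_biokinetics(
    data.frame(organ = df$organ, time_h = df$time_h,
               fraction_of_injected = df$fraction_id),
    decay_corrected = FALSE, nuclide = nuclide)
}

#' @rdname read_biokinetics_csv
#' @param bio An \code{organ_biokinetics}.
#' @export
write_biokinetics_csv <- function(bio, path) {
  utils::write.csv(
    data.frame(organ = bio$organ, time_h = bio$time_h,
               fraction_id = bio$fraction_of_injected),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format S-value matrix
#'
#' Columns: \code{source}, \code{target}, \code{mGy_per_MBq_h}.
#'
#' @param path File path.
#' @param phantom Phantom label stored with the matrix.
#' @return An \code{\link{s_matrix}}.
#' @export
read_smatrix_csv <- function(path, phantom = "unspecified") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .check_header(df, c("source", "target", "mGy_per_MBq_h"), path)
  s_matrix(df, phantom = phantom)
}

#' Read a phantom organ-mass YAML
#'
#' Expected keys: \code{species}, \code{total_body_kg},
#' \code{organ_masses_kg} (a map organ -> kg).
#'
#' @param path File path.
#' @return A \code{\link{phantom_masses}}.
#' @export
read_masses_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$species) || is.null(y$total_body_kg) ||
      is.null(y$organ_masses_kg))
    stop("malformed masses file ", path,
         ": need species, total_body_kg, organ_masses_kg", call. = FALSE)
  phantom_masses(y$species, unlist(y$organ_masses_kg), y$total_body_kg)
}

# Stable hash of an R object via its serialized form (for provenance).
.config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(x, digits.d = 15)), tf)
  unname(tools::md5sum(tf))
}

#' Write a stage report as JSON with provenance
#'
#' Every numeric report carries the package version, the seed, an MD5
#' hash of the configuration, and the nuclide constants in force.
#'
#' @param obj A list of results (coerced by jsonlite).
#' @param path Output path.
#' @param seed Seed used for the stage.
#' @param config Configuration object to hash (may be \code{NULL}).
#' @param nuclide The nuclide whose constants to record.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(obj, path, seed = NA_integer_, config = NULL,
                              nuclide = zr89()) {
  payload <- list(
    provenance = list(
      package = "petdosim",
      version = as.character(utils::packageVersion("petdosim")),
      seed = seed,
      config_md5 = if (is.null(config)) NA_character_ else .config_hash(config),
      nuclide = list(name = nuclide$name, half_life_h = nuclide$half_life_h,
                     lambda_per_h = nuclide$lambda_per_h)),
    results = obj)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
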
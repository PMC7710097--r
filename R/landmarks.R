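#' Anatomical landmark set for Couinaud plane construction
#'
#' The nine named points (scanner mm) from which the cutting planes are
#' built: the inferior/superior vena cava, the three hepatic veins, the
#' gallbladder fossa, the umbilical fissure and the left/right portal vein
#' branches.
#'
#' @format Names required by [landmark_set()]:
#' `ivc_inferior, ivc_superior, rhv, mhv, lhv, gallbladder_fossa,
#' umbilical_fissure, portal_left, portal_right`.
#' @name landmarks
NULL

LANDMARK_NAMES <- c("ivc_inferior", "ivc_superior", "rhv", "mhv", "lhv",
                    "gallbladder_fossa", "umbilical_fissure",
                    "portal_left", "portal_right")

#' Construct a landmark set
#'
#' @param points named list of numeric length-3 mm coordinates, or a 9x3
#'   matrix with rownames; all nine names of [landmarks] must be present.
#' @return object of class `landmark_set`: a 9x3 matrix (mm) with rownames.
#' @export
landmark_set <- function(points) {
  if (is.list(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  if (is.null(rownames(points))) {
    stop("landmark points must be named", call. = FALSE)
  }
  missing <- setdiff(LANDMARK_NAMES, rownames(points))
  if (length(missing)) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  points <- points[LANDMARK_NAMES, , drop = FALSE]
  storage.mode(points) <- "double"
  colnames(points) <- c("x_mm", "y_mm", "z_mm")
  if (ncol(points) != 3L || any(!is.finite(points))) {
    stop("landmarks must be finite 3D mm coordinates", call. = FALSE)
  }
  if (sqrt(sum((points["ivc_inferior", ] - points["ivc_superior", ])^2)) <
      .Machine$double.eps^0.5) {
    stop("ivc_inferior and ivc_superior must be distinct points",
         call. = FALSE)
  }
  structure(points, class = c("landmark_set", "matrix"))
}

#' Read landmarks from CSV
#'
#' Expects columns `name`, `x_mm`, `y_mm`, `z_mm`, one row per landmark.
#'
#' @param path CSV path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("landmark CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- df$name
  landmark_set(m)
}

#' Write landmarks to CSV
#' @param lm a [landmark_set()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(name = rownames(lm), x_mm = lm[, 1], y_mm = lm[, 2],
                   z_mm = lm[, 3], row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

COHORT_COLUMNS <- c("patient_id", "age_y", "sex", "bmi", "day", "inr",
                    "bilirubin_umol_l", "creatinine_umol_l", "clavien_dindo",
                    "los_days", "ct1_ms", "pdff_percent", "flr_percent",
                    "liver_volume_ml", "lesion_volume_ml", "nas_ballooning",
                    "nas_inflammation", "nas_steatosis", "ishak")

#' Read a patient cohort table
#'
#' Long format, one row per patient-visit: `day = -1` carries the
#' pre-operative covariates and imaging metrics, days 1-5 the post-operative
#' bloods (INR, bilirubin in umol/L, creatinine in umol/L), and a day >= 90
#' row the follow-up liver volume. Missing values are `NA`.
#'
#' @param path CSV path.
#' @return data.frame of class `liver_cohort` with a `units` attribute.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as_liver_cohort(df)
}

#' @keywords internal
#' @noRd
as_liver_cohort <- function(df) {
  attr(df, "units") <- c(bilirubin = "umol/L", creatinine = "umol/L",
                         ct1 = "ms", pdff = "percent", volume = "mL")
  class(df) <- c("liver_cohort", "data.frame")
  df
}

#' Write a cohort table to CSV
#' @param cohort a `liver_cohort` data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Pre-operative (wide) view of a long cohort table
#'
#' Extracts the `day = -1` rows (one per patient) and joins the follow-up
#' liver volume from the day >= 90 visit, if present.
#'
#' @param cohort a `liver_cohort` long table.
#' @return data.frame, one row per patient, with `followup_volume_ml`.
#' @export
cohort_preop <- function(cohort) {
  pre <- as.data.frame(cohort[cohort$day == -1, , drop = FALSE])
  fu <- as.data.frame(cohort[cohort$day >= 90, c("patient_id", "liver_volume_ml")])
  names(fu)[2] <- "followup_volume_ml"
  out <- merge(pre, fu, by = "patient_id", all.x = TRUE, sort = TRUE)
  out[order(out$patient_id), , drop = FALSE]
}

#' Daily post-operative bloods for one patient
#'
#' @param cohort a `liver_cohort` long table.
#' @param patient_id patient identifier.
#' @return data.frame with columns `day, inr, bilirubin_umol_l,
#'   creatinine_umol_l` for post-operative days 1..5 that were recorded.
#' @export
patient_bloods <- function(cohort, patient_id) {
  rows <- cohort$patient_id == patient_id & cohort$day >= 1 & cohort$day <= 5
  as.data.frame(cohort[rows, c("day", "inr", "bilirubin_umol_l",
                               "creatinine_umol_l"), drop = FALSE])
}
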
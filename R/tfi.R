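#' Tessellated fundus indices from channel means
#'
#' The three indices are ratios of the mean red (R), green (G) and blue (B)
#' intensities of the analysis region:
#' \deqn{TFI_1 = (R - G)/R, \quad TFI_2 = R/(R+G+B), \quad TFI_3 = (R-G)/(R+G+B).}
#' Ratios are used because overall image brightness varies between
#' photographs; multiplying all three channel means by a constant leaves every
#' index unchanged. The identity \eqn{TFI_3 = TFI_1 \times TFI_2} holds
#' algebraically.
#'
#' @param stats a [channel_stats] object (only the channel means are used).
#' @return A list of class `tfi_set` with elements `tfi1`, `tfi2`, `tfi3`.
#' @export
compute_tfi <- function(stats) {
  stopifnot(inherits(stats, "channel_stats"))
  R <- stats["R", "mean"]; G <- stats["G", "mean"]; B <- stats["B", "mean"]
  s <- R + G + B
  if (s <= 0)
    stop("undefined index: R+G+B = 0 (black region)", call. = FALSE)
  if (R <= 0)
    stop("undefined index: mean red intensity is 0", call. = FALSE)
  structure(list(tfi1 = (R - G) / R, tfi2 = R / s, tfi3 = (R - G) / s),
            class = "tfi_set")
}

#' @export
print.tfi_set <- function(x, ...) {
  cat(sprintf("TFI-1 %.3f  TFI-2 %.3f  TFI-3 %.3f\n", x$tfi1, x$tfi2, x$tfi3))
  invisible(x)
}

#' Tessellation grades
#'
#' Ordered factor levels for the three-step subjective grading:
#' `NT` (non-tessellated) < `WT` (weakly tessellated) < `ST` (strongly
#' tessellated).
#'
#' @param x character vector of grades.
#' @return Ordered factor with levels `NT`, `WT`, `ST`.
#' @export
as_grade <- function(x) {
  lv <- c("NT", "WT", "ST")
  x <- as.character(x)
  if (!all(x %in% lv))
    stop("grades must be one of NT, WT, ST; got: ",
         paste(unique(setdiff(x, lv)), collapse = ", "), call. = FALSE)
  factor(x, levels = lv, ordered = TRUE)
}

#' Consensus of three rater grades
#'
#' The consensus is the grade assigned by at least two of the three raters.
#' Three mutually different grades have no consensus and raise an error (the
#' grading protocol treats this as a protocol failure, not a data point).
#'
#' @param grades length-3 vector of grades (`NT`/`WT`/`ST`).
#' @return The consensus grade as an ordered factor scalar.
#' @export
consensus_grade <- function(grades) {
  g <- as_grade(grades)
  if (length(g) != 3L) stop("exactly three rater grades required", call. = FALSE)
  tab <- table(g)
  if (max(tab) < 2L)
    stop("no consensus: all three raters disagree (",
         paste(as.character(g), collapse = ", "), ")", call. = FALSE)
  as_grade(names(tab)[which.max(tab)])
}

#' Assemble one eye's record
#'
#' Runs the full per-eye chain: place the default 250-pixel circle between
#' the supplied fovea and disc landmarks, extract its pixels, summarize the
#' channels, and compute the three indices; optionally attach covariates and
#' rater grades.
#'
#' @param image a [fundus_image].
#' @param lm a [landmarks] object.
#' @param covariates optional named list with elements among `age`,
#'   `axial_length`, `spherical_equivalent`, `sfct`, `nct` (years, mm,
#'   diopters, micrometers, micrometers).
#' @param rater_grades optional length-3 grade vector; when present the
#'   consensus grade is derived.
#' @param diameter ROI diameter in pixels (default 250).
#' @return A one-row data frame with identifiers, covariates, grades, channel
#'   means and `tfi1`, `tfi2`, `tfi3`.
#' @export
eye_record <- function(image, lm, covariates = NULL, rater_grades = NULL,
                       diameter = 250) {
  rec <- tryCatch({
    roi <- default_roi(image, lm, diameter)
    st <- channel_stats(roi_pixels(image, roi))
    tfi <- compute_tfi(st)
    cons <- if (!is.null(rater_grades))
      as.character(consensus_grade(rater_grades)) else NA_character_
    cov <- function(nm) {
      v <- covariates[[nm]]
      if (is.null(v)) NA_real_ else {
        if (v <= 0 && nm %in% c("axial_length", "sfct", "nct"))
          stop(nm, " must be positive", call. = FALSE)
        as.numeric(v)
      }
    }
    data.frame(
      eye_id = image$eye_id,
      age = cov("age"), axial_length = cov("axial_length"),
      spherical_equivalent = if (is.null(covariates$spherical_equivalent))
        NA_real_ else as.numeric(covariates$spherical_equivalent),
      sfct = cov("sfct"), nct = cov("nct"),
      grade_rater1 = if (is.null(rater_grades)) NA_character_ else as.character(rater_grades[1]),
      grade_rater2 = if (is.null(rater_grades)) NA_character_ else as.character(rater_grades[2]),
      grade_rater3 = if (is.null(rater_grades)) NA_character_ else as.character(rater_grades[3]),
      consensus_grade = cons,
      mean_r = st["R", "mean"], mean_g = st["G", "mean"], mean_b = st["B", "mean"],
      tfi1 = tfi$tfi1, tfi2 = tfi$tfi2, tfi3 = tfi$tfi3,
      stringsAsFactors = FALSE)
  }, error = function(e) {
    stop("eye '", image$eye_id, "': ", conditionMessage(e), call. = FALSE)
  })
  rec
}

#' Write the per-eye index table
#'
#' Header is exactly
#' `eye_id,mean_r,mean_g,mean_b,tfi1,tfi2,tfi3,consensus_grade`. Values are
#' written at full double precision; rounding (3 decimals) is applied only
#' when results are displayed.
#'
#' @param records data frame holding at least those columns.
#' @param path output CSV path.
#' @export
write_tfi_csv <- function(records, path) {
  cols <- c("eye_id", "mean_r", "mean_g", "mean_b", "tfi1", "tfi2", "tfi3",
            "consensus_grade")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "), call. = FALSE)
  out <- records[, cols]
  for (nm in c("mean_r", "mean_g", "mean_b", "tfi1", "tfi2", "tfi3"))
    out[[nm]] <- formatC(out[[nm]], format = "g", digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-eye index table written by [write_tfi_csv()]
#' @param path CSV path.
#' @return Data frame with numeric index columns.
#' @export
read_tfi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "mean_r", "mean_g", "mean_b", "tfi1", "tfi2", "tfi3",
            "consensus_grade")
  if (!identical(names(df), need))
    stop("TFI CSV header must be exactly: ", paste(need, collapse = ","),
         call. = FALSE)
  df$eye_id <- as.character(df$eye_id)
  df
}
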
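# polynomial rolling hash (mod 2^31-1) of a character scalar; used only to
# fingerprint the effective configuration in run manifests
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

config_echo <- function(cfg) {
  flat <- unlist(cfg[!vapply(cfg, is.list, logical(1))])
  paste0(names(flat), "=", vapply(flat, format, character(1)))
}

write_manifest <- function(dir, subcommand, cfg_lines, seed) {
  lines <- c(
    paste0("tool=tessfundus ", as.character(utils::packageVersion("tessfundus"))),
    paste0("subcommand=", subcommand),
    paste0("seed=", format(seed)),
    paste0("config_hash=", config_hash(cfg_lines)),
    cfg_lines)
  writeLines(lines, file.path(dir, paste0("manifest_", subcommand, ".txt")))
}

#' Read a flat key=value configuration file
#'
#' Blank lines and lines starting with `#` are ignored; values are returned
#' as character and coerced by the consumer. Used by the command-line
#' interface, where flags override file entries.
#'
#' @param path config file path.
#' @return Named character vector.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  stats::setNames(vapply(kv, function(p) trimws(p[2]), character(1)),
                  vapply(kv, function(p) trimws(p[1]), character(1)))
}

#' Simulate a cohort to disk
#'
#' Renders a synthetic cohort and writes one PNG per eye plus
#' `landmarks.csv` and `cohort.csv` (and a run manifest) into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param n_eyes cohort size.
#' @param seed master seed.
#' @param config optional [cohort_config]; when given, `n_eyes`/`seed`
#'   arguments are ignored in its favor.
#' @return Invisibly, the [generate_cohort()] result.
#' @export
tfi_simulate <- function(out_dir, n_eyes = 100, seed = 1, config = NULL) {
  if (is.null(config)) config <- cohort_config(n_eyes = n_eyes, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cohort(config, render = TRUE)
  for (img in gen$images)
    save_image_png(img, file.path(out_dir, paste0(img$eye_id, ".png")))
  write_landmarks_csv(gen$landmarks, file.path(out_dir, "landmarks.csv"))
  write_cohort_csv(gen$cohort, file.path(out_dir, "cohort.csv"))
  write_manifest(out_dir, "simulate",
                 config_echo(config[setdiff(names(config), "render_defaults")]),
                 config$seed)
  message(sprintf("simulated %d eyes into %s", config$n_eyes, out_dir))
  invisible(gen)
}

#' Compute per-eye indices from images on disk
#'
#' Loads every landmark-listed image from `images_dir`, places the analysis
#' circle, and writes the per-eye index table. Eyes whose circle does not fit
#' the image (or whose image is missing/unreadable) are logged and skipped;
#' processing order follows the landmarks table, so the output is
#' independent of filesystem ordering.
#'
#' @param images_dir directory holding `<eye_id>.png` (or `.tif`/`.jpg`).
#' @param landmarks_csv landmarks table path.
#' @param out_csv output CSV path.
#' @param diameter ROI diameter in pixels (default 250).
#' @param cohort_csv optional cohort table; when given, rater grades are
#'   joined so the consensus grade is filled in.
#' @return Invisibly, the records data frame.
#' @export
tfi_compute <- function(images_dir, landmarks_csv, out_csv, diameter = 250,
                        cohort_csv = NULL) {
  lmk <- read_landmarks_csv(landmarks_csv)
  grades <- NULL
  if (!is.null(cohort_csv)) grades <- read_cohort_csv(cohort_csv)
  records <- list(); skipped <- 0L
  for (i in seq_len(nrow(lmk))) {
    id <- lmk$eye_id[i]
    path <- NULL
    for (ext in c("png", "tif", "tiff", "jpg", "jpeg")) {
      cand <- file.path(images_dir, paste0(id, ".", ext))
      if (file.exists(cand)) { path <- cand; break }
    }
    rec <- tryCatch({
      if (is.null(path)) stop("no image file for eye '", id, "'", call. = FALSE)
      img <- load_image(path, eye_id = id)
      lm <- landmarks(c(lmk$fovea_x[i], lmk$fovea_y[i]),
                      c(lmk$disc_x[i], lmk$disc_y[i]), img)
      rg <- if (!is.null(grades)) {
        row <- grades[grades$eye_id == id, ]
        if (nrow(row) == 1L)
          c(row$grade_rater1, row$grade_rater2, row$grade_rater3)
      }
      eye_record(img, lm, rater_grades = rg, diameter = diameter)
    }, error = function(e) {
      message("skipping: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) skipped <- skipped + 1L else records[[length(records) + 1L]] <- rec
  }
  if (!length(records))
    stop("no readable images: all ", nrow(lmk), " eyes failed", call. = FALSE)
  out <- do.call(rbind, records)
  write_tfi_csv(out, out_csv)
  message(sprintf("computed indices for %d eyes (%d skipped)", nrow(out), skipped))
  invisible(out)
}

#' Analyze a cohort
#'
#' Joins the cohort covariate table with the per-eye index table on
#' `eye_id`, runs the full statistical battery, and writes
#' `report_groups.csv`, `report_pairwise.csv`, `report_correlations.csv` and
#' `report_summary.txt` to `out_dir`.
#'
#' @param cohort_csv cohort table path.
#' @param tfi_csv per-eye index table path.
#' @param out_dir output directory.
#' @return Invisibly, the `study_report`.
#' @export
tfi_analyze <- function(cohort_csv, tfi_csv, out_dir) {
  cohort <- read_cohort_csv(cohort_csv)
  tfi <- read_tfi_csv(tfi_csv)
  if (nrow(cohort) == 0L || nrow(tfi) == 0L)
    stop("empty input table", call. = FALSE)
  orphans <- c(setdiff(cohort$eye_id, tfi$eye_id),
               setdiff(tfi$eye_id, cohort$eye_id))
  if (length(orphans))
    stop("eye_id mismatch between cohort and TFI tables: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  records <- merge(cohort, tfi[, c("eye_id", "mean_r", "mean_g", "mean_b",
                                   "tfi1", "tfi2", "tfi3")],
                   by = "eye_id", sort = TRUE)
  records$consensus_grade <- vapply(seq_len(nrow(records)), function(i)
    as.character(consensus_grade(c(records$grade_rater1[i],
                                   records$grade_rater2[i],
                                   records$grade_rater3[i]))),
    character(1))
  report <- run_study(records)
  write_study_report(report, out_dir)
  write_manifest(out_dir, "analyze",
                 c(paste0("cohort=", basename(cohort_csv)),
                   paste0("tfi=", basename(tfi_csv)),
                   paste0("n=", nrow(records))),
                 NA)
  invisible(report)
}
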
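#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# truncated-normal draws by rejection; ranges here are a few SDs wide so the
# acceptance rate is high
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Tessellation visibility from choroidal thickness
#'
#' Linear, strictly decreasing mapping: a thin choroid (`ct_lo`) exposes the
#' large choroidal vessels fully (`v = 1`), a thick one (`ct_hi`) hides them
#' (`v = 0`); values outside the range are clamped.
#'
#' @param ct choroidal thickness in micrometers (vectorized).
#' @param ct_lo,ct_hi thickness range mapped onto visibility `[1, 0]`;
#'   `ct_lo < ct_hi`.
#' @return Visibility in `[0, 1]`.
#' @export
visibility_from_ct <- function(ct, ct_lo = 76, ct_hi = 500) {
  if (!(ct_lo < ct_hi)) stop("ct_lo must be < ct_hi", call. = FALSE)
  pmin(pmax((ct_hi - ct) / (ct_hi - ct_lo), 0), 1)
}

#' Rendering configuration for a synthetic fundus
#'
#' Defaults approximate a macula-centered photograph: an orange retinal
#' pigment epithelium background whose mean channel intensities reproduce a
#' non-tessellated eye's index values, redder choroidal vessel bands whose
#' opacity scales with the visibility `v`, dark retinal arcade vessels kept
#' outside the fovea--disc analysis circle, and mild per-channel Gaussian
#' noise.
#'
#' @param width,height image size in pixels.
#' @param fovea,disc length-2 `(x, y)` landmark positions (0-based pixels).
#' @param background,vessel_color,arcade_color RGB triplets in 0--255.
#' @param n_vessels number of choroidal vessel bands.
#' @param vessel_width range (pixels) of the Gaussian half-width of a band.
#' @param visibility tessellation visibility `v` in `[0, 1]`.
#' @param noise_sd additive per-channel Gaussian noise SD (intensity units).
#' @param roi_diameter analysis-circle diameter the arcades must avoid.
#' @param seed integer RNG seed; identical seeds give identical rasters.
#' @return A list of class `render_config`.
#' @export
render_config <- function(width = 560, height = 420,
                          fovea = c(420, 210), disc = c(140, 210),
                          background = c(165, 110, 58),
                          vessel_color = c(190, 95, 50),
                          arcade_color = c(60, 22, 15),
                          n_vessels = 9, vessel_width = c(5, 11),
                          visibility = 0.5, noise_sd = 3,
                          roi_diameter = 250, seed = 1) {
  stopifnot(visibility >= 0, visibility <= 1, noise_sd >= 0,
            all(background >= 0 & background <= 255),
            all(vessel_color >= 0 & vessel_color <= 255),
            all(arcade_color >= 0 & arcade_color <= 255))
  inb <- function(p) p[1] >= 0 && p[1] <= width - 1 && p[2] >= 0 && p[2] <= height - 1
  if (!inb(fovea) || !inb(disc))
    stop("landmarks outside image bounds", call. = FALSE)
  structure(list(width = width, height = height, fovea = fovea, disc = disc,
                 background = background, vessel_color = vessel_color,
                 arcade_color = arcade_color, n_vessels = n_vessels,
                 vessel_width = vessel_width, visibility = visibility,
                 noise_sd = noise_sd, roi_diameter = roi_diameter, seed = seed),
            class = "render_config")
}

#' Render a synthetic fundus photograph
#'
#' The image is built in three deterministic layers given the config seed:
#' the uniform RPE background; quasi-horizontal choroidal vessel bands
#' (sinusoidally wandering Gaussian-profile stripes) alpha-blended at opacity
#' `visibility * coverage`; and two dark retinal arcade vessels arcing from
#' the disc around the macula, masked out of the analysis circle so they
#' never contaminate the index. Clipped Gaussian noise is added last and the
#' result is quantized to 8 bits.
#'
#' @param config a [render_config].
#' @param eye_id identifier for the resulting image.
#' @return A [fundus_image].
#' @export
render_fundus <- function(config, eye_id = "synthetic") {
  stopifnot(inherits(config, "render_config"))
  W <- config$width; H <- config$height
  with_seed(config$seed, {
    xv <- seq_len(W) - 0.5  # pixel-center coordinates
    yv <- seq_len(H) - 0.5

    # choroidal vessel coverage: union of Gaussian-profile wandering bands;
    # band centers depend on x only, so each band touches a narrow row slab
    nv <- config$n_vessels
    base_y <- H * (seq_len(nv) - 0.5) / nv + stats::runif(nv, -H / (4 * nv), H / (4 * nv))
    amp <- stats::runif(nv, 0.01 * H, 0.05 * H)
    freq <- stats::runif(nv, 1, 2.5)
    phase <- stats::runif(nv, 0, 2 * pi)
    hw <- stats::runif(nv, config$vessel_width[1], config$vessel_width[2])
    miss <- matrix(1, H, W)  # probability a pixel is covered by no band
    for (i in seq_len(nv)) {
      cy <- base_y[i] + amp[i] * sin(2 * pi * freq[i] * xv / W + phase[i])
      rows <- which(yv >= min(cy) - 4 * hw[i] & yv <= max(cy) + 4 * hw[i])
      if (!length(rows)) next
      d <- outer(yv[rows], cy, "-")
      miss[rows, ] <- miss[rows, ] * (1 - exp(-d^2 / (2 * hw[i]^2)))
    }
    alpha <- config$visibility * (1 - miss)

    # retinal arcades: parabolic arcs from the disc around the macula,
    # masked outside the ROI disk (plus margin) between fovea and disc
    mid <- round_half_away((config$fovea + config$disc) / 2)
    r_excl <- config$roi_diameter / 2 + 4
    dxd <- xv - config$disc[1]
    span <- max(abs(config$fovea[1] - config$disc[1]), 1)
    arc <- matrix(0, H, W)
    for (s in c(-1, 1)) {
      yarc <- config$disc[2] + s * (0.05 * H + (0.28 * H) * (dxd / span)^2)
      rows <- which(yv >= min(yarc) - 10 & yv <= max(yarc) + 10)
      if (!length(rows)) next
      d <- outer(yv[rows], yarc, "-")
      arc[rows, ] <- pmax(arc[rows, ], 0.9 * exp(-d^2 / (2 * 2.5^2)))
    }
    roi_d2 <- outer((yv - (mid[2] + 0.5))^2, (xv - (mid[1] + 0.5))^2, "+")
    arc[roi_d2 <= r_excl^2] <- 0

    px <- array(0L, c(H, W, 3))
    one_m_alpha <- 1 - alpha
    one_m_arc <- 1 - arc
    for (ch in 1:3) {
      layer <- one_m_alpha * config$background[ch] + alpha * config$vessel_color[ch]
      layer <- one_m_arc * layer + arc * config$arcade_color[ch]
      layer <- round(layer + stats::rnorm(H * W, 0, config$noise_sd))
      lo <- which(layer < 0); if (length(lo)) layer[lo] <- 0
      hi <- which(layer > 255); if (length(hi)) layer[hi] <- 255
      storage.mode(layer) <- "integer"
      px[, , ch] <- layer
    }
    new_fundus_image(px, eye_id = eye_id)
  })
}

#' Cohort simulation configuration
#'
#' Defaults emulate a 100-eye cohort of young healthy adults with a wide
#' refractive range: age 25.8 +/- 3.9 years (22--39), axial length
#' 25.3 +/- 1.4 mm (22.4--30.4), spherical equivalent tied to axial length at
#' -2.3 D/mm, subfoveal choroidal thickness 261.8 +/- 84.9 um (76--500)
#' generated as a noisy decreasing function of axial length targeting a
#' Spearman correlation of -0.382, and nasal thickness offset -17.8 um with
#' 30 um noise (76--460). Tessellation visibility derives linearly from
#' subfoveal thickness over its admissible range; grade thresholds on
#' visibility (0.60, 0.76) split the cohort roughly 57/27/16 NT/WT/ST; each
#' rater independently mis-grades one step with probability 0.12.
#'
#' @param n_eyes cohort size (>= 6 so every grade is attainable).
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param al_mean,al_sd,al_range axial length distribution (mm).
#' @param se_slope,se_noise_sd,se_range spherical equivalent vs axial length
#'   (diopters; `se = se_slope * (al - 23.3) + noise`).
#' @param sfct_mean,sfct_sd,sfct_range subfoveal choroidal thickness (um).
#' @param target_rho_al_sfct target Spearman correlation of axial length and
#'   subfoveal thickness (negative).
#' @param nct_offset,nct_noise_sd,nct_range nasal thickness vs subfoveal (um).
#' @param ct_lo,ct_hi thickness range mapped to visibility (um).
#' @param grade_thresholds increasing visibility cutpoints `(NT|WT, WT|ST)`.
#' @param rater_error_rate per-rater probability of a one-step mis-grade.
#' @param render_defaults base [render_config] whose geometry/colors are
#'   reused for every eye (visibility and seed are set per eye).
#' @param seed master seed; per-eye rendering substreams are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_eyes = 100,
                          age_mean = 25.8, age_sd = 3.9, age_range = c(22, 39),
                          al_mean = 25.3, al_sd = 1.4, al_range = c(22.4, 30.4),
                          se_slope = -2.3, se_noise_sd = 1.0, se_range = c(-13, 0),
                          sfct_mean = 261.8, sfct_sd = 84.9, sfct_range = c(76, 500),
                          target_rho_al_sfct = -0.382,
                          nct_offset = -17.8, nct_noise_sd = 30, nct_range = c(76, 460),
                          ct_lo = 76, ct_hi = 500,
                          grade_thresholds = c(0.60, 0.76),
                          rater_error_rate = 0.12,
                          render_defaults = render_config(),
                          seed = 1) {
  stopifnot(n_eyes >= 6, diff(age_range) > 0, diff(al_range) > 0,
            diff(sfct_range) > 0, ct_lo < ct_hi,
            length(grade_thresholds) == 2L,
            grade_thresholds[1] < grade_thresholds[2],
            rater_error_rate >= 0, rater_error_rate <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

# one-step rater perturbation of a true grade
perturb_grade <- function(true_grade, error_rate) {
  lv <- c("NT", "WT", "ST")
  i <- match(true_grade, lv)
  if (stats::runif(1) >= error_rate) return(true_grade)
  step <- if (i == 1L) 1L else if (i == 3L) -1L else sample(c(-1L, 1L), 1L)
  lv[i + step]
}

#' Generate a synthetic cohort
#'
#' Draws covariates from the configured truncated normal distributions,
#' derives tessellation visibility from subfoveal choroidal thickness, grades
#' each eye deterministically from visibility, perturbs the three rater
#' grades with the configured one-step error rate, and (optionally) renders
#' one fundus image per eye. The axial-length/thickness dependence is
#' calibrated through the Pearson--Spearman relation
#' \eqn{\rho_P = 2\sin(\pi\rho_S/6)} so the realized Spearman correlation
#' lands near the configured target.
#'
#' @param config a [cohort_config].
#' @param render render the per-eye images (set `FALSE` when only the
#'   covariate table is needed).
#' @return A list of class `synthetic_cohort`: `cohort` (covariate/grade data
#'   frame in the cohort-CSV column layout), `landmarks` (landmark table in
#'   the landmarks-CSV layout), `images` (list of [fundus_image] or `NULL`),
#'   `visibility`, `true_grade`, `config`.
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_eyes
  rd <- config$render_defaults
  with_seed(config$seed, {
    eye_id <- sprintf("eye%03d", seq_len(n))
    age <- rtruncnorm(n, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2])
    al <- rtruncnorm(n, config$al_mean, config$al_sd,
                     config$al_range[1], config$al_range[2])
    se <- pmin(pmax(config$se_slope * (al - 23.3) +
                      stats::rnorm(n, 0, config$se_noise_sd),
                    config$se_range[1]), config$se_range[2])
    rho_p <- 2 * sin(pi * config$target_rho_al_sfct / 6)
    beta <- rho_p * config$sfct_sd / config$al_sd
    eps_sd <- config$sfct_sd * sqrt(1 - rho_p^2)
    sfct <- config$sfct_mean + beta * (al - config$al_mean) +
      stats::rnorm(n, 0, eps_sd)
    sfct <- pmin(pmax(sfct, config$sfct_range[1]), config$sfct_range[2])
    nct <- pmin(pmax(sfct + config$nct_offset + stats::rnorm(n, 0, config$nct_noise_sd),
                     config$nct_range[1]), config$nct_range[2])
    v <- visibility_from_ct(sfct, config$ct_lo, config$ct_hi)
    thr <- config$grade_thresholds
    true_grade <- ifelse(v < thr[1], "NT", ifelse(v < thr[2], "WT", "ST"))
    # three independent one-step perturbations, conditioned on a consensus
    # existing (the grading protocol never yields three-way splits)
    rater <- t(vapply(true_grade, function(tg) {
      repeat {
        g <- c(perturb_grade(tg, config$rater_error_rate),
               perturb_grade(tg, config$rater_error_rate),
               perturb_grade(tg, config$rater_error_rate))
        if (length(unique(g)) < 3L) return(g)
      }
    }, character(3)))
    cohort <- data.frame(
      eye_id = eye_id, age = age, axial_length = al,
      spherical_equivalent = se, sfct = sfct, nct = nct,
      grade_rater1 = rater[, 1], grade_rater2 = rater[, 2],
      grade_rater3 = rater[, 3], stringsAsFactors = FALSE)
    lmk <- data.frame(eye_id = eye_id,
                      fovea_x = rd$fovea[1], fovea_y = rd$fovea[2],
                      disc_x = rd$disc[1], disc_y = rd$disc[2],
                      stringsAsFactors = FALSE)
    images <- NULL
    if (render) {
      eye_seed <- (as.numeric(config$seed) %% 100000) * 20011 + 9973 * seq_len(n)
      images <- lapply(seq_len(n), function(i) {
        rc <- rd
        rc$visibility <- v[i]
        rc$seed <- eye_seed[i] %% 2147483399
        render_fundus(rc, eye_id = eye_id[i])
      })
      names(images) <- eye_id
    }
    structure(list(cohort = cohort, landmarks = lmk, images = images,
                   visibility = v, true_grade = true_grade, config = config),
              class = "synthetic_cohort")
  })
}
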
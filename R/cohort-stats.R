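#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of mid-ranks (ties receive average ranks).
#' The two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom,
#' adequate in the n = 100 regime this pipeline targets. A perfect
#' correlation (`rho = +/-1`) reports the smallest positive double rather
#' than NaN.
#'
#' @param x,y numeric vectors of equal length, n >= 3, no missing values.
#' @return A list of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g, n = %d\n", x$rho, x$p_value, x$n))
  invisible(x)
}

steel_dwass_pair <- function(vi, vj, k) {
  ni <- length(vi); nj <- length(vj); N <- ni + nj
  r <- rank(c(vi, vj))  # mid-ranks
  Ri <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  # tie-corrected variance of the rank sum under the permutation null
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0)
    stop("degenerate pair: all pooled values identical", call. = FALSE)
  t <- (Ri - E) / sqrt(V)
  p <- stats::ptukey(sqrt(2) * abs(t), nmeans = k, df = Inf, lower.tail = FALSE)
  list(t_statistic = t, p_value = p, n_a = ni, n_b = nj)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every unordered pair of groups the two groups are pooled and
#' mid-ranked; the standardized rank-sum statistic
#' \eqn{t = (R_i - E)/\sqrt{V}} (with tie-corrected permutation variance
#' \eqn{V}) is referred to the studentized range distribution with
#' `k` groups and infinite degrees of freedom:
#' \eqn{p = P(Q_{k,\infty} \ge |t|\sqrt{2})}. This controls the familywise
#' error over all pairs without a preceding omnibus test.
#'
#' @param values numeric vector of observations.
#' @param groups vector (factor or character) of group labels, same length.
#' @return Data frame of class `steel_dwass` with one row per pair:
#'   `group_a`, `group_b`, `n_a`, `n_b`, `t_statistic`, `p_value`.
#' @export
steel_dwass <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  g <- factor(groups)
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  lv <- levels(g)
  pairs <- utils::combn(k, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- lv[pairs[1L, j]]; b <- lv[pairs[2L, j]]
    pr <- steel_dwass_pair(values[g == a], values[g == b], k)
    data.frame(group_a = a, group_b = b, n_a = pr$n_a, n_b = pr$n_b,
               t_statistic = pr$t_statistic, p_value = pr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("steel_dwass", "data.frame")
  out
}

#' Fleiss kappa for multiple raters
#'
#' Chance-corrected agreement for `n` items each rated by the same number
#' `r` of raters into `q` categories. With \eqn{n_{ij}} the count of raters
#' placing item i in category j:
#' \eqn{P_i = (\sum_j n_{ij}^2 - r) / (r(r-1))}, \eqn{\bar P} the mean of the
#' \eqn{P_i}, \eqn{p_j = \sum_i n_{ij}/(nr)}, \eqn{\bar P_e = \sum_j p_j^2},
#' and \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)}.
#'
#' @param counts items x categories matrix of rating counts; every row must
#'   sum to the same rater count `r >= 2`.
#' @return A list of class `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n_items`, `n_raters`, `n_categories`.
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  rs <- rowSums(counts)
  r <- rs[1L]
  if (any(rs != r)) stop("unequal row sums: every item needs the same number of raters",
                         call. = FALSE)
  if (r < 2L) stop("need at least 2 raters", call. = FALSE)
  n <- nrow(counts)
  Pi <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (n * r)
  Pe <- sum(pj^2)
  if (Pe >= 1)
    stop("undefined kappa: all ratings fall in a single category", call. = FALSE)
  structure(list(kappa = (Pbar - Pe) / (1 - Pe),
                 observed_agreement = Pbar, expected_agreement = Pe,
                 n_items = n, n_raters = as.integer(r),
                 n_categories = ncol(counts)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Fleiss kappa = %.3f (Pbar = %.3f, Pe = %.3f; %d items, %d raters)\n",
              x$kappa, x$observed_agreement, x$expected_agreement,
              x$n_items, x$n_raters))
  invisible(x)
}

#' Tabulate rater grades into a Fleiss count matrix
#'
#' @param grade_matrix items x raters matrix/data frame of grades
#'   (`NT`/`WT`/`ST`).
#' @return items x 3 integer count matrix with columns `NT`, `WT`, `ST`.
#' @export
grade_counts <- function(grade_matrix) {
  gm <- as.matrix(grade_matrix)
  lv <- c("NT", "WT", "ST")
  t(apply(gm, 1L, function(row) table(factor(row, levels = lv))))
}

#' Intraclass correlation: two-way model, absolute agreement, single measure
#'
#' From the two-way ANOVA decomposition of a subjects x sessions matrix
#' (mean squares for rows \eqn{MS_R}, columns \eqn{MS_C}, error \eqn{MS_E}):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}.}
#' This is the single-measurement absolute-agreement coefficient used to
#' quantify intersession repeatability of one index per eye.
#'
#' @param measurements numeric matrix, `n >= 2` subjects x `k >= 2` sessions,
#'   no missing cells.
#' @return A list of class `icc_result`: `icc`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `n_subjects`, `k_sessions`.
#' @export
icc_absolute_single <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("missing cells not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 sessions", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("undefined ICC: zero total variance", call. = FALSE)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n_subjects = n, k_sessions = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%d subjects, %d sessions)\n",
              x$icc, x$n_subjects, x$k_sessions))
  invisible(x)
}

#' Per-grade summary of the indices
#'
#' Mean and sample standard deviation (divisor n-1) of each index within each
#' consensus grade, ordered NT, WT, ST. Grades with no eyes are dropped with
#' a warning (and are skipped by the pairwise tests downstream).
#'
#' @param records data frame with `consensus_grade` and `tfi1`..`tfi3`.
#' @return Data frame with one row per present grade: `grade`, `n`, then
#'   `<index>_mean` and `<index>_sd` for each index.
#' @export
group_summary <- function(records) {
  if (anyNA(records$consensus_grade))
    stop("every record needs a consensus grade", call. = FALSE)
  g <- as_grade(records$consensus_grade)
  lv <- levels(g)
  present <- lv[lv %in% as.character(unique(g))]
  if (length(present) < length(lv))
    warning("empty grade group(s): ", paste(setdiff(lv, present), collapse = ", "),
            "; excluded from summaries and pairwise tests", call. = FALSE)
  rows <- lapply(present, function(gr) {
    sub <- records[as.character(g) == gr, , drop = FALSE]
    out <- data.frame(grade = gr, n = nrow(sub), stringsAsFactors = FALSE)
    for (idx in c("tfi1", "tfi2", "tfi3")) {
      out[[paste0(idx, "_mean")]] <- mean(sub[[idx]])
      out[[paste0(idx, "_sd")]] <- stats::sd(sub[[idx]])
    }
    out
  })
  do.call(rbind, rows)
}

#' Size-weighted pooled mean
#'
#' \eqn{\sum_i n_i m_i / \sum_i n_i}; used to cross-check per-group means
#' against the whole-cohort mean.
#'
#' @param group_means numeric vector of group means.
#' @param group_sizes positive integer vector of the same length.
#' @return The pooled mean.
#' @export
pooled_mean <- function(group_means, group_sizes) {
  if (length(group_means) != length(group_sizes))
    stop("means and sizes must have equal length", call. = FALSE)
  if (any(group_sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  sum(group_means * group_sizes) / sum(group_sizes)
}

#' Run the full cohort analysis
#'
#' Produces the study report: cohort descriptives, per-grade index summaries,
#' Steel-Dwass pairwise comparisons for each index across consensus grades,
#' Spearman correlations of each index with subfoveal/nasal choroidal
#' thickness and axial length (plus axial length vs both thicknesses), and
#' Fleiss kappa of the three rater grades. The 0.05 threshold is used only to
#' label significance in the printed report; nothing is filtered by it.
#'
#' @param records data frame with covariates (`age`, `axial_length`,
#'   `spherical_equivalent`, `sfct`, `nct`), `grade_rater1..3`,
#'   `consensus_grade` and `tfi1`..`tfi3`.
#' @return A list of class `study_report` with elements `descriptives`,
#'   `groups`, `pairwise`, `correlations`, `kappa`, `n`.
#' @export
run_study <- function(records) {
  req <- c("eye_id", "age", "axial_length", "sfct", "nct",
           "grade_rater1", "grade_rater2", "grade_rater3", "consensus_grade",
           "tfi1", "tfi2", "tfi3")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "), call. = FALSE)

  desc_vars <- c(age = "age", axial_length = "axial_length",
                 spherical_equivalent = "spherical_equivalent",
                 sfct = "sfct", nct = "nct",
                 tfi1 = "tfi1", tfi2 = "tfi2", tfi3 = "tfi3")
  desc <- do.call(rbind, lapply(names(desc_vars), function(nm) {
    v <- records[[desc_vars[[nm]]]]
    data.frame(variable = nm, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))

  groups <- group_summary(records)
  g <- as_grade(records$consensus_grade)
  usable <- groups$grade[groups$n >= 3L]
  keep <- as.character(g) %in% usable

  pairwise <- do.call(rbind, lapply(c("tfi1", "tfi2", "tfi3"), function(idx) {
    if (length(usable) < 2L) return(NULL)
    sd_res <- steel_dwass(records[[idx]][keep], droplevels(g[keep]))
    cbind(index = idx, sd_res, stringsAsFactors = FALSE)
  }))

  cor_pairs <- rbind(
    expand.grid(x = c("tfi1", "tfi2", "tfi3"),
                y = c("sfct", "nct", "axial_length"),
                stringsAsFactors = FALSE),
    data.frame(x = "axial_length", y = c("sfct", "nct"),
               stringsAsFactors = FALSE))
  correlations <- do.call(rbind, lapply(seq_len(nrow(cor_pairs)), function(i) {
    cr <- spearman_cor(records[[cor_pairs$x[i]]], records[[cor_pairs$y[i]]])
    data.frame(var_x = cor_pairs$x[i], var_y = cor_pairs$y[i],
               rho = cr$rho, p_value = cr$p_value, n = cr$n,
               significant = cr$p_value < 0.05, stringsAsFactors = FALSE)
  }))

  kappa <- fleiss_kappa(grade_counts(
    records[, c("grade_rater1", "grade_rater2", "grade_rater3")]))

  structure(list(descriptives = desc, groups = groups, pairwise = pairwise,
                 correlations = correlations, kappa = kappa,
                 n = nrow(records)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(format_study_report(x), sep = "\n")
  invisible(x)
}

#' Plain-text rendering of a study report
#'
#' @param report a `study_report`.
#' @return Character vector of report lines (table-style layout).
#' @export
format_study_report <- function(report) {
  f3 <- function(v) formatC(round_half_away(v * 1000) / 1000, format = "f", digits = 3)
  lines <- c(
    sprintf("Cohort summary (n = %d)", report$n),
    sprintf("  %-22s %10s %8s %10s %10s", "variable", "mean", "sd", "min", "max"))
  for (i in seq_len(nrow(report$descriptives))) {
    d <- report$descriptives[i, ]
    lines <- c(lines, sprintf("  %-22s %10.3f %8.3f %10.3f %10.3f",
                              d$variable, d$mean, d$sd, d$min, d$max))
  }
  lines <- c(lines, "", "Indices by consensus grade (mean +/- SD)")
  for (i in seq_len(nrow(report$groups))) {
    gr <- report$groups[i, ]
    lines <- c(lines, sprintf(
      "  %-3s (n=%3d)  TFI-1 %s+/-%s  TFI-2 %s+/-%s  TFI-3 %s+/-%s",
      gr$grade, gr$n, f3(gr$tfi1_mean), f3(gr$tfi1_sd),
      f3(gr$tfi2_mean), f3(gr$tfi2_sd), f3(gr$tfi3_mean), f3(gr$tfi3_sd)))
  }
  lines <- c(lines, "", "Steel-Dwass pairwise comparisons")
  if (!is.null(report$pairwise)) {
    for (i in seq_len(nrow(report$pairwise))) {
      pw <- report$pairwise[i, ]
      lines <- c(lines, sprintf("  %-5s %s vs %s: t = %7.3f, p = %.4f%s",
                                pw$index, pw$group_a, pw$group_b, pw$t_statistic,
                                pw$p_value, if (pw$p_value < 0.05) " *" else ""))
    }
  }
  lines <- c(lines, "", "Spearman correlations")
  for (i in seq_len(nrow(report$correlations))) {
    cr <- report$correlations[i, ]
    lines <- c(lines, sprintf("  %-12s x %-12s rho = %s, p = %.4f%s",
                              cr$var_x, cr$var_y, f3(cr$rho), cr$p_value,
                              if (cr$significant) " *" else ""))
  }
  k <- report$kappa
  c(lines, "", sprintf("Inter-rater agreement: Fleiss kappa = %s (%d eyes, %d raters)",
                       f3(k$kappa), k$n_items, k$n_raters))
}

#' Write the three report CSVs
#'
#' `report_groups.csv` (grade,n,tfi1_mean,tfi1_sd,...),
#' `report_pairwise.csv` (index,group_a,group_b,n_a,n_b,t_statistic,p_value)
#' and `report_correlations.csv` (var_x,var_y,rho,p_value,n,significant),
#' plus `report_summary.txt`, the plain-text table layout.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 15))
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  wr(report$groups, "report_groups.csv")
  if (!is.null(report$pairwise)) wr(report$pairwise, "report_pairwise.csv")
  wr(report$correlations, "report_correlations.csv")
  writeLines(format_study_report(report), file.path(dir, "report_summary.txt"))
  invisible(dir)
}

#' Read a cohort covariate/grade table
#'
#' Header must be exactly
#' `eye_id,age,axial_length,spherical_equivalent,sfct,nct,grade_rater1,grade_rater2,grade_rater3`
#' with grades `NT`/`WT`/`ST`.
#'
#' @param path CSV path.
#' @return Data frame with those columns.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "age", "axial_length", "spherical_equivalent",
            "sfct", "nct", "grade_rater1", "grade_rater2", "grade_rater3")
  if (!identical(names(df), need))
    stop("cohort CSV header must be exactly: ", paste(need, collapse = ","),
         call. = FALSE)
  df$eye_id <- as.character(df$eye_id)
  df
}

#' @rdname read_cohort_csv
#' @param df cohort data frame.
#' @export
write_cohort_csv <- function(df, path) {
  need <- c("eye_id", "age", "axial_length", "spherical_equivalent",
            "sfct", "nct", "grade_rater1", "grade_rater2", "grade_rater3")
  out <- df[, need]
  for (nm in c("age", "axial_length", "spherical_equivalent", "sfct", "nct"))
    out[[nm]] <- formatC(out[[nm]], format = "g", digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
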
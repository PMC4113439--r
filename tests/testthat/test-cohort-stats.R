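test_that("Spearman rho matches the mid-rank Pearson oracle, including ties", {
  expect_equal(spearman_cor(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(spearman_cor(1:3, 3:1)$rho, -1)
  expect_true(spearman_cor(1:4, c(2, 4, 6, 8))$p_value > 0)

  set.seed(14)
  for (i in 1:20) {
    x <- sample(1:8, 20, TRUE)  # heavy ties
    y <- sample(1:8, 20, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    r <- spearman_cor(x, y)
    expect_equal(r$rho, oracle_pearson(oracle_midranks(x), oracle_midranks(y)),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("Spearman p-value follows the t approximation and matches cor.test", {
  set.seed(15)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r <- spearman_cor(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("Steel-Dwass pair statistic matches the hand computation", {
  # pair {1,2,3} vs {4,5,6} inside a three-group call: untied ranks 1..6,
  # R1 = 6, E = 10.5, V = 5.25
  res <- steel_dwass(c(1, 2, 3, 4, 5, 6, 10, 11, 12),
                     rep(c("NT", "WT", "ST"), each = 3))
  row <- res[res$group_a == "NT" & res$group_b == "WT", ]
  expect_equal(row$t_statistic, -4.5 / sqrt(5.25), tolerance = 1e-12)
  expect_equal(row$p_value,
               ptukey(sqrt(2) * 4.5 / sqrt(5.25), 3, Inf, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(nrow(res), 3)

  expect_error(steel_dwass(rep(5, 6), rep(c("a", "b"), each = 3)), "degenerate")
  expect_error(steel_dwass(1:4, c("a", "a", "a", "b")), "at least 2 observations")
})

test_that("two-group Steel-Dwass reduces to the tie-corrected normal Wilcoxon", {
  set.seed(16)
  for (i in 1:20) {
    x <- sample(1:10, 12, TRUE); y <- sample(2:12, 15, TRUE)
    res <- steel_dwass(c(x, y), rep(c("A", "B"), c(12, 15)))
    r <- rank(c(x, y)); N <- 27
    V <- 12 * 15 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    z <- (sum(r[1:12]) - 12 * (N + 1) / 2) / sqrt(V)
    expect_equal(res$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }
})

test_that("Steel-Dwass p-values are rank-based: invariant to monotone transforms", {
  set.seed(17)
  v <- rnorm(30); g <- rep(c("NT", "WT", "ST"), each = 10)
  a <- steel_dwass(v, g)
  b <- steel_dwass(exp(2 * v) + 5, g)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$t_statistic, b$t_statistic, tolerance = 1e-12)
})

test_that("Fleiss kappa matches hand values and the pair-counting oracle", {
  # unanimity with more than one category used
  counts <- rbind(matrix(rep(c(3, 0, 0), 5), ncol = 3, byrow = TRUE),
                  matrix(rep(c(0, 3, 0), 5), ncol = 3, byrow = TRUE))
  expect_equal(fleiss_kappa(counts)$kappa, 1)
  # 2 items, 2 raters, ratings (A,B) and (B,A): Pbar = 0, kappa = -1
  k2 <- fleiss_kappa(rbind(c(1, 1), c(1, 1)))
  expect_equal(k2$observed_agreement, 0)
  expect_equal(k2$kappa, -1)

  set.seed(18)
  for (i in 1:50) {
    gm <- matrix(sample(c("NT", "WT", "ST"), 50 * 3, TRUE), ncol = 3)
    counts <- grade_counts(gm)
    expect_equal(fleiss_kappa(counts)$kappa, oracle_fleiss(counts),
                 tolerance = 1e-12)
  }
  expect_error(fleiss_kappa(rbind(c(3, 0), c(2, 0))), "unequal row sums")
  expect_error(fleiss_kappa(rbind(c(3, 0), c(3, 0))), "single category")
})

test_that("Fleiss kappa is invariant to category relabeling and item order", {
  set.seed(19)
  gm <- matrix(sample(c("NT", "WT", "ST"), 40 * 3, TRUE), ncol = 3)
  k0 <- fleiss_kappa(grade_counts(gm))$kappa
  relabel <- c(NT = "ST", WT = "NT", ST = "WT")
  gm2 <- matrix(relabel[gm], ncol = 3)
  expect_equal(fleiss_kappa(grade_counts(gm2))$kappa, k0, tolerance = 1e-12)
  expect_equal(fleiss_kappa(grade_counts(gm[sample(40), ]))$kappa, k0,
               tolerance = 1e-12)
})

test_that("ICC(A,1) equals 1 for duplicated sessions and matches aov()", {
  a <- c(1, 4, 2, 8, 5)
  expect_equal(icc_absolute_single(cbind(a, a))$icc, 1)
  # 2x2 hand decomposition: rows (1,2) and (2,1)
  r <- icc_absolute_single(rbind(c(1, 2), c(2, 1)))
  expect_equal(r$ms_rows, 0)
  expect_equal(r$ms_cols, 0)
  expect_equal(r$ms_error, 1)
  expect_equal(r$icc, -Inf)  # formula denominator vanishes

  set.seed(20)
  for (i in 1:20) {
    m <- matrix(rnorm(60), ncol = 2)
    expect_equal(icc_absolute_single(m)$icc, oracle_icc_aov(m),
                 tolerance = 1e-10)
  }
  expect_error(icc_absolute_single(matrix(3, 4, 2)), "zero total variance")
})

test_that("group summaries use sample SD and pool back to the overall mean", {
  rec <- data.frame(
    consensus_grade = rep(c("NT", "WT", "ST"), each = 2),
    tfi1 = c(0.30, 0.32, 0.35, 0.39, 0.40, 0.46),
    tfi2 = c(0.49, 0.50, 0.50, 0.52, 0.52, 0.54),
    tfi3 = c(0.15, 0.16, 0.17, 0.20, 0.21, 0.25))
  gs <- group_summary(rec)
  expect_equal(gs$grade, c("NT", "WT", "ST"))
  expect_equal(gs$tfi1_mean, c(0.31, 0.37, 0.43))
  expect_equal(gs$tfi1_sd[1], sd(c(0.30, 0.32)))
  expect_equal(pooled_mean(gs$tfi1_mean, gs$n), mean(rec$tfi1))

  expect_equal(pooled_mean(c(1, 2), c(1, 1)), 1.5)
  expect_equal(pooled_mean(5, 3), 5)
  expect_error(pooled_mean(c(1, 2), c(1, -1)), "positive")

  rec2 <- rec[rec$consensus_grade != "WT", ]
  expect_warning(group_summary(rec2), "empty grade")
})

test_that("run_study assembles the full report with sensible limits", {
  set.seed(22)
  n <- 45
  sfct <- runif(n, 80, 480)
  tfi3 <- (500 - sfct) / 500          # exact monotone decrease in SFCT
  rec <- data.frame(
    eye_id = sprintf("e%02d", 1:n), age = runif(n, 22, 39),
    axial_length = runif(n, 23, 28),
    spherical_equivalent = runif(n, -10, 0),
    sfct = sfct, nct = sfct - 15,
    grade_rater1 = "NT", grade_rater2 = "NT", grade_rater3 = "NT",
    consensus_grade = rep(c("NT", "WT", "ST"), each = 15),
    tfi1 = tfi3 * 2, tfi2 = 0.4 + tfi3 / 2, tfi3 = tfi3,
    stringsAsFactors = FALSE)
  rec$grade_rater1 <- rec$consensus_grade
  rec$grade_rater2 <- rec$consensus_grade
  rec$grade_rater3[1:5] <- "WT"; rec$grade_rater3[-(1:5)] <- rec$consensus_grade[-(1:5)]
  rep_ <- run_study(rec)
  cors <- rep_$correlations
  expect_equal(cors$rho[cors$var_x == "tfi3" & cors$var_y == "sfct"], -1)
  expect_equal(cors$rho[cors$var_x == "tfi1" & cors$var_y == "sfct"], -1)
  expect_equal(nrow(cors), 11)
  expect_equal(nrow(rep_$pairwise), 9)
  expect_equal(sum(rep_$groups$n), n)
  expect_s3_class(rep_$kappa, "kappa_result")
  txt <- format_study_report(rep_)
  expect_true(any(grepl("Fleiss kappa", txt)))
})

test_that("report CSVs are written with documented headers", {
  set.seed(23)
  n <- 30
  rec <- data.frame(
    eye_id = sprintf("e%02d", 1:n), age = runif(n, 22, 39),
    axial_length = runif(n, 23, 28), spherical_equivalent = runif(n, -8, 0),
    sfct = runif(n, 100, 450), nct = runif(n, 100, 430),
    grade_rater1 = rep(c("NT", "WT", "ST"), each = 10),
    grade_rater2 = rep(c("NT", "WT", "ST"), each = 10),
    grade_rater3 = rep(c("NT", "WT", "ST"), each = 10),
    consensus_grade = rep(c("NT", "WT", "ST"), each = 10),
    tfi1 = runif(n, 0.25, 0.55), tfi2 = runif(n, 0.44, 0.6),
    tfi3 = runif(n, 0.12, 0.32), stringsAsFactors = FALSE)
  rep_ <- run_study(rec)
  dir <- withr::local_tempdir()
  write_study_report(rep_, dir)
  expect_identical(readLines(file.path(dir, "report_groups.csv"))[1],
                   "grade,n,tfi1_mean,tfi1_sd,tfi2_mean,tfi2_sd,tfi3_mean,tfi3_sd")
  expect_identical(readLines(file.path(dir, "report_pairwise.csv"))[1],
                   "index,group_a,group_b,n_a,n_b,t_statistic,p_value")
  expect_identical(readLines(file.path(dir, "report_correlations.csv"))[1],
                   "var_x,var_y,rho,p_value,n,significant")
  expect_true(file.exists(file.path(dir, "report_summary.txt")))
})
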
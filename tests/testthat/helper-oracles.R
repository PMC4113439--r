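# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: membership by explicit distance loops, moments by
# two-pass summation, rank tests by exhaustive permutation, ANOVA by aov().

# brute-force disk rasterization: all pixels of the bounding square whose
# center lies within diameter/2 of the center pixel's center
oracle_disk_pixels <- function(center, diameter, width, height) {
  r <- diameter / 2
  out <- NULL
  for (py in 0:(height - 1)) {
    for (px in 0:(width - 1)) {
      d <- sqrt((px + 0.5 - (center[1] + 0.5))^2 + (py + 0.5 - (center[2] + 0.5))^2)
      if (d <= r) out <- rbind(out, c(px, py))
    }
  }
  out
}

# two-pass mean/SD (population divisor)
oracle_two_pass <- function(v) {
  m <- sum(v) / length(v)
  list(mean = m, sd = sqrt(sum((v - m)^2) / length(v)))
}

# mid-ranks without rank(): sort-based tie averaging
oracle_midranks <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Pearson correlation by explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# pairwise standardized rank-sum statistic (same definition as the package,
# recomputed here so the permutation oracle is self-contained)
oracle_sd_stat <- function(vi, vj) {
  ni <- length(vi); nj <- length(vj); N <- ni + nj
  r <- oracle_midranks(c(vi, vj))
  Ri <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  (Ri - E) / sqrt(V)
}

# exhaustive pair-permutation p: mid-p tail of |t| over all group-i choices,
# mapped through the same studentized-range adjustment as the implementation
oracle_sd_perm_p <- function(vi, vj, k) {
  ni <- length(vi); pooled <- c(vi, vj); N <- length(pooled)
  obs <- abs(oracle_sd_stat(vi, vj))
  idx <- utils::combn(N, ni)
  ts <- apply(idx, 2, function(ii) abs(oracle_sd_stat(pooled[ii], pooled[-ii])))
  pstar <- mean(ts > obs + 1e-9) + 0.5 * mean(abs(ts - obs) <= 1e-9)
  if (pstar <= 0) return(0)
  if (pstar >= 1) return(1)
  ptukey(sqrt(2) * -qnorm(pstar / 2), nmeans = k, df = Inf, lower.tail = FALSE)
}

# Fleiss kappa recomputed independently: per-item agreement by counting
# concordant rater pairs explicitly from a grade matrix
oracle_fleiss <- function(counts) {
  r <- sum(counts[1, ])
  n <- nrow(counts)
  agree <- function(row) {
    pairs <- 0
    for (j in seq_along(row)) pairs <- pairs + row[j] * (row[j] - 1)
    pairs / (r * (r - 1))
  }
  Pbar <- mean(apply(counts, 1, agree))
  pj <- colSums(counts) / (n * r)
  Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}

# ICC(A,1) from an aov() two-way decomposition
oracle_icc_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), times = k)),
                  sess = factor(rep(seq_len(k), each = n)))
  tab <- summary(aov(y ~ subj + sess, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]; msc <- tab["sess", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# random pixel block and its channel_stats
random_stats <- function(n = 50) {
  channel_stats(cbind(sample(1:255, n, TRUE), sample(0:255, n, TRUE),
                      sample(0:255, n, TRUE)))
}

# uniform-color test image
uniform_image <- function(color, w = 40, h = 30, eye_id = "u") {
  px <- array(rep(color, each = w * h), c(h, w, 3))
  fundus_image(px, eye_id)
}
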
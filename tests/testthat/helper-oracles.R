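# Independent oracles used to check the package's fitting and
# classification paths. Deliberately written from the closed-form normal
# equations rather than through the code under test.

ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  num <- (n * sxy - sx * sy)^2
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  list(slope = slope, intercept = intercept,
       r2 = if (den <= 0) 0 else num / den)
}

# Brute-force suffix-subset classifier: the linear-point count is the
# largest k (scanning k = n_valid .. 3) whose top-k-by-amount subset fits
# with R^2 above the threshold, all larger suffixes having failed.
suffix_oracle <- function(amounts, intensities, threshold = 0.95) {
  valid <- !is.na(intensities) & intensities > 0
  a <- amounts[valid]; y <- intensities[valid]
  ord <- order(a); a <- a[ord]; y <- y[ord]
  nv <- length(a)
  if (nv < 3) return(0L)
  for (k in nv:3) {
    idx <- (nv - k + 1):nv
    o <- ols_oracle(log10(a[idx]), log10(y[idx]))
    if (o$r2 > threshold) return(as.integer(k))
  }
  0L
}

# Random calibration peptides spanning mixed noise/floor regimes.
random_peptide_intensities <- function(amounts) {
  coef <- exp(stats::rnorm(1, log(2000), 2))
  cv <- sample(c(0, 0.1, 0.3, 0.6), 1)
  floor_ <- sample(c(0, 20, 200, 2000), 1)
  mu <- coef * amounts
  noise <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
  } else 1
  y <- mu * noise + floor_
  drop <- stats::runif(length(y)) < 0.1  # sporadic missingness
  y[drop] <- NA_real_
  y
}
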
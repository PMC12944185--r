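# First-order intensity statistics (18 features). Entropy and Uniformity are
# computed on the fixed-bin-width discretized histogram; all moments use the
# population (1/N) convention. Zero-variance input returns Skewness and
# Kurtosis of 0 so degenerate ROIs never produce NaN.

firstOrderFeatureNames <- function() c(
  "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
  "Kurtosis", "Maximum", "MeanAbsoluteDeviation", "Mean", "Median", "Minimum",
  "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
  "TotalEnergy", "Uniformity", "Variance"
)

firstOrderFeatures <- function(values, binWidth, voxelVolume = 1) {
  n <- length(values)
  stopifnot(n > 0)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inner <- values[values >= q[1] & values <= q[5]]
  p <- tabulate(discretizeValues(values, binWidth))
  p <- p[p > 0] / n
  energy <- sum(values^2)
  c(
    "10Percentile" = q[1],
    "90Percentile" = q[5],
    Energy = energy,
    Entropy = -sum(p * log2(p)),
    InterquartileRange = q[4] - q[2],
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    Mean = mu,
    Median = q[3],
    Minimum = min(values),
    Range = max(values) - min(values),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(energy / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = voxelVolume * energy,
    Uniformity = sum(p^2),
    Variance = m2
  )
}
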
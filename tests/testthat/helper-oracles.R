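# Independent brute-force oracles used to cross-check the closed-form
# implementations. Deliberately written as naive loops over the definitions.

# Global Moran's I by explicit double sum
moran_brute <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Gi* z-score for one point by direct evaluation of the Ord-Getis formula
gi_star_brute <- function(values, w, i) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  Wi <- sum(w[i, ])
  S1i <- sum(w[i, ]^2)
  num <- sum(w[i, ] * values) - xbar * Wi
  num / (S * sqrt((n * S1i - Wi^2) / (n - 1)))
}

# Least squares via explicit normal equations for the QI design
qi_normal_equations <- function(obs) {
  vf <- as.matrix(obs[, c("vf1", "vf2", "vf3", "vf4")])
  ind <- (vf > 0) * 1
  X <- cbind(ind, rowSums(ind * vf^2 / obs$vg))
  solve(t(X) %*% X, t(X) %*% obs$qi)[, 1]
}

# a modest random simplex
runif_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}
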
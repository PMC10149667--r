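# Independent oracles used to freeze expected values. These deliberately
# take different code paths from the package implementation.

# Passing-Bablok slope/intercept by literal double-loop enumeration and
# index arithmetic on the sorted slope list.
pb_oracle <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] != x[j]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- length(slopes[slopes < -1])
  half <- N / 2
  slope <- if (N %% 2 == 1) {
    slopes[(N + 1) / 2 + K]
  } else {
    (slopes[half + K] + slopes[half + 1 + K]) / 2
  }
  list(slope = slope, intercept = median(y - slope * x))
}

# Geometric sphere fit by direct Nelder-Mead over (center, radius) from the
# centroid start; independent of the package's algebraic + Gauss-Newton path.
sphere_oracle <- function(points) {
  P <- as.matrix(points[, c("x", "y", "z")])
  start <- c(colMeans(P), mean(sqrt(rowSums(sweep(P, 2, colMeans(P))^2))))
  obj <- function(par) {
    d <- sqrt(rowSums(sweep(P, 2, par[1:3])^2))
    sum((d - par[4])^2)
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  list(center = unname(fit$par[1:3]), radius = unname(fit$par[4]))
}

canonical_phantom <- function(...) {
  build_canonical_landmarks(phantom_spec(...))
}

six_angles <- function(landmarks) {
  unlist(measure_all(landmarks)[, c("fta_nc", "fta_nbc", "fia_nc",
                                    "fia_nbc", "fva_pd", "fva_td")])
}
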
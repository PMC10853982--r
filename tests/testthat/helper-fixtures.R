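# Shared fixtures and independent oracles, all built in code.

# Small cohort configuration for fast unit tests.
small_config <- function(seed = 1, ...) {
  simulation_config(
    seed = seed,
    group_sizes = c(HC = 15, RRMS = 15, SPMS = 8, PPMS = 8),
    template = list(grid_dim = c(12L, 12L, 12L), streamlines_per_tract = 10L),
    ...)
}

# Hand-built 4-fixel template with 3 streamlines, for connectivity oracles:
# s1 = {0,1}, s2 = {0,1,2}, s3 = {2,3}.
toy_template <- function() {
  fx <- data.frame(
    fixel_id = 0:3, i = 0:3, j = 0L, k = 0L,
    dx = 1, dy = 0, dz = 0,
    tract = c("ATR_L", "ATR_L", "ATR_R", "ATR_R"),
    stringsAsFactors = FALSE)
  structure(list(grid_dim = c(4L, 1L, 1L), voxel_size = 1.25, fixels = fx,
                 streamlines = list(c(0L, 1L), c(0L, 1L, 2L), c(2L, 3L)),
                 tract_names = c("ATR_L", "ATR_R")),
            class = "fixel_template")
}

# Monte-Carlo disc-area oracle for the fibre cross-section: maps a dense set
# of random points on the unit circle perpendicular to v through J, projects
# out the warped fibre direction, and measures the polygon area of the image
# relative to the original disc. Independent of the package's closed form.
fc_disc_oracle <- function(J, v, K = 20000) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * v) * v; u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  ang <- stats::runif(K, 0, 2 * pi)
  P <- outer(cos(ang), u) + outer(sin(ang), w)
  Q <- P %*% t(J)
  nv <- drop(J %*% v); nv <- nv / sqrt(sum(nv^2))
  Qp <- Q - outer(drop(Q %*% nv), nv)
  b1 <- Qp[1, ]; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(nv[2] * b1[3] - nv[3] * b1[2], nv[3] * b1[1] - nv[1] * b1[3],
          nv[1] * b1[2] - nv[2] * b1[1])
  x <- drop(Qp %*% b1); y <- drop(Qp %*% b2)
  o <- order(atan2(y, x))
  x <- x[o]; y <- y[o]
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / pi
}

random_posdet_jacobian <- function() {
  repeat {
    J <- diag(3) * stats::runif(1, 0.7, 1.3) + matrix(stats::rnorm(9, 0, 0.15), 3)
    if (det(J) > 0.05) return(J)
  }
}

# Direct-summation CFE oracle (explicit loops over fixels and thresholds).
cfe_brute <- function(t, Cmat, dh = 0.1, E = 2, C = 0.5, H = 3) {
  Cmat <- as.matrix(Cmat)
  e <- numeric(length(t))
  for (i in seq_along(t)) {
    if (t[i] <= 0) next
    K <- floor(t[i] / dh + 1e-9)
    for (k in seq_len(K)) {
      h <- k * dh
      supp <- sum(Cmat[i, ]^C * (t >= h - 1e-12))
      e[i] <- e[i] + dh * h^H * supp^E
    }
  }
  e
}

# Brute-force partial F for a group effect given covariates, via explicit
# normal equations (independent of stats::lm).
partial_f_oracle <- function(y, group, covs) {
  g <- as.factor(group)
  Xg <- stats::model.matrix(~g)
  Xc <- cbind(1, as.matrix(covs))
  Xf <- cbind(Xg, as.matrix(covs))
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  q <- nlevels(g) - 1
  n <- length(y); p <- ncol(Xf)
  Fv <- ((rss(Xc) - rss(Xf)) / q) / (rss(Xf) / (n - p))
  list(F = Fv, p = stats::pf(Fv, q, n - p, lower.tail = FALSE))
}
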
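# Shared fixtures and independent oracles, all built in code.

# brute-force farthest pair via a full distance matrix (different route
# from the package's blocked row scan)
brute_farthest <- function(P) {
  D <- as.matrix(stats::dist(P))
  w <- which(D == max(D), arr.ind = TRUE)
  w <- w[w[, 1] < w[, 2], , drop = FALSE]
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  as.integer(w[1, ])
}

# brute-force sum-distance scores with an explicit double loop
brute_scores <- function(P, V) {
  f <- numeric(nrow(P))
  for (i in seq_len(nrow(P)))
    for (j in seq_len(nrow(V)))
      f[i] <- f[i] + sqrt(sum((P[i, ] - V[j, ])^2))
  f
}

# coarse-to-fine grid minimization of total distance to 3 points:
# an independent Fermat-point oracle at ~1e-3 resolution
grid_fermat <- function(a, b, c, final_step = 1e-3) {
  tot <- function(x, y) {
    sqrt((x - a[1])^2 + (y - a[2])^2) +
      sqrt((x - b[1])^2 + (y - b[2])^2) +
      sqrt((x - c[1])^2 + (y - c[2])^2)
  }
  lo <- pmin(a, b, c); hi <- pmax(a, b, c)
  ctr <- (lo + hi) / 2
  span <- max(hi - lo)
  repeat {
    xs <- seq(ctr[1] - span / 2, ctr[1] + span / 2, length.out = 61L)
    ys <- seq(ctr[2] - span / 2, ctr[2] + span / 2, length.out = 61L)
    g <- outer(xs, ys, tot)
    w <- which(g == min(g), arr.ind = TRUE)[1, ]
    ctr <- c(xs[w[1]], ys[w[2]])
    step <- span / 60
    if (step <= final_step / 2) return(ctr)
    span <- 4 * step
  }
}

# a jittered regular m-gon trial (returns points + true vertices)
mgon_trial <- function(m, seed, radius = 80) {
  set.seed(seed)
  rot <- runif(1, 0, 2 * pi)
  sp <- shape_spec("polygon", m = m, radius = radius, rotation = rot,
                   center = c(150, 150), dim = c(300L, 300L), seed = seed)
  sample_boundary(sp)
}

# an L-shaped (concave, 6-vertex) polygon trial
lshape_trial <- function(seed, w = 50) {
  V <- rbind(c(20, 20), c(20 + 2 * w, 20), c(20 + 2 * w, 20 + w),
             c(20 + w, 20 + w), c(20 + w, 20 + 2 * w), c(20, 20 + 2 * w))
  sp <- shape_spec("polygon", vertices = V, dim = c(200L, 200L), seed = seed)
  list(boundary = sample_boundary(sp), vertices = V)
}

# a touching-pair trial with mild realistic variation
touching_trial <- function(seed) {
  tr <- seed %% 1000
  shape_spec("touching", seed = seed,
             axes = c(88 + 4 * sin(tr), 52 + 3 * cos(tr)),
             angle = (tr %% 7 - 3) * 0.1)
}

# a bean trial with mild variation
bean_trial <- function(seed) {
  tr <- seed %% 1000
  shape_spec("bean", seed = seed,
             axes = c(42 + 8 * abs(sin(tr)), 26 + 6 * abs(cos(tr))),
             angle = (tr %% 7 - 3) * 0.1,
             waist = 0.52 + 0.08 * abs(sin(tr * 3)))
}

# do the sequence's acute vertices sit within one position of each true
# junction's nearest vertex?
junctions_hit <- function(fit, labeled, junctions) {
  V <- coef(fit)
  k <- nrow(V)
  acute <- which(labeled$nonsmooth)
  all(vapply(seq_len(nrow(junctions)), function(j) {
    ji <- which.min((V[, 1] - junctions[j, 1])^2 +
                      (V[, 2] - junctions[j, 2])^2)
    any(abs(((acute - ji) %% k + k) %% k) %in% c(0L, 1L, k - 1L))
  }, logical(1)))
}

.d2 <- function(p, q) sqrt(sum((p - q)^2))
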
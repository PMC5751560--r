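test_that("farthest pair equals the brute-force scan", {
  expect_error(farthest_pair(rbind(c(1, 1))), "at least 2")
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  fp <- farthest_pair(sq)
  expect_equal(.d2(fp$points[1, ], fp$points[2, ]), sqrt(2))
  two <- rbind(c(3, 1), c(-2, 5))
  expect_equal(farthest_pair(two)$index, c(1L, 2L))
  # ellipse: the pair straddles the major axis ends
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  el <- cbind(10 * cos(th), 3 * sin(th))
  fe <- farthest_pair(el)
  expect_equal(abs(fe$points[, 1]), c(10, 10), tolerance = 1e-9)
  set.seed(21)
  for (i in 1:25) {
    P <- matrix(runif(2 * sample(5:300, 1), 0, 100), ncol = 2)
    P <- P[!duplicated(P), , drop = FALSE]
    expect_equal(sort(farthest_pair(P)$index), sort(brute_farthest(P)))
  }
})

test_that("sum-distance scores match the brute-force double loop", {
  s <- dominant_seq(rbind(c(3, 4), c(0, 0)))
  expect_equal(sum_distance_scores(rbind(c(0, 0)), s), 5)
  expect_length(sum_distance_scores(matrix(numeric(0), 0, 2), s), 0)
  set.seed(9)
  for (i in 1:20) {
    P <- matrix(runif(2 * 80, 0, 50), ncol = 2)
    V <- matrix(runif(2 * sample(2:6, 1), 0, 50), ncol = 2)
    if (anyDuplicated(V)) next
    f <- sum_distance_scores(P, dominant_seq(V))
    fb <- brute_scores(P, V)
    expect_equal(f, fb)
    expect_equal(which.max(f), which.max(fb))
    expect_equal(which.min(f), which.min(fb))
    expect_equal(order(f)[(nrow(P) + 1) %/% 2], order(fb)[(nrow(P) + 1) %/% 2])
  }
})

test_that("balance ratio is min/max of slot-endpoint distances with a degenerate convention", {
  s <- dominant_seq(rbind(c(0, 0), c(4, 0), c(4, 4)))
  expect_equal(balance_ratio(c(2, 1), s, 1), 1)          # equidistant
  expect_equal(balance_ratio(c(1, 0), s, 1), 1 / 3)      # 1 vs 3
  expect_equal(balance_ratio(c(0, 0), s, 1), 0)          # endpoint coincidence
  expect_error(balance_ratio(c(0, 0), s, 9), "out of range")
})

test_that("candidate selection follows the largest balance ratio with measure priority", {
  mk <- function(measure, ratio) list(point = c(0, 0), index = 1L, measure = measure,
                                      slot = 1L, confidence = 0, ratio = ratio)
  expect_identical(select_candidate(list(mk("max", .9), mk("min", .4)))$measure, "max")
  expect_identical(select_candidate(list(mk("max", .2), mk("min", .2)))$measure, "max")
  expect_identical(select_candidate(list(mk("max", .1), mk("min", .2), mk("median", .7)))$measure, "median")
  expect_error(select_candidate(list()), "no candidates")
})

test_that("best slot places a corner between the pair it lies between", {
  tri <- dominant_seq(rbind(c(4, 0), c(4, 4), c(0, 4)))
  C <- rbind(cbind(4, seq(0, 4, by = .25)), cbind(seq(4, 0, by = -.25), 4),
             cbind(0, seq(4, 0, by = -.25)), cbind(seq(0, 4, by = .25), 0))
  bs <- best_slot(tri, c(0, 0), confidence = "count", C = C)
  expect_identical(bs$slot, 3L)   # between (0,4) and (4,0) in cyclic order
  bl <- best_slot(tri, c(0, 0), confidence = "length")
  expect_identical(bl$slot, 3L)
  one_open <- dominant_seq(rbind(c(0, 0), c(2, 0), c(2, 2)),
                           closed = c(TRUE, TRUE, FALSE))
  expect_identical(best_slot(one_open, c(1, 1), "length")$slot, 3L)
  all_closed <- dominant_seq(rbind(c(0, 0), c(2, 0)), closed = c(TRUE, TRUE))
  expect_error(best_slot(all_closed, c(1, 1)), "terminal")
})

test_that("closedness requires dense coverage and sheds covering points", {
  v <- c(0, 0); w <- c(40, 0)
  on_seg <- cbind(seq(0, 40, by = 1), 0)
  far <- cbind(runif(10, 0, 40), runif(10, 20, 30))
  r <- test_closedness(v, w, rbind(on_seg, far))
  expect_true(r$closed)
  expect_equal(nrow(r$P), 10)          # the on-segment chain is removed
  half <- cbind(seq(0, 19, by = 1), 0)
  r2 <- test_closedness(v, w, rbind(half, far))
  expect_false(r2$closed)
  expect_equal(nrow(r2$P), 30)         # unchanged
  r3 <- test_closedness(v, w, matrix(numeric(0), 0, 2))
  expect_false(r3$closed)
})

test_that("reduction partitions surviving points by open pair and conserves points", {
  sb <- lshape_trial(31)$boundary
  fit0 <- kdp(sb$points, kdp_control(max_depth = 0))   # stop before recursion
  red <- reduce_point_set(sb$points, fit0$sequence)
  n_sub <- sum(vapply(red$subsets, function(s) nrow(s$points), integer(1)))
  expect_equal(n_sub + nrow(red$removed), nrow(sb$points))
  expect_gte(length(red$subsets), 1)
  for (s in red$subsets) expect_false(red$closed[s$slot])
})

test_that("jittered convex polygons are recovered exactly at their corners", {
  for (m in c(4, 6, 8)) {
    sb <- mgon_trial(m, seed = 100 + m)
    fit <- kdp(sb$points)
    V <- coef(fit)
    expect_equal(nrow(V), m)
    d <- vapply(seq_len(m), function(i)
      min(sqrt((V[, 1] - sb$truth$vertices[i, 1])^2 +
                 (V[, 2] - sb$truth$vertices[i, 2])^2)), numeric(1))
    expect_lt(max(d), 2)
  }
})

test_that("concave L-shapes recover all six corners through at least one reduction", {
  tr <- lshape_trial(77)
  fit <- kdp(tr$boundary$points)
  expect_identical(nrow(coef(fit)), 6L)
  d <- vapply(1:6, function(i)
    min(sqrt((coef(fit)[, 1] - tr$vertices[i, 1])^2 +
               (coef(fit)[, 2] - tr$vertices[i, 2])^2)), numeric(1))
  expect_lt(max(d), 2)
  expect_gte(fit$trace$reductions, 1)
})

test_that("max-only agrees with the full measure scheme on convex inputs", {
  for (m in c(4, 5, 6)) {
    sb <- mgon_trial(m, seed = 300 + m)
    v1 <- coef(kdp(sb$points, kdp_control(measure = "max_only")))
    v2 <- coef(kdp(sb$points, kdp_control(measure = "max_min_median")))
    expect_equal(nrow(v1), nrow(v2))
    # same vertex set (order-independent)
    reorder <- function(V) V[order(V[, 1], V[, 2]), ]
    expect_equal(reorder(v1), reorder(v2), tolerance = 1e-9)
  }
})

test_that("polyline-length confidence never decreases across insertions", {
  for (sd in c(55, 56)) {
    sb <- mgon_trial(5, seed = sd)
    fit <- kdp(sb$points)
    expect_true(all(vapply(fit$trace$conf, function(v) all(diff(v) >= -1e-9), logical(1))))
  }
  sp <- touching_trial(1234)
  fit <- kdp(sample_boundary(sp)$points)
  expect_true(all(vapply(fit$trace$conf, function(v) all(diff(v) >= -1e-9), logical(1))))
})

test_that("the fit object supports the standard methods", {
  sb <- mgon_trial(4, seed = 12)
  fit <- kdp(sb$points)
  expect_s3_class(fit, "kdp")
  expect_output(print(fit), "dominant points")
  expect_output(print(summary(fit)), "Residual")
  expect_true(is.matrix(coef(fit)))
  r <- residuals(fit)
  expect_length(r, nrow(fit$points))
  expect_true(all(r >= -1e-12))
  df <- as.data.frame(fit)
  expect_named(df, c("order", "x", "y", "closed_next"))
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})

test_that("sequences round-trip through CSV", {
  s <- dominant_seq(rbind(c(0, 0), c(5, 1), c(4, 6)), closed = c(TRUE, FALSE, TRUE))
  f <- tempfile(fileext = ".csv")
  write_sequence_csv(s, f)
  s2 <- read_sequence_csv(f)
  expect_equal(s2$vertices, s$vertices)
  expect_identical(s2$closed, s$closed)
  unlink(f)
  p <- tempfile(fileext = ".csv")
  pts <- matrix(runif(20), ncol = 2, dimnames = list(NULL, c("x", "y")))
  write_points_csv(pts, p)
  expect_equal(read_points_csv(p), as_points(pts))
  unlink(p)
})
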
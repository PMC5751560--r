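test_that("point-segment sum distance matches closed forms and rejects degenerate segments", {
  expect_equal(point_segment_sum_distance(c(0, 1), c(-1, 0), c(1, 0)), 2 * sqrt(2))
  expect_equal(point_segment_sum_distance(c(1, 0), c(0, 0), c(2, 0)), 2)
  expect_error(point_segment_sum_distance(c(3, 4), c(0, 0), c(0, 0)), "degenerate")
})

test_that("sum distance is bounded below by segment length, with equality on the segment", {
  set.seed(42)
  for (i in 1:200) {
    a <- runif(2, -5, 5); b <- runif(2, -5, 5)
    if (all(a == b)) next
    p <- runif(2, -10, 10)
    expect_gte(point_segment_sum_distance(p, a, b), sqrt(sum((a - b)^2)) - 1e-12)
    t <- runif(1)
    on_seg <- a + t * (b - a)
    expect_equal(point_segment_sum_distance(on_seg, a, b), sqrt(sum((a - b)^2)))
  }
})

test_that("insertability follows the relative bound over open pairs and is monotone in eps", {
  seq2 <- dominant_seq(rbind(c(0, 0), c(2, 0)))
  expect_true(is_insertable(c(1, 0), seq2, eps = 0))
  expect_false(is_insertable(c(1, 10), seq2, eps = 0.02))
  expect_true(is_insertable(c(1, 0.1), seq2, eps = 0.02))   # 2*sqrt(1.01) <= 2.04
  # monotone in eps
  set.seed(7)
  for (i in 1:50) {
    p <- runif(2, -1, 3)
    e1 <- runif(1, 0, 0.05); e2 <- e1 + runif(1, 0, 0.05)
    if (is_insertable(p, seq2, e1)) expect_true(is_insertable(p, seq2, e2))
  }
  # closed pairs are excluded
  closed2 <- dominant_seq(rbind(c(0, 0), c(2, 0)), closed = c(TRUE, TRUE))
  expect_false(is_insertable(c(1, 0), closed2, eps = 0.02))
  expect_error(is_insertable(c(0, 0), dominant_seq(rbind(c(0, 0)))), "at least 2")
})

test_that("coverage-count confidence counts points on polyline edges", {
  sq <- dominant_seq(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  on_edges <- rbind(cbind(seq(0.05, 0.95, length.out = 3), 0),
                    cbind(1, seq(0.1, 0.9, length.out = 3)),
                    cbind(seq(0.9, 0.1, length.out = 2), 1),
                    cbind(0, seq(0.8, 0.2, length.out = 2)))
  expect_identical(confidence_count(sq, on_edges, tol = 0), 10L)
  far <- cbind(runif(5, 4, 9), runif(5, 4, 9))
  expect_identical(confidence_count(sq, rbind(on_edges, far), tol = 0.02), 10L)
  expect_identical(confidence_count(sq, matrix(numeric(0), 0, 2)), 0L)
})

test_that("polyline-length confidence is the cyclic perimeter", {
  expect_equal(confidence_length(dominant_seq(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))), 4)
  expect_equal(confidence_length(dominant_seq(rbind(c(0, 0), c(3, 4)))), 10)
  expect_error(dominant_seq(rbind(c(1, 2), c(1, 2))), "distinct")
})

test_that("insertion never decreases polyline-length confidence", {
  set.seed(11)
  for (i in 1:50) {
    V <- matrix(runif(8, 0, 10), ncol = 2)
    if (anyDuplicated(V)) next
    s <- dominant_seq(V)
    v <- runif(2, 0, 10)
    slot <- sample(4, 1)
    gain <- confidence_length(seq_insert(s, v, slot)) - confidence_length(s)
    a <- V[slot, ]; b <- V[slot %% 4 + 1, ]
    expect_equal(gain, .d2(v, a) + .d2(v, b) - .d2(a, b))
    expect_gte(gain, -1e-12)
  }
})

test_that("Fermat point matches grid brute force and the >=120-degree vertex rule", {
  # symmetric cases
  eq <- rbind(c(1, 0), c(cos(2 * pi / 3), sin(2 * pi / 3)), c(cos(4 * pi / 3), sin(4 * pi / 3)))
  expect_equal(fermat_point(eq[1, ], eq[2, ], eq[3, ]), c(0, 0), tolerance = 1e-9)
  # obtuse (150 degrees at a): Fermat point is a
  a <- c(0, 0); b <- c(1, 0)
  c150 <- a + 0.8 * c(cos(150 * pi / 180), sin(150 * pi / 180))
  expect_equal(fermat_point(a, b, c150), a)
  expect_error(fermat_point(c(0, 0), c(1, 1), c(2, 2)), "collinear")
  # grid-oracle agreement on random triangles
  set.seed(5)
  for (i in 1:25) {
    tri <- matrix(runif(6), ncol = 2)
    area <- abs((tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
                  (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
    if (area < 0.05) next
    fp <- fermat_point(tri[1, ], tri[2, ], tri[3, ])
    or <- grid_fermat(tri[1, ], tri[2, ], tri[3, ])
    expect_lt(sqrt(sum((fp - or)^2)), 2e-3)
  }
})

test_that("vertex angle is the arccos of normalized directions and symmetric", {
  expect_equal(vertex_angle(c(0, 1), c(0, 0), c(1, 0)), pi / 2)
  expect_equal(vertex_angle(c(-1, 0), c(0, 0), c(1, 0)), pi)
  expect_equal(vertex_angle(c(1, 0.1), c(0, 0), c(1, -0.1)),
               acos(sum(c(1, .1) * c(1, -.1)) / sum(c(1, .1)^2)))
  set.seed(3)
  for (i in 1:50) {
    u <- runif(2); v <- runif(2); w <- runif(2)
    if (all(u == v) || all(w == v)) next
    expect_equal(vertex_angle(u, v, w), vertex_angle(w, v, u))
  }
  expect_error(vertex_angle(c(0, 0), c(0, 0), c(1, 0)), "coincident")
})
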
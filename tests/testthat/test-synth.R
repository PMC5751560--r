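test_that("identical specs generate identical output", {
  sp <- shape_spec("ellipse", seed = 99)
  b1 <- sample_boundary(sp); b2 <- sample_boundary(sp)
  expect_identical(b1, b2)
  r1 <- render_image(sp); r2 <- render_image(sp)
  expect_identical(r1, r2)
  # and the RNG state of the session is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(sample_boundary(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("polygon boundaries are sampled at the requested spacing", {
  sq <- shape_spec("polygon",
                   vertices = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * 1 + 50,
                   spacing = 0.1, jitter = 0, seed = 1)
  sb <- sample_boundary(sq)
  expect_identical(nrow(sb$points), 40L)
  # all exactly on the perimeter
  expect_true(all(abs(sb$points[, 1] - 50) < 1e-9 | abs(sb$points[, 1] - 51) < 1e-9 |
                    abs(sb$points[, 2] - 50) < 1e-9 | abs(sb$points[, 2] - 51) < 1e-9))
})

test_that("jittered samples stay within 4 sigma of the clean curve", {
  sp <- shape_spec("ellipse", seed = 17)
  sb <- sample_boundary(sp)
  d <- sqrt(rowSums((sb$points - sb$clean[seq_len(nrow(sb$points)), ])^2))
  expect_gte(mean(d <= 4 * 0.5 * sqrt(2)), 0.999)
})

test_that("touching specs carry exactly two junction points and reject non-intersecting pairs", {
  sp <- shape_spec("touching", seed = 2)
  expect_identical(nrow(sp$junctions), 2L)
  expect_error(shape_spec("touching", offset = 500, seed = 2), "exactly 2")
})

test_that("the bean curve has exactly two curvature sign changes and obtuse inflections", {
  sp <- shape_spec("bean", seed = 3)
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  C <- kdomseg:::.bean_xy(th, sp)
  dx <- diff(C[c(seq_len(2000), 1, 2), 1])
  dy <- diff(C[c(seq_len(2000), 1, 2), 2])
  cr <- dx[-2001] * dy[-1] - dy[-2001] * dx[-1]
  sgn <- sign(cr)
  flips <- sum(sgn != c(sgn[-1], sgn[1]))
  expect_identical(flips, 2L)
  sb <- sample_boundary(sp)
  expect_identical(nrow(sb$truth$inflections), 2L)
})

test_that("bean waist depths outside (0.5, 1) are rejected", {
  expect_error(shape_spec("bean", waist = 0.4), "waist")
  expect_error(shape_spec("bean", waist = 1.1), "waist")
})

test_that("rendering is deterministic, canvas-checked, and masks match truth at zero noise", {
  sp0 <- shape_spec("ellipse", noise = 0, seed = 5)
  r <- render_image(sp0)
  expect_identical(r$image > 0.4, r$masks[[1]])
  expect_error(render_image(shape_spec("ellipse", axes = c(300, 80), seed = 1)),
               "canvas")
  # touching renders one gray level and two truth masks
  rt <- render_image(shape_spec("touching", seed = 6))
  expect_length(rt$masks, 2)
  flat <- render_image(shape_spec("touching", noise = 0, seed = 6))$image
  expect_identical(sort(unique(round(as.numeric(flat), 3))), c(0.15, 0.65))
})

test_that("the packaged benchmark has the documented composition", {
  bench <- synth_benchmark(seed = 3, n_ellipse = 2, n_bean = 2, n_touching = 1)
  expect_length(bench, 5)
  expect_identical(vapply(bench, `[[`, character(1), "kind"),
                   c("ellipse", "ellipse", "bean", "bean", "touching"))
  expect_identical(vapply(bench, function(e) length(e$truth), integer(1)),
                   c(1L, 1L, 1L, 1L, 2L))
  # deterministic in the master seed
  bench2 <- synth_benchmark(seed = 3, n_ellipse = 2, n_bean = 2, n_touching = 1)
  expect_identical(bench, bench2)
})
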
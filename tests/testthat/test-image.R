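test_that("edge detection is empty on flat input and rings an ellipse", {
  expect_false(any(detect_edges(matrix(0.5, 60, 80))))
  sp <- shape_spec("ellipse", axes = c(30, 18), dim = c(100L, 120L), noise = 0, seed = 1)
  r <- render_image(sp)
  edges <- detect_edges(r$image)
  expect_gt(sum(edges), 100)
  # every edge pixel within ~1.5 px of the true boundary ring
  w <- which(edges, arr.ind = TRUE)
  ex <- w[, 2] - 1; ey <- w[, 1] - 1
  u <- (ex - sp$center[1]) / sp$axes[1]; v <- (ey - sp$center[2]) / sp$axes[2]
  rad <- sqrt(u^2 + v^2)
  boundary_dist <- abs(rad - 1) * min(sp$axes)
  expect_lt(max(boundary_dist), 2.5)
  # near-flat noise with a high threshold stays near-empty
  set.seed(2)
  noisy <- matrix(runif(60 * 80, 0.49, 0.51), 60, 80)
  expect_lt(sum(detect_edges(noisy, high = 0.9)), 20)
  expect_error(detect_edges(array(0.5, c(10, 10, 3))), "convert_rgb")
})

test_that("components are 8-connected and selectable by size or centrality", {
  m <- matrix(FALSE, 40, 60)
  m[10, 5:20] <- TRUE          # a 16-px line
  m[30:31, 40:45] <- TRUE      # a 12-px blob
  m[20, 30] <- TRUE; m[21, 31] <- TRUE   # diagonal touch: one component
  comps <- edge_components(m)
  expect_length(comps, 3)
  expect_identical(select_component(comps, "largest")$npix, 16L)
  ctr <- select_component(comps, "center", dim = dim(m))
  expect_identical(ctr$npix, 2L)   # the diagonal pair sits nearest the center
  expect_error(select_component(list(), "largest"), "no component")
  expect_error(select_component(comps, "center"), "dimensions")
})

test_that("component point coordinates follow the raster convention", {
  m <- matrix(FALSE, 10, 12)
  m[3, 7] <- TRUE
  cp <- edge_components(m)[[1]]
  expect_equal(unname(cp$points[1, ]), c(6, 2))  # x = col-1, y = row-1
})

test_that("grayscale PNG round-trips through disk", {
  img <- matrix(seq(0, 1, length.out = 48), 6, 8)
  f <- tempfile(fileext = ".png")
  write_gray_png(img, f)
  back <- read_gray_image(f)
  expect_equal(back, img, tolerance = 1 / 255)
  mask <- img > 0.5
  fm <- tempfile(fileext = ".png")
  write_mask_png(mask, fm)
  expect_identical(read_gray_image(fm) > 0.5, mask)
  unlink(c(f, fm))
})
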
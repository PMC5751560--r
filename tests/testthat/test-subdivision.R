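test_that("regular octagons are smooth everywhere", {
  th <- 2 * pi * (0:7) / 8
  oct <- dominant_seq(cbind(60 + 40 * cos(th), 60 + 40 * sin(th)))
  lab <- label_vertices(oct)
  expect_false(any(lab$nonsmooth))
  expect_equal(lab$angles, rep(3 * pi / 4, 8), tolerance = 1e-9)
  expect_error(label_vertices(dominant_seq(rbind(c(0, 0), c(1, 0)))), "at least 3")
})

test_that("splitting cuts the cycle at nonsmooth vertices with shared endpoints", {
  th <- 2 * pi * (0:7) / 8
  oct <- dominant_seq(cbind(60 + 40 * cos(th), 60 + 40 * sin(th)))
  lab <- label_vertices(oct)

  # 0 nonsmooth: one closed subsequence
  subs <- split_at_nonsmooth(lab)
  expect_length(subs, 1)
  expect_false(subs[[1]]$open)
  expect_identical(subs[[1]]$parent_index, 1:8)

  # forcing 2 nonsmooth: two open arcs sharing the cut vertices
  lab2 <- lab
  lab2$nonsmooth <- rep(FALSE, 8); lab2$nonsmooth[c(2, 6)] <- TRUE
  subs2 <- split_at_nonsmooth(lab2)
  expect_length(subs2, 2)
  expect_true(all(vapply(subs2, `[[`, logical(1), "open")))
  expect_identical(subs2[[1]]$parent_index, 2:6)
  expect_identical(subs2[[2]]$parent_index, c(6:8, 1:2))
  # interior vertices once, nonsmooth twice
  idx <- unlist(lapply(subs2, `[[`, "parent_index"))
  expect_identical(sort(as.integer(table(idx)[c("2", "6")])), c(2L, 2L))
  expect_true(all(table(idx)[!names(table(idx)) %in% c("2", "6")] == 1))

  # 1 nonsmooth: a single open full tour starting and ending at the cut
  lab1 <- lab; lab1$nonsmooth <- rep(FALSE, 8); lab1$nonsmooth[3] <- TRUE
  subs1 <- split_at_nonsmooth(lab1)
  expect_length(subs1, 1)
  expect_identical(subs1[[1]]$parent_index, c(3:8, 1:2, 3L))

  # all nonsmooth: k degenerate 2-vertex arcs
  laba <- lab; laba$nonsmooth <- rep(TRUE, 8)
  subsa <- split_at_nonsmooth(laba)
  expect_length(subsa, 8)
  expect_true(all(vapply(subsa, function(s) nrow(s$vertices), integer(1)) == 2L))
})

test_that("the longest smooth subsequence is the longer arc, ties going first", {
  V <- rbind(c(0, 0), c(10, 0), c(14, 3), c(10, 6), c(0, 6), c(-1, 3))
  lab <- label_vertices(dominant_seq(V))
  lab$nonsmooth <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  best <- longest_smooth_subsequence(lab)
  expect_identical(best$parent_index, c(2:6, 1L))   # the long way round
})

test_that("raising the angle threshold never decreases the nonsmooth count", {
  sp <- touching_trial(881)
  fit <- kdp(sample_boundary(sp)$points)
  counts <- vapply(seq(0.3, 2.8, by = 0.25), function(th)
    sum(label_vertices(fit$sequence, th)$nonsmooth), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("touching-pair sequences show two acute junction vertices, bean sequences none", {
  sp <- touching_trial(4242)
  sb <- sample_boundary(sp)
  fit <- kdp(sb$points)
  lab <- label_vertices(fit$sequence)
  expect_identical(sum(lab$nonsmooth), 2L)
  expect_true(junctions_hit(fit, lab, sb$truth$junctions))

  bp <- bean_trial(4243)
  fb <- kdp(sample_boundary(bp)$points)
  expect_identical(sum(label_vertices(fb$sequence)$nonsmooth), 0L)
})
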
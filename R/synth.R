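# Seeded generator of synthetic point sets and images with ground truth.
#
# Four shape families emulate the geometric situations the extractor
# targets: convex polygons (piecewise-linear contours), ellipse boundaries
# (smooth convex contours), bean shapes (smooth concave contours with
# exactly two inflection points: an ellipse whose radial profile is dented
# by a cosine term), and touching ellipse pairs whose union contour has two
# acute junctions.

#' Specify a synthetic shape
#'
#' The spec together with its `seed` fully determines every output
#' (bit-reproducible sampling and rendering).
#'
#' @param kind `"polygon"`, `"ellipse"`, `"bean"` or `"touching"`.
#' @param vertices polygon only: explicit vertex matrix (simple polygon,
#'   counter-clockwise or clockwise). Alternatively give `m`, `radius`,
#'   `rotation` for a regular polygon.
#' @param m,radius,rotation regular-polygon parameters (`radius` may be a
#'   per-vertex vector).
#' @param center shape center in pixel coordinates; defaults to the image
#'   center.
#' @param axes semi-axes `c(a, b)` for `"ellipse"` and `"bean"` (default
#'   `c(60, 32)`) and for the first ellipse of a touching pair (default
#'   `c(88, 52)`).
#' @param angle shape orientation in radians.
#' @param waist bean only: depth of the radial dent, in `(0.5, 1)` so the
#'   curve has exactly two inflection points (default 0.55; the dent's
#'   radius of curvature is `(1-waist)^2 / (2*waist - 1)` times the shape
#'   scale, so depths much beyond 0.6 produce dents far sharper than a
#'   gently concave embryo).
#' @param axes2,offset touching only: semi-axes of the second ellipse and
#'   the center-to-center distance along the (rotated) minor axis — the
#'   pair lies side by side, flanks touching, like adjacent embryos; the
#'   default overlap is 15\% of the summed minor semi-axes. The two
#'   ellipses must intersect in exactly 2 points (checked at
#'   construction).
#' @param spacing boundary sample spacing in pixels (default 1).
#' @param jitter Gaussian jitter sigma of boundary samples in pixels
#'   (default 0.5). Together these mimic 1-px edge maps.
#' @param noise additive Gaussian grayscale noise sigma for rendered images
#'   (default 0.02 on the `[0, 1]` scale).
#' @param dim image dimensions `c(nrow, ncol)`; default `c(160, 200)`,
#'   or `c(320, 400)` for touching pairs.
#' @param seed integer RNG seed.
#' @return a list of class `"shape_spec"`.
#' @export
shape_spec <- function(kind = c("ellipse", "bean", "touching", "polygon"),
                       vertices = NULL, m = 6L, radius = 55, rotation = 0,
                       center = NULL, axes = NULL, angle = 0,
                       waist = 0.55, axes2 = NULL, offset = NULL,
                       spacing = 1, jitter = 0.5, noise = 0.02,
                       dim = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (spacing <= 0 || jitter < 0 || noise < 0) stop("invalid sampling parameters")
  # touching pairs default to full-resolution frames: the junction
  # structure must sit well above the extractor's pixel-scale tolerances
  if (is.null(dim)) dim <- if (kind == "touching") c(320L, 400L) else c(160L, 200L)
  if (is.null(axes)) axes <- if (kind == "touching") c(88, 52) else c(60, 32)
  if (is.null(center)) center <- c((dim[2L] - 1) / 2, (dim[1L] - 1) / 2)
  spec <- list(kind = kind, center = center, spacing = spacing,
               jitter = jitter, noise = noise, dim = as.integer(dim),
               seed = as.integer(seed))
  if (kind == "polygon") {
    if (is.null(vertices)) {
      r <- rep_len(radius, m)
      th <- rotation + 2 * pi * (seq_len(m) - 1L) / m
      vertices <- cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
    }
    vertices <- as_points(vertices)
    if (nrow(vertices) < 3L) stop("polygon needs at least 3 vertices")
    if (!.is_simple_polygon(vertices)) stop("non-simple polygon")
    spec$vertices <- vertices
  } else if (kind == "ellipse") {
    spec$axes <- axes; spec$angle <- angle
  } else if (kind == "bean") {
    if (waist <= 0.5 || waist >= 1)
      stop("waist must lie in (0.5, 1) for exactly two inflection points")
    spec$axes <- axes; spec$angle <- angle; spec$waist <- waist
  } else {                              # touching
    if (is.null(axes2)) axes2 <- c(0.92, 0.94) * axes
    if (is.null(offset)) offset <- 0.85 * (axes[2L] + axes2[2L])
    spec$axes <- axes; spec$axes2 <- axes2
    spec$offset <- offset; spec$angle <- angle
    spec$centers <- .touching_centers(center, offset, angle)
    ji <- .ellipse_intersections(spec)
    if (nrow(ji$junctions) != 2L)
      stop("touching ellipses must intersect in exactly 2 points")
    spec$junctions <- ji$junctions
  }
  structure(spec, class = "shape_spec")
}

.touching_centers <- function(center, offset, angle) {
  d <- c(-sin(angle), cos(angle)) * offset / 2   # along the minor axis
  rbind(center - d, center + d)
}

# segment intersection test for the simple-polygon check
.segs_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o(p1, p2, p3) != o(p1, p2, p4) && o(p3, p4, p1) != o(p3, p4, p2)
}

.is_simple_polygon <- function(V) {
  n <- nrow(V)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (cyclically)
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      a <- V[i, ]; b <- V[i %% n + 1L, ]
      c <- V[j, ]; d <- V[j %% n + 1L, ]
      if (.segs_intersect(a, b, c, d)) return(FALSE)
    }
  }
  TRUE
}

# parametric boundary points of one ellipse
.ellipse_xy <- function(theta, center, axes, angle) {
  u <- axes[1L] * cos(theta); v <- axes[2L] * sin(theta)
  ca <- cos(angle); sa <- sin(angle)
  cbind(center[1L] + ca * u - sa * v, center[2L] + sa * u + ca * v)
}

.ellipse_inside <- function(px, py, center, axes, angle) {
  ca <- cos(angle); sa <- sin(angle)
  dx <- px - center[1L]; dy <- py - center[2L]
  u <- (ca * dx + sa * dy) / axes[1L]
  v <- (-sa * dx + ca * dy) / axes[2L]
  u * u + v * v <= 1
}

# bean: polar radius r(t) = 1 - waist * sin(t) in the unit frame — the
# dent sits on a long side, like the concave flank of a kidney-shaped
# embryo — scaled anisotropically by the semi-axes (affine maps preserve
# inflections)
.bean_xy <- function(theta, spec) {
  r <- 1 - spec$waist * sin(theta)
  u <- spec$axes[1L] * r * cos(theta); v <- spec$axes[2L] * r * sin(theta)
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  cbind(spec$center[1L] + ca * u - sa * v, spec$center[2L] + sa * u + ca * v)
}

.bean_inside <- function(px, py, spec) {
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  dx <- px - spec$center[1L]; dy <- py - spec$center[2L]
  u <- (ca * dx + sa * dy) / spec$axes[1L]
  v <- (-sa * dx + ca * dy) / spec$axes[2L]
  sqrt(u * u + v * v) <= 1 - spec$waist * sin(atan2(v, u))
}

# dense union contour of the touching pair: the arc of each ellipse lying
# outside the other, plus the junction points (boundary crossings)
.ellipse_intersections <- function(spec, n = 4096L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  P1 <- .ellipse_xy(th, spec$centers[1L, ], spec$axes, spec$angle)
  in2 <- .ellipse_inside(P1[, 1L], P1[, 2L], spec$centers[2L, ], spec$axes2,
                         spec$angle)
  flips <- which(in2 != in2[c(2:n, 1L)])
  junctions <- t(vapply(flips, function(i) {
    j <- i %% n + 1L
    (P1[i, ] + P1[j, ]) / 2
  }, numeric(2)))
  list(junctions = junctions, theta = th, P1 = P1, in2 = in2)
}

# resample an open polyline at (at most) `spacing` intervals
.resample_polyline <- function(XY, spacing, closed = FALSE) {
  if (closed) XY <- rbind(XY, XY[1L, ])
  seg <- sqrt(diff(XY[, 1L])^2 + diff(XY[, 2L])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  targets <- seq(0, if (closed) L - spacing / 2 else L, by = spacing)
  xi <- stats::approx(s, XY[, 1L], xout = targets, ties = "ordered")$y
  yi <- stats::approx(s, XY[, 2L], xout = targets, ties = "ordered")$y
  cbind(xi, yi)
}

# clean (jitter-free) boundary samples + ground-truth features
.clean_boundary <- function(spec) {
  if (spec$kind == "polygon") {
    V <- spec$vertices
    n <- nrow(V)
    pts <- do.call(rbind, lapply(seq_len(n), function(i) {
      a <- V[i, ]; b <- V[i %% n + 1L, ]
      len <- .d(a, b)
      t <- seq(0, len - 1e-9, by = spec$spacing) / len
      cbind(a[1L] + t * (b[1L] - a[1L]), a[2L] + t * (b[2L] - a[2L]))
    }))
    return(list(points = pts, truth = list(vertices = V)))
  }
  if (spec$kind == "ellipse") {
    th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
    C <- .ellipse_xy(th, spec$center, spec$axes, spec$angle)
    return(list(points = .resample_polyline(C, spec$spacing, closed = TRUE),
                truth = list(ellipse = list(center = spec$center,
                                            axes = spec$axes,
                                            angle = spec$angle))))
  }
  if (spec$kind == "bean") {
    th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
    C <- .bean_xy(th, spec)
    # inflection points: sign changes of the discrete curvature
    dx <- diff(C[c(seq_len(4096L), 1L, 2L), 1L])
    dy <- diff(C[c(seq_len(4096L), 1L, 2L), 2L])
    cr <- dx[-4097L] * dy[-1L] - dy[-4097L] * dx[-1L]
    sgn <- sign(cr)
    flips <- which(sgn != c(sgn[-1L], sgn[1L]))
    infl <- C[(flips %% 4096L) + 1L, , drop = FALSE]
    return(list(points = .resample_polyline(C, spec$spacing, closed = TRUE),
                truth = list(inflections = infl)))
  }
  # touching: resample each outside-arc separately
  pts <- NULL
  for (k in 1:2) {
    ctr <- spec$centers[k, ]
    ax <- if (k == 1L) spec$axes else spec$axes2
    other <- spec$centers[3L - k, ]
    axo <- if (k == 1L) spec$axes2 else spec$axes
    th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
    P <- .ellipse_xy(th, ctr, ax, spec$angle)
    outside <- !.ellipse_inside(P[, 1L], P[, 2L], other, axo, spec$angle)
    # rotate so the kept arc is contiguous
    first_in <- which(!outside)[1L]
    ordr <- ((first_in - 1L + seq_len(4096L) - 1L) %% 4096L) + 1L
    keep <- ordr[outside[ordr]]
    pts <- rbind(pts, .resample_polyline(P[keep, , drop = FALSE], spec$spacing))
  }
  list(points = pts, truth = list(junctions = spec$junctions))
}

# analytic per-object masks at pixel centers
.shape_masks <- function(spec) {
  nr <- spec$dim[1L]; nc <- spec$dim[2L]
  px <- rep(0:(nc - 1L), each = nr)
  py <- rep(0:(nr - 1L), times = nc)
  msk <- function(v) matrix(v, nr, nc)
  switch(spec$kind,
    polygon = list(polygon_mask(spec$vertices, spec$dim)),
    ellipse = list(msk(.ellipse_inside(px, py, spec$center, spec$axes,
                                       spec$angle))),
    bean = list(msk(.bean_inside(px, py, spec))),
    touching = list(
      msk(.ellipse_inside(px, py, spec$centers[1L, ], spec$axes, spec$angle)),
      msk(.ellipse_inside(px, py, spec$centers[2L, ], spec$axes2, spec$angle))))
}

#' Sample a shape boundary with jitter
#'
#' Samples the boundary at (at most) `spacing` pixel intervals, adds
#' Gaussian jitter, and returns the samples together with the shape's
#' ground truth (polygon vertices, junction points, inflection points,
#' and per-object analytic masks). Identical specs give identical output.
#'
#' @param spec a [shape_spec()].
#' @return a list with `points` (jittered samples, duplicates collapsed),
#'   `clean` (jitter-free samples) and `truth` (a list; always contains
#'   `masks`).
#' @export
sample_boundary <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  cb <- .clean_boundary(spec)
  pts <- with_seed(spec$seed, {
    cb$points + matrix(stats::rnorm(2L * nrow(cb$points), 0, spec$jitter),
                       ncol = 2L)
  })
  truth <- cb$truth
  truth$masks <- .shape_masks(spec)
  list(points = as_points(pts), clean = cb$points, truth = truth)
}

#' Render a shape as a grayscale image with ground-truth masks
#'
#' Fills the shape(s) over a darker background, adds Gaussian grayscale
#' noise, and returns the per-object analytic truth masks. The two members
#' of a touching pair are filled at the same gray level — like the equal
#' staining of adjacent embryos, so the only edges are on the union
#' contour. Identical specs render identical images.
#'
#' @param spec a [shape_spec()].
#' @param background,foreground gray levels (defaults 0.15 and 0.65).
#' @return a list with `image` (matrix in `[0, 1]`) and `masks` (list of
#'   logical matrices, one per object).
#' @export
render_image <- function(spec, background = 0.15, foreground = 0.65) {
  stopifnot(inherits(spec, "shape_spec"))
  cb <- .clean_boundary(spec)
  rng <- apply(cb$points, 2L, range)
  if (rng[1L, 1L] < 0 || rng[1L, 2L] < 0 ||
      rng[2L, 1L] > spec$dim[2L] - 1L || rng[2L, 2L] > spec$dim[1L] - 1L)
    stop("shape exceeds the image canvas")
  masks <- .shape_masks(spec)
  img <- matrix(background, spec$dim[1L], spec$dim[2L])
  for (mk in masks) img[mk] <- foreground
  if (spec$noise > 0) {
    img <- with_seed(spec$seed + 1L, {
      img + matrix(stats::rnorm(length(img), 0, spec$noise),
                   nrow(img), ncol(img))
    })
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, masks = masks)
}

#' Build the packaged synthetic benchmark
#'
#' A seeded set of rendered images with ground truth: 25 single ellipses,
#' 15 bean shapes and 10 touching pairs by default, with randomized sizes,
#' orientations and centers at the generator's documented jitter and noise
#' levels. The result plugs directly into [evaluate_contours()].
#'
#' @param seed integer master seed.
#' @param n_ellipse,n_bean,n_touching counts per shape family.
#' @return a list of entries, each with `image`, `truth` (list of masks),
#'   `kind` and `spec`.
#' @export
synth_benchmark <- function(seed = 1L, n_ellipse = 25L, n_bean = 15L,
                            n_touching = 10L) {
  specs <- with_seed(seed, {
    out <- list()
    for (i in seq_len(n_ellipse)) {
      out[[length(out) + 1L]] <- shape_spec(
        "ellipse",
        center = c(99.5, 79.5) + stats::runif(2, -5, 5),
        axes = c(stats::runif(1, 50, 65), stats::runif(1, 28, 28 + 10)),
        angle = stats::runif(1, 0, pi),
        seed = sample.int(1e6, 1))
    }
    for (i in seq_len(n_bean)) {
      out[[length(out) + 1L]] <- shape_spec(
        "bean",
        center = c(99.5, 79.5) + stats::runif(2, -4, 4),
        axes = c(stats::runif(1, 42, 50), stats::runif(1, 26, 34)),
        angle = stats::runif(1, -0.35, 0.35),
        waist = stats::runif(1, 0.52, 0.6),
        seed = sample.int(1e6, 1))
    }
    for (i in seq_len(n_touching)) {
      out[[length(out) + 1L]] <- shape_spec(
        "touching",
        center = c(199.5, 159.5) + stats::runif(2, -6, 6),
        axes = c(stats::runif(1, 84, 92), stats::runif(1, 49, 55)),
        angle = stats::runif(1, -0.3, 0.3),
        seed = sample.int(1e6, 1))
    }
    out
  })
  lapply(specs, function(sp) {
    r <- render_image(sp)
    list(image = r$image, truth = r$masks, kind = sp$kind, spec = sp)
  })
}
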
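# End-to-end contour extraction pipeline:
# edge map -> components -> k-dominant points -> subdivision -> closing ->
# masks -> overlap evaluation.

#' Rasterize a polygon to a binary mask
#'
#' Even-odd (crossing-number) fill evaluated at pixel centers
#' (x = col - 1, y = row - 1).
#'
#' @param poly polygon vertices, n x 2 matrix (closed implicitly).
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return logical matrix.
#' @export
polygon_mask <- function(poly, dim) {
  poly <- as_points(poly, dedup = FALSE)
  n <- nrow(poly)
  if (n < 3L) stop("polygon needs at least 3 vertices")
  nr <- dim[1L]; nc <- dim[2L]
  cx <- rep(0:(nc - 1L), each = nr)
  cy <- rep(0:(nr - 1L), times = nc)
  inside <- rep(FALSE, nr * nc)
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
    if (y1 != y2) {
      cross <- ((y1 > cy) != (y2 > cy)) &
        (cx < (x2 - x1) * (cy - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Overlap (intersection-over-union) of two masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @return numeric in `[0, 1]`; 1 iff the masks are identical (two empty
#'   masks count as identical).
#' @export
mask_overlap <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Direct least-squares ellipse fit
#'
#' Fitzgibbon-style ellipse-specific conic fit, returned in parametric form.
#'
#' @param pts n x 2 matrix of points, n >= 5 and not collinear.
#' @return a list with `center` (length 2), `axes` (semi-axes, major first),
#'   `angle` (radians, orientation of the major axis), or `NULL` when no
#'   ellipse can be fitted (degenerate input).
#' @export
fit_ellipse <- function(pts) {
  pts <- as_points(pts, dedup = FALSE)
  if (nrow(pts) < 5L) return(NULL)
  mu <- colMeans(pts)
  x <- pts[, 1L] - mu[1L]; y <- pts[, 2L] - mu[2L]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev) || any(Mod(Im(ev$values)) > 1e-8)) {
    if (is.null(ev)) return(NULL)
  }
  V <- Re(ev$vectors)
  cond <- 4 * V[1L, ] * V[3L, ] - V[2L, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) return(NULL)
  a1 <- V[, ok[1L]]
  coefs <- c(a1, as.numeric(T1 %*% a1))   # A B C D E F (centered frame)
  A <- coefs[1L]; B <- coefs[2L]; C <- coefs[3L]
  D <- coefs[4L]; E <- coefs[5L]; F <- coefs[6L]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  a2 <- num * (A + C + s)
  b2 <- num * (A + C - s)
  if (a2 <= 0 || b2 <= 0) {
    ax1 <- -sqrt(abs(a2)) / den
    ax2 <- -sqrt(abs(b2)) / den
  } else {
    ax1 <- -sqrt(a2) / den
    ax2 <- -sqrt(b2) / den
  }
  ax1 <- abs(ax1); ax2 <- abs(ax2)
  ang <- if (B == 0) {
    if (A < C) 0 else pi / 2
  } else atan2(C - A - s, B)
  if (ax2 > ax1) { tmp <- ax1; ax1 <- ax2; ax2 <- tmp; ang <- ang + pi / 2 }
  list(center = unname(c(cx + mu[1L], cy + mu[2L])),
       axes = unname(c(ax1, ax2)), angle = unname(ang %% pi))
}

#' Sample a polygon from ellipse parameters
#'
#' @param el ellipse list from [fit_ellipse()].
#' @param n number of polygon vertices (default 72).
#' @return n x 2 matrix of vertices.
#' @export
ellipse_polygon <- function(el, n = 72L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ca <- cos(el$angle); sa <- sin(el$angle)
  u <- el$axes[1L] * cos(t); v <- el$axes[2L] * sin(t)
  cbind(x = el$center[1L] + ca * u - sa * v,
        y = el$center[2L] + sa * u + ca * v)
}

#' Close a subsequence into a polygon
#'
#' A closed subsequence (a full smooth cycle) is already a polygon and is
#' returned as-is. An open arc is closed either by a direct chord between
#' its endpoints (`"chord"`) or by least-squares ellipse fitting to its
#' vertices and sampling the fitted ellipse (`"ellipse"`, the default —
#' appropriate for roughly ellipsoidal objects such as embryos). Collinear
#' or otherwise unfittable vertices fall back to the chord with a warning.
#'
#' @param sub a subsequence from [split_at_nonsmooth()], or a vertex matrix
#'   (treated as an open arc); at least 3 distinct vertices.
#' @param method `"ellipse"` or `"chord"`.
#' @param n_ellipse vertices sampled from a fitted ellipse.
#' @return polygon vertex matrix.
#' @export
close_contour <- function(sub, method = c("ellipse", "chord"), n_ellipse = 72L) {
  method <- match.arg(method)
  if (is.matrix(sub) || is.data.frame(sub))
    sub <- list(vertices = as_points(sub, dedup = FALSE), open = TRUE)
  V <- sub$vertices
  # a full-tour arc repeats its cut vertex at the end; drop the repeat
  if (nrow(V) > 1L && all(V[1L, ] == V[nrow(V), ])) V <- V[-nrow(V), , drop = FALSE]
  if (nrow(V) < 3L) stop("need at least 3 vertices to close a contour")
  if (!isTRUE(sub$open) || method == "chord") return(V)
  el <- fit_ellipse(V)
  if (is.null(el)) {
    warning("ellipse fit failed (degenerate vertices); falling back to chord")
    return(V)
  }
  ellipse_polygon(el, n_ellipse)
}

#' Extract object contours from a grayscale image
#'
#' Runs the full chain: edge detection, 8-connected components, component
#' selection, k-dominant point extraction, labeling of nonsmooth (acute)
#' vertices, subdivision at junctions, contour closing and mask
#' rasterization. When at least two nonsmooth vertices are found the merged
#' contour is split and each arc closed separately (one contour per
#' touching object); otherwise the dominant-point polygon itself is the
#' single contour. Deterministic for fixed inputs and configuration.
#'
#' @param img numeric image matrix in `[0, 1]`, or a path readable by
#'   [read_gray_image()].
#' @param control [kdp_control()] parameters for the extractor.
#' @param close_method contour-closing method for split arcs, see
#'   [close_contour()].
#' @param strategy component selection, see [select_component()].
#' @param angle_threshold nonsmooth-vertex threshold in radians, see
#'   [label_vertices()].
#' @param sigma,low,high edge-detector parameters, see [detect_edges()].
#' @param convert_rgb convert RGB input by luminance.
#' @return object of class `"contour_result"`: list with `contours` (a list
#'   of per-object lists: `polygon`, `mask`), `fit` (the `"kdp"` object),
#'   `labeled`, `component_id`, `dim` and `meta` (configuration echo).
#' @export
extract_contours <- function(img, control = kdp_control(),
                             close_method = c("ellipse", "chord"),
                             strategy = c("largest", "center"),
                             angle_threshold = pi / 2,
                             sigma = 1, low = 0.1, high = 0.25,
                             convert_rgb = FALSE) {
  close_method <- match.arg(close_method)
  strategy <- match.arg(strategy)
  if (is.character(img)) img <- read_gray_image(img, convert_rgb = convert_rgb)
  edges <- detect_edges(img, sigma = sigma, low = low, high = high,
                        convert_rgb = convert_rgb)
  comps <- edge_components(edges)
  if (length(comps) == 0L) stop("no component in edge map")
  comp <- select_component(comps, strategy, dim = dim(img))
  # Edge responses weaken where boundaries meet (the junction of touching
  # objects), which can break one contour into several components; pieces
  # lying within the coverage gap tolerance of the selected component are
  # part of the same contour and are merged back before extraction.
  pts <- comp$points
  repeat {
    grew <- FALSE
    for (other in comps) {
      if (other$id == comp$id) next
      dmin <- min(vapply(seq_len(nrow(other$points)), function(i) {
        min((pts[, 1L] - other$points[i, 1L])^2 +
              (pts[, 2L] - other$points[i, 2L])^2)
      }, numeric(1)))
      if (sqrt(dmin) <= control$gap_tol &&
          !any(other$points[1L, 1L] == pts[, 1L] &
                 other$points[1L, 2L] == pts[, 2L])) {
        pts <- rbind(pts, other$points)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  fit <- kdp(pts, control)
  k <- seq_size(fit$sequence)
  labeled <- if (k >= 3L) label_vertices(fit$sequence, angle_threshold) else NULL
  contours <- NULL
  if (!is.null(labeled) && sum(labeled$nonsmooth) >= 2L) {
    subs <- split_at_nonsmooth(labeled)
    subs <- Filter(function(s) nrow(unique(s$vertices)) >= 3L, subs)
    contours <- lapply(subs, function(s)
      list(polygon = close_contour(s, close_method)))
  }
  if (is.null(contours) || length(contours) == 0L) {
    if (k < 3L) stop("degenerate dominant sequence (fewer than 3 vertices)")
    contours <- list(list(polygon = fit$sequence$vertices))
  }
  contours <- lapply(contours, function(ct) {
    ct$mask <- polygon_mask(ct$polygon, dim(img))
    ct
  })
  structure(list(contours = contours, fit = fit, labeled = labeled,
                 component_id = comp$id, dim = dim(img),
                 meta = list(measure = control$measure, eps = control$eps,
                             confidence = control$confidence,
                             close_method = close_method, strategy = strategy,
                             angle_threshold = angle_threshold,
                             sigma = sigma, low = low, high = high)),
            class = "contour_result")
}

#' @export
print.contour_result <- function(x, ...) {
  cat(sprintf("Contour result: %d object(s) from component %d (%dx%d image)\n",
              length(x$contours), x$component_id, x$dim[1L], x$dim[2L]))
  for (i in seq_along(x$contours))
    cat(sprintf("  contour %d: %d vertices, area %d px\n", i,
                nrow(x$contours[[i]]$polygon), sum(x$contours[[i]]$mask)))
  invisible(x)
}

#' Write extracted contours to disk
#'
#' `write_contours_csv` serializes the polygons of a [extract_contours()]
#' result as CSV with columns `component_id,order,x,y`;
#' `write_contours_geojson` writes a GeoJSON FeatureCollection of Polygon
#' features (one per contour, coordinates in pixel units).
#'
#' @param result a `"contour_result"` from [extract_contours()], or a list
#'   of polygon matrices.
#' @param path output file path.
#' @export
write_contours_csv <- function(result, path) {
  polys <- if (inherits(result, "contour_result"))
    lapply(result$contours, `[[`, "polygon") else result
  rows <- do.call(rbind, lapply(seq_along(polys), function(i) {
    p <- as_points(polys[[i]], dedup = FALSE)
    data.frame(component_id = i, order = seq_len(nrow(p)),
               x = p[, 1L], y = p[, 2L])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
write_contours_geojson <- function(result, path) {
  polys <- if (inherits(result, "contour_result"))
    lapply(result$contours, `[[`, "polygon") else result
  features <- lapply(seq_along(polys), function(i) {
    p <- as_points(polys[[i]], dedup = FALSE)
    ring <- rbind(p, p[1L, , drop = FALSE])          # closed ring
    list(type = "Feature",
         properties = list(component_id = i),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)), function(j)
                             as.numeric(ring[j, ]))))))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection",
                                features = features),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Evaluate contour extraction against ground truth
#'
#' Runs [extract_contours()] on every image of a dataset and scores each
#' object against its ground-truth mask by intersection-over-union. An
#' image is a successful detection when every ground-truth object is
#' matched by some extracted contour with IoU above 0.9. Per-image errors
#' are recorded as failures and never abort the batch.
#'
#' @param dataset either a list of entries — each a list with `image` (a
#'   matrix or file path) and `truth` (a list of logical ground-truth
#'   masks) — or a manifest data frame with columns `image`,
#'   `truth_mask_1` and optionally `truth_mask_2`, ... holding file paths.
#' @param iou_threshold success threshold (default 0.9).
#' @param ... passed on to [extract_contours()].
#' @return a list with `rate` (fraction of successful detections) and
#'   `records` (data frame: `id`, `n_truth`, `n_contours`, `iou` — minimum
#'   best-match IoU over the image's objects — and `success`).
#' @export
evaluate_contours <- function(dataset, iou_threshold = 0.9, ...) {
  if (is.data.frame(dataset)) {
    mcols <- grep("^truth_mask", names(dataset), value = TRUE)
    dataset <- lapply(seq_len(nrow(dataset)), function(i) {
      paths <- unlist(dataset[i, mcols], use.names = FALSE)
      paths <- paths[!is.na(paths) & nzchar(paths)]
      list(image = dataset$image[i],
           truth = lapply(paths, function(p) read_gray_image(p) > 0.5))
    })
  }
  records <- lapply(seq_along(dataset), function(i) {
    entry <- dataset[[i]]
    res <- tryCatch(extract_contours(entry$image, ...),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(id = i, n_truth = length(entry$truth),
                        n_contours = 0L, iou = NA_real_, success = FALSE))
    best <- vapply(entry$truth, function(tm) {
      max(vapply(res$contours, function(ct) mask_overlap(ct$mask, tm),
                 numeric(1)))
    }, numeric(1))
    data.frame(id = i, n_truth = length(entry$truth),
               n_contours = length(res$contours),
               iou = min(best), success = all(best > iou_threshold))
  })
  records <- do.call(rbind, records)
  list(rate = mean(records$success), records = records)
}
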
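# Raster plumbing: grayscale I/O, Canny-style edge detection and
# 8-connected component labeling.
#
# Images are numeric matrices in [0, 1], indexed [row, col]; the pixel at
# [r, c] has coordinates x = c - 1, y = r - 1 (x right, y down, 0-based
# pixel centers).

#' Read a grayscale image (PNG or TIFF)
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @param convert_rgb convert RGB input to grayscale by Rec. 709 luminance;
#'   without this flag multi-channel input is an error.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path, convert_rgb = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 2L) img <- img[, , 1L]          # gray + alpha
    else if (!convert_rgb) stop("multi-channel image; set convert_rgb = TRUE")
    else img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
  }
  img
}

#' Write a grayscale image or a binary mask as PNG
#'
#' Masks are written as 0/255 images.
#'
#' @param img numeric matrix in `[0, 1]`, or logical matrix for
#'   `write_mask_png`.
#' @param path output file path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_gray_png
#' @param mask logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Shift a matrix by (dr, dc) with replicate padding.
.shift <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  M[ri, ci, drop = FALSE]
}

# Separable Gaussian blur, replicate boundary.
.gaussian_blur <- function(M, sigma) {
  if (sigma <= 0) return(M)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  out <- matrix(0, nrow(M), ncol(M))
  for (k in -r:r) out <- out + w[k + r + 1L] * .shift(M, k, 0L)
  M <- out
  out <- matrix(0, nrow(M), ncol(M))
  for (k in -r:r) out <- out + w[k + r + 1L] * .shift(M, 0L, k)
  out
}

#' Detect edges in a grayscale image
#'
#' Canny-style detector: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the gradient direction, and hysteresis thresholding
#' (thresholds are fractions of the maximum gradient magnitude). Fully
#' deterministic for fixed parameters.
#'
#' @param img numeric matrix in `[0, 1]`; multi-channel arrays are an error
#'   unless `convert_rgb = TRUE`.
#' @param sigma smoothing scale in pixels (default 1).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (defaults 0.1 and 0.25).
#' @param min_grad absolute gradient-magnitude floor (on the `[0, 1]` gray
#'   scale, default 0.05): responses below it are never edges, so a
#'   featureless noisy frame yields an empty map even though the
#'   hysteresis thresholds are relative.
#' @param convert_rgb convert RGB input by luminance instead of erroring.
#' @return logical matrix of edge pixels.
#' @export
detect_edges <- function(img, sigma = 1, low = 0.1, high = 0.25,
                         min_grad = 0.05, convert_rgb = FALSE) {
  if (length(dim(img)) == 3L) {
    if (!convert_rgb) stop("multi-channel image; set convert_rgb = TRUE")
    img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
  }
  S <- .gaussian_blur(img, sigma)
  # Sobel; x is the column direction, y the row direction
  gx <- (.shift(S, -1, -1) + 2 * .shift(S, 0, -1) + .shift(S, 1, -1)) -
        (.shift(S, -1,  1) + 2 * .shift(S, 0,  1) + .shift(S, 1,  1))
  gx <- -gx
  gy <- (.shift(S, -1, -1) + 2 * .shift(S, -1, 0) + .shift(S, -1, 1)) -
        (.shift(S,  1, -1) + 2 * .shift(S,  1, 0) + .shift(S,  1, 1))
  gy <- -gy
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  # non-maximum suppression: compare against the two neighbors along the
  # gradient direction, quantized to 4 sectors
  theta <- atan2(gy, gx) %% pi
  sector <- (floor(theta / (pi / 4) + 0.5)) %% 4   # 0=E, 1=SE, 2=S, 3=SW
  keep <- matrix(FALSE, nrow(img), ncol(img))
  nb <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L))
  for (s in 0:3) {
    d <- nb[[as.character(s)]]
    m1 <- .shift(mag,  d[1L],  d[2L])
    m2 <- .shift(mag, -d[1L], -d[2L])
    keep <- keep | (sector == s & mag >= m1 & mag >= m2)
  }
  nms <- mag * keep
  nms[nms < min_grad] <- 0
  strong <- nms >= high * mx & nms > 0
  weak <- nms >= low * mx & nms > 0
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- .label8(weak)
  keep_ids <- unique(lab[strong])
  weak & matrix(lab %in% keep_ids, nrow(lab), ncol(lab))
}

# 8-connected labeling of a logical matrix via flood fill.
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  seeds <- which(mask)
  stack <- integer(length(seeds))
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- cur
    while (top > 0L) {
      i <- stack[top]; top <- top - 1L
      r <- (i - 1L) %% nr + 1L
      for (o in offs) {
        j <- i + o
        if (j < 1L || j > nr * nc) next
        rj <- (j - 1L) %% nr + 1L
        if (abs(rj - r) > 1L) next        # column wrap guard
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- j
        }
      }
    }
  }
  lab
}

#' Connected components of an edge map
#'
#' 8-connected labeling of a binary edge raster; each component is returned
#' as a point set in pixel coordinates.
#'
#' @param edges logical matrix (from [detect_edges()] or any binary map).
#' @return a list of components, each a list with `id`, `points` (n x 2
#'   matrix, x = col - 1, y = row - 1), `npix`, and `bbox`
#'   (`xmin, xmax, ymin, ymax`).
#' @export
edge_components <- function(edges) {
  lab <- .label8(edges)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  nr <- nrow(edges)
  lapply(ids, function(id) {
    w <- which(lab == id)
    x <- (w - 1L) %/% nr
    y <- (w - 1L) %% nr
    pts <- cbind(x = as.numeric(x), y = as.numeric(y))
    list(id = id, points = pts, npix = length(w),
         bbox = c(xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y)))
  })
}

#' Select one edge component
#'
#' @param comps component list from [edge_components()]; must be nonempty.
#' @param strategy `"largest"` (most edge pixels, default) or `"center"`
#'   (component whose centroid is nearest the image center — the usual
#'   heuristic when the object of interest is centered).
#' @param dim image dimensions `c(nrow, ncol)`, required for `"center"`.
#' @return a single component.
#' @export
select_component <- function(comps, strategy = c("largest", "center"),
                             dim = NULL) {
  strategy <- match.arg(strategy)
  if (length(comps) == 0L) stop("no component in edge map")
  if (strategy == "largest") {
    comps[[which.max(vapply(comps, `[[`, numeric(1), "npix"))]]
  } else {
    if (is.null(dim)) stop("center strategy needs image dimensions")
    ctr <- c((dim[2L] - 1) / 2, (dim[1L] - 1) / 2)
    d <- vapply(comps, function(cp) {
      mu <- colMeans(cp$points)
      .d(mu, ctr)
    }, numeric(1))
    comps[[which.min(d)]]
  }
}
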
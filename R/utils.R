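#' @keywords internal
"_PACKAGE"

# Euclidean distance between two length-2 points (always unnamed)
.d <- function(p, q) sqrt((p[[1]] - q[[1]])^2 + (p[[2]] - q[[2]])^2)

#' Coerce to a point-set matrix
#'
#' Point sets are plain numeric matrices with two columns, `x` and `y`
#' (pixel units, x right, y down, 0-based pixel centers). Duplicate
#' coordinates are collapsed and non-finite coordinates rejected.
#'
#' @param x a two-column matrix or data frame of coordinates, or a numeric
#'   vector of length 2 (a single point).
#' @param dedup collapse duplicate rows (default `TRUE`).
#' @return a numeric matrix with columns `x`, `y`.
#' @export
as_points <- function(x, dedup = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.null(dim(x))) {
    if (length(x) != 2L) stop("a point must have exactly 2 coordinates")
    x <- matrix(x, ncol = 2L)
  }
  if (ncol(x) < 2L) stop("point sets need two coordinate columns")
  x <- x[, 1:2, drop = FALSE]
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite coordinates in point set")
  if (dedup && nrow(x) > 1L) x <- x[!duplicated(x), , drop = FALSE]
  colnames(x) <- c("x", "y")
  rownames(x) <- NULL
  x
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read / write point sets as CSV
#'
#' The on-disk format is a plain CSV with header `x,y`, one point per row.
#'
#' @param path file path.
#' @return `read_points_csv` returns a point-set matrix.
#' @export
read_points_csv <- function(path) {
  as_points(utils::read.csv(path))
}

#' @rdname read_points_csv
#' @param points a point-set matrix (see [as_points()]).
#' @export
write_points_csv <- function(points, path) {
  points <- as_points(points, dedup = FALSE)
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}
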
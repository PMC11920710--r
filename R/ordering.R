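#' Canonical PCA ordering of a point cloud
#'
#' Centers the coordinates, computes the eigenvectors of their 3 x 3
#' covariance matrix, and sorts the points by ascending projection onto the
#' leading eigenvector. The eigenvector sign is fixed deterministically:
#' the leading axis is oriented to have nonnegative dot product with +x
#' (the LM inflow direction in the canonical frame); if that projection is
#' numerically zero, the component of largest magnitude is made
#' nonnegative. Ties are broken by the projections onto the second and
#' third eigenvectors, then by input index, so the permutation is a total
#' order.
#'
#' @param coords N x 3 coordinate matrix, N >= 3.
#' @return Object of class `cloud_ordering`: `permutation` (1-based index
#'   vector), `method`, `axes` (3 x 3 eigenvector matrix, columns in
#'   decreasing eigenvalue order).
#' @examples
#' xy <- cbind(c(3, 1, 2), 0, 0)
#' pca_order(xy)$permutation  # 2 3 1
#' @export
pca_order <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  ctr <- sweep(coords, 2, colMeans(coords))
  cv <- crossprod(ctr) / (n - 1)
  if (max(abs(cv)) == 0) {
    stop("degenerate input: all points identical", call. = FALSE)
  }
  eg <- eigen(cv, symmetric = TRUE)
  axes <- eg$vectors
  for (j in 1:3) axes[, j] <- fix_sign(axes[, j])
  pr <- ctr %*% axes
  perm <- order(pr[, 1], pr[, 2], pr[, 3], seq_len(n))
  structure(list(permutation = perm, method = "PCA", axes = axes),
            class = "cloud_ordering")
}

fix_sign <- function(v, tol = 1e-12) {
  d <- v[1]  # dot with +x
  if (abs(d) > tol) {
    if (d < 0) v <- -v
  } else if (v[which.max(abs(v))] < 0) {
    v <- -v
  }
  v
}

#' Axis ordering of a point cloud
#'
#' Ascending sort on one coordinate, ties broken by the remaining
#' coordinates (in x, y, z cyclic order) and then by input index.
#'
#' @param coords N x 3 coordinate matrix.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return A `cloud_ordering` with `method` set to the axis.
#' @examples
#' axis_order(cbind(c(2, 0.5, 1), 0, 0), "x")$permutation  # 2 3 1
#' @export
axis_order <- function(coords, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("empty input", call. = FALSE)
  k <- match(axis, c("x", "y", "z"))
  ks <- c(k, setdiff(1:3, k))
  perm <- order(coords[, ks[1]], coords[, ks[2]], coords[, ks[3]],
                seq_len(nrow(coords)))
  structure(list(permutation = perm, method = toupper(axis), axes = NULL),
            class = "cloud_ordering")
}

#' Resolve an ordering method name to an ordering of a cloud
#' @param coords N x 3 matrix.
#' @param method `"pca"`, `"x"`, `"y"` or `"z"`.
#' @return A `cloud_ordering`.
#' @export
order_cloud <- function(coords, method = c("pca", "x", "y", "z")) {
  method <- match.arg(tolower(method), c("pca", "x", "y", "z"))
  if (method == "pca") pca_order(coords) else axis_order(coords, method)
}

#' Reshape ordered per-point features into a rows x cols grid
#'
#' Applies the ordering permutation, then lays consecutive blocks of
#' `cols` points into grid rows (row-major). `from_grid()` is its exact
#' inverse: `from_grid(to_grid(f, o, r, c), o) == f` bitwise.
#'
#' @param features N x C matrix (or length-N vector) in cloud order.
#' @param ordering a `cloud_ordering` over the same N points.
#' @param rows,cols grid shape with `rows * cols == N`.
#' @return `to_grid`: rows x cols x C array of class `ordered_grid` with
#'   attributes `ordering`; `from_grid`: the N x C feature matrix in
#'   original cloud order.
#' @examples
#' o <- structure(list(permutation = 1:4, method = "X"),
#'                class = "cloud_ordering")
#' to_grid(0:3, o, 2, 2)[, , 1]  # rbind(c(0, 1), c(2, 3))
#' @export
to_grid <- function(features, ordering, rows, cols) {
  f <- as.matrix(features)
  n <- nrow(f)
  if (n != rows * cols) {
    stop("cannot reshape ", n, " points into ", rows, " x ", cols,
         call. = FALSE)
  }
  f <- f[ordering$permutation, , drop = FALSE]
  g <- aperm(array(f, dim = c(cols, rows, ncol(f))), c(2L, 1L, 3L))
  structure(g, class = "ordered_grid", ordering = ordering)
}

#' @rdname to_grid
#' @param grid a rows x cols x C array from [to_grid()].
#' @export
from_grid <- function(grid, ordering = attr(grid, "ordering")) {
  d <- dim(grid)
  m <- aperm(unclass(grid), c(2L, 1L, 3L))
  dim(m) <- c(d[1] * d[2], d[3])
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[ordering$permutation, ] <- m
  out
}
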
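# Planar Delaunay triangulation (Bowyer-Watson incremental insertion).
# Returns an integer matrix, one row per triangle, of indices into the
# input points.  Written here because no triangulation library ships with
# the package's dependency set; adequate for the point counts produced by
# subspace sampling (hundreds to a few thousand).
delaunay_triangulation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  # scale into a well-conditioned box (isotropically: the Delaunay
  # topology is not invariant under per-axis scaling)
  sc <- max(diff(range(x)), diff(range(y)), .Machine$double.eps)
  cx <- (x - min(x)) / sc
  cy <- (y - min(y)) / sc
  # super-triangle (counterclockwise)
  px <- c(cx, -20, 21, 0.5)
  py <- c(cy, -20, -20, 40)
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  for (ip in seq_len(n)) {
    # incircle determinant, vectorized over triangles; triangles are kept
    # counterclockwise so a positive determinant means "strictly inside"
    ax <- px[tri[, 1]] - px[ip]; ay <- py[tri[, 1]] - py[ip]
    bx <- px[tri[, 2]] - px[ip]; by <- py[tri[, 2]] - py[ip]
    cx2 <- px[tri[, 3]] - px[ip]; cy2 <- py[tri[, 3]] - py[ip]
    a2 <- ax * ax + ay * ay
    b2 <- bx * bx + by * by
    c2 <- cx2 * cx2 + cy2 * cy2
    det <- ax * (by * c2 - b2 * cy2) - ay * (bx * c2 - b2 * cx2) +
      a2 * (bx * cy2 - by * cx2)
    bad <- which(det > 0)
    if (length(bad) == 0) next   # duplicate or cocircular-degenerate point
    # boundary of the cavity: edges of bad triangles that appear once
    edges <- rbind(tri[bad, c(1, 2), drop = FALSE],
                   tri[bad, c(2, 3), drop = FALSE],
                   tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    edges <- edges[keep, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    if (nrow(edges)) {
      newt <- cbind(edges, ip)
      # enforce counterclockwise orientation of the new triangles
      cr <- (px[newt[, 2]] - px[newt[, 1]]) * (py[newt[, 3]] - py[newt[, 1]]) -
        (py[newt[, 2]] - py[newt[, 1]]) * (px[newt[, 3]] - px[newt[, 1]])
      flip <- cr < 0
      tmp <- newt[flip, 2]
      newt[flip, 2] <- newt[flip, 3]
      newt[flip, 3] <- tmp
      tri <- rbind(tri, newt)
    }
  }
  out <- tri[rowSums(tri <= n) == 3, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

.tri_circumradius <- function(x, y, tri) {
  apply(tri, 1, function(tr) {
    a <- sqrt((x[tr[1]] - x[tr[2]])^2 + (y[tr[1]] - y[tr[2]])^2)
    b <- sqrt((x[tr[2]] - x[tr[3]])^2 + (y[tr[2]] - y[tr[3]])^2)
    cl <- sqrt((x[tr[3]] - x[tr[1]])^2 + (y[tr[3]] - y[tr[1]])^2)
    s <- (a + b + cl) / 2
    ar2 <- s * (s - a) * (s - b) * (s - cl)
    if (ar2 <= 0) return(Inf)
    a * b * cl / (4 * sqrt(ar2))
  })
}

.median_nn_spacing <- function(x, y) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  median(apply(d, 1, min))
}

# Alpha-complex restriction of a Delaunay triangulation: keep triangles
# whose circumradius does not exceed alpha.  alpha = NULL picks 2x the
# median nearest-neighbour spacing, which tracks sampling density and
# avoids convex-hull overestimation of non-convex regions.
#
# The triangulation and the alpha criterion operate on per-axis
# standardized coordinates: the accepted regions are strongly
# anisotropic (the feedback constants differ by an order of magnitude in
# extent), and raw-coordinate circumradii would discard every triangle
# of a thin region.  Triangle indices refer to the original points, so
# areas are still measured in raw units.
alpha_complex <- function(x, y, alpha = NULL) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || sx <= 0) sx <- max(abs(x), 1)
  if (!is.finite(sy) || sy <= 0) sy <- max(abs(y), 1)
  xs <- x / sx; ys <- y / sy
  tri <- delaunay_triangulation(xs, ys)
  if (is.null(alpha)) alpha <- 2 * .median_nn_spacing(xs, ys)
  r <- .tri_circumradius(xs, ys, tri)
  list(triangles = tri[r <= alpha, , drop = FALSE], alpha = alpha)
}

# Area of the 2-manifold z = f(x, y) sampled at scattered points: planar
# alpha-complex triangulation lifted to 3D, summing 3D triangle areas.
lifted_surface_area <- function(x, y, z, alpha = NULL) {
  n <- length(x)
  if (n < 3) stop("degenerate geometry: need at least 3 points")
  if (abs(stats::sd(x)) < 1e-300 || abs(stats::sd(y)) < 1e-300 ||
      qr(cbind(1, x, y))$rank < 3)
    stop("degenerate geometry: points are collinear")
  ac <- alpha_complex(x, y, alpha)
  tri <- ac$triangles
  if (nrow(tri) == 0) return(0)
  area <- 0
  for (k in seq_len(nrow(tri))) {
    i <- tri[k, 1]; j <- tri[k, 2]; l <- tri[k, 3]
    u <- c(x[j] - x[i], y[j] - y[i], z[j] - z[i])
    v <- c(x[l] - x[i], y[l] - y[i], z[l] - z[i])
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    area <- area + 0.5 * sqrt(sum(cr^2))
  }
  area
}

# TRUE if point (qx, qy) lies inside (or on the boundary of) any triangle
# of the alpha complex of (x, y).
point_in_alpha_region <- function(qx, qy, x, y, alpha = NULL) {
  ac <- alpha_complex(x, y, alpha)
  tri <- ac$triangles
  if (nrow(tri) == 0) return(FALSE)
  for (k in seq_len(nrow(tri))) {
    i <- tri[k, 1]; j <- tri[k, 2]; l <- tri[k, 3]
    d <- (y[j] - y[l]) * (x[i] - x[l]) + (x[l] - x[j]) * (y[i] - y[l])
    if (abs(d) < 1e-300) next
    a <- ((y[j] - y[l]) * (qx - x[l]) + (x[l] - x[j]) * (qy - y[l])) / d
    b <- ((y[l] - y[i]) * (qx - x[l]) + (x[i] - x[l]) * (qy - y[l])) / d
    g <- 1 - a - b
    if (a >= -1e-9 && b >= -1e-9 && g >= -1e-9) return(TRUE)
  }
  FALSE
}
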
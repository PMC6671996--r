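test_that("planar triangles have their exact areas", {
  # unit right triangle, flat lift
  df <- data.frame(K_p1 = c(0, 1, 0), K_p2 = c(0, 0, 1),
                   k_p3 = c(0.5, 0.5, 0.5))
  expect_equal(surface_area(df, alpha = Inf), 0.5)
  # lift tilted 45 degrees along the first axis: area scales by sqrt(2)
  df$k_p3 <- c(0, 1, 0)
  expect_equal(surface_area(df, alpha = Inf), 0.5 * sqrt(2))
})

test_that("degenerate point sets are rejected", {
  expect_error(surface_area(data.frame(K_p1 = 1:2, K_p2 = 1:2,
                                       k_p3 = 1:2)), "degenerate")
  expect_error(
    surface_area(data.frame(K_p1 = c(1, 2, 3), K_p2 = c(1, 2, 3),
                            k_p3 = c(0, 0, 0))), "collinear")
})

test_that("delaunay triangulation covers the convex hull exactly", {
  set.seed(5)
  x <- runif(60); y <- runif(60)
  tri <- hpaclock:::delaunay_triangulation(x, y)
  # total triangle area equals the convex hull area
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  tri_area <- sum(apply(tri, 1, function(tr)
    abs((x[tr[2]] - x[tr[1]]) * (y[tr[3]] - y[tr[1]]) -
          (x[tr[3]] - x[tr[1]]) * (y[tr[2]] - y[tr[1]])) / 2))
  expect_equal(tri_area, hull_area, tolerance = 1e-9)
  # no triangle's circumcircle strictly contains another point
  bad <- 0
  for (k in seq_len(nrow(tri))) {
    tr <- tri[k, ]
    d <- 2 * (x[tr[1]] * (y[tr[2]] - y[tr[3]]) +
                x[tr[2]] * (y[tr[3]] - y[tr[1]]) +
                x[tr[3]] * (y[tr[1]] - y[tr[2]]))
    ux <- ((x[tr[1]]^2 + y[tr[1]]^2) * (y[tr[2]] - y[tr[3]]) +
             (x[tr[2]]^2 + y[tr[2]]^2) * (y[tr[3]] - y[tr[1]]) +
             (x[tr[3]]^2 + y[tr[3]]^2) * (y[tr[1]] - y[tr[2]])) / d
    uy <- ((x[tr[1]]^2 + y[tr[1]]^2) * (x[tr[3]] - x[tr[2]]) +
             (x[tr[2]]^2 + y[tr[2]]^2) * (x[tr[1]] - x[tr[3]]) +
             (x[tr[3]]^2 + y[tr[3]]^2) * (x[tr[2]] - x[tr[1]])) / d
    r2 <- (x[tr[1]] - ux)^2 + (y[tr[1]] - uy)^2
    others <- setdiff(seq_along(x), tr)
    if (any((x[others] - ux)^2 + (y[others] - uy)^2 < r2 * (1 - 1e-9)))
      bad <- bad + 1
  }
  expect_equal(bad, 0)
})

test_that("area of a sampled analytic surface approaches the true value", {
  # z = 0.3 x^2 + 0.2 y on the unit square; area = integral of
  # sqrt(1 + (0.6 x)^2 + 0.2^2)
  f <- function(x, y) 0.3 * x^2 + 0.2 * y
  true_area <- stats::integrate(function(x)
    sqrt(1 + (0.6 * x)^2 + 0.04), 0, 1)$value  # independent of y
  set.seed(8)
  n <- 900
  x <- runif(n); y <- runif(n)
  est <- hpaclock:::lifted_surface_area(x, y, f(x, y), alpha = Inf)
  expect_equal(est, true_area, tolerance = 0.02)
})

test_that("alpha complex excludes far-flung triangles of concave sets", {
  # two clusters: convex-hull area would bridge the gap
  set.seed(2)
  x <- c(runif(40, 0, 1), runif(40, 3, 4))
  y <- c(runif(40), runif(40))
  ac <- hpaclock:::alpha_complex(x, y)
  # no triangle spans both clusters
  spans <- apply(ac$triangles, 1, function(tr)
    length(unique(x[tr] > 2)) > 1)
  expect_false(any(spans))
})

test_that("convex-hull containment test classifies interior points", {
  df <- data.frame(K_p1 = c(0, 1, 1, 0), K_p2 = c(0, 0, 1, 1))
  expect_true(subspace_contains(df, c(K_p1 = 0.5, K_p2 = 0.5)))
  expect_false(subspace_contains(df, c(K_p1 = 1.5, K_p2 = 0.5)))
  expect_false(subspace_contains(df[1:2, ], c(K_p1 = 0.5, K_p2 = 0)))
})
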
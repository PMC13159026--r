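# Shared analytic fixtures, built in code (no stored data).

# 20 x 8 mm rectangle, vertices on a regular grid, counter-clockwise
rect_poly <- function(w = 20, h = 8, step = 0.5) {
  xs <- seq(0, w, by = step)
  ys <- seq(-h / 2, h / 2, by = step)
  p <- rbind(cbind(xs, -h / 2), cbind(w, ys[-1]),
             cbind(rev(xs)[-1], h / 2), cbind(0, rev(ys)[-1]))
  p[-nrow(p), ]
}

# upward-arching half-annulus sector (inner radius r1, outer r2)
annulus_poly <- function(r1 = 10, r2 = 15, n = 240) {
  th <- seq(0, pi, length.out = n + 1)
  rr <- seq(r2, r1, length.out = 21)
  rr2 <- seq(r1, r2, length.out = 21)
  rbind(cbind(r2 * cos(th), r2 * sin(th))[-1, ],
        cbind(-rr, 0)[-1, ],
        cbind(r1 * cos(rev(th)), r1 * sin(rev(th)))[-1, ],
        cbind(rr2, 0)[-1, ])
}

# partitioned rectangle mesh with endpoints at the side-edge midpoints
make_rect_mesh <- function(max_edge = 0.5) {
  mesh <- contour_to_mesh(rect_poly(step = max_edge), max_edge)
  partition_boundary(mesh, find_endpoints(mesh, AC = c(-1, 0), PC = c(21, 0)))
}

# partitioned annulus-sector mesh with endpoints at the cap midpoints
make_annulus_mesh <- function(max_edge = 0.25, n = 240) {
  mesh <- contour_to_mesh(annulus_poly(n = n), max_edge)
  partition_boundary(mesh,
                     find_endpoints(mesh, AC = c(-12.5, -2), PC = c(12.5, -2)))
}

# full Laplace stack on a partitioned mesh
laplace_stack <- function(mesh, n = 100) {
  u <- solve_laplace(mesh)
  v <- conjugate_potential(mesh, u)
  line <- intercallosal_line(mesh, u)
  profile <- thickness_profile(mesh, u, v, line, n = n)
  list(mesh = mesh, u = u, v = v, line = line, profile = profile)
}

# random star-shaped polygon around a center (smooth radial perturbation)
random_star_poly <- function(seed, n = 80, radius = 10, wobble = 0.25) {
  set.seed(seed)
  k <- 2:5
  a <- stats::runif(length(k), 0, wobble / length(k))
  ph <- stats::runif(length(k), 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  r <- radius * (1 + colSums(a * sin(outer(k, th) + ph)))
  cbind(r * cos(th), r * sin(th))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
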
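# Laplace solve, conjugate potential, level sets, intercallosal line,
# thickness profile, curvature, and the streamline cross-check.

rect_stack <- NULL
ann_stack <- NULL
get_rect <- function() {
  if (is.null(rect_stack)) rect_stack <<- laplace_stack(make_rect_mesh(0.5))
  rect_stack
}
get_ann <- function() {
  if (is.null(ann_stack)) ann_stack <<- laplace_stack(make_annulus_mesh(0.25))
  ann_stack
}

test_that("harmonic solution matches closed forms on analytic shapes", {
  st <- get_rect()
  exact <- st$mesh$vertices[, 2] / 4   # u = 2s/8 - 1 with s in [-4, 4]
  expect_lt(max(abs(st$u$u - exact)), 1e-6)

  # Dirichlet data reproduced exactly on the charged chain portions
  charged <- st$u$dirichlet
  inf_ch <- intersect(which(charged), st$mesh$chains$inferior)
  sup_ch <- intersect(which(charged), st$mesh$chains$superior)
  expect_true(all(st$u$u[inf_ch] == -1))
  expect_true(all(st$u$u[sup_ch] == 1))

  sa <- get_ann()
  r <- sqrt(rowSums(sa$mesh$vertices^2))
  exact_a <- 2 * log(r / 10) / log(1.5) - 1
  expect_lt(max(abs(sa$u$u - exact_a)), 1e-3)

  # discrete maximum principle: interior values strictly inside (-1, 1)
  for (st_i in list(st, sa)) {
    interior <- !(seq_len(nrow(st_i$mesh$vertices)) %in% st_i$mesh$boundary)
    expect_gt(min(st_i$u$u[interior]), -1)
    expect_lt(max(st_i$u$u[interior]), 1)
  }

  # degenerate triangle -> error naming the triangle
  bad <- make_rect_mesh(1)
  bad$vertices[bad$triangles[5, 2], ] <- bad$vertices[bad$triangles[5, 1], ]
  expect_error(solve_laplace(bad), "degenerate")
})

test_that("conjugate potential is the rotated-gradient potential", {
  st <- get_rect()
  fit <- stats::lm(st$v ~ st$mesh$vertices[, 1])
  expect_lt(max(abs(stats::residuals(fit))), 1e-6)
  # v increases anterior -> posterior
  expect_gt(st$v[st$mesh$endpoints[["posterior"]]],
            st$v[st$mesh$endpoints[["anterior"]]])

  # orthogonality of the conjugate gradients (exact for linear fields)
  gu <- ccmorph:::tri_gradients(st$mesh, st$u$u)
  gv <- ccmorph:::tri_gradients(st$mesh, st$v)
  cosang <- abs(rowSums(gu * gv)) / sqrt(rowSums(gu^2) * rowSums(gv^2))
  expect_lt(median(cosang), 1e-3)

  # annulus: v ~ theta; P1 gradients are O(h), so the pointwise residual is
  # discretization-limited (~2e-3 at h = 0.25, converging with h)
  sa <- get_ann()
  th <- atan2(sa$mesh$vertices[, 2], sa$mesh$vertices[, 1])
  fa <- stats::lm(sa$v ~ th)
  expect_lt(sqrt(mean(stats::residuals(fa)^2)), 1e-3)
  expect_lt(max(abs(stats::residuals(fa))), 5e-3)
  gu <- ccmorph:::tri_gradients(sa$mesh, sa$u$u)
  gv <- ccmorph:::tri_gradients(sa$mesh, sa$v)
  cosang <- abs(rowSums(gu * gv)) / sqrt(rowSums(gu^2) * rowSums(gv^2))
  expect_lt(median(cosang), 2e-2)
  expect_lt(median(abs(90 - acos(cosang * sign(1)) * 180 / pi)), 1.5)
})

test_that("level sets are linear-interpolation curves with correct geometry", {
  st <- get_rect()
  pls <- extract_level_set(st$mesh, st$u, 0)
  expect_length(pls, 1)
  expect_lt(max(abs(pls[[1]]$points[, 2])), 1e-6)  # mid-height line

  sa <- get_ann()
  pls_a <- extract_level_set(sa$mesh, sa$u, 0)
  r0 <- sqrt(rowSums(pls_a[[1]]$points^2))
  expect_lt(max(abs(r0 - sqrt(150))), 5e-3)

  # out-of-range value -> empty
  expect_length(extract_level_set(st$mesh, st$u, 2), 0)

  # v-level path at a midline value crosses inferior -> superior
  vmid <- mean(range(st$v))
  plv <- extract_level_set(st$mesh, st$v, vmid)
  ends_s <- range(plv[[1]]$points[, 2])
  expect_equal(ends_s, c(-4, 4), tolerance = 1e-6)
})

test_that("intercallosal line has correct length, ends, and orientation", {
  st <- get_rect()
  expect_rel_equal(st$line$length_mm, 20, 0.005)
  sa <- get_ann()
  expect_rel_equal(sa$line$length_mm, pi * sqrt(150), 0.005)

  # ends within one local edge length of the endpoint vertices
  for (s in list(st, sa)) {
    epv <- s$mesh$vertices[s$mesh$endpoints, , drop = FALSE]
    d1 <- sqrt(sum((s$line$points[1, ] - epv[1, ])^2))
    d2 <- sqrt(sum((s$line$points[nrow(s$line$points), ] - epv[2, ])^2))
    edge <- 0.5  # >= max_edge of both fixtures
    expect_lt(d1, edge)
    expect_lt(d2, edge)
  }

  # swapping the landmark roles reverses the polyline order only
  m2 <- contour_to_mesh(rect_poly(step = 0.5), 0.5)
  m2 <- partition_boundary(m2, find_endpoints(m2, AC = c(21, 0), PC = c(-1, 0)))
  u2 <- solve_laplace(m2)
  l2 <- intercallosal_line(m2, u2)
  expect_equal(l2$points[1, ], st$line$points[nrow(st$line$points), ],
               tolerance = 1e-9)
  expect_equal(l2$length_mm, st$line$length_mm, tolerance = 1e-9)
})

test_that("thickness profiles recover analytic cross-cut lengths", {
  st <- get_rect()
  expect_true(all(st$profile$valid))
  expect_rel_equal(st$profile$thickness, 8, 0.01)

  sa <- get_ann()
  interior <- 3:98
  expect_rel_equal(sa$profile$thickness[interior], 5, 0.01)

  # level paths end on oppositely labeled chains by construction
  expect_true(all(sa$profile$valid))
})

test_that("thickness is invariant under rigid motion of the input", {
  spec0 <- ribbon_spec(resolution = 0.5)
  spec1 <- ribbon_spec(resolution = 0.5, rotation_deg = 17,
                       shift_mm = c(3.2, -1.7))
  pr <- lapply(list(spec0, spec1), function(sp) {
    rib <- generate_ribbon(sp)
    out <- run_pipeline(pipeline_config(mask = rib$mask,
                                        resolution = rib$resolution,
                                        landmarks = rib$landmarks,
                                        max_edge = 0.75, profile_n = 50))
    out$results$profile$thickness
  })
  # tolerance: rasterization error of the rotated grid
  expect_lt(stats::median(abs(pr[[1]] - pr[[2]])), 0.05)
  expect_lt(max(abs(pr[[1]] - pr[[2]])[5:46]), 0.2)
})

test_that("mesh refinement reduces thickness error", {
  errs <- sapply(c(1, 0.5, 0.25), function(h) {
    stk <- laplace_stack(make_annulus_mesh(max_edge = h,
                                           n = ceiling(60 / h)), n = 50)
    max(abs(stk$profile$thickness[5:46] - 5))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("level-path thickness matches explicit streamline tracing", {
  for (stk in list(get_rect(), get_ann())) {
    tgt <- c(0.15, 0.5, 0.85) * stk$line$length_mm
    for (t0 in tgt) {
      p <- c(ccmorph:::interp1(stk$line$arclen, stk$line$points[, 1], t0),
             ccmorph:::interp1(stk$line$arclen, stk$line$points[, 2], t0))
      t_stream <- thickness_by_streamline(stk$mesh, stk$u, p)
      i <- which.min(abs(stk$line$arclen[1] +
                           stk$profile$positions * stk$line$length_mm - t0))
      expect_rel_equal(t_stream, stk$profile$thickness[i], 0.02)
    }
  }
})

test_that("curvature and length behave on canonical polylines", {
  straight <- cbind(seq(0, 10, 0.1), 0)
  expect_equal(line_curvature(straight), 0)

  th <- seq(0, pi, length.out = 200)
  arc <- sqrt(150) * cbind(cos(th), sin(th))
  expect_rel_equal(line_curvature(arc), 1 / sqrt(150), 0.02)

  # scale covariance
  expect_rel_equal(line_curvature(3 * arc), 1 / (3 * sqrt(150)), 0.02)

  expect_equal(line_length(rbind(c(0, 0), c(3, 0))), 3)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(line_length(sq), 4)

  set.seed(5)
  rnd <- matrix(rnorm(20), 10, 2)
  expect_equal(line_length(rnd),
               sum(sqrt(rowSums((rnd[-1, ] - rnd[-10, ])^2))))
})
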
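# Sub-segmentation schemes: exact splits, conservation, cross-scheme
# agreement on straight ribbons, and the perpendicular property on bent ones.

test_that("anchor-line cuts give exact projection-proportional areas", {
  mesh <- make_rect_mesh(0.5)
  anchor <- rbind(c(0, 0), c(20, 0))

  half <- subsegment_anchor_line(mesh, anchor, 0.5)
  expect_equal(half$region_areas, c(80, 80), tolerance = 1e-9)

  hf <- subsegment_anchor_line(mesh, anchor, c(1 / 6, 1 / 2, 2 / 3, 3 / 4))
  expect_equal(hf$region_areas / 160,
               c(1 / 6, 1 / 3, 1 / 6, 1 / 12, 1 / 4), tolerance = 1e-9)
  expect_equal(sum(hf$region_areas), 160, tolerance = 1e-9)
  expect_length(hf$face_labels, nrow(mesh$triangles))

  expect_error(subsegment_anchor_line(mesh, rbind(c(1, 1), c(1, 1)), 0.5),
               "degenerate")
})

test_that("eigendirection cuts equal widths along the principal axis", {
  mesh <- make_rect_mesh(0.5)
  se <- subsegment_eigendirection(mesh, 5)
  expect_equal(se$region_areas, rep(32, 5), tolerance = 1e-6)

  # rotation equivariance: areas unchanged under rotation
  rot <- mesh
  ang <- 37 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  rot$vertices <- mesh$vertices %*% t(R)
  se2 <- subsegment_eigendirection(rot, 5)
  expect_equal(se2$region_areas, se$region_areas, tolerance = 1e-6)

  # isotropic shape -> ambiguous axis
  sq <- contour_to_mesh(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), 1)
  expect_error(subsegment_eigendirection(sq, 3), "ambiguous")
})

test_that("ray scheme yields equal sectors on the symmetric half annulus", {
  mesh <- make_annulus_mesh(max_edge = 0.5, n = 180)
  sr <- subsegment_rays(mesh, 3)
  expect_rel_equal(sr$region_areas, mean(sr$region_areas), 0.01)
  expect_equal(sum(sr$region_areas), sum(triangle_areas(mesh)),
               tolerance = 1e-6)

  # left-right reflection reverses the region order
  refl <- mesh
  refl$vertices <- cbind(-mesh$vertices[, 1], mesh$vertices[, 2])
  refl$triangles <- refl$triangles[, c(1, 3, 2)]  # restore orientation
  sr2 <- subsegment_rays(refl, 3)
  expect_equal(sr2$region_areas, rev(sr$region_areas), tolerance = 1e-6)

  # origin inside the shape is invalid geometry
  sq <- contour_to_mesh(rbind(c(-5, 0), c(5, 0), c(5, 10), c(-5, 10)), 1)
  sq$vertices[, 2] <- sq$vertices[, 2] - 0.5  # origin now strictly inside
  expect_error(subsegment_rays(sq, 3), "inside")
})

test_that("arclength cuts coincide with anchor cuts on a straight ribbon", {
  st <- laplace_stack(make_rect_mesh(0.5))
  fr <- c(1 / 6, 1 / 2, 2 / 3, 3 / 4)
  sa <- subsegment_arclength(st$mesh, st$v, st$line, fr)
  sl <- subsegment_anchor_line(st$mesh, rbind(c(0, 0), c(20, 0)), fr)
  expect_lt(max(abs(sa$region_areas - sl$region_areas)) / 160, 0.01)
  expect_equal(sum(sa$region_areas), 160, tolerance = 1e-6)

  # angular symmetry on the half annulus
  ann <- laplace_stack(make_annulus_mesh(max_edge = 0.4, n = 180))
  sh <- subsegment_arclength(ann$mesh, ann$v, ann$line, 0.5)
  expect_rel_equal(sh$region_areas[1], sh$region_areas[2], 0.01)
})

test_that("arclength cuts cross the intercallosal line perpendicularly on a
           bent shape, anchor-line cuts do not", {
  ann <- laplace_stack(make_annulus_mesh(max_edge = 0.4, n = 180))
  fr <- c(1 / 6, 1 / 2, 2 / 3, 3 / 4)
  # cut level paths: v-level sets at the cut values
  v_line <- ccmorph:::interp_on_line(ann$line, ann$v)
  cuts <- ccmorph:::interp1(ann$line$arclen, v_line, fr * ann$line$length_mm)
  angles <- sapply(cuts, function(cv) {
    pl <- extract_level_set(ann$mesh, ann$v, cv)[[1]]
    # direction of the cut at its crossing with the line (radius ~ sqrt(150))
    rr <- sqrt(rowSums(pl$points^2))
    i <- which.min(abs(rr - sqrt(150)))
    j <- max(2, min(i, nrow(pl$points) - 1))
    cut_dir <- pl$points[j + 1, ] - pl$points[j - 1, ]
    # local line direction: tangent of the circle at that angle
    th <- atan2(pl$points[j, 2], pl$points[j, 1])
    line_dir <- c(-sin(th), cos(th))
    ang <- acos(abs(sum(ccmorph:::unit(cut_dir) * line_dir))) * 180 / pi
    90 - ang  # deviation of the crossing angle from 90 degrees
  })
  expect_lt(median(abs(angles)), 5)

  # the anchor-line (vertical) cut at the apex is ~parallel-to-radius there,
  # but at fraction 1/6 (theta = 5pi/6) a vertical cut meets the circle
  # tangent at |90 - angle| = 30 degrees: clearly not perpendicular
  th_16 <- pi - pi / 6
  vert_dev <- abs(90 - acos(abs(sum(c(0, 1) * c(-sin(th_16), cos(th_16)))))
                  * 180 / pi)
  expect_gt(vert_dev, 25)
})

test_that("all schemes conserve total area on random bent ribbons", {
  set.seed(77)
  for (k in 1:6) {
    spec <- ribbon_spec(radius_mm = runif(1, 15, 25),
                        span_rad = runif(1, 2, pi),
                        half_width = local({
                          a <- runif(1, 2, 3); b <- runif(1, 0, 1.5)
                          function(s) a + b * s
                        }),
                        resolution = 0.7,
                        rotation_deg = runif(1, -10, 10))
    rib <- generate_ribbon(spec)
    ct <- mask_to_contour(rib$mask, rib$resolution)
    mesh <- contour_to_mesh(ct, 1)
    mesh <- partition_boundary(mesh, find_endpoints(mesh, rib$landmarks$AC,
                                                    rib$landmarks$PC))
    total <- sum(triangle_areas(mesh))
    u <- solve_laplace(mesh)
    v <- conjugate_potential(mesh, u)
    line <- intercallosal_line(mesh, u)
    res <- list(
      subsegment(mesh, "hofer_frahm"),
      subsegment(mesh, "witelson"),
      subsegment(mesh, "eigen", n_regions = 5),
      subsegment(mesh, "rays", n_regions = 5),
      subsegment(mesh, "arclength", v = v, line = line))
    for (r in res) {
      expect_lt(abs(sum(r$region_areas) / total - 1), 1e-6)
      expect_true(all(r$region_areas >= 0))
      expect_true(all(r$face_labels %in% seq_len(r$n_regions)))
    }
  }
})
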
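# Mask -> contour -> mesh conversion, endpoint localization, and boundary
# partitioning.

test_that("mask_to_contour extracts the largest sub-voxel component", {
  expect_error(mask_to_contour(matrix(0, 5, 5)), "empty")

  # filled rectangle: polygon area within 2% of pixel-count area
  m <- matrix(0, 26, 14)
  m[4:23, 4:11] <- 1
  ct <- mask_to_contour(m, resolution = 1)
  expect_rel_equal(abs(polygon_area(ct$vertices)), sum(m), 0.02)
  expect_gt(polygon_area(ct$vertices), 0)  # counter-clockwise

  # two disjoint blobs: the larger one wins (per-component pixel counts)
  m2 <- matrix(0, 40, 20)
  m2[3:13, 3:13] <- 1          # ~121 px
  m2[30:32, 6:8] <- 1          # 9 px
  ct2 <- mask_to_contour(m2, resolution = 1)
  expect_lt(max(ct2$vertices[, 1]), 20)  # encloses only the big blob
  expect_rel_equal(abs(polygon_area(ct2$vertices)), 121, 0.05)

  expect_error(mask_to_contour(m2, min_area_mm2 = 1000), "below minimum")

  # resolution scaling
  ct3 <- mask_to_contour(m, resolution = 0.5)
  expect_rel_equal(abs(polygon_area(ct3$vertices)), sum(m) * 0.25, 0.02)
})

test_that("contour area converges to analytic area with resolution", {
  # rasterized disk, radius 7 mm, antialiased; order >= 1 convergence
  errs <- sapply(c(1, 0.5, 0.25), function(res) {
    xs <- seq(-10, 10, by = res)
    sub <- (1:4 - 2.5) / 4 * res
    cov <- 0
    for (ox in sub) for (oy in sub)
      cov <- cov + outer(xs + ox, xs + oy, function(x, y) x^2 + y^2 <= 49)
    ct <- mask_to_contour(cov / 16, resolution = res)
    abs(abs(polygon_area(ct$vertices)) - pi * 49)
  })
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[3], 4)  # at least first order over a 4x ladder
})

test_that("contour_to_mesh triangulates exactly to the polygon", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  msq <- contour_to_mesh(sq, 0.2)
  expect_equal(sum(triangle_areas(msq)), 1, tolerance = 1e-9)
  expect_true(all(triangle_areas(msq) > 0))  # all CCW

  ct <- mask_to_contour({m <- matrix(0, 30, 16); m[5:26, 5:12] <- 1; m}, 0.7)
  mm <- contour_to_mesh(ct, 0.5)
  expect_equal(sum(triangle_areas(mm)), polygon_area(ct$vertices),
               tolerance = 1e-9)
  # interior edges respect the target length (boundary edges come from the
  # contour and are densified to at most max_edge)
  tr <- mm$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  elen <- sqrt(rowSums((mm$vertices[e[, 1], ] - mm$vertices[e[, 2], ])^2))
  expect_lt(max(elen), 2 * 0.5)

  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(contour_to_mesh(bow, 0.5), "self-intersecting")
})

test_that("find_endpoints picks the nearest boundary vertices", {
  mesh <- make_annulus_mesh(max_edge = 0.5, n = 120)
  # exhaustive oracle
  bv <- mesh$vertices[mesh$boundary, ]
  for (lm in list(list(AC = c(-12.5, -5), PC = c(12.5, -5)),
                  list(AC = c(-14, -1), PC = c(11, -2)))) {
    ep <- find_endpoints(mesh, lm$AC, lm$PC)
    oa <- mesh$boundary[which.min(colSums((t(bv) - lm$AC)^2))]
    op <- mesh$boundary[which.min(colSums((t(bv) - lm$PC)^2))]
    expect_equal(unname(ep), c(oa, op))
  }

  # rectangle with AC/PC below the bottom corners -> bottom corners
  rmesh <- contour_to_mesh(rect_poly(), 0.5)
  ep2 <- find_endpoints(rmesh, AC = c(0, -9), PC = c(20, -9))
  expect_equal(unname(rmesh$vertices[ep2["anterior"], ]), c(0, -4))
  expect_equal(unname(rmesh$vertices[ep2["posterior"], ]), c(20, -4))

  # joint translation leaves endpoint indices unchanged
  shifted <- rmesh
  shifted$vertices <- sweep(rmesh$vertices, 2, c(-13, 7), `+`)
  ep3 <- find_endpoints(shifted, c(0, -9) + c(-13, 7), c(20, -9) + c(-13, 7))
  expect_equal(ep3, ep2)

  expect_error(find_endpoints(rmesh, c(0, -9), c(0.01, -9)), "coincide")
})

test_that("partition_boundary labels inferior/superior chains", {
  mesh <- contour_to_mesh(rect_poly(), 0.5)
  ep <- find_endpoints(mesh, c(-1, 0), c(21, 0))  # side-edge midpoints
  mesh <- partition_boundary(mesh, ep)

  inf_s <- mean(mesh$vertices[mesh$chains$inferior, 2])
  sup_s <- mean(mesh$vertices[mesh$chains$superior, 2])
  expect_lt(inf_s, 0)
  expect_gt(sup_s, 0)

  # every boundary edge labeled exactly once, chains meet at the endpoints
  expect_length(mesh$chain_labels, length(mesh$boundary))
  expect_true(all(mesh$chain_labels %in% c("inferior", "superior")))
  expect_setequal(intersect(mesh$chains$inferior, mesh$chains$superior),
                  unname(ep))

  # arch: inner arc is the inferior chain (mean superior coordinate
  # (2/pi) r1 < (2/pi) r2)
  am <- make_annulus_mesh(max_edge = 0.5, n = 120)
  r_inf <- mean(sqrt(rowSums(am$vertices[am$chains$inferior, ]^2)))
  r_sup <- mean(sqrt(rowSums(am$vertices[am$chains$superior, ]^2)))
  expect_lt(r_inf, r_sup)

  # adjacent endpoints -> error
  loop <- mesh$boundary
  expect_error(partition_boundary(mesh, c(anterior = loop[1],
                                          posterior = loop[2])),
               "adjacent")
})

test_that("meshes and contours export to OFF/VTK/CSV", {
  mesh <- make_rect_mesh(1)
  f_off <- tempfile(fileext = ".off")
  write_mesh_off(mesh, f_off)
  lines <- readLines(f_off)
  expect_equal(lines[1], "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_equal(counts[1:2], c(nrow(mesh$vertices), nrow(mesh$triangles)))

  f_vtk <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, f_vtk, point_scalars = list(u = rnorm(nrow(mesh$vertices))))
  expect_true(any(grepl("^POLYGONS", readLines(f_vtk))))

  ct <- mask_to_contour({m <- matrix(0, 10, 10); m[3:8, 3:8] <- 1; m}, 1)
  f_csv <- tempfile(fileext = ".csv")
  write_contour_csv(ct, f_csv)
  df <- utils::read.csv(f_csv)
  expect_equal(nrow(df), nrow(ct$vertices))
  unlink(c(f_off, f_vtk, f_csv))
})
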
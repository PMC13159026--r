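# Mid-sagittal plane estimation: centroids, Kabsch registration, plane
# mapping, slice extraction, plane disagreement, head-pose standardization.

make_cloud <- function(points, labels = seq_len(nrow(points))) {
  structure(list(labels = labels, points = points), class = "cc_centroids")
}

test_that("label centroids equal brute-force voxel means under any affine", {
  vox <- array(0L, c(12, 12, 12))
  vox[5, 7, 3] <- 1L
  lm <- label_map(vox)
  cl <- compute_label_centroids(lm)
  expect_equal(as.numeric(cl$points), c(4, 6, 2))  # 0-based voxel center

  # two voxels symmetric about the origin
  vox2 <- array(0L, c(11, 11, 11))
  vox2[3, 5, 7] <- 2L
  vox2[9, 7, 5] <- 2L
  aff <- diag(4); aff[1:3, 4] <- -c(5, 5, 5)
  cl2 <- compute_label_centroids(label_map(vox2, aff))
  expect_equal(as.numeric(cl2$points), c(0, 0, 0))

  # random 50-voxel blob, oblique affine: exhaustive-mean oracle
  set.seed(11)
  vox3 <- array(0L, c(20, 20, 20))
  idx <- unique(matrix(sample(0:19, 180, replace = TRUE), ncol = 3))[1:50, ]
  vox3[idx + 1] <- 7L
  aff3 <- diag(4)
  aff3[1:3, 1:3] <- matrix(c(0.9, 0.1, 0, -0.2, 1.1, 0.05, 0, 0.1, 0.95), 3, 3)
  aff3[1:3, 4] <- c(-3, 2, 5)
  cl3 <- compute_label_centroids(label_map(vox3, aff3), labels = 7)
  world <- cbind(idx, 1) %*% t(aff3)
  expect_equal(as.numeric(cl3$points), colMeans(world[, 1:3]), tolerance = 1e-12)

  expect_error(compute_label_centroids(label_map(vox), labels = 99), "99")
})

test_that("Kabsch registration recovers rigid transforms exactly", {
  set.seed(21)
  pts <- matrix(rnorm(30, sd = 25), 10, 3)
  cl <- make_cloud(pts)

  expect_equal(unclass(rigid_register_centroids(cl, cl)), diag(4),
               tolerance = 1e-12, ignore_attr = TRUE)

  T_true <- rigid_transform(30, c(0, 0, 1), shift = c(5, -3, 2))
  tgt <- make_cloud(ccmorph:::apply_rigid(T_true, pts))
  T_est <- rigid_register_centroids(cl, tgt)
  expect_lt(max(abs(T_est - T_true)), 1e-9)

  # noisy clouds: residual RMS bounded, rotation stays proper
  for (rep in 1:20) {
    noisy <- make_cloud(tgt$points + matrix(rnorm(30, sd = 0.1), 10, 3))
    T_n <- rigid_register_centroids(cl, noisy)
    expect_equal(det(T_n[1:3, 1:3]), 1, tolerance = 1e-9)
    res <- ccmorph:::apply_rigid(T_n, pts) - noisy$points
    expect_lt(sqrt(mean(res^2)), 3 * 0.1)
  }

  # near-planar cloud: reflection correction keeps det = +1
  flat <- matrix(rnorm(30, sd = 20), 10, 3)
  flat[, 3] <- flat[, 3] * 1e-6
  T_f <- rigid_register_centroids(
    make_cloud(flat),
    make_cloud(ccmorph:::apply_rigid(rigid_transform(170, c(1, 0, 0)), flat)))
  expect_equal(det(T_f[1:3, 1:3]), 1, tolerance = 1e-9)

  expect_error(rigid_register_centroids(make_cloud(pts[1:2, ], 1:2),
                                        make_cloud(pts[1:2, ], 1:2)),
               "at least 3")
  line_pts <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(rigid_register_centroids(make_cloud(line_pts),
                                        make_cloud(line_pts)),
               "rank-deficient")
})

test_that("template mid-plane maps back through the inverse transform", {
  pl <- plane(point = c(1, 2, 3), normal = c(1, 0.1, -0.2))

  id <- rigid_transform(0)
  pl_id <- map_template_midplane(id, pl)
  expect_equal(pl_id$point, pl$point)
  expect_equal(pl_id$normal, pl$normal)

  d <- c(4, -7, 2)
  pl_tr <- map_template_midplane(rigid_transform(0, shift = d), pl)
  expect_equal(pl_tr$point, pl$point - d)
  expect_equal(pl_tr$normal, pl$normal)

  # composition: mapping by T2 T1 equals mapping by T1 then by T2
  T1 <- rigid_transform(25, c(0.2, 1, 0.1), shift = c(1, 2, 3))
  T2 <- rigid_transform(-40, c(1, 0.3, 0), shift = c(-2, 0, 5))
  T21 <- structure(T2 %*% T1, class = c("cc_rigid", "matrix"))
  a <- map_template_midplane(T21, pl)
  b <- map_template_midplane(T1, map_template_midplane(T2, pl))
  expect_equal(a$point, b$point, tolerance = 1e-12)
  expect_equal(a$normal, b$normal, tolerance = 1e-12)

  # serialization round trip
  M <- plane_to_matrix(pl)
  pl2 <- plane_from_matrix(M)
  expect_equal(pl2$point, pl$point)
  expect_equal(pl2$axes, pl$axes, ignore_attr = TRUE)
})

test_that("slice extraction follows the counting rule and interpolates", {
  vol <- array(3.5, c(20, 20, 20))
  pl <- plane(c(9, 10, 10), c(1, 0, 0))
  st <- extract_midsagittal_slices(vol, diag(4), pl, half_width_mm = 2.5,
                                   spacing = 1, in_plane_res = 1,
                                   extent = c(-4, 4, -4, 4))
  expect_length(st$slices, 5)
  expect_equal(st$offsets, -2:2)
  expect_true(all(vapply(st$slices, function(s) all(s == 3.5), logical(1))))

  st2 <- extract_midsagittal_slices(vol, diag(4), pl, half_width_mm = 2.5,
                                    spacing = 0.5, in_plane_res = 1,
                                    extent = c(-4, 4, -4, 4))
  expect_length(st2$slices, 11)

  # linear ramp, plane halfway between voxel planes -> midpoint values
  ramp <- array(rep(0:19, times = 400), c(20, 20, 20))
  plh <- plane(c(10.5, 10, 10), c(1, 0, 0))
  sth <- extract_midsagittal_slices(ramp, diag(4), plh, half_width_mm = 0,
                                    spacing = 1, in_plane_res = 1,
                                    extent = c(-3, 3, -3, 3))
  expect_equal(mean(sth$slices[[1]]), 10.5, tolerance = 1e-12)

  # nearest-neighbor keeps masks binary
  maskv <- array(0L, c(20, 20, 20)); maskv[8:12, 8:12, 8:12] <- 1L
  stn <- extract_midsagittal_slices(maskv, diag(4), plh, half_width_mm = 1,
                                    spacing = 1, in_plane_res = 0.5,
                                    extent = c(-5, 5, -5, 5),
                                    interp = "nearest")
  expect_true(all(unlist(stn$slices) %in% c(0, 1)))

  # whatever the spacing, the requested half-width is always covered and
  # the slice count is odd
  cover <- function(sp) {
    s <- extract_midsagittal_slices(vol, diag(4), pl, half_width_mm = 2.5,
                                    spacing = sp, in_plane_res = 2,
                                    extent = c(-2, 2, -2, 2))
    expect_true(length(s$slices) %% 2 == 1)
    max(s$offsets) + sp / 2
  }
  sps <- c(2, 1, 0.5, 0.25)
  expect_true(all(vapply(sps, cover, numeric(1)) >= 2.5 - 1e-9))

  expect_error(extract_midsagittal_slices(vol, diag(4),
                                          plane(c(1e5, 0, 0), c(1, 0, 0)),
                                          extent = c(-2, 2, -2, 2)),
               "outside")
})

test_that("plane disagreement matches closed forms and is symmetric", {
  p0 <- plane(c(0, 0, 0), c(1, 0, 0))
  expect_equal(plane_disagreement(p0, p0, 10), 0)

  p1 <- plane(c(3, 0, 0), c(1, 0, 0))
  expect_equal(plane_disagreement(p0, p1, 10), pi * 100 * 3, tolerance = 1e-10)
  expect_equal(plane_disagreement(p1, p0, 10), plane_disagreement(p0, p1, 10))

  # planes through the axis tilted by +-alpha/2: V = (8/3) tan(alpha/2) R^3
  for (alpha in c(5, 12) * pi / 180) {
    pa <- plane(c(0, 0, 0), c(cos(alpha / 2), sin(alpha / 2), 0))
    pb <- plane(c(0, 0, 0), c(cos(alpha / 2), -sin(alpha / 2), 0))
    expect_equal(plane_disagreement(pa, pb, 8),
                 8 / 3 * tan(alpha / 2) * 8^3, tolerance = 1e-4)
  }
})

test_that("head-pose standardization places AC/PC/mid-plane canonically", {
  std <- plane(c(0, 0, 0), c(1, 0, 0))
  T_id <- standardize_head_pose(c(0, 0, 0), c(0, -25, 0), std)
  expect_equal(unclass(T_id), diag(4), tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(31)
  for (rep in 1:10) {
    pl <- plane(rnorm(3, sd = 10), rnorm(3))
    AC <- pl$point + runif(1, -10, 10) * pl$axes[1, ] +
      runif(1, -10, 10) * pl$axes[2, ]
    PC <- AC - runif(1, 20, 30) * pl$axes[1, ] + runif(1, -3, 3) * pl$axes[2, ]
    Tsp <- standardize_head_pose(AC, PC, pl)
    ac2 <- as.numeric(ccmorph:::apply_rigid(Tsp, AC))
    pc2 <- as.numeric(ccmorph:::apply_rigid(Tsp, PC))
    expect_equal(ac2, c(0, 0, 0), tolerance = 1e-9)
    expect_lt(max(abs(pc2[c(1, 3)])), 1e-9)  # on the AP axis
    expect_lt(pc2[2], 0)                     # on the negative anterior side

    # pre-perturbing the scene leaves the standardized coordinates unchanged
    P <- rigid_transform(runif(1, -90, 90), rnorm(3), shift = rnorm(3, sd = 20))
    pl_p <- plane(ccmorph:::apply_rigid(P, pl$point),
                  as.vector(P[1:3, 1:3] %*% pl$normal),
                  axes = pl$axes %*% t(P[1:3, 1:3]))
    T_p <- standardize_head_pose(ccmorph:::apply_rigid(P, AC),
                                 ccmorph:::apply_rigid(P, PC), pl_p)
    pc3 <- as.numeric(ccmorph:::apply_rigid(
      T_p, ccmorph:::apply_rigid(P, PC)))
    expect_equal(pc3, pc2, tolerance = 1e-8)
  }
  expect_error(standardize_head_pose(c(0, 0, 0), c(0, 0, 0), std), "coincide")
  expect_error(standardize_head_pose(c(1, 0, 0), c(0, 0, 0), std), "parallel")
})

test_that("landmark and plane JSON files round-trip", {
  tmp <- tempfile(fileext = ".json")
  write_landmarks(list(AC = c(1.5, 2, 3), PC = c(0, -24.5, 1)), tmp)
  lm <- read_landmarks(tmp)
  expect_equal(lm$AC, c(1.5, 2, 3))
  expect_equal(lm$PC, c(0, -24.5, 1))

  tmp2 <- tempfile(fileext = ".json")
  pl <- plane(c(1, 2, 3), c(0.2, 1, -0.4))
  write_plane(pl, tmp2)
  pl2 <- read_plane(tmp2)
  expect_equal(pl2$point, pl$point)
  expect_equal(pl2$normal, pl$normal)
  unlink(c(tmp, tmp2))
})
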
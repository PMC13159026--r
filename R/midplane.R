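# Mid-sagittal plane estimation and handling.
#
# The subject mid-plane is found by rigidly registering centroids of a
# whole-brain label map to the corresponding template centroids (Kabsch /
# orthogonal Procrustes via SVD) and pulling the template's mid-plane back
# through the inverse transform.  World coordinates are RAS mm throughout;
# voxel centers sit at integer (0-based) indices, mapped by the affine.

#' Construct a label map
#'
#' @param voxels 3D integer array of label IDs (0 = background).
#' @param affine 4x4 voxel-index (0-based) to world RAS mm transform.
#' @return Object of class `cc_labelmap`.
#' @export
label_map <- function(voxels, affine = diag(4)) {
  stopifnot(length(dim(voxels)) == 3, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("label map affine is not invertible")
  structure(list(voxels = voxels, affine = affine,
                 voxel_sizes = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "cc_labelmap")
}

#' Per-label centroids in world coordinates
#'
#' Centroid of a label is the mean world position of the centers of all
#' voxels carrying that label.
#'
#' @param map A [label_map()].
#' @param labels Integer label IDs; default: all non-zero labels present.
#' @return Object of class `cc_centroids` with `labels` and `points`
#'   (n x 3, world mm).
#' @export
compute_label_centroids <- function(map, labels = NULL) {
  stopifnot(inherits(map, "cc_labelmap"))
  if (is.null(labels)) {
    labels <- sort(setdiff(unique(as.vector(map$voxels)), 0))
  }
  pts <- matrix(NA_real_, length(labels), 3)
  for (i in seq_along(labels)) {
    idx <- which(map$voxels == labels[i], arr.ind = TRUE)
    if (nrow(idx) == 0) stop("label ", labels[i], " not present in label map")
    world <- cbind(idx - 1, 1) %*% t(map$affine)
    pts[i, ] <- colMeans(world[, 1:3, drop = FALSE])
  }
  structure(list(labels = labels, points = pts), class = "cc_centroids")
}

#' Rigid registration of matched centroid clouds (Kabsch)
#'
#' Least-squares rigid transform mapping `source` points onto `target`
#' points, matched by label ID.  A reflection in the SVD solution is
#' corrected by flipping the singular vector of the smallest singular value,
#' so the rotation is always proper (det = +1).
#'
#' @param source,target `cc_centroids` objects sharing at least 3
#'   non-collinear labels.
#' @param exclude Label IDs to drop before matching (e.g. strongly
#'   bilateral-asymmetric structures).
#' @return 4x4 homogeneous transform (class `cc_rigid`) mapping source to
#'   target coordinates.
#' @export
rigid_register_centroids <- function(source, target, exclude = NULL) {
  stopifnot(inherits(source, "cc_centroids"), inherits(target, "cc_centroids"))
  shared <- intersect(source$labels, target$labels)
  shared <- setdiff(shared, exclude)
  if (length(shared) < 3)
    stop("need at least 3 shared labels for rigid registration, got ",
         length(shared))
  X <- source$points[match(shared, source$labels), , drop = FALSE]
  Y <- target$points[match(shared, target$labels), , drop = FALSE]
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  if (qr(Xc)$rank < 2)
    stop("centroid configuration is rank-deficient (collinear labels)")
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ym - as.vector(R %*% xm)
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t_vec
  structure(T, class = c("cc_rigid", "matrix"))
}

#' Build a rigid transform from axis-angle rotation about a center
#'
#' @param angle_deg Rotation angle (degrees).
#' @param axis Rotation axis (3-vector, normalized internally).
#' @param center Center of rotation (world mm).
#' @param shift Additional translation (world mm).
#' @return 4x4 `cc_rigid` transform.
#' @export
rigid_transform <- function(angle_deg = 0, axis = c(0, 0, 1),
                            center = c(0, 0, 0), shift = c(0, 0, 0)) {
  a <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- center - as.vector(R %*% center) + shift
  structure(T, class = c("cc_rigid", "matrix"))
}

#' Construct a plane (point + unit normal + in-plane frame)
#'
#' The two in-plane axes point anterior+ and superior+; together with the
#' normal they form a right-handed frame (`normal = anterior x superior`,
#' i.e. the RAS right direction when axes are anatomical).
#'
#' @param point Point on the plane (world mm).
#' @param normal Plane normal (normalized internally).
#' @param axes 2 x 3 matrix of in-plane axes (rows: anterior+, superior+).
#'   Default: an arbitrary orthonormal completion.
#' @return Object of class `cc_plane`.
#' @export
plane <- function(point, normal, axes = NULL) {
  normal <- unit(normal)
  if (is.null(axes)) {
    ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    a2 <- unit(ref - sum(ref * normal) * normal)   # superior-ish
    a1 <- unit(cross3(a2, normal))                 # anterior = superior x right
    axes <- rbind(a1, a2)
  } else {
    axes[1, ] <- unit(axes[1, ] - sum(axes[1, ] * normal) * normal)
    axes[2, ] <- unit(cross3(normal, axes[1, ]))
  }
  structure(list(point = as.numeric(point), normal = normal, axes = axes),
            class = "cc_plane")
}

#' Serialize a plane as a 4x4 plane-frame-to-world transform
#'
#' Columns are (anterior axis, superior axis, normal, point).
#' @param p A [plane()].
#' @return 4x4 matrix.
#' @export
plane_to_matrix <- function(p) {
  M <- diag(4)
  M[1:3, 1] <- p$axes[1, ]
  M[1:3, 2] <- p$axes[2, ]
  M[1:3, 3] <- p$normal
  M[1:3, 4] <- p$point
  M
}

#' Deserialize a plane from a 4x4 plane-frame-to-world transform
#' @param M 4x4 matrix as produced by [plane_to_matrix()].
#' @return A [plane()].
#' @export
plane_from_matrix <- function(M) {
  plane(point = M[1:3, 4], normal = M[1:3, 3],
        axes = rbind(M[1:3, 1], M[1:3, 2]))
}

#' Map the template mid-plane into subject space
#'
#' Given the subject-to-template transform `T`, the subject plane is the
#' template plane pulled back through `T^-1` (point mapped affinely, frame
#' vectors by the rotation only).
#'
#' @param transform `cc_rigid` subject-to-template transform.
#' @param template_plane Template mid-plane, a [plane()].
#' @return Subject-space [plane()].
#' @export
map_template_midplane <- function(transform, template_plane) {
  Tinv <- solve(transform)
  Rinv <- Tinv[1:3, 1:3]
  plane(point = as.vector(Tinv %*% c(template_plane$point, 1))[1:3],
        normal = as.vector(Rinv %*% template_plane$normal),
        axes = rbind(as.vector(Rinv %*% template_plane$axes[1, ]),
                     as.vector(Rinv %*% template_plane$axes[2, ])))
}

# trilinear (or nearest) sampling of a 3D array at fractional 0-based voxel
# coordinates; out-of-volume samples fill with `fill`
sample_volume <- function(vol, ijk, method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  dims <- dim(vol)
  n <- nrow(ijk)
  out <- rep(fill, n)
  if (method == "nearest") {
    idx <- round(ijk)
    ok <- idx[, 1] >= 0 & idx[, 1] <= dims[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= dims[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= dims[3] - 1
    if (any(ok)) {
      lin <- idx[ok, 1] + dims[1] * (idx[ok, 2] + dims[2] * idx[ok, 3]) + 1
      out[ok] <- vol[lin]
    }
    return(out)
  }
  f <- floor(ijk)
  w <- ijk - f
  acc <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- f[, 1] + dx; iy <- f[, 2] + dy; iz <- f[, 3] + dz
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
          (if (dy == 1) w[, 2] else 1 - w[, 2]) *
          (if (dz == 1) w[, 3] else 1 - w[, 3])
    ok <- ix >= 0 & ix <= dims[1] - 1 & iy >= 0 & iy <= dims[2] - 1 &
          iz >= 0 & iz <= dims[3] - 1
    v <- numeric(n)
    if (any(ok)) {
      lin <- ix[ok] + dims[1] * (iy[ok] + dims[2] * iz[ok]) + 1
      v[ok] <- vol[lin]
    }
    v[!ok] <- fill
    acc <- acc + wt * v
  }
  acc
}

#' Resample slices in the mid-sagittal frame
#'
#' Extracts an odd number of parallel slices around the plane, using the
#' smallest slice count whose outermost slice center plus half a spacing
#' covers `half_width_mm` on either side.  Intensities are sampled with
#' trilinear interpolation, masks/labels with nearest-neighbor; out-of-volume
#' samples fill with 0.
#'
#' @param volume 3D array.
#' @param affine 4x4 voxel-to-world transform of `volume`.
#' @param plane The mid-sagittal [plane()].
#' @param half_width_mm Coverage to either side of the plane (mm).
#' @param spacing Slice spacing (mm).
#' @param in_plane_res In-plane sampling resolution (mm).
#' @param extent In-plane extent `c(a_min, a_max, s_min, s_max)` in mm
#'   relative to the plane point; default: projection of the volume corners.
#' @param interp `"linear"` for intensities, `"nearest"` for masks/labels.
#' @return Object of class `cc_slicestack`: `slices` (list of 2D arrays),
#'   `offsets` (signed mm), `spacing`, `in_plane_resolution`, `a`, `s`
#'   (in-plane sample coordinates, mm).
#' @export
extract_midsagittal_slices <- function(volume, affine, plane,
                                       half_width_mm = 2.5, spacing = 1,
                                       in_plane_res = spacing,
                                       extent = NULL,
                                       interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(spacing > 0, half_width_mm >= 0)
  k_max <- max(0, ceiling(half_width_mm / spacing - 0.5 - 1e-9))
  offsets <- seq(-k_max, k_max) * spacing

  if (is.null(extent)) {
    dims <- dim(volume)
    corners <- as.matrix(expand.grid(c(0, dims[1] - 1), c(0, dims[2] - 1),
                                     c(0, dims[3] - 1)))
    world <- cbind(corners, 1) %*% t(affine)
    rel <- sweep(world[, 1:3, drop = FALSE], 2, plane$point)
    a_rng <- range(rel %*% plane$axes[1, ])
    s_rng <- range(rel %*% plane$axes[2, ])
    extent <- c(a_rng, s_rng)
  }
  a <- seq(extent[1], extent[2], by = in_plane_res)
  s <- seq(extent[3], extent[4], by = in_plane_res)
  grid <- as.matrix(expand.grid(a = a, s = s))
  inv_aff <- solve(affine)

  any_inside <- FALSE
  dims <- dim(volume)
  slices <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    pts <- matrix(plane$point, nrow(grid), 3, byrow = TRUE) +
      grid[, 1] %o% plane$axes[1, ] + grid[, 2] %o% plane$axes[2, ] +
      offsets[i] * matrix(plane$normal, nrow(grid), 3, byrow = TRUE)
    ijk <- cbind(pts, 1) %*% t(inv_aff)
    ijk <- ijk[, 1:3, drop = FALSE]
    inside <- ijk[, 1] >= -0.5 & ijk[, 1] <= dims[1] - 0.5 &
              ijk[, 2] >= -0.5 & ijk[, 2] <= dims[2] - 0.5 &
              ijk[, 3] >= -0.5 & ijk[, 3] <= dims[3] - 0.5
    if (any(inside)) any_inside <- TRUE
    slices[[i]] <- matrix(sample_volume(volume, ijk, interp),
                          nrow = length(a), ncol = length(s))
  }
  if (!any_inside) stop("plane lies entirely outside the volume")
  structure(list(slices = slices, offsets = offsets, spacing = spacing,
                 in_plane_resolution = in_plane_res, a = a, s = s),
            class = "cc_slicestack")
}

#' Volume enclosed between two plane estimates within a cylinder
#'
#' Disagreement metric between two mid-plane candidates: the volume enclosed
#' between the planes inside an infinite cylinder of radius `radius_mm`
#' whose axis passes through the RAS origin along the mean unit normal.
#' Computed by midpoint quadrature on a polar grid over the disk (exact for
#' parallel planes).
#'
#' @param a,b [plane()] objects (normals within 90 degrees after sign
#'   alignment).
#' @param radius_mm Cylinder radius (mm).
#' @param n_r,n_theta Quadrature resolution.
#' @return Enclosed volume (mm^3).
#' @export
plane_disagreement <- function(a, b, radius_mm, n_r = 256, n_theta = 512) {
  na <- a$normal
  nb <- b$normal
  if (sum(na * nb) < 0) nb <- -nb
  if (sum(na * nb) <= 0) stop("plane normals are orthogonal or worse")
  nbar <- unit(na + nb)
  ref <- if (abs(nbar[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * nbar) * nbar)
  e2 <- cross3(nbar, e1)
  r <- (seq_len(n_r) - 0.5) / n_r * radius_mm
  th <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
  gr <- expand.grid(r = r, th = th)
  x <- outer(gr$r * cos(gr$th), e1) + outer(gr$r * sin(gr$th), e2)
  t_for <- function(p) {
    denom <- sum(p$normal * nbar)
    (matrix(p$point, nrow(x), 3, byrow = TRUE) - x) %*% p$normal / denom
  }
  ta <- t_for(a)
  tb <- t_for(b)
  dA <- gr$r * (radius_mm / n_r) * (2 * pi / n_theta)
  sum(abs(ta - tb) * dA)
}

#' Head-pose standardization transform
#'
#' Rigid transform placing AC at the origin, PC on the negative anterior
#' axis, and the mid-plane normal on the left-right axis.  The frame is the
#' Gram-Schmidt orthonormalization of (mid-plane normal, AC-PC direction
#' projected into the plane, their cross product); PC lands exactly on the
#' AP axis when AC and PC lie on the mid-plane (anatomically they do).
#'
#' @param AC,PC Landmarks, world RAS mm.
#' @param midplane The mid-sagittal [plane()].
#' @return 4x4 `cc_rigid` transform mapping world to standardized
#'   coordinates (x = left-right, y = anterior+, z = superior+).
#' @export
standardize_head_pose <- function(AC, PC, midplane) {
  AC <- as.numeric(AC); PC <- as.numeric(PC)
  d <- AC - PC
  if (sqrt(sum(d^2)) < 1e-9) stop("AC and PC coincide")
  e1 <- midplane$normal
  d_proj <- d - sum(d * e1) * e1
  if (sqrt(sum(d_proj^2)) < 1e-9)
    stop("AC-PC direction is parallel to the mid-plane normal")
  e2 <- unit(d_proj)       # anterior+
  e3 <- cross3(e1, e2)     # superior+
  R <- rbind(e1, e2, e3)
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- -as.vector(R %*% AC)
  structure(T, class = c("cc_rigid", "matrix"))
}

#' Read AC/PC landmarks from JSON
#'
#' File format: JSON object with keys `"AC"` and `"PC"`, each 3 floats
#' (world RAS mm) or 2 floats (mid-sagittal frame mm).
#' @param path JSON file path.
#' @return List with numeric `AC` and `PC`.
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$AC) || is.null(x$PC)) stop("landmark file must contain AC and PC")
  list(AC = as.numeric(x$AC), PC = as.numeric(x$PC))
}

#' Write AC/PC landmarks to JSON
#' @param landmarks List with `AC` and `PC`.
#' @param path Output path.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks[c("AC", "PC")], as.numeric), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a plane as a JSON 4x4 row-major matrix
#' @param p A [plane()].
#' @param path Output path.
#' @export
write_plane <- function(p, path) {
  M <- plane_to_matrix(p)
  jsonlite::write_json(lapply(seq_len(4), function(i) as.numeric(M[i, ])),
                       path, digits = NA)
  invisible(path)
}

#' Read a plane from a JSON 4x4 row-major matrix
#' @param path JSON file path.
#' @return A [plane()].
#' @export
read_plane <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- if (is.matrix(rows)) rows else do.call(rbind, rows)
  plane_from_matrix(M)
}
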
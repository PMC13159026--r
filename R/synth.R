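# Synthetic CC-like fixtures with analytic ground truth.
#
# The default ribbon is an upward-arching half-annulus band ("CC arch")
# with a smoothly varying half-width (thicker splenium end), AC below the
# anterior end and PC below the posterior end -- the same topology the
# endpoint and chain-labeling rules face on real data.  End caps are flat
# (the ribbon is the set of points whose centerline projection falls inside
# the arc), so cap corners exist exactly as on the analytic test shapes.

# save/restore the global RNG around seeded generation
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic CC-like ribbon
#'
#' @param kind `"arc"` (curved band, centerline a circular arc) or
#'   `"straight"` (rectangle ribbon).
#' @param radius_mm Arc centerline radius (arc kind).
#' @param span_rad Angular span of the arc (default half turn).
#' @param length_mm Centerline length (straight kind).
#' @param half_width Half-width in mm: a constant or a function of the
#'   normalized arc position s in \[0, 1\].
#' @param resolution Rasterization grid spacing (mm).
#' @param cap_style `"flat"` (default) or `"round"`.
#' @param landmark_drop_mm AC/PC are placed this far below (superior-)
#'   the anterior/posterior centerline ends.
#' @param rotation_deg In-plane pose rotation applied to the shape (about
#'   its centerline midpoint) before rasterization.
#' @param shift_mm Length-2 in-plane translation applied with the rotation.
#' @param noise_flip_prob Probability of flipping each boundary pixel
#'   (segmentation-jitter model; implies a binary mask).
#' @param antialias Rasterize with 4x4 subpixel coverage sampling (values
#'   in \[0, 1\]), emulating thresholded soft segmentation maps whose
#'   iso-0.5 contour carries sub-voxel boundary information.  Set FALSE for
#'   a hard binary mask (boundary accuracy then limited to half a pixel).
#' @return Object of class `cc_ribbon_spec`.
#' @export
ribbon_spec <- function(kind = c("arc", "straight"), radius_mm = 20,
                        span_rad = pi, length_mm = 20,
                        half_width = function(s) 2.5 + 1.5 * s,
                        resolution = 0.5, cap_style = c("flat", "round"),
                        landmark_drop_mm = 5, rotation_deg = 0,
                        shift_mm = c(0, 0), noise_flip_prob = 0,
                        antialias = TRUE) {
  kind <- match.arg(kind)
  cap_style <- match.arg(cap_style)
  hfun <- if (is.function(half_width)) half_width else function(s) rep(half_width, length(s))
  stopifnot(resolution > 0, all(hfun(seq(0, 1, 0.01)) > 0))
  structure(list(kind = kind, radius_mm = radius_mm, span_rad = span_rad,
                 length_mm = length_mm, half_width = hfun,
                 resolution = resolution, cap_style = cap_style,
                 landmark_drop_mm = landmark_drop_mm,
                 rotation_deg = rotation_deg, shift_mm = shift_mm,
                 noise_flip_prob = noise_flip_prob, antialias = antialias),
            class = "cc_ribbon_spec")
}

# analytic centerline quantities of a spec (unrotated frame)
ribbon_truth <- function(spec) {
  h <- spec$half_width
  sgrid <- seq(0, 1, length.out = 2001)
  hbar <- mean(h(sgrid))
  if (spec$kind == "arc") {
    len <- spec$span_rad * spec$radius_mm
    curv <- 1 / spec$radius_mm
    area <- 2 * spec$radius_mm * spec$span_rad * hbar
  } else {
    len <- spec$length_mm
    curv <- 0
    area <- 2 * spec$length_mm * hbar
  }
  list(length_mm = len, curvature_per_mm = curv, area_mm2 = area,
       thickness = function(s) 2 * h(s))
}

# centerline endpoints in the unrotated frame (anterior first)
ribbon_ends <- function(spec) {
  if (spec$kind == "arc") {
    th <- c(pi, pi - spec$span_rad)
    rbind(spec$radius_mm * c(cos(th[1]), sin(th[1])),
          spec$radius_mm * c(cos(th[2]), sin(th[2])))
  } else {
    rbind(c(0, 0), c(spec$length_mm, 0))
  }
}

#' Rasterize a synthetic ribbon with ground truth
#'
#' Deterministic given the seed.  Landmarks and the ground-truth geometry
#' are returned in the mask frame (mm; pixel centers at
#' `(i - 1, j - 1) * resolution`).
#'
#' @param spec A [ribbon_spec()].
#' @param seed RNG seed (only used when `noise_flip_prob > 0`).
#' @return List: `mask` (binary matrix), `resolution`, `landmarks`
#'   (`AC`, `PC`, 2D mm), `truth` (length, curvature, area, thickness
#'   function), `spec`.
#' @export
generate_ribbon <- function(spec = ribbon_spec(), seed = NULL) {
  res <- spec$resolution
  ends <- ribbon_ends(spec)
  mid <- colMeans(ends)
  ang <- spec$rotation_deg * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)

  # forward pose map (shape -> scanner) and its inverse
  fwd <- function(p) sweep(p %*% t(R) - matrix(mid %*% t(R), nrow(p), 2,
                                               byrow = TRUE), 2,
                           -(mid + spec$shift_mm))
  inv <- function(p) sweep(p, 2, mid + spec$shift_mm) %*% R +
    matrix(mid, nrow(p), 2, byrow = TRUE)

  # generous bounding box of the posed shape
  hmax <- max(spec$half_width(seq(0, 1, 0.01)))
  base_bb <- if (spec$kind == "arc") {
    r2 <- spec$radius_mm + hmax
    rbind(c(-r2, -hmax - 1), c(r2, r2 + 1))
  } else {
    rbind(c(-hmax - 1, -hmax - 1),
          c(spec$length_mm + hmax + 1, hmax + 1))
  }
  corners <- as.matrix(expand.grid(base_bb[, 1], base_bb[, 2]))
  pc <- fwd(corners)
  lo <- floor((apply(pc, 2, min) - 2 * res) / res) * res
  hi <- ceiling((apply(pc, 2, max) + 2 * res) / res) * res

  xs <- seq(lo[1], hi[1], by = res)
  ys <- seq(lo[2], hi[2], by = res)
  grid <- as.matrix(expand.grid(x = xs, y = ys))

  h <- spec$half_width
  inside_at <- function(pts) {
    g0 <- inv(pts)  # points in the unrotated shape frame
    if (spec$kind == "arc") {
      r <- sqrt(rowSums(g0^2))
      alpha <- atan2(g0[, 2], g0[, 1])
      s <- (pi - alpha) / spec$span_rad
      dist_c <- abs(r - spec$radius_mm)
      inside <- s >= 0 & s <= 1 & alpha >= 0 & dist_c <= h(pmin(pmax(s, 0), 1))
    } else {
      s <- g0[, 1] / spec$length_mm
      inside <- s >= 0 & s <= 1 & abs(g0[, 2]) <= h(pmin(pmax(s, 0), 1))
    }
    if (spec$cap_style == "round") {
      for (e in 1:2) {
        dd <- sqrt((g0[, 1] - ends[e, 1])^2 + (g0[, 2] - ends[e, 2])^2)
        inside <- inside | dd <= h(c(0, 1)[e])
      }
    }
    inside
  }

  if (isTRUE(spec$antialias) && spec$noise_flip_prob == 0) {
    # 4x4 subpixel coverage: soft mask, sub-voxel iso-0.5 boundary
    k <- 4
    offs <- (seq_len(k) - (k + 1) / 2) / k * res
    cov <- numeric(nrow(grid))
    for (ox in offs) for (oy in offs)
      cov <- cov + inside_at(cbind(grid[, 1] + ox, grid[, 2] + oy))
    mask <- matrix(cov / (k * k), nrow = length(xs), ncol = length(ys))
  } else {
    mask <- matrix(as.numeric(inside_at(grid)),
                   nrow = length(xs), ncol = length(ys))
  }

  if (spec$noise_flip_prob > 0) {
    mask <- with_seed(seed, {
      b <- mask_boundary(mask)
      flips <- stats::rbinom(nrow(b), 1, spec$noise_flip_prob) == 1
      for (i in which(flips)) mask[b[i, 1], b[i, 2]] <- 1 - mask[b[i, 1], b[i, 2]]
      mask
    })
  }

  # landmarks: placed outward along the centerline tangent beyond each end
  # (for the default arch this is below the downward-pointing ends, mimicking
  # AC below the genu and PC below the splenium); the nearest boundary vertex
  # to each landmark is then the end-cap midpoint
  if (spec$kind == "arc") {
    th_ends <- c(pi, pi - spec$span_rad)
    tangent <- cbind(-sin(th_ends), cos(th_ends)) *
      (spec$radius_mm * spec$span_rad)
    # travel direction is -tangent (theta decreases with s); outward at the
    # anterior end is +tangent, at the posterior end -tangent
    outward <- rbind(unit(tangent[1, ]), -unit(tangent[2, ]))
  } else {
    outward <- rbind(c(-1, 0), c(1, 0))
  }
  lm0 <- ends + spec$landmark_drop_mm * outward
  lm <- fwd(lm0)
  # convert to mask frame: pixel (1,1) center sits at (lo[1], lo[2])
  lm <- sweep(lm, 2, lo)
  list(mask = mask, resolution = res,
       landmarks = list(AC = lm[1, ], PC = lm[2, ]),
       truth = ribbon_truth(spec), spec = spec, origin = lo)
}

#' Paired label volumes under a known rigid transform
#'
#' Template volume with compact spherical label blobs plus the same volume
#' resampled (nearest neighbor) under the given rigid transform; the
#' ground-truth transform maps template coordinates to moved coordinates.
#'
#' @param n_labels Number of blobs (>= 4; placed non-coplanar).
#' @param transform 4x4 rigid transform (world = voxel index here).
#' @param seed RNG seed for blob placement.
#' @param dim Volume dimensions.
#' @param blob_radius Blob radius in voxels.
#' @return List: `template`, `moved` (both [label_map()]), `transform`.
#' @export
generate_label_volume <- function(n_labels = 16, transform = diag(4),
                                  seed = 1, dim = c(112, 112, 112),
                                  blob_radius = 9) {
  stopifnot(n_labels >= 4)
  centers <- with_seed(seed, {
    out <- matrix(NA_real_, 0, 3)
    # keep blobs clear of the walls so moderate transforms stay in frame
    margin <- blob_radius + max(6, 0.15 * max(dim))
    tries <- 0
    while (nrow(out) < n_labels && tries < 5000) {
      tries <- tries + 1
      cand <- stats::runif(3, margin, dim - margin)
      if (nrow(out) == 0 || min(sqrt(rowSums(sweep(out, 2, cand)^2))) > 2.5 * blob_radius)
        out <- rbind(out, cand)
    }
    if (nrow(out) < n_labels) stop("could not place blobs with separation")
    out
  })
  # ensure non-coplanar placement
  if (qr(sweep(centers, 2, colMeans(centers)))$rank < 3)
    stop("blob placement is coplanar; use another seed")

  fill_blobs <- function(cts) {
    vol <- array(0L, dim)
    for (l in seq_len(nrow(cts))) {
      c0 <- cts[l, ]
      if (any(c0 < blob_radius) || any(c0 > dim - blob_radius))
        stop("blob pushed outside the field of view")
      rng <- lapply(1:3, function(a) {
        seq(max(0, floor(c0[a] - blob_radius)), min(dim[a] - 1, ceiling(c0[a] + blob_radius)))
      })
      g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      d <- sqrt(rowSums(sweep(g, 2, c0)^2))
      sel <- g[d <= blob_radius, , drop = FALSE]
      vol[sel + 1] <- l
    }
    vol
  }
  template <- fill_blobs(centers)
  moved_centers <- apply_rigid(transform, centers)
  # moved volume: nearest-neighbor resample of the template under transform
  inv_t <- solve(transform)
  moved <- array(0L, dim)
  idx <- as.matrix(expand.grid(0:(dim[1] - 1), 0:(dim[2] - 1), 0:(dim[3] - 1)))
  src <- round(apply_rigid(inv_t, idx))
  ok <- src[, 1] >= 0 & src[, 1] < dim[1] & src[, 2] >= 0 & src[, 2] < dim[2] &
        src[, 3] >= 0 & src[, 3] < dim[3]
  lin_dst <- idx[ok, 1] + dim[1] * (idx[ok, 2] + dim[2] * idx[ok, 3]) + 1
  lin_src <- src[ok, 1] + dim[1] * (src[ok, 2] + dim[2] * src[ok, 3]) + 1
  moved[lin_dst] <- template[lin_src]
  if (any(moved_centers < blob_radius) || any(moved_centers > dim - blob_radius))
    stop("transform pushes blobs outside the field of view")
  list(template = label_map(template), moved = label_map(moved),
       transform = transform)
}

#' Test-retest mask pairs with pose jitter and covariates
#'
#' Per subject, two rasterizations of the same ribbon under independent
#' small pose perturbations and optional boundary noise; covariates (age,
#' sex, brain-volume stand-in) are drawn once per subject.  An optional
#' group effect thins the ribbon of patients.
#'
#' @param spec Base [ribbon_spec()].
#' @param pose_jitter_deg SD of the per-scan rotation jitter (degrees).
#' @param noise_level Boundary-pixel flip probability per scan.
#' @param n_subjects Number of subjects.
#' @param seed RNG seed (drives everything).
#' @param group_effect_mm Thickness reduction (mm) applied to the ribbon of
#'   subjects in group 1 (half assigned per subject).
#' @param subject_sd Relative SD of the per-subject thickness scale.
#' @return List: `subjects` (each: `scans` list of two [generate_ribbon()]
#'   outputs, `scale`), `covariates` (data.frame with `group`, `age`,
#'   `sex`, `brain_volume`).
#' @export
generate_test_retest <- function(spec = ribbon_spec(), pose_jitter_deg = 2,
                                 noise_level = 0, n_subjects = 20, seed = 1,
                                 group_effect_mm = 0, subject_sd = 0.05) {
  params <- with_seed(seed, {
    list(scale = stats::rnorm(n_subjects, 1, subject_sd),
         group = stats::rbinom(n_subjects, 1, 0.5),
         age = stats::runif(n_subjects, 40, 80),
         sex = stats::rbinom(n_subjects, 1, 0.5),
         bvol = stats::rnorm(n_subjects, 1.15e6, 1e5),
         rot = matrix(stats::rnorm(2 * n_subjects, 0, pose_jitter_deg),
                      n_subjects, 2),
         shift = array(stats::runif(4 * n_subjects, -1, 1),
                       c(n_subjects, 2, 2)),
         noise_seeds = sample.int(2^30, 2 * n_subjects))
  })
  subjects <- vector("list", n_subjects)
  base_h <- spec$half_width
  for (i in seq_len(n_subjects)) {
    eff <- if (params$group[i] == 1) group_effect_mm / 2 else 0
    sc <- params$scale[i]
    hfun <- local({
      sc_i <- sc; eff_i <- eff
      function(s) pmax(0.5, base_h(s) * sc_i - eff_i)
    })
    scans <- lapply(1:2, function(k) {
      sp <- spec
      sp$half_width <- hfun
      sp$rotation_deg <- spec$rotation_deg + params$rot[i, k]
      sp$shift_mm <- spec$shift_mm + params$shift[i, , k]
      sp$noise_flip_prob <- noise_level
      generate_ribbon(sp, seed = params$noise_seeds[(i - 1) * 2 + k])
    })
    subjects[[i]] <- list(scans = scans, scale = sc)
  }
  list(subjects = subjects,
       covariates = data.frame(group = params$group, age = params$age,
                               sex = params$sex, brain_volume = params$bvol))
}
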
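# Parametric CC sub-segmentation schemes.
#
# All schemes reduce to cutting the mesh along level lines of per-vertex
# linear scalar fields; triangles crossing a cut are split exactly by
# polygon clipping, so region areas always sum to the total mesh area.
#
# Default cut fractions: Witelson (1/3, 1/2, 2/3, 4/5) and Hofer-Frahm
# (1/6, 1/2, 2/3, 3/4), both fully configurable.

#' Default sub-segmentation fractions
#' @param scheme `"witelson"` or `"hofer_frahm"`.
#' @return Numeric vector of cut fractions.
#' @export
subseg_fractions <- function(scheme = c("hofer_frahm", "witelson")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         witelson = c(1 / 3, 1 / 2, 2 / 3, 4 / 5),
         hofer_frahm = c(1 / 6, 1 / 2, 2 / 3, 3 / 4))
}

# Sutherland-Hodgman clip of a polygon against {s <= c} (below = TRUE) or
# {s >= c}; pts k x 2, s per-vertex scalar (linear over the polygon)
clip_halfplane <- function(pts, s, c, below = TRUE) {
  d <- if (below) c - s else s - c
  k <- nrow(pts)
  out_p <- matrix(0, 0, 2); out_s <- numeric(0)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di >= 0) {
      out_p <- rbind(out_p, pts[i, ]); out_s <- c(out_s, s[i])
    }
    if ((di >= 0) != (dj >= 0)) {
      t <- di / (di - dj)
      out_p <- rbind(out_p, pts[i, ] + t * (pts[j, ] - pts[i, ]))
      out_s <- c(out_s, s[i] + t * (s[j] - s[i]))
    }
  }
  list(pts = out_p, s = out_s)
}

poly_area_abs <- function(pts) if (nrow(pts) < 3) 0 else abs(polygon_area(pts))

# region areas + face labels for cuts along level values of one linear field
field_subseg <- function(mesh, phi, cuts) {
  stopifnot(all(diff(cuts) > 0))
  k <- length(cuts)
  tr <- mesh$triangles
  vtx <- mesh$vertices
  areas <- triangle_areas(mesh)
  phi_t <- cbind(phi[tr[, 1]], phi[tr[, 2]], phi[tr[, 3]])
  reg_v <- matrix(findInterval(phi_t, cuts), ncol = 3) + 1L
  reg_cent <- findInterval(rowMeans(phi_t), cuts) + 1L
  region_areas <- numeric(k + 1)
  same <- reg_v[, 1] == reg_v[, 2] & reg_v[, 2] == reg_v[, 3]
  if (any(same)) {
    sums <- rowsum(areas[same], reg_v[same, 1])
    region_areas[as.integer(rownames(sums))] <- sums[, 1]
  }
  for (ti in which(!same)) {
    lo_r <- min(reg_v[ti, ]); hi_r <- max(reg_v[ti, ])
    pts <- vtx[tr[ti, ], , drop = FALSE]
    sv <- phi_t[ti, ]
    for (r in lo_r:hi_r) {
      poly <- list(pts = pts, s = sv)
      if (r > 1) poly <- clip_halfplane(poly$pts, poly$s, cuts[r - 1], below = FALSE)
      if (r <= k && nrow(poly$pts) > 0)
        poly <- clip_halfplane(poly$pts, poly$s, cuts[r], below = TRUE)
      region_areas[r] <- region_areas[r] + poly_area_abs(poly$pts)
    }
  }
  structure(list(face_labels = reg_cent, region_areas = region_areas,
                 n_regions = k + 1L),
            class = "cc_subseg")
}

#' Sub-segmentation by cuts orthogonal to an anchor line
#'
#' Witelson-style scheme: points are assigned by their normalized projection
#' onto the anchor line (0 at the minimal, 1 at the maximal mesh
#' projection); cuts fall at the given fractions.  The anchor runs through
#' the most anterior and posterior CC points (Witelson) or through AC and
#' PC (Jancke variant).
#'
#' @param mesh A `cc_mesh`.
#' @param anchor 2 x 2 matrix: anchor line through `anchor[1, ]` (anterior)
#'   and `anchor[2, ]` (posterior).  Default: extremal boundary vertices
#'   along the anterior axis.
#' @param fractions Strictly increasing cut positions in (0, 1).
#' @return A `cc_subseg` (regions numbered from the first anchor point).
#' @export
subsegment_anchor_line <- function(mesh, anchor = NULL,
                                   fractions = subseg_fractions("hofer_frahm")) {
  if (is.null(anchor)) {
    bv <- mesh$vertices[mesh$boundary, , drop = FALSE]
    anchor <- rbind(bv[which.max(bv[, 1]), ], bv[which.min(bv[, 1]), ])
  }
  d <- anchor[2, ] - anchor[1, ]
  if (sqrt(sum(d^2)) < 1e-9) stop("degenerate anchor line")
  d <- unit(d)
  phi <- (mesh$vertices[, 1] - anchor[1, 1]) * d[1] +
         (mesh$vertices[, 2] - anchor[1, 2]) * d[2]
  rng <- range(phi)
  phi <- (phi - rng[1]) / diff(rng)
  field_subseg(mesh, phi, sort(fractions))
}

#' Sub-segmentation by equal widths along the primary eigendirection
#'
#' mri_cc-style scheme: the principal axis is the first principal component
#' of the area-weighted triangle centroids; the extent along it is cut into
#' `n_regions` equal widths.
#'
#' @param mesh A `cc_mesh`.
#' @param n_regions Number of regions (>= 2).
#' @return A `cc_subseg`.
#' @export
subsegment_eigendirection <- function(mesh, n_regions = 5) {
  stopifnot(n_regions >= 2)
  tr <- mesh$triangles
  vtx <- mesh$vertices
  cent <- (vtx[tr[, 1], , drop = FALSE] + vtx[tr[, 2], , drop = FALSE] +
           vtx[tr[, 3], , drop = FALSE]) / 3
  w <- triangle_areas(mesh)
  mu <- colSums(cent * w) / sum(w)
  cc <- sweep(cent, 2, mu)
  C <- t(cc * w) %*% cc / sum(w)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[1] < 1.05 * eg$values[2])
    stop("shape is near-isotropic: primary eigendirection is ambiguous")
  axis <- eg$vectors[, 1]
  if (axis[1] < 0) axis <- -axis
  phi <- vtx %*% axis
  rng <- range(phi)
  phi <- (phi - rng[1]) / diff(rng)
  cuts <- seq_len(n_regions - 1) / n_regions
  field_subseg(mesh, as.numeric(phi), cuts)
}

#' Sub-segmentation by equally spaced rays
#'
#' Rays originate from the midpoint of the inferior edge of the axis-aligned
#' bounding rectangle (in the pose-standardized frame) and are spaced at
#' equal angles over (0, pi), giving `n_rays + 1` angular sectors.
#'
#' @param mesh A `cc_mesh`.
#' @param n_rays Number of rays (>= 1).
#' @return A `cc_subseg` (region 1 at angle 0).
#' @export
subsegment_rays <- function(mesh, n_rays = 4) {
  stopifnot(n_rays >= 1)
  vtx <- mesh$vertices
  origin <- c(mean(range(vtx[, 1])), min(vtx[, 2]))
  poly <- vtx[mesh$boundary, , drop = FALSE]
  if (.points_in_polygon(matrix(origin, 1, 2), poly)[1])
    stop("ray origin lies inside the mesh (invalid geometry)")
  rel <- sweep(vtx, 2, origin)
  thetas <- seq_len(n_rays) * pi / (n_rays + 1)
  # cross_j(p) = cos(theta_j) * y - sin(theta_j) * x ; > 0 iff angle(p) > theta_j
  cross_f <- function(th) cos(th) * rel[, 2] - sin(th) * rel[, 1]
  ang <- atan2(rel[, 2], rel[, 1])
  tr <- mesh$triangles
  areas <- triangle_areas(mesh)
  k <- n_rays
  sector_of <- function(a) pmin(pmax(findInterval(a, thetas) + 1L, 1L), k + 1L)
  ang_t <- cbind(ang[tr[, 1]], ang[tr[, 2]], ang[tr[, 3]])
  reg_v <- matrix(sector_of(ang_t), ncol = 3)
  cent_ang <- atan2(rowMeans(matrix(rel[tr, 2], ncol = 3)),
                    rowMeans(matrix(rel[tr, 1], ncol = 3)))
  face_labels <- sector_of(cent_ang)
  region_areas <- numeric(k + 1)
  same <- reg_v[, 1] == reg_v[, 2] & reg_v[, 2] == reg_v[, 3]
  if (any(same)) {
    sums <- rowsum(areas[same], reg_v[same, 1])
    region_areas[as.integer(rownames(sums))] <- sums[, 1]
  }
  cross_all <- vapply(thetas, cross_f, numeric(nrow(vtx)))
  for (ti in which(!same)) {
    lo_r <- min(reg_v[ti, ]); hi_r <- max(reg_v[ti, ])
    vids <- tr[ti, ]
    for (r in lo_r:hi_r) {
      poly_pts <- vtx[vids, , drop = FALSE]
      if (r > 1) {
        cl <- clip_halfplane(poly_pts, cross_all[vids, r - 1], 0, below = FALSE)
        poly_pts <- cl$pts
      }
      if (r <= k && nrow(poly_pts) > 0) {
        # cross fields are linear in the coordinates, so recompute directly
        s_next <- cos(thetas[r]) * (poly_pts[, 2] - origin[2]) -
                  sin(thetas[r]) * (poly_pts[, 1] - origin[1])
        cl <- clip_halfplane(poly_pts, s_next, 0, below = TRUE)
        poly_pts <- cl$pts
      }
      region_areas[r] <- region_areas[r] + poly_area_abs(poly_pts)
    }
  }
  structure(list(face_labels = face_labels, region_areas = region_areas,
                 n_regions = k + 1L),
            class = "cc_subseg")
}

#' Shape-aware sub-segmentation perpendicular to the intercallosal line
#'
#' The novel scheme: for each fraction, the point at that arc-length
#' position on the intercallosal line defines a conjugate-potential value,
#' and the cut runs along that level path -- perpendicular to the
#' intercallosal line even in strongly bent shapes.  Anatomically motivated
#' fractions (e.g. Hofer-Frahm) can be reused unchanged.
#'
#' @param mesh A partitioned `cc_mesh`.
#' @param v Conjugate potential (see [conjugate_potential()]).
#' @param line A [intercallosal_line()].
#' @param fractions Strictly increasing arc-length fractions in (0, 1).
#' @return A `cc_subseg` (regions numbered anterior to posterior).
#' @export
subsegment_arclength <- function(mesh, v, line,
                                 fractions = subseg_fractions("hofer_frahm")) {
  fractions <- sort(fractions)
  v_line <- interp_on_line(line, v)
  cuts <- interp1(line$arclen, v_line, fractions * line$length_mm)
  if (any(diff(cuts) <= 0))
    stop("conjugate potential is not monotone at the requested fractions")
  res <- field_subseg(mesh, v, cuts)
  if (any(res$region_areas <= 0))
    stop("a level cut failed to separate the mesh")
  res
}

#' Run a named sub-segmentation scheme
#'
#' @param mesh A partitioned `cc_mesh`.
#' @param scheme One of `"witelson"`, `"hofer_frahm"`, `"jancke"`,
#'   `"eigen"`, `"rays"`, `"arclength"`.
#' @param fractions Cut fractions (anchor/arclength schemes); defaults to
#'   the scheme's classical values.
#' @param n_regions Regions for `"eigen"`; rays + 1 for `"rays"`.
#' @param landmarks List with `AC`, `PC` (2D mm) for the `"jancke"` anchor.
#' @param v,line Conjugate potential and intercallosal line (for
#'   `"arclength"`).
#' @return A `cc_subseg`.
#' @export
subsegment <- function(mesh, scheme = c("hofer_frahm", "witelson", "jancke",
                                        "eigen", "rays", "arclength"),
                       fractions = NULL, n_regions = 5, landmarks = NULL,
                       v = NULL, line = NULL) {
  scheme <- match.arg(scheme)
  if (scheme %in% c("hofer_frahm", "witelson")) {
    if (is.null(fractions)) fractions <- subseg_fractions(scheme)
    subsegment_anchor_line(mesh, fractions = fractions)
  } else if (scheme == "jancke") {
    if (is.null(landmarks)) stop("jancke scheme needs AC/PC landmarks")
    if (is.null(fractions)) fractions <- subseg_fractions("witelson")
    subsegment_anchor_line(mesh, anchor = rbind(landmarks$AC, landmarks$PC),
                           fractions = fractions)
  } else if (scheme == "eigen") {
    subsegment_eigendirection(mesh, n_regions)
  } else if (scheme == "rays") {
    subsegment_rays(mesh, n_regions - 1)
  } else {
    if (is.null(v) || is.null(line))
      stop("arclength scheme needs the conjugate potential and line")
    if (is.null(fractions)) fractions <- subseg_fractions("hofer_frahm")
    subsegment_arclength(mesh, v, line, fractions)
  }
}
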
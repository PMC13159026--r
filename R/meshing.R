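# Binary mask -> sub-voxel contour -> triangle mesh, plus endpoint
# localization from AC/PC landmarks and inferior/superior boundary
# partitioning.
#
# The 2D frame is (a, s) = (anterior+, superior+) in mm, derived from the
# mid-sagittal plane's in-plane axes.

# -- marching squares ---------------------------------------------------------

# Segment endpoints for one cell edge, linear interpolation at iso level.
ms_edge_point <- function(i, j, edge, v00, v10, v11, v01, iso) {
  switch(edge,
    S = c(i + (iso - v00) / (v10 - v00), j),
    E = c(i + 1, j + (iso - v10) / (v11 - v10)),
    N = c(i + (iso - v01) / (v11 - v01), j + 1),
    W = c(i, j + (iso - v00) / (v01 - v00)))
}

# marching squares on a padded grid; returns list of closed loops
# (matrices of pixel-unit coordinates, voxel centers at integer positions)
marching_squares <- function(mask, iso = 0.5) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nx <- nrow(m); ny <- ncol(m)
  v00 <- m[-nx, -ny]; v10 <- m[-1, -ny]; v01 <- m[-nx, -1]; v11 <- m[-1, -1]
  b00 <- v00 >= iso; b10 <- v10 >= iso; b01 <- v01 >= iso; b11 <- v11 >= iso
  idx <- b00 + 2L * b10 + 4L * b11 + 8L * b01
  mixed <- which(idx > 0L & idx < 15L, arr.ind = TRUE)

  seg_a <- list(); seg_b <- list(); nseg <- 0L
  case_edges <- list(
    `1` = list(c("S", "W")), `2` = list(c("S", "E")), `3` = list(c("W", "E")),
    `4` = list(c("E", "N")), `6` = list(c("S", "N")), `7` = list(c("W", "N")),
    `8` = list(c("W", "N")), `9` = list(c("S", "N")), `11` = list(c("E", "N")),
    `12` = list(c("W", "E")), `13` = list(c("S", "E")), `14` = list(c("S", "W")))
  for (r in seq_len(nrow(mixed))) {
    ci <- mixed[r, 1]; cj <- mixed[r, 2]
    code <- idx[ci, cj]
    vv <- c(v00[ci, cj], v10[ci, cj], v11[ci, cj], v01[ci, cj])
    if (code == 5L || code == 10L) {
      center_in <- mean(vv) >= iso
      pairs <- if (code == 5L) {
        if (center_in) list(c("S", "E"), c("W", "N"))
        else list(c("S", "W"), c("E", "N"))
      } else {
        if (center_in) list(c("S", "W"), c("E", "N"))
        else list(c("S", "E"), c("W", "N"))
      }
    } else {
      pairs <- case_edges[[as.character(code)]]
    }
    for (pr in pairs) {
      nseg <- nseg + 1L
      seg_a[[nseg]] <- ms_edge_point(ci, cj, pr[1], vv[1], vv[2], vv[3], vv[4], iso)
      seg_b[[nseg]] <- ms_edge_point(ci, cj, pr[2], vv[1], vv[2], vv[3], vv[4], iso)
    }
  }
  if (nseg == 0L) return(list())

  key <- function(p) paste(round(p[1] * 1e7), round(p[2] * 1e7))
  ends <- character(2L * nseg)
  for (k in seq_len(nseg)) {
    ends[2L * k - 1L] <- key(seg_a[[k]])
    ends[2L * k] <- key(seg_b[[k]])
  }
  adj <- split(seq_len(2L * nseg), ends)

  used <- logical(nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    pts <- list(seg_a[[start]], seg_b[[start]])
    used[start] <- TRUE
    cur_key <- key(seg_b[[start]])
    repeat {
      slots <- adj[[cur_key]]
      nxt <- 0L
      for (sl in slots) {
        sid <- (sl + 1L) %/% 2L
        if (!used[sid]) { nxt <- sl; break }
      }
      if (nxt == 0L) break
      sid <- (nxt + 1L) %/% 2L
      used[sid] <- TRUE
      nxt_pt <- if (nxt %% 2L == 1L) seg_b[[sid]] else seg_a[[sid]]
      if (key(nxt_pt) == key(pts[[1]])) break  # loop closed
      pts[[length(pts) + 1L]] <- nxt_pt
      cur_key <- key(nxt_pt)
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, pts)
  }
  # shift for padding: padded grid index k corresponds to original index k-1
  lapply(loops, function(L) L - 2)  # back to 0-based voxel-center coordinates
}

#' Extract the sub-voxel CC contour from a binary mask
#'
#' Iso-0.5 contour of the bilinearly interpolated mask (marching squares,
#' saddle cells resolved by the interpolated cell-center value), scaled to
#' mm.  If several closed contours exist, the one with the largest enclosed
#' area is returned; holes are discarded.
#'
#' @param mask 2D binary matrix; rows index the anterior+ direction, columns
#'   the superior+ direction; pixel centers at `(i-1, j-1) * resolution` mm.
#' @param resolution Pixel size in mm.
#' @param min_area_mm2 Minimum area of the largest component (error below).
#' @return Object of class `cc_contour`: `vertices` (n x 2 mm,
#'   counter-clockwise), `resolution`.
#' @export
mask_to_contour <- function(mask, resolution = 1, min_area_mm2 = 0) {
  if (!any(mask >= 0.5)) stop("mask is empty")
  loops <- marching_squares(mask)
  if (length(loops) == 0) stop("mask is empty")
  areas <- vapply(loops, polygon_area, numeric(1))
  best <- which.max(abs(areas))
  verts <- loops[[best]]
  if (areas[best] < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
  verts <- verts * resolution
  area <- abs(areas[best]) * resolution^2
  if (area < min_area_mm2)
    stop("largest contour area ", signif(area, 4), " mm^2 below minimum ",
         min_area_mm2)
  structure(list(vertices = verts, resolution = resolution),
            class = "cc_contour")
}

# -- triangulation ------------------------------------------------------------

# deterministic jitter in [-0.5, 0.5) from an integer index (keeps the CDT
# free of exactly-cocircular lattice configurations without touching the RNG)
hash_jitter <- function(i) {
  x <- sin(i * 12.9898 + 78.233) * 43758.5453
  x - floor(x) - 0.5
}

#' Triangulate the interior of a contour
#'
#' Conforming constrained Delaunay triangulation whose boundary equals the
#' input polygon; boundary edges are densified to `max_edge_mm` (points
#' inserted exactly on the segments, preserving the polygon geometry) and
#' the interior is filled with a hexagonal point lattice.
#'
#' @param contour A [mask_to_contour()] result, or an n x 2 matrix of
#'   polygon vertices in mm (counter-clockwise).
#' @param max_edge_mm Target maximum edge length (mm).
#' @return Object of class `cc_mesh`: `vertices` (V x 2 mm), `triangles`
#'   (F x 3, counter-clockwise), `boundary` (ordered vertex index loop).
#' @export
contour_to_mesh <- function(contour, max_edge_mm = 1) {
  poly <- if (inherits(contour, "cc_contour")) contour$vertices else contour
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  # drop duplicate consecutive vertices
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-12)
  poly <- poly[keep, , drop = FALSE]
  if (sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) < 1e-12)
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (polygon_area(poly) < 0)
    poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  if (!.polygon_is_simple(poly)) stop("contour polygon is self-intersecting")

  # densify boundary to max_edge_mm (new points exactly on the segments)
  dens <- list()
  n <- nrow(poly)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
    L <- sqrt(sum((q - p)^2))
    k <- max(1L, ceiling(L / max_edge_mm))
    t <- (seq_len(k) - 1) / k
    dens[[i]] <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }
  bpts <- do.call(rbind, dens)
  nb <- nrow(bpts)

  # hexagonal interior lattice, kept clear of the boundary
  h <- max_edge_mm
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  ys <- seq(yr[1] + h / 2, yr[2], by = h * sqrt(3) / 2)
  ipts <- NULL
  if (length(ys) > 0) {
    rows <- lapply(seq_along(ys), function(r) {
      x0 <- xr[1] + if (r %% 2 == 0) h / 2 else 0
      xs <- seq(x0, xr[2], by = h)
      if (length(xs) == 0) return(NULL)
      cbind(xs, ys[r])
    })
    ipts <- do.call(rbind, rows)
  }
  if (!is.null(ipts) && nrow(ipts) > 0) {
    jit <- cbind(hash_jitter(seq_len(nrow(ipts))),
                 hash_jitter(seq_len(nrow(ipts)) + 7919L)) * (h * 1e-4)
    ipts <- ipts + jit
    inside <- .points_in_polygon(ipts, poly)
    ipts <- ipts[inside, , drop = FALSE]
    if (nrow(ipts) > 0) {
      d <- .dist_to_polygon(ipts, poly)
      ipts <- ipts[d >= 0.45 * h, , drop = FALSE]
    }
  }
  pts <- rbind(bpts, ipts)

  # normalize to ~unit box for fixed-tolerance predicates
  ctr <- colMeans(pts)
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  norm_pts <- sweep(pts, 2, ctr) / scale
  tri <- .cdt_triangulate(norm_pts, nb)
  if (nrow(tri) == 0) stop("triangulation produced no interior triangles")

  mesh <- structure(list(vertices = pts, triangles = tri,
                         boundary = seq_len(nb)),
                    class = "cc_mesh")
  mesh
}

#' Triangle areas of a mesh
#' @param mesh A `cc_mesh`.
#' @return Numeric vector of (positive) triangle areas in mm^2.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  ax <- v[tr[, 1], 1]; ay <- v[tr[, 1], 2]
  bx <- v[tr[, 2], 1]; by <- v[tr[, 2], 2]
  cx <- v[tr[, 3], 1]; cy <- v[tr[, 3], 2]
  ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
}

# -- endpoints and boundary partition -----------------------------------------

#' Locate the anterior and posterior CC endpoints
#'
#' Default rule: the anterior endpoint is the boundary vertex nearest to AC
#' (rostrum tip), the posterior endpoint the boundary vertex nearest to PC
#' (inferior splenium tip).  Alternative rule `"projection"`: extremal
#' boundary projections onto the AC-PC line.
#'
#' @param mesh A `cc_mesh`.
#' @param AC,PC Landmarks in the same 2D mid-sagittal (a, s) frame as the
#'   mesh, mm.
#' @param rule `"nearest"` (default) or `"projection"`.
#' @return Integer vector `c(anterior = i, posterior = j)` of vertex indices.
#' @export
find_endpoints <- function(mesh, AC, PC, rule = c("nearest", "projection")) {
  rule <- match.arg(rule)
  bidx <- mesh$boundary
  bv <- mesh$vertices[bidx, , drop = FALSE]
  if (rule == "nearest") {
    da <- (bv[, 1] - AC[1])^2 + (bv[, 2] - AC[2])^2
    dp <- (bv[, 1] - PC[1])^2 + (bv[, 2] - PC[2])^2
    ia <- bidx[which.min(da)]
    ip <- bidx[which.min(dp)]
  } else {
    dir <- unit(c(AC[1] - PC[1], AC[2] - PC[2]))
    proj <- bv %*% dir
    ia <- bidx[which.max(proj)]
    ip <- bidx[which.min(proj)]
  }
  if (ia == ip) stop("anterior and posterior endpoints coincide")
  c(anterior = ia, posterior = ip)
}

#' Partition the mesh boundary into inferior and superior chains
#'
#' Splits the boundary loop at the two endpoint vertices; the chain with
#' the lower mean superior coordinate is labeled inferior (the CC's
#' fornix-facing boundary lies below the superior boundary in standardized
#' pose).
#'
#' @param mesh A `cc_mesh`.
#' @param endpoints Result of [find_endpoints()].
#' @return The mesh with `chains` (list of ordered vertex index vectors
#'   `inferior`, `superior`, both including the endpoint vertices),
#'   `chain_labels` (per boundary edge, `"inferior"`/`"superior"`), and
#'   `endpoints` attached.
#' @export
partition_boundary <- function(mesh, endpoints) {
  loop <- mesh$boundary
  B <- length(loop)
  pa <- match(endpoints[["anterior"]], loop)
  pp <- match(endpoints[["posterior"]], loop)
  if (is.na(pa) || is.na(pp)) stop("endpoints must lie on the boundary loop")
  walk <- function(from, to) {
    if (from <= to) loop[from:to]
    else loop[c(from:B, 1:to)]
  }
  chain1 <- walk(pa, pp)   # anterior -> posterior along loop direction
  chain2 <- rev(walk(pp, pa))  # anterior -> posterior the other way
  if (length(chain1) < 3 || length(chain2) < 3)
    stop("endpoints are adjacent on the boundary loop (empty chain)")
  ms1 <- mean(mesh$vertices[chain1[-c(1, length(chain1))], 2])
  ms2 <- mean(mesh$vertices[chain2[-c(1, length(chain2))], 2])
  if (ms1 < ms2) {
    chains <- list(inferior = chain1, superior = chain2)
  } else {
    chains <- list(inferior = chain2, superior = chain1)
  }
  # per-boundary-edge labels (edge i connects loop[i] -> loop[i+1], wrapped);
  # edges at positions pa..pp-1 (wrapped) belong to chain1, the rest to chain2
  edge_range <- function(from, to) {
    if (from < to) from:(to - 1L)
    else if (from > to) c(from:B, seq_len(max(0L, to - 1L)))
    else integer(0)
  }
  labels <- character(B)
  lab1 <- if (ms1 < ms2) "inferior" else "superior"
  lab2 <- if (ms1 < ms2) "superior" else "inferior"
  labels[edge_range(pa, pp)] <- lab1
  labels[edge_range(pp, pa)] <- lab2
  mesh$chains <- chains
  mesh$chain_labels <- labels
  mesh$endpoints <- endpoints
  mesh
}

#' Detect the natural end caps of the boundary
#'
#' Walks the boundary from each endpoint in both directions until the
#' boundary direction (averaged over a short window) turns by more than
#' `angle_deg`, i.e. up to the first boundary corner.  Vertices before the
#' corner form the end cap, which the Laplace stage treats as a natural
#' (zero-flux) boundary rather than a charged one.
#'
#' @param mesh A partitioned `cc_mesh` (with `endpoints`).
#' @param window_mm Direction-averaging window (mm).
#' @param angle_deg Turning angle threshold (degrees).
#' @param max_frac Maximum cap arc length as a fraction of the boundary
#'   loop length; beyond it the fallback `fallback_mm` cap is used.
#' @param fallback_mm Cap arc length when no corner is found.
#' @return Logical vector over mesh vertices, TRUE for cap vertices
#'   (endpoint vertices included).
#' @export
detect_end_caps <- function(mesh, window_mm = 0.75, angle_deg = 40,
                            max_frac = 0.25, fallback_mm = 2) {
  stopifnot(!is.null(mesh$endpoints))
  loop <- mesh$boundary
  B <- length(loop)
  P <- mesh$vertices[loop, , drop = FALSE]
  seglen <- sqrt(rowSums((P[c(2:B, 1), ] - P)^2))  # edge i: loop[i]->loop[i+1]
  total <- sum(seglen)
  cap <- logical(nrow(mesh$vertices))

  avg_dir <- function(pos, forward) {
    # average boundary direction over window_mm starting at loop position pos
    acc <- c(0, 0); walked <- 0; p <- pos
    while (walked < window_mm) {
      if (forward) {
        q <- if (p == B) 1L else p + 1L
        d <- P[q, ] - P[p, ]
      } else {
        q <- if (p == 1L) B else p - 1L
        d <- P[q, ] - P[p, ]
      }
      acc <- acc + d
      walked <- walked + sqrt(sum(d^2))
      p <- q
      if (p == pos) break
    }
    acc
  }

  # local turn angle at loop position q (single adjacent edges)
  local_turn <- function(q) {
    prv <- if (q == 1L) B else q - 1L
    nxt <- if (q == B) 1L else q + 1L
    d1 <- P[q, ] - P[prv, ]
    d2 <- P[nxt, ] - P[q, ]
    acos(max(-1, min(1, sum(unit(d1) * unit(d2)))))
  }

  cos_thr <- cos(angle_deg * pi / 180)
  for (ep in mesh$endpoints) {
    pos0 <- match(ep, loop)
    for (forward in c(TRUE, FALSE)) {
      walked <- 0; p <- pos0
      capped <- c(loop[pos0])
      found <- FALSE
      while (walked <= max_frac * total) {
        q <- if (forward) (if (p == B) 1L else p + 1L) else (if (p == 1L) B else p - 1L)
        step <- sqrt(sum((P[q, ] - P[p, ])^2))
        walked <- walked + step
        # turning at q: direction before (towards q) vs after (leaving q)
        d_in <- avg_dir(q, !forward); d_in <- -d_in
        d_out <- avg_dir(q, forward)
        cs <- sum(unit(d_in) * unit(d_out))
        if (cs < cos_thr) { found <- TRUE; break }
        capped <- c(capped, loop[q])
        p <- q
      }
      if (found) {
        # the windowed test can fire up to a window early; take the corner
        # as the strongest local turn within the look-ahead window and cap
        # everything before it
        corner <- q; best <- local_turn(q)
        extra <- 0; pp <- q
        repeat {
          qq <- if (forward) (if (pp == B) 1L else pp + 1L) else (if (pp == 1L) B else pp - 1L)
          extra <- extra + sqrt(sum((P[qq, ] - P[pp, ])^2))
          if (extra > window_mm) break
          if (local_turn(qq) > best) { best <- local_turn(qq); corner <- qq }
          pp <- qq
        }
        pp <- p
        while (pp != corner) {
          qq <- if (forward) (if (pp == B) 1L else pp + 1L) else (if (pp == 1L) B else pp - 1L)
          if (qq == corner) break
          capped <- c(capped, loop[qq])
          pp <- qq
        }
      }
      if (!found) {
        # no corner: cap a fixed fallback arc length
        walked <- 0; p <- pos0
        capped <- c(loop[pos0])
        while (walked < fallback_mm) {
          q <- if (forward) (if (p == B) 1L else p + 1L) else (if (p == 1L) B else p - 1L)
          walked <- walked + sqrt(sum((P[q, ] - P[p, ])^2))
          if (walked >= fallback_mm) break
          capped <- c(capped, loop[q])
          p <- q
        }
      }
      cap[capped] <- TRUE
    }
  }
  cap
}

# -- export -------------------------------------------------------------------

#' Write a mesh as an OFF file
#' @param mesh A `cc_mesh`.
#' @param path Output path.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh as ASCII VTK polydata, optionally with per-vertex or
#' per-face scalars
#' @param mesh A `cc_mesh`.
#' @param path Output path.
#' @param point_scalars Optional named list of per-vertex numeric vectors.
#' @param cell_scalars Optional named list of per-triangle numeric vectors.
#' @export
write_mesh_vtk <- function(mesh, path, point_scalars = NULL,
                           cell_scalars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "ccmorph mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nv)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  if (!is.null(point_scalars)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_scalars[[nm]]), con)
    }
  }
  if (!is.null(cell_scalars)) {
    writeLines(sprintf("CELL_DATA %d", nf), con)
    for (nm in names(cell_scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", cell_scalars[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a contour as a CSV vertex list
#' @param contour A `cc_contour`.
#' @param path Output path.
#' @export
write_contour_csv <- function(contour, path) {
  df <- data.frame(a_mm = contour$vertices[, 1], s_mm = contour$vertices[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
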
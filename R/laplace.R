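# Laplace-equation thickness machinery on the CC mesh.
#
# A harmonic potential u is solved with Dirichlet charges -1/+1 on the
# inferior/superior boundary chains; the boundary near the two CC endpoints
# (the "end caps", up to the first boundary corner) is left natural
# (zero-Neumann), so on a straight ribbon the field is exactly linear and on
# an annulus sector exactly logarithmic.  The zero level set of u is the
# intercallosal line; level sets of the harmonic-conjugate potential v (the
# least-squares potential of the 90-degree-rotated gradient) are the
# cross-cut "level paths" whose lengths define local thickness -- an exact
# shortcut around explicit gradient-streamline tracing.

# per-triangle gradient of a per-vertex scalar (m x 2 matrix)
tri_gradients <- function(mesh, f) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1x <- v[tr[, 2], 1] - v[tr[, 1], 1]; e1y <- v[tr[, 2], 2] - v[tr[, 1], 2]
  e2x <- v[tr[, 3], 1] - v[tr[, 1], 1]; e2y <- v[tr[, 3], 2] - v[tr[, 1], 2]
  d1 <- f[tr[, 2]] - f[tr[, 1]]; d2 <- f[tr[, 3]] - f[tr[, 1]]
  det <- e1x * e2y - e1y * e2x
  cbind((d1 * e2y - d2 * e1y) / det, (-d1 * e2x + d2 * e1x) / det)
}

# accumulate contributions into a length-n vector by index (handles repeats)
accumulate_at <- function(n, idx, values) {
  out <- numeric(n)
  sums <- rowsum(values, idx)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out
}

#' Cotangent-weight Laplacian of a triangle mesh
#'
#' @param mesh A `cc_mesh`.
#' @return Sparse symmetric positive semi-definite matrix;
#'   `(Lu)_i = sum_j w_ij (u_i - u_j)` with `w_ij = (cot a + cot b) / 2`.
#' @export
cotan_laplacian <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  cot_at <- function(a, b, c) {
    u1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    u2 <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- u1[, 1] * u2[, 1] + u1[, 2] * u2[, 2]
    cr <- u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1]
    dt / cr
  }
  # angle at vertex k weights the opposite edge (i, j)
  ii <- c(tr[, 2], tr[, 3], tr[, 1])
  jj <- c(tr[, 3], tr[, 1], tr[, 2])
  ww <- c(cot_at(tr[, 1], tr[, 2], tr[, 3]),
          cot_at(tr[, 2], tr[, 3], tr[, 1]),
          cot_at(tr[, 3], tr[, 1], tr[, 2])) / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

#' Solve the Laplace equation on a partitioned CC mesh
#'
#' Linear finite elements with Dirichlet data `u = -1` on the inferior
#' chain, `u = +1` on the superior chain, and natural (zero-Neumann)
#' boundary on the end caps around the two endpoint vertices.  The discrete
#' maximum principle keeps interior values strictly inside (-1, 1).
#'
#' @param mesh A `cc_mesh` with chains (see [partition_boundary()]).
#' @param caps Logical per-vertex cap mask; default [detect_end_caps()].
#' @param charges Dirichlet values, `c(inferior = -1, superior = 1)`.
#' @return Object of class `cc_laplace`: `u` (per-vertex potential), `caps`,
#'   `dirichlet` (logical mask).
#' @export
solve_laplace <- function(mesh, caps = NULL,
                          charges = c(inferior = -1, superior = 1)) {
  stopifnot(!is.null(mesh$chains))
  areas <- triangle_areas(mesh)
  scale2 <- mean(areas)
  bad <- which(areas <= 1e-12 * scale2)
  if (length(bad) > 0)
    stop("degenerate triangles in mesh (indices ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  if (is.null(caps)) caps <- detect_end_caps(mesh)
  n <- nrow(mesh$vertices)
  ubc <- rep(NA_real_, n)
  ubc[mesh$chains$inferior] <- charges[["inferior"]]
  ubc[mesh$chains$superior] <- charges[["superior"]]
  ubc[caps] <- NA_real_
  dir_mask <- !is.na(ubc)
  if (sum(dir_mask) < 2) stop("no Dirichlet boundary left after cap removal")
  L <- cotan_laplacian(mesh)
  free <- which(!dir_mask)
  fixed <- which(dir_mask)
  u <- numeric(n)
  u[fixed] <- ubc[fixed]
  rhs <- -L[free, fixed, drop = FALSE] %*% ubc[fixed]
  sol <- tryCatch(Matrix::solve(L[free, free], rhs),
                  error = function(e) stop("singular Laplace system: ",
                                           conditionMessage(e)))
  u[free] <- as.numeric(sol)
  structure(list(u = u, caps = caps, dirichlet = dir_mask),
            class = "cc_laplace")
}

# accept either the cc_laplace object or a bare numeric vector
field_values <- function(field) {
  if (inherits(field, "cc_laplace")) field$u else as.numeric(field)
}

#' Harmonic-conjugate potential of the Laplace solution
#'
#' Least-squares potential `v` whose per-triangle gradient matches the
#' 90-degree-rotated gradient of `u` (discrete Poisson problem with the
#' rotated-gradient divergence as source, area-weighted).  Gauge: `v = 0`
#' at the anterior endpoint; the sign is fixed so `v` increases toward the
#' posterior endpoint.
#'
#' @param mesh A partitioned `cc_mesh` (needs `endpoints`).
#' @param u A `cc_laplace` object or per-vertex potential vector.
#' @return Per-vertex conjugate potential (numeric vector).
#' @export
conjugate_potential <- function(mesh, u) {
  stopifnot(!is.null(mesh$endpoints))
  uv <- field_values(u)
  g <- tri_gradients(mesh, uv)
  w <- cbind(-g[, 2], g[, 1])  # 90-degree rotation of grad u
  areas <- triangle_areas(mesh)
  vtx <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(vtx)
  b <- numeric(n)
  for (k in 1:3) {
    a_idx <- tr[, k]
    b_idx <- tr[, k %% 3 + 1]
    c_idx <- tr[, (k + 1) %% 3 + 1]
    ex <- vtx[c_idx, 1] - vtx[b_idx, 1]
    ey <- vtx[c_idx, 2] - vtx[b_idx, 2]
    # grad(lambda_a) = rot90(pc - pb) / (2A); A_T * grad . w_T
    contrib <- (-ey * w[, 1] + ex * w[, 2]) / 2
    b <- b + accumulate_at(n, a_idx, contrib)
  }
  L <- cotan_laplacian(mesh)
  pin <- mesh$endpoints[["anterior"]]
  free <- setdiff(seq_len(n), pin)
  v <- numeric(n)
  v[free] <- as.numeric(Matrix::solve(L[free, free], b[free]))
  if (v[mesh$endpoints[["posterior"]]] < v[pin]) v <- -v
  v
}

# -- level sets ---------------------------------------------------------------

#' Extract a level set of a per-vertex field
#'
#' Piecewise-linear level curves via linear interpolation on triangle
#' edges, chained into ordered polylines (open polylines end on the mesh
#' boundary; closed loops are possible for non-monotone fields).
#'
#' @param mesh A `cc_mesh`.
#' @param field Per-vertex values (or a `cc_laplace` object).
#' @param value Level value; outside the field range yields an empty list.
#' @return List of polylines; each has `points` (k x 2), `edges` (k x 2
#'   vertex indices of the crossed mesh edge), `t` (interpolation weight
#'   toward the second edge vertex).
#' @export
extract_level_set <- function(mesh, field, value) {
  f <- field_values(field)
  rng <- range(f)
  if (value < rng[1] || value > rng[2]) return(list())
  s <- f - value
  # nudge exact-zero vertices off the level to keep crossings on edge interiors
  eps <- 1e-12 * max(diff(rng), 1)
  s[s == 0] <- eps
  tr <- mesh$triangles
  cross <- function(i, j) s[tr[, i]] * s[tr[, j]] < 0
  c12 <- cross(1, 2); c23 <- cross(2, 3); c31 <- cross(3, 1)
  hit <- which(c12 | c23 | c31)
  if (length(hit) == 0) return(list())

  edge_pt <- function(va, vb) {
    t <- s[va] / (s[va] - s[vb])
    list(va = va, vb = vb, t = t,
         p = mesh$vertices[va, , drop = FALSE] * (1 - t) +
             mesh$vertices[vb, , drop = FALSE] * t)
  }
  # each crossed triangle contributes one segment between its two crossed edges
  segs <- vector("list", length(hit))
  for (si in seq_along(segs)) {
    ti <- hit[si]
    es <- list()
    if (c12[ti]) es[[length(es) + 1]] <- c(tr[ti, 1], tr[ti, 2])
    if (c23[ti]) es[[length(es) + 1]] <- c(tr[ti, 2], tr[ti, 3])
    if (c31[ti]) es[[length(es) + 1]] <- c(tr[ti, 3], tr[ti, 1])
    a <- edge_pt(es[[1]][1], es[[1]][2])
    b <- edge_pt(es[[2]][1], es[[2]][2])
    segs[[si]] <- list(a = a, b = b)
  }
  ekey <- function(e) paste(min(e$va, e$vb), max(e$va, e$vb))
  keys_a <- vapply(segs, function(s) ekey(s$a), character(1))
  keys_b <- vapply(segs, function(s) ekey(s$b), character(1))
  adj <- split(rep(seq_along(segs), 2), c(keys_a, keys_b))
  degree <- lengths(adj)

  visited <- logical(length(segs))
  node_of <- function(sid, key) if (keys_a[sid] == key) segs[[sid]]$a else segs[[sid]]$b
  other_key <- function(sid, key) if (keys_a[sid] == key) keys_b[sid] else keys_a[sid]

  walk <- function(start_key) {
    pts <- list(); edges <- list(); ts <- c()
    cur_key <- start_key
    repeat {
      sid <- NA_integer_
      for (cand in adj[[cur_key]]) if (!visited[cand]) { sid <- cand; break }
      if (is.na(sid)) break
      visited[sid] <<- TRUE
      nd <- node_of(sid, cur_key)
      if (length(pts) == 0) {
        pts[[1]] <- nd$p; edges[[1]] <- c(nd$va, nd$vb); ts[1] <- nd$t
      }
      nk <- other_key(sid, cur_key)
      nd2 <- node_of(sid, nk)
      pts[[length(pts) + 1]] <- nd2$p
      edges[[length(edges) + 1]] <- c(nd2$va, nd2$vb)
      ts[length(ts) + 1] <- nd2$t
      cur_key <- nk
    }
    if (length(pts) < 2) return(NULL)
    list(points = do.call(rbind, pts), edges = do.call(rbind, edges), t = ts)
  }

  polylines <- list()
  open_starts <- names(degree)[degree == 1]
  for (k in open_starts) {
    if (all(visited[adj[[k]]])) next
    pl <- walk(k)
    if (!is.null(pl)) polylines[[length(polylines) + 1]] <- pl
  }
  # remaining segments form closed loops
  for (sid in seq_along(segs)) {
    if (visited[sid]) next
    pl <- walk(keys_a[sid])
    if (!is.null(pl)) polylines[[length(polylines) + 1]] <- pl
  }
  polylines
}

#' The intercallosal line (zero level set of u)
#'
#' Extracts the `u = 0` level curve, orients it anterior to posterior, and
#' attaches an arc-length parameterization.  Its ends lie where the level
#' set exits through the natural end caps, within one local edge length of
#' the endpoint vertices.
#'
#' @param mesh A partitioned `cc_mesh`.
#' @param u A `cc_laplace` object or per-vertex potential.
#' @param endpoints Endpoint vertex indices; default `mesh$endpoints`.
#' @return Object of class `cc_icline`: `points`, `edges`, `t`, `arclen`
#'   (cumulative mm), `s` (normalized 0..1), `length_mm`.
#' @export
intercallosal_line <- function(mesh, u, endpoints = mesh$endpoints) {
  pls <- extract_level_set(mesh, u, 0)
  if (length(pls) == 0) stop("zero level set is empty")
  lens <- vapply(pls, function(p) polyline_length(p$points), numeric(1))
  if (sum(lens > 0.05 * max(lens)) > 1)
    stop("zero level set is disconnected (mesh or chain labeling defect)")
  pl <- pls[[which.max(lens)]]
  ant <- mesh$vertices[endpoints[["anterior"]], ]
  d_first <- sum((pl$points[1, ] - ant)^2)
  d_last <- sum((pl$points[nrow(pl$points), ] - ant)^2)
  if (d_last < d_first) {
    pl$points <- pl$points[rev(seq_len(nrow(pl$points))), , drop = FALSE]
    pl$edges <- pl$edges[rev(seq_len(nrow(pl$edges))), , drop = FALSE]
    pl$t <- rev(pl$t)
  }
  arclen <- cum_arclength(pl$points)
  structure(list(points = pl$points, edges = pl$edges, t = pl$t,
                 arclen = arclen, s = arclen / max(arclen),
                 length_mm = max(arclen)),
            class = "cc_icline")
}

# interpolate a per-vertex field along a level-set polyline
interp_on_line <- function(line, f) {
  f[line$edges[, 1]] * (1 - line$t) + f[line$edges[, 2]] * line$t
}

# map from unordered boundary-edge key to chain label
boundary_edge_labels <- function(mesh) {
  loop <- mesh$boundary
  B <- length(loop)
  u <- loop; v <- loop[c(2:B, 1)]
  keys <- paste(pmin(u, v), pmax(u, v))
  stats::setNames(mesh$chain_labels, keys)
}

#' Thickness profile along the intercallosal line
#'
#' Samples `n` positions equally spaced in arc length (half-step offset,
#' `s_i = (i - 0.5) / n`); at each, the conjugate potential is evaluated,
#' its level path extracted, and the connected portion through the sample
#' point measured from the inferior to the superior boundary.  Its polyline
#' length is the local thickness.
#'
#' @param mesh A partitioned `cc_mesh`.
#' @param u A `cc_laplace` object or per-vertex potential.
#' @param v Conjugate potential (see [conjugate_potential()]).
#' @param line A [intercallosal_line()].
#' @param n Number of samples (default 100).
#' @param keep_paths Keep the level-path polylines (memory).
#' @return Object of class `cc_profile`: `n`, `positions` (s in (0,1)),
#'   `thickness` (mm, NA where a level path misses a chain), `valid`,
#'   `level_paths` (list or NULL).
#' @export
thickness_profile <- function(mesh, u, v, line, n = 100, keep_paths = TRUE) {
  stopifnot(n >= 2)
  v_line <- interp_on_line(line, v)
  total <- line$length_mm
  s_i <- (seq_len(n) - 0.5) / n
  target <- s_i * total
  px <- interp1(line$arclen, line$points[, 1], target)
  py <- interp1(line$arclen, line$points[, 2], target)
  v_i <- interp1(line$arclen, v_line, target)
  elabels <- boundary_edge_labels(mesh)

  thickness <- rep(NA_real_, n)
  paths <- if (keep_paths) vector("list", n) else NULL
  for (i in seq_len(n)) {
    pls <- extract_level_set(mesh, v, v_i[i])
    if (length(pls) == 0) next
    d_min <- vapply(pls, function(pl) {
      min((pl$points[, 1] - px[i])^2 + (pl$points[, 2] - py[i])^2)
    }, numeric(1))
    pl <- pls[[which.min(d_min)]]
    k <- nrow(pl$edges)
    key1 <- paste(min(pl$edges[1, ]), max(pl$edges[1, ]))
    key2 <- paste(min(pl$edges[k, ]), max(pl$edges[k, ]))
    lab1 <- elabels[key1]; lab2 <- elabels[key2]
    ok <- !is.na(lab1) && !is.na(lab2) && lab1 != lab2
    if (ok) {
      thickness[i] <- polyline_length(pl$points)
      if (keep_paths) paths[[i]] <- pl$points
    }
  }
  if (anyNA(thickness))
    warning(sum(is.na(thickness)), " of ", n,
            " thickness samples have no inferior-to-superior level path")
  structure(list(n = n, positions = s_i, thickness = thickness,
                 valid = !is.na(thickness), level_paths = paths),
            class = "cc_profile")
}

#' Mean unsigned curvature of a polyline
#'
#' Discrete mean |curvature|: sum of absolute turning angles between
#' consecutive segments divided by total arc length.  Level-set polylines
#' carry sub-edge jitter that inflates raw turning angles, so the line is
#' first resampled at uniform arc spacing (`resample_mm`); for a circular
#' arc the turning-angle sum of the inscribed polygon equals the swept
#' angle exactly, so resampling is unbiased.  Set `resample_mm = 0` to use
#' the raw vertices.
#'
#' @param line A `cc_icline` or an n x 2 point matrix.
#' @param resample_mm Arc-length resampling step (mm); capped at a tenth
#'   of the total length.
#' @return Curvature in 1/mm.
#' @export
line_curvature <- function(line, resample_mm = 1) {
  pts <- if (inherits(line, "cc_icline")) line$points else line
  if (nrow(pts) < 3) stop("need at least 3 polyline points")
  if (resample_mm > 0) {
    al <- cum_arclength(pts)
    total <- al[length(al)]
    step <- min(resample_mm, total / 10)
    tgt <- seq(0, total, by = step)
    if (tail(tgt, 1) < total - 1e-9) tgt <- c(tgt, total)
    pts <- cbind(interp1(al, pts[, 1], tgt), interp1(al, pts[, 2], tgt))
  }
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  d <- d[len > 1e-12, , drop = FALSE]
  if (nrow(d) < 2) return(0)
  a1 <- d[-nrow(d), , drop = FALSE]
  a2 <- d[-1, , drop = FALSE]
  ang <- abs(atan2(a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1],
                   a1[, 1] * a2[, 1] + a1[, 2] * a2[, 2]))
  seglen <- sqrt(rowSums(d^2))
  # turning is observed between segment midpoints only; normalize by the
  # arc length they span (exact for circular arcs)
  span <- sum(seglen) - (seglen[1] + seglen[length(seglen)]) / 2
  sum(ang) / span
}

#' Length of a polyline
#' @param line A `cc_icline` or an n x 2 point matrix.
#' @return Length in mm.
#' @export
line_length <- function(line) {
  pts <- if (inherits(line, "cc_icline")) line$points else line
  stopifnot(nrow(pts) >= 2)
  polyline_length(pts)
}

# -- streamline oracle --------------------------------------------------------

# adjacency: unordered edge key -> triangle indices
edge_triangle_map <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  u <- c(tr[, 1], tr[, 2], tr[, 3])
  v <- c(tr[, 2], tr[, 3], tr[, 1])
  keys <- paste(pmin(u, v), pmax(u, v))
  split(rep(seq_len(m), 3), keys)
}

# barycentric location of a point; returns triangle index or NA
locate_triangle <- function(mesh, p) {
  vtx <- mesh$vertices; tr <- mesh$triangles
  ax <- vtx[tr[, 1], 1]; ay <- vtx[tr[, 1], 2]
  bx <- vtx[tr[, 2], 1]; by <- vtx[tr[, 2], 2]
  cx <- vtx[tr[, 3], 1]; cy <- vtx[tr[, 3], 2]
  o1 <- (bx - ax) * (p[2] - ay) - (by - ay) * (p[1] - ax)
  o2 <- (cx - bx) * (p[2] - by) - (cy - by) * (p[1] - bx)
  o3 <- (ax - cx) * (p[2] - cy) - (ay - cy) * (p[1] - cx)
  tol <- -1e-9
  hit <- which(o1 >= tol & o2 >= tol & o3 >= tol)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Thickness by explicit gradient-streamline tracing
#'
#' Independent (slow) alternative to the conjugate-potential level paths:
#' from a point on the intercallosal line, integrate the piecewise-constant
#' gradient of `u` in both directions until the charged boundary is reached;
#' thickness is the sum of both path lengths.  Used to validate the
#' level-set shortcut.
#'
#' @param mesh A partitioned `cc_mesh`.
#' @param u A `cc_laplace` object or per-vertex potential.
#' @param point Start point (2D mm), typically on the zero level set.
#' @param max_steps Safety bound on triangle traversals per direction.
#' @return Thickness in mm (NA if tracing fails).
#' @export
thickness_by_streamline <- function(mesh, u, point, max_steps = 10000) {
  uv <- field_values(u)
  g <- tri_gradients(mesh, uv)
  emap <- edge_triangle_map(mesh)
  vtx <- mesh$vertices; tr <- mesh$triangles

  bpoly <- vtx[mesh$boundary, , drop = FALSE]
  trace_dir <- function(sign_dir) {
    ti <- locate_triangle(mesh, point)
    if (is.na(ti)) return(NA_real_)
    x <- point
    total <- 0
    for (step in seq_len(max_steps)) {
      dir <- sign_dir * g[ti, ]
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-14) return(NA_real_)
      dir <- dir / nd
      verts <- tr[ti, ]
      best_tau <- Inf; best_edge <- NULL; best_q <- NULL
      for (k in 1:3) {
        a <- verts[k]; b <- verts[k %% 3 + 1]
        pa <- vtx[a, ]; pb <- vtx[b, ]
        e <- pb - pa
        den <- dir[1] * (-e[2]) + dir[2] * e[1]
        if (abs(den) < 1e-14) next
        # solve x + tau*dir = pa + w*e
        rx <- pa[1] - x[1]; ry <- pa[2] - x[2]
        tau <- (rx * (-e[2]) + ry * e[1]) / den
        w <- (dir[1] * ry - dir[2] * rx) / den
        if (tau > 1e-9 && w > -1e-9 && w < 1 + 1e-9 && tau < best_tau) {
          best_tau <- tau
          best_edge <- c(a, b)
          best_q <- c(pa[1] + min(max(w, 1e-9), 1 - 1e-9) * e[1],
                      pa[2] + min(max(w, 1e-9), 1 - 1e-9) * e[2])
        }
      }
      if (is.null(best_edge)) {
        # exactly on the boundary (e.g. stepped onto a boundary vertex):
        # that is a successful termination, not a failure
        if (.dist_to_polygon(matrix(x, 1, 2), bpoly)[1] < 1e-6) return(total)
        return(NA_real_)
      }
      total <- total + best_tau
      x <- best_q
      key <- paste(min(best_edge), max(best_edge))
      tris <- emap[[key]]
      nxt <- setdiff(tris, ti)
      if (length(nxt) == 0) return(total)  # boundary reached
      ti <- nxt[1]
    }
    NA_real_
  }
  up <- trace_dir(+1)
  down <- trace_dir(-1)
  up + down
}
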
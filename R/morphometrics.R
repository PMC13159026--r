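# Summary shape metrics of the mid-sagittal CC.

#' Mesh area and boundary perimeter
#'
#' @param mesh A `cc_mesh`.
#' @return Named numeric `c(area_mm2 = ..., perimeter_mm = ...)`.
#' @export
area_perimeter <- function(mesh) {
  area <- sum(triangle_areas(mesh))
  per <- polyline_length(mesh$vertices[mesh$boundary, , drop = FALSE],
                         closed = TRUE)
  c(area_mm2 = area, perimeter_mm = per)
}

#' Circularity (isoperimetric quotient)
#'
#' `4 * pi * area / perimeter^2`: 1 for a disk, smaller for elongated or
#' irregular shapes.
#'
#' @param area Area in mm^2.
#' @param perimeter Perimeter in mm (> 0).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area, perimeter) {
  if (perimeter <= 0) stop("perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' CC index
#'
#' Dimensionless ratio of thicknesses sampled at three arc-length fractions
#' of the intercallosal line (defaults approximate the classical
#' genu/body/splenium measurements) to the anterior-posterior extent of the
#' shape (extremal boundary projections onto the anterior axis).
#'
#' @param profile A `cc_profile`.
#' @param mesh The `cc_mesh` (for the AP extent).
#' @param fractions Three arc-length fractions in (0, 1).
#' @return Dimensionless CC index.
#' @export
cc_index <- function(profile, mesh, fractions = c(0.1, 0.5, 0.9)) {
  stopifnot(length(fractions) == 3)
  ok <- profile$valid
  if (any(fractions < min(profile$positions[ok])) ||
      any(fractions > max(profile$positions[ok])))
    stop("profile does not cover the requested fractions")
  t3 <- interp1(profile$positions[ok], profile$thickness[ok], fractions)
  if (anyNA(t3)) stop("missing thickness at a requested fraction")
  # AP axis: the chord between the CC endpoints (equals the anterior axis in
  # standardized pose, and keeps the index invariant under in-plane rotation
  # of the input mask); falls back to the first coordinate axis
  dir <- c(1, 0)
  if (!is.null(mesh$endpoints)) {
    chord <- mesh$vertices[mesh$endpoints[["posterior"]], ] -
             mesh$vertices[mesh$endpoints[["anterior"]], ]
    if (sqrt(sum(chord^2)) > 1e-9) dir <- unit(chord)
  }
  proj <- mesh$vertices[mesh$boundary, , drop = FALSE] %*% dir
  ap_extent <- max(proj) - min(proj)
  sum(t3) / ap_extent
}

#' Resolution-corrected CC volume at 5 mm width
#'
#' Each slice contributes its area times the overlap of its
#' `[offset - spacing/2, offset + spacing/2]` band with
#' `[-half_width, +half_width]`, yielding a volume that reflects a
#' consistent 5 mm width independent of voxel resolution.
#'
#' @param slice_areas Per-slice areas (mm^2), ordered by offset.
#' @param spacing Slice spacing (mm).
#' @param half_width Half of the target width (mm), default 2.5.
#' @param offsets Slice offsets (mm); default symmetric around 0.
#' @return Volume in mm^3.
#' @export
volume_5mm <- function(slice_areas, spacing, half_width = 2.5,
                       offsets = NULL) {
  stopifnot(spacing > 0)
  n <- length(slice_areas)
  if (is.null(offsets)) offsets <- (seq_len(n) - (n + 1) / 2) * spacing
  lo <- offsets - spacing / 2
  hi <- offsets + spacing / 2
  if (min(lo) > -half_width + 1e-9 || max(hi) < half_width - 1e-9)
    stop("slice stack does not cover the +-", half_width, " mm band")
  overlap <- pmax(0, pmin(hi, half_width) - pmax(lo, -half_width))
  sum(slice_areas * overlap)
}

#' Mean thickness of a profile
#' @param profile A `cc_profile` or numeric vector of thicknesses.
#' @return Mean over valid samples (mm).
#' @export
mean_thickness <- function(profile) {
  t <- if (inherits(profile, "cc_profile")) profile$thickness else profile
  t <- t[!is.na(t)]
  if (length(t) == 0) stop("no valid thickness samples")
  mean(t)
}

#' All summary shape metrics
#'
#' Convenience wrapper computing the full metric set from the pipeline
#' objects.
#'
#' @param mesh A partitioned `cc_mesh`.
#' @param line A `cc_icline`.
#' @param profile A `cc_profile`.
#' @param slice_areas,spacing Optional multi-slice areas for [volume_5mm()];
#'   when omitted, the 5 mm volume is approximated as mid-slice area x 5.
#' @param cc_index_fractions Fractions for [cc_index()].
#' @return Named list with `area_mm2`, `perimeter_mm`, `circularity`,
#'   `cc_index`, `length_mm`, `curvature_per_mm`, `mean_thickness_mm`,
#'   `volume5_mm3`.
#' @export
shape_metrics <- function(mesh, line, profile, slice_areas = NULL,
                          spacing = NULL, cc_index_fractions = c(0.1, 0.5, 0.9)) {
  ap <- area_perimeter(mesh)
  vol5 <- if (is.null(slice_areas)) {
    unname(ap["area_mm2"]) * 5
  } else {
    volume_5mm(slice_areas, spacing)
  }
  list(area_mm2 = unname(ap["area_mm2"]),
       perimeter_mm = unname(ap["perimeter_mm"]),
       circularity = unname(circularity(ap[["area_mm2"]], ap[["perimeter_mm"]])),
       cc_index = cc_index(profile, mesh, cc_index_fractions),
       length_mm = line$length_mm,
       curvature_per_mm = line_curvature(line),
       mean_thickness_mm = mean_thickness(profile),
       volume5_mm3 = unname(vol5))
}
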
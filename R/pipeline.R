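# End-to-end orchestration: mask -> contour -> mesh -> Laplace fields ->
# intercallosal line -> thickness profile -> metrics -> sub-segmentation.

#' Pipeline configuration
#'
#' @param mask Binary matrix (mid-sagittal CC mask) or NULL when
#'   `mask_path` is given.
#' @param mesh Optional precomputed, partitioned `cc_mesh`; when given the
#'   contour and meshing stages are skipped.
#' @param mask_path NIfTI file with the mask (first slice used).
#' @param resolution In-plane resolution (mm) of `mask`.
#' @param landmarks List with 2D `AC`, `PC` (mask-frame mm) or NULL when
#'   `landmarks_path` (JSON) is given.
#' @param landmarks_path JSON landmark file.
#' @param max_edge Mesh target edge length (mm).
#' @param profile_n Thickness samples along the intercallosal line.
#' @param scheme Sub-segmentation scheme (see [subsegment()]).
#' @param fractions Optional cut fractions for the scheme.
#' @param endpoint_rule `"nearest"` or `"projection"` ([find_endpoints()]).
#' @param cc_index_fractions Fractions for [cc_index()].
#' @param out_dir Output directory (NULL: no files written).
#' @param keep_paths Keep thickness level-path polylines in memory.
#' @return A `cc_config` list.
#' @export
pipeline_config <- function(mask = NULL, mesh = NULL, mask_path = NULL,
                            resolution = 0.5,
                            landmarks = NULL, landmarks_path = NULL,
                            max_edge = 0.75, profile_n = 100,
                            scheme = "arclength", fractions = NULL,
                            endpoint_rule = "nearest",
                            cc_index_fractions = c(0.1, 0.5, 0.9),
                            out_dir = NULL, keep_paths = FALSE) {
  cfg <- list(mask = mask, mesh = mesh, mask_path = mask_path,
              resolution = resolution,
              landmarks = landmarks, landmarks_path = landmarks_path,
              max_edge = max_edge, profile_n = profile_n, scheme = scheme,
              fractions = fractions, endpoint_rule = endpoint_rule,
              cc_index_fractions = cc_index_fractions, out_dir = out_dir,
              keep_paths = keep_paths)
  stopifnot(cfg$resolution > 0, cfg$max_edge > 0, cfg$profile_n >= 2)
  for (p in c("mask_path", "landmarks_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("file not found: ", cfg[[p]])
  structure(cfg, class = "cc_config")
}

# stable hash of a configuration (md5 of its serialized value)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the CC morphometry pipeline
#'
#' Executes contouring, meshing, Laplace/thickness, metrics, and
#' sub-segmentation.  Any stage error aborts the run with a stage-tagged
#' diagnostic recorded in the report; downstream stages are marked
#' `"skipped"`.
#'
#' @param config A [pipeline_config()].
#' @return List with `report` (per-stage status, warnings, metric table,
#'   config hash) and `results` (contour, mesh, laplace, v, line, profile,
#'   metrics, subseg).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cc_config"))
  stages <- c("inputs", "contour", "mesh", "laplace", "thickness",
              "metrics", "subseg", "outputs")
  report <- list(stages = stats::setNames(rep("pending", length(stages)), stages),
                 warnings = character(0), metrics = NULL,
                 config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("ccmorph")))
  results <- list()
  note <- function(w) report$warnings <<- c(report$warnings, w)
  failed <- NULL

  run_stage <- function(name, fun) {
    if (!is.null(failed)) {
      report$stages[[name]] <<- "skipped"
      return(NULL)
    }
    withCallingHandlers(
      tryCatch({
        r <- fun()
        report$stages[[name]] <<- "ok"
        r
      }, error = function(e) {
        report$stages[[name]] <<- paste0("error: ", conditionMessage(e))
        failed <<- name
        message("[", name, "] ERROR: ", conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        note(paste0("[", name, "] ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  inp <- run_stage("inputs", function() {
    mask <- config$mask
    res <- config$resolution
    if (is.null(mask) && is.null(config$mesh)) {
      if (is.null(config$mask_path)) stop("no mask provided")
      nii <- read_nifti(config$mask_path)
      mask <- nii$data[, , 1]
      res <- nii$pixdim[1]
    }
    lm <- config$landmarks
    if (is.null(lm) && !is.null(config$landmarks_path))
      lm <- read_landmarks(config$landmarks_path)
    if (is.null(lm) && is.null(config$mesh)) stop("no landmarks provided")
    list(mask = mask, resolution = res, landmarks = lm)
  })

  contour <- run_stage("contour", function() {
    if (!is.null(config$mesh)) return(NULL)
    mask_to_contour(inp$mask, inp$resolution)
  })
  if (!is.null(config$mesh) && is.null(failed))
    report$stages[["contour"]] <- "skipped (mesh provided)"
  results$contour <- contour

  mesh <- run_stage("mesh", function() {
    if (!is.null(config$mesh)) {
      if (is.null(config$mesh$chains)) stop("provided mesh is not partitioned")
      return(config$mesh)
    }
    m <- contour_to_mesh(contour, config$max_edge)
    ep <- find_endpoints(m, inp$landmarks$AC, inp$landmarks$PC,
                         rule = config$endpoint_rule)
    partition_boundary(m, ep)
  })
  results$mesh <- mesh

  lap <- run_stage("laplace", function() {
    u <- solve_laplace(mesh)
    v <- conjugate_potential(mesh, u)
    list(u = u, v = v)
  })
  results$laplace <- lap$u
  results$v <- lap$v

  thick <- run_stage("thickness", function() {
    line <- intercallosal_line(mesh, lap$u)
    profile <- thickness_profile(mesh, lap$u, lap$v, line,
                                 n = config$profile_n,
                                 keep_paths = config$keep_paths)
    list(line = line, profile = profile)
  })
  results$line <- thick$line
  results$profile <- thick$profile

  metrics <- run_stage("metrics", function()
    shape_metrics(mesh, thick$line, thick$profile,
                  cc_index_fractions = config$cc_index_fractions))
  results$metrics <- metrics
  report$metrics <- metrics

  subseg <- run_stage("subseg", function()
    subsegment(mesh, config$scheme, fractions = config$fractions,
               v = lap$v, line = thick$line))
  results$subseg <- subseg

  run_stage("outputs", function() {
    if (is.null(config$out_dir)) return(invisible(NULL))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$out_dir, f)
    prof_df <- data.frame(s = thick$profile$positions,
                          thickness_mm = thick$profile$thickness)
    utils::write.table(prof_df, fp("profile.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    mdf <- as.data.frame(metrics)
    utils::write.table(mdf, fp("metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(metrics, fp("metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    sdf <- data.frame(region = seq_along(subseg$region_areas),
                      area_mm2 = subseg$region_areas)
    utils::write.table(sdf, fp("subseg.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_mesh_off(mesh, fp("mesh.off"))
    write_mesh_vtk(mesh, fp("mesh.vtk"),
                   point_scalars = list(u = lap$u$u, v = lap$v),
                   cell_scalars = list(region = subseg$face_labels))
    invisible(NULL)
  })

  report$status <- if (is.null(failed)) "ok" else paste0("failed at ", failed)
  list(report = report, results = results)
}

#' Write a run report as JSON
#'
#' @param report The `report` element of a [run_pipeline()] result.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- list(status = report$status,
              stages = as.list(report$stages),
              warnings = report$warnings,
              metrics = report$metrics,
              config_hash = report$config_hash,
              package_version = report$package_version)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
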
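#' Default pipeline configuration
#'
#' A single nested list drives the whole pipeline; every entry can be
#' overridden by the caller (or by a YAML file via [readRunConfig()]).
#'
#' @return nested configuration list
#' @export
defaultRunConfig <- function() {
  list(
    input = list(kind = "phantom",       # or "files"
                 volume = NULL, landmarks = NULL,
                 phantom = list(type = "vault", inner_radius_mm = 15,
                                thickness_anterior_mm = 10,
                                thickness_posterior_mm = 3.5,
                                roots_on = TRUE, canal_on = FALSE,
                                spacing_mm = 0.4)),
    thresholds = list(lo_hu = 400, hi_hu = 2000, teeth_lo_hu = 1500,
                      min_voxels = 1000),
    roi = list(paramedian_limit_mm = 10, min_paramedian_mm = 0),
    probe = list(paramedian_offset_mm = 3, angles_deg = c(0, 10, 20, 30)),
    implant = list(diameter_mm = 2.2, length_mm = 9),
    map = list(direction_rule = "antinormal", max_ray_mm = 40),
    cohort = list(enabled = FALSE, n_patients = 100),
    seed = 1L,
    out_dir = NULL)
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file
#' @return configuration list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modifyList(defaultRunConfig(), user)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full thickness-cartography pipeline
#'
#' Phantom generation (or volume + landmark loading), bone/teeth
#' segmentation, anatomical framing, ROI partition, distance map with
#' AA/MD/Vol summaries, angulated probe measurements with root-conflict
#' and corridor-fit checks, and (optionally) the cohort statistics layer.
#' When `config$out_dir` is set, a report bundle is written: meshes (STL),
#' the color-coded map (PLY + JSON sidecar), CSV tables, model reports and
#' a manifest with the configuration hash and seed.
#'
#' @param config configuration list, see [defaultRunConfig()]
#' @return list with `meshes`, `frame`, `partition`, `dmap`,
#'   `roi_summary`, `probe_points`, `probe_results`, `corridor`,
#'   `roots_in_roi`, and (if enabled) `cohort` results
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- modifyList(defaultRunConfig(), config)

  ph <- NULL
  if (cfg$input$kind == "phantom") {
    ph <- stage("phantom", {
      p <- cfg$input$phantom
      if (identical(p$type, "vault"))
        makeVaultPhantom(inner_radius_mm = p$inner_radius_mm,
                         thickness_anterior_mm = p$thickness_anterior_mm,
                         thickness_posterior_mm = p$thickness_posterior_mm,
                         roots_on = isTRUE(p$roots_on),
                         canal_on = isTRUE(p$canal_on),
                         spacing_mm = p$spacing_mm)
      else
        makeSlabPhantom(thickness_mm = p$thickness_mm %||% 5,
                        spacing_mm = p$spacing_mm)
    })
    volume <- ph$volume
    landmarks <- ph$truth@landmarks
  } else {
    volume <- stage("load-volume", readVolume(cfg$input$volume))
    landmarks <- stage("load-landmarks", {
      if (is.null(cfg$input$landmarks) || !file.exists(cfg$input$landmarks))
        stop("landmark file missing: ", cfg$input$landmarks %||% "<NULL>")
      readLandmarks(cfg$input$landmarks)
    })
  }

  seg <- stage("segmentation", with(cfg$thresholds,
    segmentBoneTeeth(volume, lo_hu = lo_hu, hi_hu = hi_hu,
                     teeth_lo_hu = teeth_lo_hu, min_voxels = min_voxels)))

  frame <- stage("frame", buildFrame(landmarks))
  bone_f <- stage("frame", transformToFrame(seg$bone, frame))
  teeth_f <- stage("frame", if (nrow(seg$teeth@vertices))
    transformToFrame(seg$teeth, frame) else seg$teeth)

  oral <- stage("roi", selectOralPatch(bone_f))
  nasal <- stage("roi", selectNasalPatch(bone_f))
  part <- stage("roi", partitionRoi(oral, landmarks,
    paramedian_limit_mm = cfg$roi$paramedian_limit_mm,
    min_paramedian_mm = cfg$roi$min_paramedian_mm))

  dmap <- stage("map", computeDistanceMap(oral, nasal,
    direction_rule = cfg$map$direction_rule,
    max_ray_mm = cfg$map$max_ray_mm))
  roi_sum <- stage("map", summarizeRoi(oral, part, dmap))

  pts <- stage("probe", placeProbePoints(oral, landmarks,
    paramedian_offset_mm = cfg$probe$paramedian_offset_mm))
  probes <- stage("probe", measurePointThickness(pts,
    angles_deg = cfg$probe$angles_deg, nasal_surface = nasal,
    teeth_mesh = teeth_f, max_ray_mm = cfg$map$max_ray_mm))
  imp <- implantSpec(cfg$implant$diameter_mm, cfg$implant$length_mm)
  corridor <- stage("probe", do.call(rbind, lapply(seq_len(nrow(pts)),
    function(i) {
      fit <- corridorFit(pts[i, ], theta_deg = 0, implant = imp,
                         nasal_surface = nasal, teeth_mesh = teeth_f,
                         max_ray_mm = cfg$map$max_ray_mm)
      data.frame(point_id = pts$id[i], fits = fit$fits,
                 limiting_structure = fit$limiting_structure,
                 min_thickness_mm = fit$min_thickness_mm,
                 min_root_depth_mm = fit$min_root_depth_mm)
    })))
  roots <- stage("probe", rootsInRegion(oral, part, teeth_f,
    corridor_depth_mm = imp$length_mm))

  cohort <- NULL
  if (isTRUE(cfg$cohort$enabled)) {
    cohort <- stage("stats", {
      cs <- cohortSpec(n_patients = cfg$cohort$n_patients,
                       seed = cfg$seed)
      tab <- sampleCohort(cs)
      desc <- do.call(rbind, lapply(split(tab, interaction(
        tab$roi, tab$side, lex.order = TRUE)), function(gr) {
          cbind(roi = paste0(gr$roi[1], gr$side[1]),
                describeValues(gr$response))
        }))
      fit <- fitLmm(tab, response ~ sex + age_group + teeth + side + roi)
      list(table = tab, descriptives = desc, lmm = fit, spec = cs)
    })
  }

  res <- list(volume = volume, truth = if (!is.null(ph)) ph$truth,
              meshes = list(bone = bone_f, teeth = teeth_f, oral = oral,
                            nasal = nasal,
                            merged = mergeMeshes(bone_f, teeth_f)),
              frame = frame, partition = part, dmap = dmap,
              roi_summary = roi_sum, probe_points = pts,
              probe_results = probes, corridor = corridor,
              roots_in_roi = roots, cohort = cohort, config = cfg)
  if (!is.null(cfg$out_dir)) writeReportBundle(res, cfg$out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the pipeline report bundle
#'
#' @param res result of [runPipeline()]
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
writeReportBundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  writeSTL(res$meshes$bone, fp("bone.stl"))
  if (nrow(res$meshes$teeth@vertices))
    writeSTL(res$meshes$teeth, fp("teeth.stl"))
  writeSTL(res$meshes$merged, fp("merged.stl"))
  exportColorMap(res$meshes$oral, res$dmap, fp("thickness_map.ply"))
  utils::write.csv(res$roi_summary, fp("roi_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$probe_results, fp("probe_results.csv"),
                   row.names = FALSE)
  utils::write.csv(res$corridor, fp("corridor_fit.csv"), row.names = FALSE)
  lab_csv <- data.frame(face = seq_along(res$partition@labels),
                        roi = as.character(res$partition@labels))
  utils::write.csv(lab_csv, fp("roi_faces.csv"), row.names = FALSE)
  # partition as a labelled PLY: vertices colored by their ROI
  roi_cols <- rbind(`1r` = c(0.89, 0.10, 0.11), `1l` = c(0.98, 0.60, 0.60),
                    `2r` = c(0.12, 0.47, 0.71), `2l` = c(0.65, 0.81, 0.89),
                    `3r` = c(0.20, 0.63, 0.17), `3l` = c(0.70, 0.87, 0.54),
                    none = c(0.6, 0.6, 0.6))
  oral <- res$meshes$oral
  vcol <- matrix(0.6, nrow(oral@vertices), 3L)
  lab <- as.character(res$partition@labels)
  for (roi in rownames(roi_cols)[1:6]) {
    vids <- unique(as.vector(oral@faces[lab == roi, ]))
    if (length(vids)) vcol[vids, ] <- matrix(roi_cols[roi, ],
                                             length(vids), 3L, byrow = TRUE)
  }
  roi_mesh <- oral
  roi_mesh@vertexColors <- vcol
  writePLY(roi_mesh, fp("roi_partition.ply"))
  if (!is.null(res$cohort)) {
    utils::write.csv(res$cohort$table, fp("cohort.csv"), row.names = FALSE)
    utils::write.csv(res$cohort$descriptives, fp("cohort_descriptives.csv"),
                     row.names = FALSE)
    ct <- coefTable(res$cohort$lmm)
    jsonlite::write_json(
      list(coefficients = ct, sigma_b = res$cohort$lmm@sigmaB,
           sigma_e = res$cohort$lmm@sigmaE,
           n_groups = res$cohort$lmm@nGroups),
      fp("lmm_fit.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  cfg_file <- fp("config.yaml")
  yaml::write_yaml(res$config, cfg_file)
  manifest <- list(
    package = "palatemap",
    version = as.character(utils::packageVersion("palatemap")),
    seed = res$config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = list.files(out_dir))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
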
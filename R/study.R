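#' Configuration of the synthetic replica-accuracy study
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults are
#' the study conditions emulated throughout the package: 0.2 mm
#' isotropic CBCT voxels, hard tissue 2000 HU against a 0 HU background
#' with 300 HU pulp canals (straddling the 1600 HU segmentation
#' threshold with dentin-like contrast), mild partial-volume blur and
#' detector noise, a stereophotogrammetry-grade reference scan
#' (0.01 mm surface noise), 0.05 mm milling noise on the replica, and
#' one localized defect per tooth at the clinically reported weak spots
#' (premolar root tip, canine crown patch, molar furcation).
#'
#' @param tooth_kinds which phantoms to run.
#' @param seed global integer seed; every stochastic stage derives its
#'   own stream from it.
#' @param phantom_resolution ground-truth surface grid step, mm.
#' @param voxel_spacing CBCT voxel size, mm.
#' @param hu_hard_tissue,hu_canal,hu_background phantom HU levels.
#' @param blur_sigma partial-volume blur sigma, mm.
#' @param noise_sd voxel noise sd, HU.
#' @param scanner_noise_sd optical-scan surface noise sd, mm (the
#'   reference scanner is far more accurate than the CBCT voxel).
#' @param milling_noise_sd replica milling noise sd, mm.
#' @param bumps named list (per tooth kind) of localized defects, each
#'   `list(center=, radius=, amplitude=)` in mm; `center` is snapped to
#'   the nearest natural-mesh vertex. `NULL` entries disable the defect.
#' @param segmentation a [segmentation_config()].
#' @param icp an [icp_config()].
#' @param max_range normal-distance search range, mm.
#' @param out_dir output directory (`NULL` = keep results in memory
#'   only).
#' @param write_meshes write STL/PLY artifacts when `out_dir` is set.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tooth_kinds = c("premolar", "canine", "molar"),
                            seed = 1L,
                            phantom_resolution = 0.15,
                            voxel_spacing = 0.2,
                            hu_hard_tissue = 2000, hu_canal = 300,
                            hu_background = 0,
                            blur_sigma = 0.15, noise_sd = 30,
                            scanner_noise_sd = 0.01,
                            milling_noise_sd = 0.05,
                            bumps = default_bumps(),
                            segmentation = segmentation_config(),
                            icp = icp_config(subsample_count = 3000L),
                            max_range = 5,
                            out_dir = NULL, write_meshes = TRUE) {
  structure(list(tooth_kinds = match.arg(tooth_kinds,
                                         c("premolar", "canine", "molar"),
                                         several.ok = TRUE),
                 seed = as.integer(seed),
                 phantom_resolution = phantom_resolution,
                 voxel_spacing = voxel_spacing,
                 hu_hard_tissue = hu_hard_tissue, hu_canal = hu_canal,
                 hu_background = hu_background,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 scanner_noise_sd = scanner_noise_sd,
                 milling_noise_sd = milling_noise_sd,
                 bumps = bumps, segmentation = segmentation, icp = icp,
                 max_range = max_range, out_dir = out_dir,
                 write_meshes = isTRUE(write_meshes)),
            class = "pipeline_config")
}

#' Default localized defects of the study scenario
#'
#' One defect per tooth kind, at the anatomical weak spots of CBCT
#' reproduction: an outward 0.5 mm bump at the premolar root tip, a
#' 1.0 mm crown-surface patch on the canine (a filling-sized defect)
#' and a 1.9 mm bump in the molar furcation. All amplitudes are
#' positive (natural tooth locally larger than the models).
#' @return Named list of defect descriptions.
#' @export
default_bumps <- function() {
  list(premolar = list(center = c(0.8, 0, -14), radius = 2.5,
                       amplitude = 0.5),
       canine = list(center = c(3.6, 0, 1.5), radius = 2.5,
                     amplitude = 1.0),
       molar = list(center = c(0, 0, -4.2), radius = 3.5, amplitude = 1.9))
}

# derive a bounded sub-seed from the global seed and a stage index
subseed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647)
}

# small normal-direction surface noise (scanner roughness stand-in)
perturb_along_normals <- function(mesh, sd, seed) {
  if (sd <= 0) return(mesh)
  n <- vertex_normals(mesh)
  mesh$vertices <- mesh$vertices +
    n * with_local_seed(seed, rnorm(nrow(mesh$vertices), 0, sd))
  mesh
}

#' Run the synthetic replica-accuracy study
#'
#' For each requested tooth kind: generate the ground-truth phantom,
#' derive the natural-tooth scan (ground truth plus the configured
#' localized defect and scanner noise), voxelize the defect-free
#' geometry into a CBCT-like volume (blur + noise + pulp canals),
#' segment it into the CBCT reconstruction model, mill a simulated
#' replica from that model, and run both accuracy comparisons
#' (CBCT vs natural on the model basis, replica vs natural on the
#' natural basis). Deterministic for a fixed config and seed; a failure
#' in one tooth does not abort the others.
#'
#' @param cfg a [pipeline_config()].
#' @return A list with `reports` (list of [comparison_report()]),
#'   `table` (the [build_report()] data frame), `details` (per-tooth
#'   comparison objects) and `errors` (per-tooth error messages, if
#'   any). When `cfg$out_dir` is set, the table, fields, transforms,
#'   meshes and volumes are written beneath it.
#' @export
run_study <- function(cfg = pipeline_config()) {
  out <- !is.null(cfg$out_dir)
  if (out) dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  details <- list()
  errors <- list()
  for (ki in seq_along(cfg$tooth_kinds)) {
    kind <- cfg$tooth_kinds[ki]
    res <- tryCatch(
      run_one_tooth(kind, ki, cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[kind]] <- conditionMessage(res)
      next
    }
    reports <- c(reports, res$reports)
    details[[kind]] <- res
  }
  if (length(reports) == 0) stop("every tooth failed: ",
                                 paste(unlist(errors), collapse = "; "))
  tab <- build_report(reports,
                      path = if (out) file.path(cfg$out_dir,
                                                "deviation_table.csv"))
  list(reports = reports, table = tab, details = details, errors = errors)
}

run_one_tooth <- function(kind, ki, cfg) {
  ph <- make_phantom(kind, seed = subseed(cfg$seed, ki),
                     resolution = cfg$phantom_resolution)
  ground_truth <- ph$mesh

  # natural-tooth optical scan: ground truth + localized defect + scanner noise
  natural <- ground_truth
  bump <- cfg$bumps[[kind]]
  bump_used <- NULL
  if (!is.null(bump) && !is.null(bump$amplitude) && bump$amplitude != 0) {
    d2 <- colSums((t(natural$vertices) - bump$center)^2)
    center <- natural$vertices[which.min(d2), ]
    natural <- deform_bump(natural, center, bump$radius, bump$amplitude)
    bump_used <- list(center = center, radius = bump$radius,
                      amplitude = bump$amplitude)
  }
  natural <- perturb_along_normals(natural, cfg$scanner_noise_sd,
                                   subseed(cfg$seed, 10 + ki))

  # CBCT chain: voxelize the true (defect-free) geometry, then segment
  vol <- voxelize(ground_truth, spacing = cfg$voxel_spacing,
                  hu_hard_tissue = cfg$hu_hard_tissue,
                  hu_canal = cfg$hu_canal,
                  hu_background = cfg$hu_background,
                  blur_sigma = cfg$blur_sigma, noise_sd = cfg$noise_sd,
                  canals = canal_paths(ph$spec),
                  seed = subseed(cfg$seed, 20 + ki))
  cbct <- segment_volume(vol, cfg$segmentation)
  replica <- simulate_replica(cbct, cfg$milling_noise_sd,
                              seed = subseed(cfg$seed, 30 + ki))

  icp_cfg <- cfg$icp
  icp_cfg$seed <- subseed(cfg$seed, 40 + ki)
  cmp_cbct <- compare_models(natural, cbct, "model", icp_cfg,
                             cfg$max_range)
  cmp_repl <- compare_models(natural, replica, "natural", icp_cfg,
                             cfg$max_range)

  paths <- character()
  if (!is.null(cfg$out_dir)) {
    base <- file.path(cfg$out_dir, kind)
    dir.create(base, recursive = TRUE, showWarnings = FALSE)
    write_field_csv(cmp_cbct$euclidean, cmp_cbct$basis,
                    file.path(base, "cbct_euclidean.csv"))
    write_field_csv(cmp_cbct$normal, cmp_cbct$basis,
                    file.path(base, "cbct_normal.csv"))
    write_field_csv(cmp_repl$euclidean, cmp_repl$basis,
                    file.path(base, "replica_euclidean.csv"))
    write_field_csv(cmp_repl$normal, cmp_repl$basis,
                    file.path(base, "replica_normal.csv"))
    write_transform(cmp_cbct$transform, file.path(base, "cbct_transform.json"))
    write_transform(cmp_repl$transform,
                    file.path(base, "replica_transform.json"))
    paths <- file.path(base, c("cbct_euclidean.csv", "cbct_normal.csv",
                               "replica_euclidean.csv", "replica_normal.csv"))
    if (cfg$write_meshes) {
      write_stl(natural, file.path(base, "natural_scan.stl"))
      write_stl(cbct, file.path(base, "cbct_model.stl"))
      write_stl(replica, file.path(base, "replica_model.stl"))
      write_volume(vol, file.path(base, "cbct_volume.json"))
      cm <- colormap_mesh(cmp_cbct$basis, cmp_cbct$euclidean, "magnitude")
      write_ply(cm$mesh, file.path(base, "cbct_euclidean.ply"), cm$colors)
      cm2 <- colormap_mesh(cmp_repl$basis, cmp_repl$normal, "signed")
      write_ply(cm2$mesh, file.path(base, "replica_normal.ply"), cm2$colors)
    }
  }

  list(reports = list(
         comparison_report(kind, "cbct_vs_natural",
                           cmp_cbct$euclidean_stats, cmp_cbct$normal_stats,
                           paths[1:2]),
         comparison_report(kind, "replica_vs_natural",
                           cmp_repl$euclidean_stats, cmp_repl$normal_stats,
                           paths[3:4])),
       phantom = ph, natural = natural, cbct = cbct, replica = replica,
       cmp_cbct = cmp_cbct, cmp_repl = cmp_repl, bump = bump_used)
}
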
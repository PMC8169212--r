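#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it by a
#'   stable hash so stages can be rerun independently.
#' @param shape synthetic canvas extents `(z, y, x)`, voxels.
#' @param voxel_size_um voxel size.
#' @param stages character vector of stages to run, a subset of
#'   `c("generate", "fuse", "vessels", "pores", "flow", "morphuq",
#'   "stereology")`.
#' @return A config list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1, shape = c(96, 96, 96),
                           voxel_size_um = 2,
                           stages = c("generate", "fuse", "vessels", "pores",
                                      "flow", "morphuq", "stereology")) {
  list(seed = as.integer(seed), shape = as.integer(shape),
       voxel_size_um = voxel_size_um, stages = stages,
       target_phi = 0.65, grain_radius_mean = 16, grain_radius_sd = 4,
       vote_threshold = "blood", predictor_threshold = 0.4,
       noise_sd = 0.08, blur_sigma = 1,
       tree = list(generations = 2, radius_root = 10, radius_decay = 0.8,
                   segment_length_mean = 60, branch_angle = 40,
                   wiggle_amplitude = 0.1),
       min_diameter_vox = 3, pore_sigma = 2,
       flow_direction = "y", viscosity = 0.003,
       roi_sizes_vox = c(12, 16, 24, 32, 48),
       z_thickness_um = 243.75,
       stereology_every_k = 10)
}

#' Run the end-to-end analysis pipeline
#'
#' Generates (or loads) the volumes, then runs the enabled stages in
#' dependency order: fusion of a thresholding predictor on the rendered
#' grayscale, vessel skeleton morphometrics, pore-network extraction
#' with percolation analysis, Stokes/Darcy flow, direct 3D
#' morphometrics with ROI scaling and autocorrelation, and virtual 2D
#' stereology. All stage summaries are aggregated into a single report
#' (written as `report.json` together with a run manifest); reruns with
#' the same config are byte-identical.
#'
#' @param config a config list from [default_config()] or a path to a
#'   JSON file with the same fields.
#' @param out_dir output directory (created).
#' @return The report list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- config$stages
  report <- list(seed = config$seed)
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  }
  # --- generate -----------------------------------------------------
  spec <- synthetic_spec(shape = config$shape,
                         voxel_size_um = config$voxel_size_um,
                         target_phi = config$target_phi,
                         grain_radius_mean = config$grain_radius_mean,
                         grain_radius_sd = config$grain_radius_sd,
                         seed = derive_seed(config$seed, "medium"))
  medium <- tryCatch(generate_boolean_medium(spec),
                     error = function(e) fail("generate", e))
  tr <- config$tree
  tree <- tree_spec(generations = tr$generations, radius_root = tr$radius_root,
                    radius_decay = tr$radius_decay,
                    segment_length_mean = tr$segment_length_mean,
                    branch_angle = tr$branch_angle,
                    wiggle_amplitude = tr$wiggle_amplitude,
                    seed = derive_seed(config$seed, "tree"))
  vt <- tryCatch(generate_vessel_tree(tree, spec),
                 error = function(e) fail("generate", e))
  combined <- medium$data
  combined[vt$labels$data == 2L] <- 2L
  labels <- label_volume(combined, config$voxel_size_um)
  if ("generate" %in% stages) {
    write_volume(labels, file.path(out_dir, "labels.tif"))
    report$generate <- list(realized_phi = attr(medium, "realized_phi"),
                            n_grains = attr(medium, "n_grains"),
                            n_branches = nrow(vt$truth),
                            tree_clipped = vt$clipped)
  }
  # --- fuse ---------------------------------------------------------
  if ("fuse" %in% stages) {
    gray <- render_grayscale(labels, blur_sigma = config$blur_sigma,
                             noise_sd = config$noise_sd,
                             seed = derive_seed(config$seed, "render"))
    pred <- threshold_predictor(config$predictor_threshold)
    votes <- tryCatch(multi_view_predict(gray, pred),
                      error = function(e) fail("fuse", e))
    fused <- threshold_votes(votes, config$vote_threshold)
    truth <- array(as.integer(labels$data > 0), dim = dim(labels$data))
    report$fuse <- list(dice_vs_truth = dice(fused$data, truth),
                        iou_vs_truth = iou(fused$data, truth),
                        vote_threshold = config$vote_threshold)
    write_volume(fused, file.path(out_dir, "fused_mask.tif"))
  }
  # --- vessels ------------------------------------------------------
  if ("vessels" %in% stages) {
    g <- tryCatch({
      g <- skeletonize(labels, phase = "vessel")
      g <- branch_metrics(g, labels, phase = "vessel")
      filter_min_diameter(g, config$min_diameter_vox * config$voxel_size_um)
    }, error = function(e) fail("vessels", e))
    summ <- summarize_branches(largest_connected_tree(g),
                               scope = "single_tree")
    utils::write.csv(tidy(g), file.path(out_dir, "branches.csv"),
                     row.names = FALSE)
    report$vessels <- list(n_branches = nrow(g$edges),
                           summary = as.list(tidyr::pivot_wider(
                             summ[, c("metric", "median")],
                             names_from = "metric",
                             values_from = "median")))
  }
  # --- pores --------------------------------------------------------
  if ("pores" %in% stages) {
    net <- tryCatch({
      regs <- separate_pores(labels, smoothing_sigma = config$pore_sigma,
                             largest_component = TRUE)
      build_pore_network(regs)
    }, error = function(e) fail("pores", e))
    dstar <- critical_percolation_diameter(
      net, seed = derive_seed(config$seed, "percolation"))
    summ <- summarize_pores(net, d_star = dstar)
    write_pore_network(net, file.path(out_dir, "pore_network"))
    report$pores <- list(
      n_pores = nrow(net$pores), n_throats = nrow(net$throats),
      median_pore_diameter_um = summ$median[summ$metric == "pore_diameter_um"],
      median_coordination = summ$median[summ$metric == "coordination"],
      critical_diameter_um = as.numeric(dstar),
      d_star_to_median_pore = attr(summ, "d_star_to_median_pore"))
  }
  # --- flow ---------------------------------------------------------
  if ("flow" %in% stages) {
    field <- tryCatch(
      solve_stokes(flow_problem(labels, direction = config$flow_direction,
                                viscosity = config$viscosity)),
      error = function(e) fail("flow", e))
    k <- permeability(field)
    vd <- velocity_distribution(field)
    report$flow <- list(direction = config$flow_direction,
                        pressure_drop_pa = field$problem$pressure_drop,
                        permeability_um2 = k,
                        mean_speed_um_s = attr(vd, "mean_speed"),
                        max_speed_um_s = attr(vd, "max_speed"),
                        percolating = field$percolating)
    utils::write.csv(vd, file.path(out_dir, "velocity_distribution.csv"),
                     row.names = FALSE)
  }
  # --- morphuq ------------------------------------------------------
  if ("morphuq" %in% stages) {
    mu_res <- tryCatch({
      phi <- volume_fraction(labels, "tissue")
      sv <- specific_surface_area(labels, "tissue")
      curve <- roi_fluctuations(labels, "tissue",
                                roi_sizes_vox = config$roi_sizes_vox,
                                z_thickness_um = config$z_thickness_um)
      ac <- two_point_autocorrelation(labels, "tissue")
      lam <- tryCatch(correlation_length(ac), error = function(e) NA_real_)
      list(phi = phi, sv = sv, curve = curve, ac = ac, lambda = lam)
    }, error = function(e) fail("morphuq", e))
    utils::write.csv(
      mu_res$curve[, c("size_um", "v_roi_um3", "n_roi", "mean", "sd",
                       "rel_err")],
      file.path(out_dir, "roi_curve.csv"), row.names = FALSE)
    utils::write.csv(mu_res$ac, file.path(out_dir, "corr_curve.csv"),
                     row.names = FALSE)
    report$morphuq <- list(phi = mu_res$phi, s_v_um1 = mu_res$sv,
                           lambda_um = mu_res$lambda)
  }
  # --- stereology ---------------------------------------------------
  if ("stereology" %in% stages) {
    st <- tryCatch(
      stereology_volume(labels, "tissue",
                        stereology_design(every_k = config$stereology_every_k)),
      error = function(e) fail("stereology", e))
    s <- attr(st, "summary")
    utils::write.csv(st, file.path(out_dir, "stereology.csv"),
                     row.names = FALSE)
    report$stereology <- list(v_v = s$v_v_mean, v_v_sd = s$v_v_sd,
                              s_v_um1 = s$s_v_mean, n_images = s$n_images)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("mesotissue")),
                   outputs = setdiff(list.files(out_dir, recursive = TRUE),
                                     "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
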
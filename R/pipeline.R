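## End-to-end pipeline: simulate -> smooth/parcellate -> track null ->
## assign -> connectivity matrices -> significance.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis, with defaults matching the
#' standard protocol where one exists (SNR threshold 5, 4 smoothing
#' iterations, curvature 30 degrees, step 0.2 mm, amplitude threshold 0.1,
#' lengths 3-120 mm, 80% intracortical filter, 10 null repeats, alpha
#' 0.05) and desk-scale defaults for the synthetic study (mesh size,
#' hemisphere count, planted streamline counts, null seeding).
#'
#' @param seed Master integer seed; all per-hemisphere and per-repeat
#'   seeds are derived from it.
#' @param n_hemispheres Number of synthetic hemispheres.
#' @param n_rows,n_cols,fold_amplitude,fold_wavelength Mesh geometry
#'   (see [make_mesh()]).
#' @param noise_sd,low_snr_fraction Retinotopy noise parameters
#'   (see [make_retinotopy()]).
#' @param snr_threshold,smoothing_iterations Phase-map smoothing gate and
#'   iteration count.
#' @param n_retinotopic,n_nonretinotopic,n_intra,noise_length_scale
#'   Planted tractogram composition per hemisphere
#'   (see [make_planted_tractogram()]).
#' @param thickness Cortical thickness in mm.
#' @param voxel_size,n_directions ODF field grid parameters.
#' @param tracking A [tracking_params()] object.
#' @param null_repeats Null tractography repetitions per hemisphere.
#' @param null_seed_stride Take every `stride`-th cortical voxel as a null
#'   seed voxel (broad coverage at desk scale).
#' @param null_seeds_per_voxel_axis Seeds per axis per null seed voxel.
#' @param max_intracortical Intracortical-fraction rejection threshold.
#' @param end_tolerance Termination distance tolerance in mm.
#' @param alpha Significance level.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_hemispheres = 6,
                            n_rows = 36, n_cols = 60,
                            fold_amplitude = 2, fold_wavelength = 12,
                            noise_sd = 8, low_snr_fraction = 0.1,
                            snr_threshold = 5, smoothing_iterations = 4,
                            n_retinotopic = 600, n_nonretinotopic = 6,
                            n_intra = 25, noise_length_scale = 2,
                            thickness = 2.5,
                            voxel_size = 1, n_directions = 42,
                            tracking = tracking_params(),
                            null_repeats = 10,
                            null_seed_stride = 5,
                            null_seeds_per_voxel_axis = 1,
                            max_intracortical = 0.8, end_tolerance = 2,
                            alpha = 0.05) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_hemispheres >= 1, cfg$null_repeats >= 1,
            inherits(cfg$tracking, "tracking_params"))
  class(cfg) <- "pipeline_config"
  cfg
}

## 31-bit polynomial rolling hash of the serialised configuration, for
## provenance fingerprinting only.
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic SAF connectivity pipeline
#'
#' Executes, per hemisphere: synthetic retinotopy generation, SNR-gated
#' phase-map smoothing, sub-area segmentation, planted-tractogram
#' generation, null tractography (`null_repeats` repeats), streamline
#' assignment and count-matrix construction; then group-level percent and
#' closeness matrices, retinotopic-order ratios, Poisson and paired t
#' significance tests with per-block sensitivity/specificity, and
#' planted-pair recovery.  Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, matrices (CSV), the
#'   mesh (PLY), the first hemisphere's parcellation (CSV/JSON) and
#'   planted tractogram (TCK), a summary JSON and a provenance JSON are
#'   written there.
#' @param verbose Print per-stage timings.
#' @return List of class `safmap_result`; see Details.
#' @details The result carries `counts`, `null_means`, `percent`,
#'   `closeness` (per-hemisphere lists), `group_percent`,
#'   `group_closeness`, `ratios` (per inter-area block and overall),
#'   `p_poisson`, `p_ttest`, masks, `sensspec` (per test, per scope),
#'   `recovery` (fraction of planted streamlines recovered with their
#'   planted pair), and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  timings <- c()
  say <- function(stage, t0) {
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
    timings[[stage]] <<- dt
    if (verbose) message(sprintf("[safmap] %-12s %6.1f s", stage, dt))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say(name, t0)
    res
  }

  geom <- stage("simulate", {
    mesh <- make_mesh(config$n_rows, config$n_cols, config$fold_amplitude,
                      seed = config$seed, fold_wavelength = config$fold_wavelength)
    labels <- make_area_labels(mesh)
    field <- make_odf_field(mesh, voxel_size = config$voxel_size,
                            n_directions = config$n_directions,
                            thickness = config$thickness)
    ribbon <- cortical_ribbon(mesh, thickness = config$thickness)
    ## broad cortical null seeding: every stride-th ribbon voxel
    vox <- which(field$wm_mask, arr.ind = TRUE)
    cen <- sweep((vox - 1) * field$voxel_size, 2, field$origin, "+")
    ctx <- vox[ribbon_classify(cen, ribbon)$inside, , drop = FALSE]
    list(mesh = mesh, labels = labels, field = field, ribbon = ribbon,
         null_seeds = ctx[seq(1, nrow(ctx), by = config$null_seed_stride), ,
                          drop = FALSE])
  })

  hemis <- vector("list", config$n_hemispheres)
  for (h in seq_len(config$n_hemispheres)) {
    hemis[[h]] <- stage(sprintf("hemisphere %d", h), {
      hseed <- config$seed * 100L + h
      rt <- make_retinotopy(geom$mesh, geom$labels,
                            noise_sd = config$noise_sd,
                            low_snr_fraction = config$low_snr_fraction,
                            seed = hseed)
      sm <- list(
        eccentricity = smooth_phase_map(geom$mesh, rt$eccentricity, rt$snr,
                                        config$snr_threshold,
                                        config$smoothing_iterations,
                                        circular = FALSE),
        polar_angle = smooth_phase_map(geom$mesh, rt$polar_angle, rt$snr,
                                       config$snr_threshold,
                                       config$smoothing_iterations,
                                       circular = TRUE),
        snr = rt$snr)
      parc <- segment_subareas(geom$mesh, geom$labels, sm,
                               snr_threshold = config$snr_threshold)
      pl <- make_planted_tractogram(parc, geom$mesh,
                                    config$n_retinotopic,
                                    config$n_nonretinotopic, config$n_intra,
                                    seed = hseed,
                                    thickness = config$thickness,
                                    noise_length_scale = config$noise_length_scale)
      asg <- assign_streamlines(pl$tractogram, geom$ribbon, parc,
                                max_intracortical = config$max_intracortical,
                                tol = config$end_tolerance)
      counts <- build_count_matrix(asg)
      nparams <- config$tracking
      nparams$rng_seed <- config$seed * 100L + 50L + h * config$null_repeats
      nparams$seeds_per_voxel_axis <- config$null_seeds_per_voxel_axis
      nulls <- track_null(geom$field, geom$null_seeds, nparams,
                          repeats = config$null_repeats)
      null_counts <- lapply(nulls, function(tg)
        build_count_matrix(assign_streamlines(tg, geom$ribbon, parc,
                                              max_intracortical = config$max_intracortical,
                                              tol = config$end_tolerance)))
      rec <- asg$status == "accepted" &
        asg$subarea_i == pl$truth$subarea_i &
        asg$subarea_j == pl$truth$subarea_j
      list(parcellation = parc, truth = pl$truth, tractogram = pl$tractogram,
           assignments = asg, counts = counts,
           null_mean = null_mean_matrix(null_counts),
           percent = percent_matrix(counts),
           closeness = closeness_matrix(asg),
           recovered = rec)
    })
  }

  res <- stage("stats", {
    counts <- lapply(hemis, `[[`, "counts")
    null_means <- lapply(hemis, `[[`, "null_mean")
    pct <- lapply(hemis, `[[`, "percent")
    group_pct <- group_average(pct)
    cl <- lapply(hemis, `[[`, "closeness")
    group_cl <- Reduce(`+`, lapply(cl, function(m) {
      m[is.na(m)] <- 0; m
    })) / length(cl)
    ratios <- list(
      v1v2 = retinotopic_ratio(subarea_block(group_pct, "V1", "V2")),
      v2v3 = retinotopic_ratio(subarea_block(group_pct, "V2", "V3")),
      v1v3 = retinotopic_ratio(subarea_block(group_pct, "V1", "V3")),
      overall = overall_retinotopic_ratio(group_pct))
    p_pois <- poisson_test(counts, null_means)
    p_t <- if (length(counts) >= 2) paired_t_test(counts, null_means) else NULL
    scopes <- list(v1v2 = c("V1", "V2"), v2v3 = c("V2", "V3"),
                   v1v3 = c("V1", "V3"), inter = "inter")
    ss <- function(p) if (is.null(p)) NULL else
      lapply(scopes, function(sc)
        sensitivity_specificity(significance_mask(p, config$alpha), sc))
    recovery <- mean(unlist(lapply(hemis, `[[`, "recovered")))
    list(counts = counts, null_means = null_means, percent = pct,
         closeness = cl, group_percent = group_pct, group_closeness = group_cl,
         ratios = ratios, p_poisson = p_pois, p_ttest = p_t,
         mask_poisson = significance_mask(p_pois, config$alpha),
         mask_ttest = if (is.null(p_t)) NULL else significance_mask(p_t, config$alpha),
         sensspec = list(poisson = ss(p_pois), ttest = ss(p_t)),
         recovery = recovery)
  })

  res$mesh <- geom$mesh
  res$labels <- geom$labels
  res$hemispheres <- hemis
  res$config <- config
  res$provenance <- list(
    package = "safmap",
    version = as.character(utils::packageVersion("safmap")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = config_hash(config),
    timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    timings_s = timings,
    streamline_conservation = all(vapply(hemis, function(h)
      nrow(h$assignments) == length(h$tractogram$streamlines), logical(1))))
  class(res) <- "safmap_result"

  if (!is.null(out_dir)) {
    stage("write", write_result_bundle(res, out_dir))
  }
  res
}

write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ply(res$mesh, file.path(out_dir, "mesh.ply"))
  write_parcellation(res$hemispheres[[1]]$parcellation,
                     file.path(out_dir, "parcellation_h1.csv"),
                     file.path(out_dir, "parcellation_h1.json"))
  write_tck(res$hemispheres[[1]]$tractogram,
            file.path(out_dir, "planted_h1.tck"))
  for (h in seq_along(res$hemispheres)) {
    write_matrix_csv(res$counts[[h]],
                     file.path(out_dir, sprintf("counts_h%d.csv", h)))
    write_matrix_csv(res$null_means[[h]],
                     file.path(out_dir, sprintf("null_mean_h%d.csv", h)))
  }
  write_matrix_csv(res$group_percent, file.path(out_dir, "group_percent.csv"))
  write_matrix_csv(res$group_closeness,
                   file.path(out_dir, "group_closeness.csv"))
  summary <- list(
    ratios = lapply(res$ratios, function(r)
      r[c("retinotopic", "nonretinotopic", "ratio", "ratio_1dp")]),
    sensspec = res$sensspec, recovery = res$recovery,
    alpha = res$config$alpha)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.safmap_result <- function(x, ...) {
  cat("safmap pipeline result\n")
  cat(sprintf("  hemispheres: %d; planted recovery: %.3f\n",
              length(x$counts), x$recovery))
  for (nm in names(x$ratios)) {
    r <- x$ratios[[nm]]
    cat(sprintf("  %-7s retinotopic %5.1f%%  non-retinotopic %5.1f%%  ratio %.1f\n",
                nm, r$retinotopic, r$nonretinotopic, r$ratio_1dp))
  }
  if (!is.null(x$sensspec$poisson)) {
    ss <- x$sensspec$poisson$inter
    cat(sprintf("  Poisson test (inter-area): sensitivity %.2f specificity %.2f\n",
                ss$sensitivity, ss$specificity))
  }
  if (!is.null(x$sensspec$ttest)) {
    ss <- x$sensspec$ttest$inter
    cat(sprintf("  paired t-test (inter-area): sensitivity %.2f specificity %.2f\n",
                ss$sensitivity, ss$specificity))
  }
  invisible(x)
}
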
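# End-to-end orchestration: scene -> segmentation -> alignment -> thermal
# extraction -> per-unit CT -> merged record table -> statistics.

#' Default pipeline parameters
#'
#' Segmentation, alignment and thermal settings used by [process_scene()] and
#' [run_experiment()]; all overridable per call or through the YAML config of
#' [run_pipeline()].
#'
#' @return nested list of defaults: `segmentation` (bandwidth, subsample,
#'   a_threshold, selem_radius, iterations), `thermal` (emissivity 0.98,
#'   reflected_temp_c, apparent: whether input imagery is uncorrected apparent
#'   temperature, bin_width_c), `stats` (alpha, correlation variable list).
#' @export
pipeline_defaults <- function() {
  list(
    segmentation = list(bandwidth = "auto", subsample = 500, a_threshold = 0,
                        selem_radius = 1, iterations = 1),
    thermal = list(emissivity = 0.98, reflected_temp_c = 20,
                   apparent = FALSE, bin_width_c = 0.5),
    stats = list(alpha = 0.05,
                 variables = c("CT", "A", "gs", "E", "Ci", "iWUE", "LRWC",
                               "SWC", "DWC", "AGB", "GY"))
  )
}

merge_params <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  defaults
}

#' Process one paired scene into a canopy temperature sample
#'
#' The documented chain: CIELAB conversion -> mean-shift clustering of a*/b* ->
#' plant-cluster selection -> morphological erosion -> homography estimated
#' from the scene's corresponding points -> mask warped onto the thermal grid
#' -> (optional) greybody correction -> masked pixel extraction -> CT summary.
#'
#' @param rgb H x W x 3 visible frame (sRGB 0..255).
#' @param thermal a [thermal_image()] (or matrix of deg C).
#' @param points list with `src`/`dst` correspondences (visible -> thermal).
#' @param segmentation,thermal_params overrides of [pipeline_defaults()]
#'   entries.
#' @param seed seed for the segmentation subsample.
#' @return list with `ct` (from [canopy_temperature()]), `pixels`,
#'   `histogram`, `mask` (visible, eroded), `mask_thermal`, `H`, `residuals`.
#' @export
process_scene <- function(rgb, thermal, points, segmentation = NULL,
                          thermal_params = NULL, seed = 1L) {
  seg <- merge_params(pipeline_defaults()$segmentation, segmentation)
  thp <- merge_params(pipeline_defaults()$thermal, thermal_params)
  lab <- rgb_to_lab(rgb)
  labels <- mean_shift_ab(lab, bandwidth = seg$bandwidth,
                          subsample = seg$subsample, seed = seed)
  mask <- select_plant_mask(labels, a_threshold = seg$a_threshold)
  mask <- erode_mask(mask, seg$selem_radius, seg$iterations)
  est <- estimate_homography(points$src, points$dst)
  tm <- as_temp_matrix(thermal)
  mask_th <- warp_mask(mask, est$H, dim(tm))
  img <- if (isTRUE(thp$apparent)) {
    greybody_correct(thermal, thp$emissivity, thp$reflected_temp_c)
  } else thermal
  px <- extract_canopy_pixels(img, mask_th)
  list(ct = canopy_temperature(px), pixels = px,
       histogram = thermal_histogram(px, thp$bin_width_c),
       mask = mask, mask_thermal = mask_th,
       H = est$H, residuals = est$residuals, labels = labels)
}

#' Per-genotype delta-CT with Tukey letters across genotypes
#'
#' Builds the replicate-level drought-minus-control-mean table per genotype
#' (see [delta_ct()]), then compares genotype delta-CT means by one-way ANOVA
#' and Tukey's test, summarizing with a compact letter display (the letters
#' over the delta-CT boxes).
#'
#' @param records data.frame with `genotype`, `treatment` and a CT column.
#' @param ct_col name of the CT column (default `"CT"`).
#' @param alpha significance level.
#' @return list with `summary` (per-genotype delta-CT, SE, letter), `table`
#'   (replicate-level deltas), `tukey_p` and `letters`.
#' @export
delta_ct_analysis <- function(records, ct_col = "CT", alpha = 0.05) {
  gl <- unique(records$genotype)
  tabs <- lapply(gl, function(g) {
    d <- delta_ct(records[[ct_col]][records$genotype == g & records$treatment == "drought"],
                  records[[ct_col]][records$genotype == g & records$treatment == "control"])
    cbind(genotype = g, d$table, mean_delta = d$delta_ct_c, se = d$se)
  })
  tab <- do.call(rbind, tabs)
  fit <- stats::aov(delta_c ~ genotype, data = tab)
  at <- summary(fit)[[1]]
  mse <- at$`Mean Sq`[2]; dfe <- at$Df[2]
  means <- tapply(tab$delta_c, tab$genotype, mean)[gl]
  ns <- tapply(tab$delta_c, tab$genotype, length)[gl]
  pm <- tukey_pairwise_p(means, ns, mse, dfe)
  lt <- compact_letters(pm, alpha)
  summary <- data.frame(genotype = gl, delta_ct_c = as.numeric(means),
                        se = as.numeric(tapply(tab$se, tab$genotype, mean)[gl]),
                        letter = lt[gl], row.names = NULL)
  list(summary = summary, table = tab, tukey_p = pm, letters = lt)
}

#' Run the full pipeline over an in-memory synthetic experiment
#'
#' Generates (or accepts) a synthetic factorial experiment, processes every
#' scene through [process_scene()], merges the measured CT into the record
#' table, and runs the statistical stage: per-genotype delta-CT with letters,
#' a factorial analysis of CT (and any further responses requested), and the
#' Pearson correlation report. Scene failures are isolated: a failing scene is
#' reported in `failures` and the remaining scenes still run.
#'
#' @param experiment a `"synthetic_experiment"` (default: generated from
#'   `design`).
#' @param design an [experiment_design()], used when `experiment` is NULL.
#' @param segmentation,thermal_params,stats_params overrides of
#'   [pipeline_defaults()].
#' @param correspondence_noise_sd annotation noise on the per-scene
#'   corresponding points (px).
#' @param responses responses to run [factorial_analysis()] on (default
#'   `"CT"`).
#' @param seed top-level seed for pipeline randomness (segmentation
#'   subsamples, annotation jitter).
#' @return object of class `"run_report"`: `records` (with measured `CT`),
#'   `ct_table`, `delta_ct`, `analyses`, `correlation`, `failures`.
#' @export
run_experiment <- function(experiment = NULL, design = experiment_design(),
                           segmentation = NULL, thermal_params = NULL,
                           stats_params = NULL, correspondence_noise_sd = 0,
                           responses = "CT", seed = 1L) {
  if (is.null(experiment)) experiment <- generate_experiment(design)
  stp <- merge_params(pipeline_defaults()$stats, stats_params)
  scenes <- experiment$scenes
  if (length(scenes) == 0) stopf("experiment carries no scenes; regenerate with make_scenes = TRUE")
  records <- experiment$records
  ct <- rep(NA_real_, nrow(records))
  failures <- list()
  rows <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    res <- tryCatch({
      pts <- annotate_correspondences(sc, noise_sd = correspondence_noise_sd,
                                      seed = child_seed(seed, i, salt = 3L))
      process_scene(sc$rgb, sc$thermal, pts, segmentation = segmentation,
                    thermal_params = thermal_params,
                    seed = child_seed(seed, i, salt = 5L))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(scene = i, unit = sc$unit,
                                               stage = "process_scene",
                                               message = conditionMessage(res))
      next
    }
    ct[i] <- res$ct$mean
    rows[[i]] <- data.frame(scene = i, genotype = sc$unit$genotype,
                            treatment = sc$unit$treatment,
                            replicate = sc$unit$replicate,
                            ct_mean_c = res$ct$mean, ct_median_c = res$ct$median,
                            ct_p5_c = res$ct$p5, ct_p95_c = res$ct$p95,
                            n_pixels = res$ct$n)
  }
  records$CT <- ct
  ok <- !is.na(ct)
  alpha <- stp$alpha
  analyses <- list()
  dct <- NULL
  corr <- NULL
  if (sum(ok) == nrow(records)) {
    for (resp in responses) {
      analyses[[resp]] <- suppressWarnings(factorial_analysis(records, resp, alpha))
    }
    dct <- delta_ct_analysis(records, alpha = alpha)
    vars <- intersect(stp$variables, names(records))
    corr <- suppressWarnings(pearson_report(records, vars))
  } else {
    warnf("%d scene(s) failed; statistical stage skipped (see failures)",
          sum(!ok))
  }
  structure(list(records = records,
                 ct_table = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
                 delta_ct = dct, analyses = analyses, correlation = corr,
                 failures = failures, alpha = alpha),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run: %d scenes processed, %d failed\n",
              if (is.null(x$ct_table)) 0 else nrow(x$ct_table), length(x$failures)))
  if (!is.null(x$delta_ct)) {
    cat("drought-induced canopy temperature increase (deg C):\n")
    print(x$delta_ct$summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Run the pipeline from a configuration (file-based mode)
#'
#' Reads a YAML configuration, loads (or simulates) a fixture set, processes
#' every scene, and writes the CT table, delta-CT summary, analysis tables,
#' correlation matrix and a run manifest (with the config hash and seed) to
#' the output directory. Per-scene failures are isolated and summarized.
#'
#' Config keys: `paths:` (`scenes` fixture dir, `output` dir), `simulate:`
#' (optional: `n_replicates`, `rng_seed` — generate the default synthetic
#' experiment instead of reading `paths$scenes`), `segmentation:`, `thermal:`,
#' `stats:` (see [pipeline_defaults()]), `seed`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the `"run_report"`, invisibly; outputs are written to
#'   `paths$output`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  out_dir <- cfg$paths$output
  if (is.null(out_dir)) stopf("config must set paths$output")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stopf("cannot create output directory %s", out_dir)
  }
  thp <- merge_params(pipeline_defaults()$thermal, cfg$thermal)
  if (thp$emissivity <= 0 || thp$emissivity > 1) stopf("emissivity must be in (0, 1]")

  if (!is.null(cfg$simulate)) {
    des <- experiment_design(
      n_replicates = if (!is.null(cfg$simulate$n_replicates)) cfg$simulate$n_replicates else 5,
      rng_seed = if (!is.null(cfg$simulate$rng_seed)) cfg$simulate$rng_seed else seed)
    experiment <- generate_experiment(des)
    report <- run_experiment(experiment, segmentation = cfg$segmentation,
                             thermal_params = cfg$thermal, stats_params = cfg$stats,
                             seed = seed)
  } else {
    if (is.null(cfg$paths$scenes)) stopf("config must set paths$scenes or simulate:")
    fx <- read_fixture_set(cfg$paths$scenes)
    experiment <- list(
      scenes = lapply(fx$scenes, function(s) {
        list(rgb = s$rgb, thermal = s$thermal, unit = s$unit,
             points = s$points,
             params = list(rng_seed = seed,
                           image_width_px = ncol(s$rgb), image_height_px = nrow(s$rgb)))
      }),
      records = fx$records)
    # fixture scenes carry their own annotated points
    report <- run_experiment_from_fixtures(experiment, cfg, seed)
  }

  write_outputs(report, out_dir)
  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(seed = seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   outputs = list.files(out_dir),
                   n_failures = length(report$failures),
                   failures = report$failures)
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(report)
}

run_experiment_from_fixtures <- function(experiment, cfg, seed) {
  stp <- merge_params(pipeline_defaults()$stats, cfg$stats)
  records <- experiment$records
  ct <- rep(NA_real_, nrow(records))
  failures <- list(); rows <- list()
  for (i in seq_along(experiment$scenes)) {
    sc <- experiment$scenes[[i]]
    res <- tryCatch(
      process_scene(sc$rgb, sc$thermal, sc$points, segmentation = cfg$segmentation,
                    thermal_params = cfg$thermal, seed = child_seed(seed, i, salt = 5L)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(scene = i, unit = sc$unit,
                                               stage = "process_scene",
                                               message = conditionMessage(res))
      next
    }
    ct[i] <- res$ct$mean
    rows[[length(rows) + 1]] <- data.frame(
      scene = i, genotype = sc$unit$genotype, treatment = sc$unit$treatment,
      replicate = sc$unit$replicate, ct_mean_c = res$ct$mean,
      ct_median_c = res$ct$median, ct_p5_c = res$ct$p5, ct_p95_c = res$ct$p95,
      n_pixels = res$ct$n)
  }
  records$CT <- ct
  analyses <- list(); dct <- NULL; corr <- NULL
  if (all(!is.na(ct))) {
    analyses$CT <- suppressWarnings(factorial_analysis(records, "CT", stp$alpha))
    dct <- delta_ct_analysis(records, alpha = stp$alpha)
    corr <- suppressWarnings(pearson_report(records, intersect(stp$variables, names(records))))
  } else {
    warnf("%d scene(s) failed; statistical stage skipped", sum(is.na(ct)))
  }
  structure(list(records = records, ct_table = do.call(rbind, rows),
                 delta_ct = dct, analyses = analyses, correlation = corr,
                 failures = failures, alpha = stp$alpha),
            class = "run_report")
}

write_outputs <- function(report, out_dir) {
  utils::write.csv(report$records, file.path(out_dir, "records_with_ct.csv"),
                   row.names = FALSE)
  if (!is.null(report$ct_table)) {
    utils::write.csv(report$ct_table, file.path(out_dir, "ct_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$delta_ct)) {
    utils::write.csv(report$delta_ct$summary, file.path(out_dir, "delta_ct.csv"),
                     row.names = FALSE)
  }
  for (resp in names(report$analyses)) {
    a <- report$analyses[[resp]]
    utils::write.csv(a$anova_table,
                     file.path(out_dir, paste0("anova_", resp, ".csv")),
                     row.names = FALSE)
    lt <- do.call(rbind, lapply(names(a$letters), function(f) {
      data.frame(family = f, group = names(a$letters[[f]]),
                 letter = unname(a$letters[[f]]))
    }))
    utils::write.csv(lt, file.path(out_dir, paste0("letters_", resp, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$correlation)) {
    utils::write.csv(report$correlation$r_matrix,
                     file.path(out_dir, "correlation_r.csv"))
    utils::write.csv(report$correlation$interpretation_matrix,
                     file.path(out_dir, "correlation_interpretation.csv"))
  }
  invisible(out_dir)
}
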
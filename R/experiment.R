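# Synthetic factorial experiments: genotype x treatment x replicate.
#
# The generator emulates a completely randomized pot experiment contrasting
# well-watered controls with drought-stressed plants across several genotypes:
# one scene per experimental unit whose canopy temperature is drawn from the
# programmed genotype-x-treatment cell mean plus replicate noise, and one
# record of physiological variables per unit drawn the same way. All cell
# means stay retrievable for parameter-recovery tests.

#' Default genotype-by-treatment cell means for the canopy temperature
#'
#' Controls share a common canopy temperature; drought raises it by a
#' genotype-specific offset (strongly responsive, intermediate, and two
#' tolerant genotypes whose offsets coincide).
#'
#' @param genotypes character vector of genotype labels.
#' @param control_ct_c control canopy temperature, deg C.
#' @param drought_offsets_c per-genotype drought-induced increase, deg C.
#' @return matrix genotypes x c("control", "drought").
#' @export
default_ct_effects <- function(genotypes = c("G1", "G2", "G3", "G4"),
                               control_ct_c = 28,
                               drought_offsets_c = c(5, 3, 1, 1)) {
  if (length(drought_offsets_c) != length(genotypes)) {
    stopf("one drought offset per genotype is required")
  }
  m <- cbind(control = rep(control_ct_c, length(genotypes)),
             drought = control_ct_c + drought_offsets_c)
  rownames(m) <- genotypes
  m
}

#' Default cell means for the physiological variables
#'
#' Realistic magnitudes for a well-watered maize control and a severe drought
#' response (strong reduction in gas exchange, lowered leaf and soil water
#' content, raised Ci and Fo, genotype-dependent grain-yield reduction).
#'
#' @param genotypes character vector of genotype labels.
#' @return named list of genotype x treatment matrices, one per variable.
#' @export
default_physiology_effects <- function(genotypes) {
  cell <- function(control, drought) {
    m <- cbind(control = rep(control, length(genotypes)),
               drought = rep(drought, length.out = length(genotypes)))
    rownames(m) <- genotypes
    m
  }
  list(
    A = cell(30, 8), gs = cell(0.25, 0.05), E = cell(5, 1.5),
    Ci = cell(150, 210), LRWC = cell(95, 65), SWC = cell(0.35, 0.08),
    DWC = cell(1.2, 0.3), Fo = cell(400, 520), Fm = cell(2000, 1900),
    CCI = cell(30, 18), AGB = cell(250, 180),
    GY = cell(180, 180 * c(0.67, 0.77, 0.88, 1.0))
  )
}

#' Default replicate-to-replicate noise SDs per variable
#' @return named numeric vector of SDs in each variable's own units.
#' @export
default_noise_sds <- function() {
  c(CT = 0.3, A = 2, gs = 0.02, E = 0.4, Ci = 12, LRWC = 4, SWC = 0.02,
    DWC = 0.08, Fo = 25, Fm = 80, CCI = 2, AGB = 15, GY = 12)
}

#' Design of a synthetic factorial experiment
#'
#' @param genotypes genotype labels (default four contrasting genotypes).
#' @param treatments treatment labels; must be `c("control", "drought")`.
#' @param n_replicates replicates per cell (>= 2; default 5).
#' @param ct_effects genotype x treatment matrix of canopy-temperature cell
#'   means, deg C (default [default_ct_effects()]).
#' @param physiology_effects named list of genotype x treatment matrices, one
#'   per physiological variable (A, gs, E, Ci, LRWC, SWC, DWC, Fo, Fm, CCI,
#'   AGB, GY).
#' @param noise_sds named per-variable SDs (must include `CT`).
#' @param day_of_stress recorded stress day (default 12).
#' @param rng_seed top-level seed; per-unit substreams derive from it.
#' @return validated list of class `"experiment_design"`.
#' @export
experiment_design <- function(genotypes = c("G1", "G2", "G3", "G4"),
                              treatments = c("control", "drought"),
                              n_replicates = 5,
                              ct_effects = default_ct_effects(genotypes),
                              physiology_effects = default_physiology_effects(genotypes),
                              noise_sds = default_noise_sds(),
                              day_of_stress = 12,
                              rng_seed = 1L) {
  if (!identical(sort(treatments), c("control", "drought"))) {
    stopf('treatments must be c("control", "drought")')
  }
  if (!is_count(n_replicates, min = 2)) stopf("n_replicates must be an integer >= 2")
  check_cells <- function(m, what) {
    if (!is.matrix(m)) stopf("%s must be a genotype x treatment matrix", what)
    for (g in genotypes) for (tr in treatments) {
      if (!(g %in% rownames(m)) || !(tr %in% colnames(m)) || !is.finite(m[g, tr])) {
        stopf("missing cell mean for genotype '%s', treatment '%s' in %s", g, tr, what)
      }
    }
  }
  check_cells(ct_effects, "ct_effects")
  for (v in names(physiology_effects)) check_cells(physiology_effects[[v]], paste0("physiology_effects$", v))
  for (v in c("A", "gs", "E")) {
    m <- physiology_effects[[v]]
    if (is.null(m)) stopf("physiology_effects must include %s", v)
    if (any(m[genotypes, "drought"] > m[genotypes, "control"])) {
      stopf("drought cell means for %s exceed control: gas exchange must not increase under drought", v)
    }
  }
  if (!("CT" %in% names(noise_sds))) stopf("noise_sds must include 'CT'")
  if (any(noise_sds < 0)) stopf("noise SDs must be >= 0")
  structure(list(genotypes = genotypes, treatments = treatments,
                 n_replicates = n_replicates, ct_effects = ct_effects,
                 physiology_effects = physiology_effects, noise_sds = noise_sds,
                 day_of_stress = day_of_stress, rng_seed = as.integer(rng_seed)),
            class = "experiment_design")
}

#' Generate a full synthetic experiment (scenes + plant records)
#'
#' One scene per genotype x treatment x replicate with the unit's canopy
#' temperature drawn from its cell mean plus noise, and one plant record per
#' unit with all physiological variables drawn from their cell means plus
#' noise. Derived variables (iWUE, Fv/Fm, FW/TW/DW consistent with LRWC) are
#' computed through the physiology formulas.
#'
#' @param design an [experiment_design()].
#' @param scene_template a [scene_params()] used for every scene (its
#'   `n_plants` is forced to 1 — one pot per frame — and its `canopy_temp_c`
#'   and `rng_seed` are set per unit). Default: a compact 96 x 72 visible /
#'   48 x 36 thermal frame with one 14 px canopy and 0.3 degC pixel noise.
#' @param make_scenes set `FALSE` to generate only the record table (fast).
#' @return list of class `"synthetic_experiment"`: `scenes` (list of scene
#'   triples, each tagged with `unit`), `records` (data.frame with one row per
#'   unit, including the generator-truth canopy temperature `CT_true`) and
#'   `design`.
#' @export
generate_experiment <- function(design = experiment_design(),
                                scene_template = scene_params(
                                  image_width_px = 96, image_height_px = 72,
                                  thermal_width_px = 48, thermal_height_px = 36,
                                  n_plants = 1, canopy_radius_px = 14,
                                  temp_noise_sd = 0.3),
                                make_scenes = TRUE) {
  if (!inherits(design, "experiment_design")) stopf("design must be an experiment_design")
  units <- expand.grid(replicate = seq_len(design$n_replicates),
                       treatment = design$treatments,
                       genotype = design$genotypes,
                       stringsAsFactors = FALSE)
  ns <- design$noise_sds
  eff <- design$physiology_effects
  scenes <- vector("list", nrow(units))
  rec <- vector("list", nrow(units))
  # one record-level noise stream for the whole experiment (taking the first
  # draw of a fresh stream per unit would correlate replicates across the
  # arithmetic progression of unit seeds); scene pixel noise keeps independent
  # per-scene substreams below
  set.seed(child_seed(design$rng_seed, 0L, salt = 11L))
  for (i in seq_len(nrow(units))) {
    g <- units$genotype[i]; tr <- units$treatment[i]
    draw <- function(v) {
      sd <- if (v %in% names(ns)) ns[[v]] else 0
      eff[[v]][g, tr] + stats::rnorm(1, 0, sd)
    }
    ct_true <- design$ct_effects[g, tr] + stats::rnorm(1, 0, ns[["CT"]])
    A <- draw("A"); gs <- max(draw("gs"), 1e-3); E <- max(draw("E"), 0.05)
    Ci <- draw("Ci")
    LRWC <- min(max(draw("LRWC"), 1), 100)
    SWC <- max(draw("SWC"), 0.001)
    DWC <- max(draw("DWC"), 0.01)
    Fo <- max(draw("Fo"), 1); Fm <- max(draw("Fm"), Fo + 1)
    CCI <- max(draw("CCI"), 0.1)
    AGB <- max(draw("AGB"), 1); GY <- max(draw("GY"), 0)
    DW <- 0.15; TW <- 0.75
    FW <- DW + LRWC / 100 * (TW - DW)
    wilted <- if (tr == "drought") 4L + sample(0:2, 1) else sample(0:1, 1)
    dead <- if (tr == "drought") 1L + sample(0:1, 1) else 0L
    rec[[i]] <- data.frame(
      genotype = g, treatment = tr, replicate = units$replicate[i],
      day_of_stress = design$day_of_stress,
      A = A, gs = gs, E = E, Ci = Ci, iWUE = iwue(A, E),
      FW = FW, TW = TW, DW = DW, LRWC = LRWC,
      SWC = SWC, DWC = DWC,
      Fo = Fo, Fm = Fm, FvFm = fv_fm(Fo, Fm), CCI = CCI,
      leaves_total = 14L, leaves_wilted = wilted, leaves_dead = dead,
      AGB = AGB, GY = GY, CT_true = ct_true,
      stringsAsFactors = FALSE)
    if (make_scenes) {
      sp <- scene_template
      sp$n_plants <- 1L
      sp$canopy_temp_c <- ct_true
      sp$rng_seed <- child_seed(design$rng_seed, i, salt = 13L)
      sp <- do.call(scene_params, sp[setdiff(names(sp), c("canopy_ab", "background_ab"))])
      sc <- generate_scene(sp)
      sc$unit <- list(genotype = g, treatment = tr, replicate = units$replicate[i])
      scenes[[i]] <- sc
    }
  }
  structure(list(scenes = if (make_scenes) scenes else list(),
                 records = do.call(rbind, rec), design = design),
            class = "synthetic_experiment")
}
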
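# Config-driven orchestration of the whole workflow: summed-PET -> MR rigid
# co-registration, template <-> MR symmetric diffeomorphic normalization
# (with constrained cost-function masking when a lesion mask is supplied),
# transform concatenation, reference-region TAC extraction, parametric map
# generation (CBF, nCBF, R_I, R_P), region statistics and agreement report.

#' Write a complete phantom input bundle to disk
#'
#' Generates everything [run_workflow()] consumes: the undeformed phantom as
#' template (structural + atlas + label table + region set), a deformed
#' (and optionally lesioned) subject anatomy, rigidly offset PET-space
#' dynamic series for both tracers with timing sidecars, the degraded
#' arterial curve, and a ready-to-run workflow config YAML.
#'
#' @param dir output directory (created if needed).
#' @param spec a [phantom_spec()].
#' @param deformation_amplitude subject-vs-template warp size (voxels).
#' @param lesion logical: insert a focal lesion and write its mask.
#' @param pet_shift_voxels,pet_rotation_deg rigid offset of the PET frames
#'   relative to the subject MR.
#' @param delta_t_s,tau_s arterial delay/dispersion applied to the measured
#'   blood curve.
#' @param seed master seed for all randomness.
#' @return Invisibly, the path of the written config YAML.
#' @export
make_phantom_bundle <- function(dir, spec = phantom_spec(),
                                deformation_amplitude = 5, lesion = TRUE,
                                pet_shift_voxels = c(2, -3),
                                pet_rotation_deg = 0,
                                delta_t_s = 6, tau_s = 5,
                                seed = spec$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  ph <- make_phantom(spec)
  geom <- ph$geometry

  # template space: the undeformed phantom
  save_volume(ph$structural, geom, p("template.nii.gz"))
  save_volume(ph$labels$data, geom, p("atlas.nii.gz"))
  utils::write.table(ph$labels$labels, p("atlas_labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  save_region_set(phantom_region_set(spec), p("regions.tsv"))

  # subject space: deformed anatomy (+ lesion)
  warp <- if (deformation_amplitude > 0)
    make_deformation(geom, deformation_amplitude, seed = seed + 11)
  else zero_field(geom)
  subj_struct <- warp_image(ph$structural, warp)
  subj_labels <- label_volume(warp_image(ph$labels$data, warp, "nearest"),
                              geom, ph$labels$labels)
  lesion_mask <- NULL
  if (lesion) {
    les <- insert_lesion(subj_struct,
                         center = spec$center + c(-18, 16),
                         radii = c(8, 7), intensity = 220)
    subj_struct <- les$volume
    lesion_mask <- les$mask
    save_volume(lesion_mask, geom, p("lesion_mask.nii.gz"))
  }
  save_volume(subj_struct, geom, p("subject_mr.nii.gz"))

  # PET space: subject anatomy under a small rigid offset
  rt <- rigid_transform(if (length(geom$shape) == 2) pet_rotation_deg
                        else c(0, 0, pet_rotation_deg), pet_shift_voxels)
  pet_labels <- label_volume(
    warp_image(subj_labels$data, rt, "nearest", geometry = geom),
    geom, ph$labels$labels)

  input_true <- synth_input(fine = TRUE)
  measured <- degrade_input(input_true, delta_t_s, tau_s,
                            noise_percent = 0, seed = seed + 3)
  save_blood_curve(blood_curve(arterial_sample_times_s() / 60,
                               stats::approx(measured$time_min, measured$value,
                                             xout = arterial_sample_times_s() / 60,
                                             yleft = 0, rule = 2)$y),
                   p("blood.tsv"))

  water <- simulate_dynamic(pet_labels, spec, "water", input_true,
                            seed = seed + 5)
  save_dynamic_image(water, p("water_dynamic.nii.gz"), p("water_timing.tsv"))
  fddnp <- simulate_dynamic(pet_labels, spec, "fddnp", input_true,
                            seed = seed + 6)
  save_dynamic_image(fddnp, p("fddnp_dynamic.nii.gz"), p("fddnp_timing.tsv"))

  cfg <- list(
    paths = list(
      structural = p("subject_mr.nii.gz"),
      template = p("template.nii.gz"),
      atlas = p("atlas.nii.gz"),
      atlas_labels = p("atlas_labels.tsv"),
      regions = p("regions.tsv"),
      water_image = p("water_dynamic.nii.gz"),
      water_timing = p("water_timing.tsv"),
      fddnp_image = p("fddnp_dynamic.nii.gz"),
      fddnp_timing = p("fddnp_timing.tsv"),
      blood = p("blood.tsv"),
      lesion_mask = if (lesion) p("lesion_mask.nii.gz") else NULL),
    parameters = list(extraction_fraction = spec$extraction_fraction,
                      syn_levels = c(8, 4, 2, 1), syn_max_iter = 250,
                      cc_radius = 4, theta_n = 100,
                      theta_lo = 0.00636, theta_hi = 1.0),
    output_dir = p("out"),
    seed = seed)
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(p("config.yaml"))
}

read_workflow_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  needed <- c("structural", "template", "atlas", "atlas_labels", "regions",
              "water_image", "water_timing", "fddnp_image", "fddnp_timing",
              "blood")
  for (nm in needed) {
    f <- config$paths[[nm]]
    if (is.null(f) || !file.exists(f)) stop("missing input file for '", nm, "'")
  }
  config
}

#' Run the full multimodal workflow
#'
#' Executes, in order: frame integration of both tracers (water 0-10 min,
#' FDDNP 0-6 min), rigid mutual-information co-registration of each summed
#' PET to the subject MR, symmetric diffeomorphic normalization between the
#' subject MR and the template (constrained cost-function masking when a
#' lesion mask is configured), atlas label propagation through the
#' concatenated transform into PET space, cerebellar reference TAC
#' extraction, delay/dispersion-corrected voxel-wise CBF mapping, SRTM
#' basis-function mapping, normalized maps (nCBF, R_P), per-region
#' statistics, gray/white ratio, and Bland-Altman agreement of the
#' relative-perfusion measures against normalized CBF.  All outputs are new
#' files under `output_dir`; inputs are never mutated; the run is
#' deterministic for a given config.
#'
#' @param config path to a workflow YAML or an equivalent list (see
#'   [make_phantom_bundle()]).
#' @param verbose print stage progress.
#' @return Invisibly, a list with region statistics per measure, the
#'   agreement results, transforms, and output paths.
#' @export
run_workflow <- function(config, verbose = FALSE) {
  cfg <- read_workflow_config(config)
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  op <- function(...) file.path(out_dir, ...)
  prm <- cfg$parameters %||% list()
  E <- prm$extraction_fraction %||% 0.85
  stage <- function(nm, expr) {
    if (verbose) message("[", nm, "]")
    tryCatch(expr, error = function(e)
      stop("workflow stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  log <- list(config = cfg, stages = list())

  mr <- stage("load", {
    list(structural = load_volume(cfg$paths$structural),
         template = load_volume(cfg$paths$template),
         atlas_img = load_volume(cfg$paths$atlas),
         atlas_tab = utils::read.delim(cfg$paths$atlas_labels),
         regions = load_region_set(cfg$paths$regions),
         water = load_dynamic_image(cfg$paths$water_image, cfg$paths$water_timing),
         fddnp = load_dynamic_image(cfg$paths$fddnp_image, cfg$paths$fddnp_timing),
         blood = load_blood_curve(cfg$paths$blood),
         lesion = if (!is.null(cfg$paths$lesion_mask))
           load_volume(cfg$paths$lesion_mask)$data else NULL)
  })
  geom <- mr$structural$geometry
  atlas <- label_volume(mr$atlas_img$data, mr$atlas_img$geometry, mr$atlas_tab)

  summed <- stage("integrate", list(
    water = integrate_frames(mr$water, 0, 10),
    fddnp = integrate_frames(mr$fddnp, 0, 6)))

  rigid <- stage("rigid", list(
    water = rigid_register(summed$water, mr$structural$data,
                           fixed_mask = mr$lesion),
    fddnp = rigid_register(summed$fddnp, mr$structural$data,
                           fixed_mask = mr$lesion)))

  syn <- stage("syn", syn_register(
    S = mr$structural$data, T = mr$template$data,
    levels = prm$syn_levels %||% c(8, 4, 2, 1),
    max_iter = prm$syn_max_iter %||% 250,
    radius = prm$cc_radius %||% 4,
    mask = mr$lesion))

  # atlas (template space) -> subject MR -> PET space, one resampling
  labels_pet <- stage("labels", {
    lp <- list(
      water = propagate_labels(atlas,
        list(syn$inverse, invert_transform(rigid$water)), mr$water$geometry),
      fddnp = propagate_labels(atlas,
        list(syn$inverse, invert_transform(rigid$fddnp)), mr$fddnp$geometry))
    save_volume(lp$water$data, geom, op("labels_water_space.nii.gz"))
    save_volume(lp$fddnp$data, geom, op("labels_fddnp_space.nii.gz"))
    lp
  })

  cgm_ids <- mr$regions$groups[["CGM"]]
  if (is.null(cgm_ids)) stop("region set must define a CGM group")

  water_maps <- stage("water_kinetics", {
    brain <- labels_pet$water$data > 0
    wb_tac <- region_tac(mr$water, labels_pet$water,
                         unique(as.integer(labels_pet$water$data[brain])))
    corr <- correct_delay_dispersion(mr$blood, wb_tac, mr$water$schedule)
    maps <- ridge_parametric_fit(mr$water, corr$corrected, brain)
    cbf <- flow_map(maps$K1, E)
    cgm_mask <- group_mask(labels_pet$water, cgm_ids)
    ncbf <- normalize_map(cbf, mean(cbf$data[cgm_mask & is.finite(cbf$data)]))
    save_volume(ifelse(is.finite(cbf$data), cbf$data, 0), geom, op("cbf.nii.gz"))
    save_volume(ifelse(is.finite(ncbf$data), ncbf$data, 0), geom, op("ncbf.nii.gz"))
    list(cbf = cbf, ncbf = ncbf, dd = corr$dd, K1 = maps$K1)
  })

  fddnp_maps <- stage("srtm", {
    cgm_mask <- group_mask(labels_pet$fddnp, cgm_ids)
    ref <- region_tac(mr$fddnp, labels_pet$fddnp, cgm_ids)
    brain <- labels_pet$fddnp$data > 0
    maps <- srtm_parametric_map(mr$fddnp, ref, brain,
                                thetas = theta_grid(prm$theta_n %||% 100,
                                                    prm$theta_lo %||% 0.00636,
                                                    prm$theta_hi %||% 1.0))
    rp <- early_sum_ratio(mr$fddnp, c(0, 6), cgm_mask)
    save_volume(ifelse(is.finite(maps$R_I$data), maps$R_I$data, 0), geom,
                op("r_i.nii.gz"))
    save_volume(rp$data, geom, op("r_p.nii.gz"))
    list(R_I = maps$R_I, BP = maps$BP, R_P = rp, ref = ref)
  })

  stats <- stage("regions", {
    st <- list(
      CBF = region_statistics(water_maps$cbf, labels_pet$water, mr$regions),
      nCBF = region_statistics(water_maps$ncbf, labels_pet$water, mr$regions),
      R_I = region_statistics(fddnp_maps$R_I, labels_pet$fddnp, mr$regions),
      R_P = region_statistics(fddnp_maps$R_P, labels_pet$fddnp, mr$regions))
    for (nm in names(st))
      save_region_stats(st[[nm]], op(paste0("region_stats_", nm, ".tsv")))
    st
  })

  agreement <- stage("agreement", {
    reg <- function(st) st$mean[st$region != "WBGM"]
    ncbf <- reg(stats$nCBF)
    ba_ri <- bland_altman(reg(stats$R_I), ncbf)
    ba_rp <- bland_altman(reg(stats$R_P), ncbf)
    tab <- data.frame(
      comparison = c("R_I_vs_nCBF", "R_P_vs_nCBF"),
      bias = c(ba_ri$bias, ba_rp$bias),
      sd_diff = c(ba_ri$sd_diff, ba_rp$sd_diff),
      loa_low = c(ba_ri$loa_low, ba_rp$loa_low),
      loa_high = c(ba_ri$loa_high, ba_rp$loa_high), n = c(ba_ri$n, ba_rp$n))
    utils::write.table(tab, op("agreement.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(R_I = ba_ri, R_P = ba_rp)
  })

  gw <- with(stats$CBF, mean[region == "WBGM"] / mean[region == "SWM"])

  log$stages <- list(
    rigid_water = list(angles_deg = rigid$water$angles_deg,
                       translation = rigid$water$translation),
    rigid_fddnp = list(angles_deg = rigid$fddnp$angles_deg,
                       translation = rigid$fddnp$translation),
    syn_score = syn$score,
    delay_dispersion = water_maps$dd,
    gray_white_ratio = gw)
  yaml::write_yaml(log$stages, op("workflow_log.yaml"))

  invisible(list(stats = stats, agreement = agreement,
                 gray_white_ratio = gw,
                 rigid = rigid, syn = syn, labels = labels_pet,
                 maps = list(CBF = water_maps$cbf, nCBF = water_maps$ncbf,
                             R_I = fddnp_maps$R_I, R_P = fddnp_maps$R_P),
                 dd = water_maps$dd, output_dir = out_dir))
}
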
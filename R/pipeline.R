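#' Run configuration for the full analysis
#'
#' Bundles every knob of the end-to-end pipeline: panel generation,
#' mixing-image specs, masticator constants, the in vitro grid, texture
#' model parameters and the output location. Real measurements can be
#' substituted for any synthetic block by passing the corresponding table
#' to [run_pipeline()] directly.
#'
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Output directory (NULL: return results only).
#' @param panel A [panel_spec()].
#' @param child_mix,adult_mix [mix_spec()] objects for the two groups.
#' @param invitro_mix [mix_spec()] for masticator boli.
#' @param masticator A [masticator_config()].
#' @param compressions,speeds In vitro grid definition.
#' @param image_replicates In vitro images per operating point.
#' @param invivo_rotation_speed Nominal in vivo shear level.
#' @param hardness_base,hardness_decay,hardness_rpm_slope Parameters of
#'   [bolus_hardness_model()].
#' @param hardness_noise_sd Instrument noise SD (N) on force curves.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       panel = panel_spec(),
                       child_mix = default_mix_spec("child"),
                       adult_mix = default_mix_spec("adult"),
                       invitro_mix = mix_spec(),
                       masticator = masticator_config(),
                       compressions = c(1, 2, 6, 8, 10, 14, 18),
                       speeds = c(4, 15),
                       image_replicates = 2L,
                       invivo_rotation_speed = 8,
                       hardness_base = 130, hardness_decay = 0.11,
                       hardness_rpm_slope = 0.01,
                       hardness_noise_sd = 0.5) {
  if (!length(compressions) || !length(speeds))
    stop("configuration error: the in vitro grid must be nonempty", call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir, panel = panel,
                 child_mix = child_mix, adult_mix = adult_mix,
                 invitro_mix = invitro_mix, masticator = masticator,
                 compressions = compressions, speeds = speeds,
                 image_replicates = as.integer(image_replicates),
                 invivo_rotation_speed = invivo_rotation_speed,
                 hardness_base = hardness_base, hardness_decay = hardness_decay,
                 hardness_rpm_slope = hardness_rpm_slope,
                 hardness_noise_sd = hardness_noise_sd),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Scalar fields of [run_config()] (seed, grid, model parameters,
#' masticator constants, image size) can be overridden from a config
#' file; unknown keys are rejected.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "out_dir", "compressions", "speeds", "image_replicates",
             "invivo_rotation_speed", "hardness_base", "hardness_decay",
             "hardness_rpm_slope", "hardness_noise_sd", "image_size",
             "container_volume", "n_pieces", "piece_mass")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("configuration error: unknown keys ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- raw[intersect(names(raw), c(
    "seed", "out_dir", "compressions", "speeds", "image_replicates",
    "invivo_rotation_speed", "hardness_base", "hardness_decay",
    "hardness_rpm_slope", "hardness_noise_sd"))]
  cfg <- do.call(run_config, args)
  if (!is.null(raw$container_volume) || !is.null(raw$n_pieces) ||
      !is.null(raw$piece_mass)) {
    m <- masticator_config()
    for (f in c("container_volume", "n_pieces", "piece_mass"))
      if (!is.null(raw[[f]])) m[[f]] <- raw[[f]]
    cfg$masticator <- m
  }
  if (!is.null(raw$image_size)) {
    for (f in c("child_mix", "adult_mix", "invitro_mix"))
      cfg[[f]]$size <- as.integer(raw$image_size)
  }
  cfg
}

aggregate_scores <- function(scores, by) {
  stats::aggregate(scores["value"], by = scores[by], mean)
}

#' Run the full in vivo / in vitro comparison pipeline
#'
#' End to end: generate (or accept) a panel, derive the masticatory
#' parameters and summarize them; transpose to the masticator (cheese
#' mass, saliva schedule, operating grid); generate and score the in vivo
#' and in vitro bolus images (red-channel variance) and force curves
#' (hardness); run the mixed three-way ANOVA on the in vivo measurements;
#' match every group x stage x metric to its nearest in vitro setting and
#' recommend one setting per group. Deterministic given the seed: two
#' runs with the same configuration write byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return List: `panel_summary`, `transposition` (fixed + grid),
#'   `invivo_measurements`, `invitro_measurements`, `anova_image`,
#'   `anova_texture`, `matches`, `recommendation`, `manifest`. When
#'   `config$out_dir` is set, each table is also written as CSV together
#'   with `manifest.json` and a Markdown report.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- panel and transposition -------------------------------------------
  panel <- generate_panel(config$panel, seed = seed)
  panel <- derive_params(panel)
  panel_summary <- summarize_panel(panel)
  transposition <- transpose_parameters(panel_summary, config$masticator,
                                        config$compressions, config$speeds)
  grid <- transposition$grid

  # --- imaging ------------------------------------------------------------
  vivo_images <- generate_invivo_image_set(
    panel, config$child_mix, config$adult_mix,
    n_replicates = config$image_replicates,
    rotation_speed = config$invivo_rotation_speed, seed = seed + 1L)
  vivo_img_scores <- score_images(vivo_images)

  vitro_images <- with_rng_seed(seed + 2L, {
    imgs <- list()
    for (i in seq_len(nrow(grid)))
      for (rep in seq_len(config$image_replicates))
        imgs[[length(imgs) + 1L]] <- generate_bolus_image(
          config$invitro_mix, n_compressions = grid$n_compressions[i],
          rotation_speed = grid$rotation_speed[i], replicate = rep)
    imgs
  })
  vitro_img_scores <- score_images(vitro_images)

  # --- texture ------------------------------------------------------------
  subj <- stats::aggregate(panel["n_compressions"],
                           by = list(id = panel$id, group = panel$group), mean)
  hard_target <- function(n, rpm)
    bolus_hardness_model(n, rpm, config$hardness_base, config$hardness_decay,
                         config$hardness_rpm_slope)
  vivo_curves <- with_rng_seed(seed + 3L, {
    cvs <- list()
    for (i in seq_len(nrow(subj)))
      for (st in c(33, 66, 99))
        for (rep in seq_len(config$image_replicates)) {
          eff <- max(0, round(st / 100 * subj$n_compressions[i]))
          cvs[[length(cvs) + 1L]] <- generate_force_curve(
            hard_target(eff, config$invivo_rotation_speed),
            mode = "back_extrusion", noise_sd = config$hardness_noise_sd,
            origin = list(type = "in_vivo", subject = subj$id[i],
                          group = subj$group[i], stage = st),
            replicate = rep)
        }
    cvs
  })
  vivo_tex_scores <- score_texture(vivo_curves)

  vitro_curves <- with_rng_seed(seed + 4L, {
    cvs <- list()
    for (i in seq_len(nrow(grid)))
      for (rep in seq_len(config$image_replicates))
        cvs[[length(cvs) + 1L]] <- generate_force_curve(
          hard_target(grid$n_compressions[i], grid$rotation_speed[i]),
          mode = "back_extrusion", noise_sd = config$hardness_noise_sd,
          origin = list(type = "in_vitro",
                        n_compressions = grid$n_compressions[i],
                        rotation_speed = grid$rotation_speed[i]),
          replicate = rep)
    cvs
  })
  vitro_tex_scores <- score_texture(vitro_curves)

  # --- stage summaries and inference --------------------------------------
  iv_img <- vivo_img_scores; iv_img$value <- iv_img$variance
  iv_tex <- vivo_tex_scores; iv_tex$value <- iv_tex$hardness
  invivo <- rbind(
    cbind(aggregate_scores(iv_img, c("group", "stage")), metric = "red_variance"),
    cbind(aggregate_scores(iv_tex, c("group", "stage")), metric = "hardness"))

  vt_img <- vitro_img_scores; vt_img$value <- vt_img$variance
  vt_tex <- vitro_tex_scores; vt_tex$value <- vt_tex$hardness
  invitro <- rbind(
    cbind(aggregate_scores(vt_img, c("n_compressions", "rotation_speed")),
          metric = "red_variance"),
    cbind(aggregate_scores(vt_tex, c("n_compressions", "rotation_speed")),
          metric = "hardness"))

  anova_image <- mixed_anova(vivo_img_scores$variance, vivo_img_scores$subject,
                             vivo_img_scores[c("group", "stage")])
  anova_texture <- mixed_anova(vivo_tex_scores$hardness,
                               vivo_tex_scores$subject,
                               vivo_tex_scores[c("group", "stage")])

  matched <- match_all(invivo, invitro)

  manifest <- list(
    seed = seed,
    panel = list(group_sizes = as.list(config$panel$group_sizes),
                 n_replicates = config$panel$n_replicates),
    image_size = config$invitro_mix$size,
    grid = list(compressions = config$compressions, speeds = config$speeds),
    n_invivo_images = length(vivo_images),
    n_invitro_images = length(vitro_images),
    outputs = character(0))

  results <- list(panel_summary = panel_summary,
                  transposition = transposition,
                  invivo_measurements = invivo,
                  invitro_measurements = invitro,
                  anova_image = anova_image,
                  anova_texture = anova_texture,
                  matches = matched$matches,
                  recommendation = matched$recommendation,
                  manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- list(panel_summary = panel_summary,
                   transposition_fixed = transposition$fixed,
                   transposition_grid = as.data.frame(transposition$grid),
                   invivo_measurements = invivo,
                   invitro_measurements = invitro,
                   anova_image = anova_image,
                   anova_texture = anova_texture,
                   matches = matched$matches,
                   recommendation = matched$recommendation)
    for (nm in names(tables)) {
      f <- file.path(config$out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], f, row.names = FALSE)
      manifest$outputs <- c(manifest$outputs, basename(f))
    }
    report <- c("# In vivo / in vitro mastication comparison", "",
                "## Stage matches", "", format_match_table(matched$matches), "",
                "## Recommended masticator settings", "",
                sprintf("- %s: %d compressions - %g rpm",
                        matched$recommendation$group,
                        matched$recommendation$n_compressions,
                        matched$recommendation$rotation_speed))
    writeLines(report, file.path(config$out_dir, "report.md"))
    manifest$outputs <- c(manifest$outputs, "report.md")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results$manifest <- manifest
  }
  results
}
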
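# All generators take an explicit `seed`; RNG state of the caller is
# restored afterwards so generators compose without side effects.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# moments of a normal(mu, sigma) truncated to (0, Inf)
trunc_moments <- function(mu, sigma) {
  a <- -mu / sigma
  lam <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# underlying normal parameters such that the zero-truncated law has the
# requested mean and sd (so generating targets are honoured exactly in
# distribution despite the truncation)
solve_trunc_params <- function(mean, sd) {
  if (sd == 0 || mean / sd > 6) return(c(mu = mean, sigma = sd))
  obj <- function(p) {
    mm <- trunc_moments(p[1], exp(p[2]))
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# truncated-at-lower normal by rejection; sd = 0 degenerates to the mean.
# mean/sd are the moments of the truncated distribution itself.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  p <- solve_trunc_params(mean, sd)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), p[["mu"]], p[["sigma"]])
    ok <- draw > lower
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Panel generating specification
#'
#' Per-group generating means and SDs for the five measured masticatory
#' parameters. Defaults are the reference panel values (see
#' [reference_panel_parameters()]): 30 children and 30 adults measured in
#' triplicate. Subjects are drawn from truncated-at-zero normals;
#' replicate measurements add small within-subject noise
#' (`rep_noise_frac` of the group SD).
#'
#' @param parameters Data.frame `group`, `variable`, `mean`, `sd`
#'   covering `mouth_volume`, `quantity_consumed`, `mastication_time`,
#'   `n_compressions`, `saliva_volume` for each group.
#' @param group_sizes Named integer vector of subjects per group.
#' @param n_replicates Replicate measurements per subject (default 3).
#' @param rep_noise_frac Within-subject replicate noise as a fraction of
#'   the group SD.
#' @param cheese Cheese [composition()] used to back out a bolus
#'   composition consistent with each drawn saliva volume.
#' @param consumed_mass Cheese piece mass in g.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(parameters = reference_panel_parameters(),
                       group_sizes = c(child = 30L, adult = 30L),
                       n_replicates = 3L, rep_noise_frac = 0.05,
                       cheese = reference_cheese_composition(),
                       consumed_mass = 4.5) {
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  if (any(parameters$sd < 0)) stop("generating SDs must be >= 0", call. = FALSE)
  need <- c("mouth_volume", "quantity_consumed", "mastication_time",
            "n_compressions", "saliva_volume")
  for (g in names(group_sizes)) {
    have <- parameters$variable[parameters$group == g]
    if (!all(need %in% have))
      stop("parameters incomplete for group ", g, call. = FALSE)
  }
  structure(list(parameters = parameters, group_sizes = group_sizes,
                 n_replicates = as.integer(n_replicates),
                 rep_noise_frac = rep_noise_frac, cheese = cheese,
                 consumed_mass = consumed_mass),
            class = "panel_spec")
}

# bolus DM/WC consistent with a saliva volume: invert the moisture balance
bolus_from_saliva <- function(volume, cheese, consumed_mass) {
  content <- volume / consumed_mass * 100
  r <- (content + cheese$water_content) / cheese$dry_matter  # bolus WC/DM
  wc <- 100 * r / (1 + r)
  list(dry_matter = 100 - wc, water_content = wc)
}

#' Generate a synthetic masticatory panel
#'
#' Draws per-subject parameters from truncated-at-zero normal
#' distributions (spec means/SDs), rounds compression counts to integers
#' with a floor of 1, and emits replicate rows with small within-subject
#' noise. Bolus compositions are constructed so that the moisture-balance
#' saliva computation ([saliva_content()]) recovers each replicate's
#' drawn saliva volume.
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed; generation is bit-reproducible under a fixed
#'   seed.
#' @return Data.frame, one row per subject per replicate, with the
#'   columns expected by [derive_params()].
#' @export
generate_panel <- function(spec = panel_spec(), seed = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  with_rng_seed(seed, {
    rows <- list()
    for (g in names(spec$group_sizes)) {
      n <- spec$group_sizes[[g]]
      par <- spec$parameters[spec$parameters$group == g, ]
      gp <- function(v, fld) par[[fld]][par$variable == v]
      subj <- list()
      for (v in c("mouth_volume", "quantity_consumed", "mastication_time",
                  "n_compressions", "saliva_volume"))
        subj[[v]] <- rtrunc_norm(n, gp(v, "mean"), gp(v, "sd"))
      for (i in seq_len(n)) {
        for (rep in seq_len(spec$n_replicates)) {
          noise <- function(v)
            max(subj[[v]][i] + stats::rnorm(1, 0, spec$rep_noise_frac * gp(v, "sd")),
                1e-3)
          sv <- noise("saliva_volume")
          bol <- bolus_from_saliva(sv, spec$cheese, spec$consumed_mass)
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("%s_%02d", g, i), group = g, replicate = rep,
            mouth_volume = noise("mouth_volume"),
            quantity_consumed = noise("quantity_consumed"),
            mastication_time = noise("mastication_time"),
            n_compressions = max(1L, as.integer(round(noise("n_compressions")))),
            bolus_dry_matter = bol$dry_matter,
            bolus_water_content = bol$water_content,
            cheese_dry_matter = spec$cheese$dry_matter,
            cheese_water_content = spec$cheese$water_content,
            consumed_mass = spec$consumed_mass,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Two-phase mixing image specification
#'
#' Forward model of a surface-coloured bolus photographed on a green
#' backdrop: a disk (the flattened bolus in its dish) in which the
#' coloured surface phase, of total area fraction `colored_fraction`,
#' lies in `n_folds` angular streaks over the uncoloured interior --- the
#' trace the folded, coloured surface leaves through the mass. Each
#' tongue--palate compression applies one fold step: a differential
#' in-plane rotation proportional to the rotation speed, which twists the
#' streaks into spirals and stretches the phase interface, followed by a
#' Gaussian blur of scale `sigma_c`, which diffuses across it. This
#' stretch-and-diffuse pair is the simplest operator combination whose
#' two-phase variance decreases with both the compression count and the
#' rotation speed. (A rotationally symmetric annulus would be invariant
#' under azimuthal shear, which is why the phase must carry angular
#' structure.)
#'
#' @param size Image side in pixels (square frame).
#' @param colored_fraction Area fraction f of the coloured phase, in
#'   (0, 1).
#' @param n_folds Number of angular streaks carrying the coloured phase.
#' @param colored_rgb,base_rgb,background_rgb RGB triples in `[0, 1]` for
#'   the coloured phase, the uncoloured core and the backdrop.
#' @param sigma_c Blur scale per compression, in pixels (> 0).
#' @param shear_rate Differential rotation per compression per rpm
#'   (radians at the disk centre).
#' @param noise_sd Additive Gaussian pixel noise SD (>= 0).
#' @return A list of class `mix_spec`.
#' @export
mix_spec <- function(size = 64L, colored_fraction = 0.4, n_folds = 4L,
                     colored_rgb = c(0.55, 0.20, 0.45),
                     base_rgb = c(0.95, 0.93, 0.90),
                     background_rgb = c(0.20, 0.70, 0.25),
                     sigma_c = 1.4, shear_rate = 0.012, noise_sd = 0.02) {
  if (colored_fraction <= 0 || colored_fraction >= 1)
    stop("colored_fraction must lie in (0, 1)", call. = FALSE)
  if (sigma_c <= 0) stop("sigma_c must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  for (col in list(colored_rgb, base_rgb, background_rgb))
    if (length(col) != 3L || any(col < 0) || any(col > 1))
      stop("colours must be RGB triples in [0, 1]", call. = FALSE)
  if (n_folds < 1L) stop("n_folds must be >= 1", call. = FALSE)
  structure(list(size = as.integer(size), colored_fraction = colored_fraction,
                 n_folds = as.integer(n_folds),
                 colored_rgb = colored_rgb, base_rgb = base_rgb,
                 background_rgb = background_rgb, sigma_c = sigma_c,
                 shear_rate = shear_rate, noise_sd = noise_sd),
            class = "mix_spec")
}

#' Default mixing specs per group
#'
#' Children destructure the cheese less efficiently per compression than
#' adults (weaker tongue--palate force, fewer teeth), modelled as a
#' smaller per-compression blur scale.
#'
#' @param group `"child"` or `"adult"`.
#' @param ... Overrides passed to [mix_spec()].
#' @return A [mix_spec()].
#' @export
default_mix_spec <- function(group = c("child", "adult"), ...) {
  group <- match.arg(group)
  args <- list(...)
  if (is.null(args$sigma_c))
    args$sigma_c <- if (group == "child") 1.2 else 1.6
  do.call(mix_spec, args)
}

#' Generate one synthetic bolus image
#'
#' Builds the initial two-phase disk, applies `n_compressions` fold steps
#' (shear rotation scaled by `rotation_speed`, then Gaussian blur), adds
#' pixel noise, clips to `[0, 1]` and composites the green backdrop
#' outside the disk. With zero compressions and zero noise the
#' red-channel ROI variance equals the closed two-point form
#' `f (1 - f) (r1 - r0)^2`, where `f` is the realized coloured pixel
#' fraction (attached as attribute `colored_fraction`) and `r1`, `r0` the
#' red levels of the two phases.
#'
#' @param spec A [mix_spec()].
#' @param n_compressions Number of fold steps (>= 0).
#' @param rotation_speed Rotation speed in rpm (>= 0).
#' @param origin,replicate Provenance, as in [bolus_image()]; defaults to
#'   an in vitro origin at this operating point.
#' @param seed Optional integer seed.
#' @return A [bolus_image()] whose `roi` is the bolus disk; attribute
#'   `colored_fraction` holds the realized coloured-phase pixel share.
#' @export
generate_bolus_image <- function(spec = mix_spec(), n_compressions,
                                 rotation_speed = 4, origin = NULL,
                                 replicate = 1L, seed = NULL) {
  stopifnot(inherits(spec, "mix_spec"))
  if (n_compressions < 0) stop("n_compressions must be >= 0", call. = FALSE)
  with_rng_seed(seed, {
    s <- spec$size
    ctr <- (s + 1) / 2
    xs <- matrix(rep(seq_len(s), each = s), s, s)   # columns
    ys <- matrix(rep(seq_len(s), times = s), s, s)  # rows
    rr <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
    R <- 0.42 * s
    disk <- rr <= R
    # coloured phase: n_folds angular streaks of total area fraction f; the
    # pattern continues past the disk edge so the blur sees no rim seam
    ang0 <- atan2(ys - ctr, xs - ctr)
    streak <- ((ang0 / (2 * pi) + 0.5) * spec$n_folds) %% 1 <
      spec$colored_fraction
    colored <- disk & streak

    fields <- lapply(1:3, function(k) {
      f <- matrix(spec$base_rgb[k], s, s)
      f[streak] <- spec$colored_rgb[k]
      f
    })

    if (n_compressions >= 1) {
      # precompute the per-step shear remap: bilinear source weights for each
      # disk pixel (bilinear sampling avoids aliasing, so shear is purely a
      # stretch of the phase interface)
      theta <- spec$shear_rate * rotation_speed * (1 - rr / R)
      ang <- atan2(ys - ctr, xs - ctr)
      didx <- which(disk)
      sxf <- pmin(pmax(ctr + rr * cos(ang - theta), 1), s)[didx]
      syf <- pmin(pmax(ctr + rr * sin(ang - theta), 1), s)[didx]
      x0 <- pmin(floor(sxf), s - 1L); y0 <- pmin(floor(syf), s - 1L)
      wx <- sxf - x0; wy <- syf - y0
      i00 <- (x0 - 1L) * s + y0
      i01 <- i00 + 1L
      i10 <- i00 + s
      i11 <- i10 + 1L
      w00 <- (1 - wx) * (1 - wy); w01 <- (1 - wx) * wy
      w10 <- wx * (1 - wy); w11 <- wx * wy
      for (step in seq_len(n_compressions)) {
        fields <- lapply(fields, function(f) {
          f[didx] <- w00 * f[i00] + w01 * f[i01] + w10 * f[i10] + w11 * f[i11]
          EBImage::gblur(f, sigma = spec$sigma_c)
        })
      }
    }

    pixels <- array(0, c(s, s, 3))
    for (k in 1:3) {
      f <- fields[[k]]
      f[!disk] <- spec$background_rgb[k]
      if (spec$noise_sd > 0) f <- f + stats::rnorm(s * s, 0, spec$noise_sd)
      pixels[, , k] <- pmin(pmax(f, 0), 1)
    }
    if (is.null(origin))
      origin <- list(type = "in_vitro", n_compressions = n_compressions,
                     rotation_speed = rotation_speed)
    img <- bolus_image(pixels, roi = disk, origin = origin,
                       replicate = replicate)
    attr(img, "colored_fraction") <- sum(colored) / sum(disk)
    img
  })
}

#' Generate the in vivo bolus image set
#'
#' One image per subject x stage x replicate. Each subject's effective
#' number of fold steps at a stage is `round(stage/100 x n_compressions)`
#' (compressions are assumed to accumulate roughly uniformly over the
#' mastication time), floored at 0; child and adult images use their own
#' mixing specs. With the default 60-subject panel, 3 stages and
#' duplicates this yields 360 images.
#'
#' @param panel Panel data.frame from [generate_panel()] (replicate rows
#'   are averaged per subject to get the compression count).
#' @param child_mix,adult_mix [mix_spec()] objects per group.
#' @param stages Mastication stages in percent.
#' @param n_replicates Images per subject per stage (default 2).
#' @param rotation_speed Nominal in vivo shear level (rpm-equivalent)
#'   applied to every subject.
#' @param seed Optional integer seed.
#' @return List of [bolus_image()] objects with in vivo origins.
#' @export
generate_invivo_image_set <- function(panel,
                                      child_mix = default_mix_spec("child"),
                                      adult_mix = default_mix_spec("adult"),
                                      stages = c(33, 66, 99),
                                      n_replicates = 2L, rotation_speed = 8,
                                      seed = NULL) {
  subj <- stats::aggregate(panel["n_compressions"],
                           by = list(id = panel$id, group = panel$group), mean)
  with_rng_seed(seed, {
    images <- list()
    for (i in seq_len(nrow(subj))) {
      grp <- subj$group[i]
      spec <- if (grp == "child") child_mix else adult_mix
      for (st in stages) {
        eff <- max(0L, as.integer(round(st / 100 * subj$n_compressions[i])))
        for (rep in seq_len(n_replicates)) {
          images[[length(images) + 1L]] <- generate_bolus_image(
            spec, n_compressions = eff, rotation_speed = rotation_speed,
            origin = list(type = "in_vivo", subject = subj$id[i], group = grp,
                          stage = st),
            replicate = rep)
        }
      }
    }
    images
  })
}

#' In vitro bolus hardness forward model
#'
#' Deterministic mean hardness at a masticator operating point: an
#' exponential softening in both the compression count and the rotation
#' speed, `base * exp(-decay * n - rpm_slope * rpm)`. Hardness decreases
#' with compressions and is lower at higher rotation speed, mirroring how
#' saliva incorporation and destructuring soften the bolus.
#'
#' @param n_compressions Compression count (>= 0).
#' @param rotation_speed Rotation speed in rpm (>= 0).
#' @param base Initial back-extrusion hardness scale (N).
#' @param decay Softening rate per compression.
#' @param rpm_slope Softening rate per rpm.
#' @return Hardness in newtons.
#' @export
bolus_hardness_model <- function(n_compressions, rotation_speed,
                                 base = 130, decay = 0.11, rpm_slope = 0.01) {
  base * exp(-decay * n_compressions - rpm_slope * rotation_speed)
}

#' Generate a synthetic force--displacement curve
#'
#' Saturating-ramp profile ending exactly at `true_hardness` before noise:
#' `F(d) = H (1 - exp(-5 d / D)) / (1 - exp(-5))` over the travel `D`,
#' plus i.i.d. Gaussian noise on every sample. With zero noise,
#' [extract_hardness()] inverts the generator exactly.
#'
#' @param true_hardness Target final charge in N (>= 0).
#' @param mode `"penetration"` (7 mm travel) or `"back_extrusion"`
#'   (10 mm travel).
#' @param noise_sd Noise SD in N.
#' @param seed Optional integer seed.
#' @param n_samples Number of displacement samples.
#' @param origin,replicate Provenance metadata.
#' @return A [force_curve()].
#' @export
generate_force_curve <- function(true_hardness,
                                 mode = c("penetration", "back_extrusion"),
                                 noise_sd = 0, seed = NULL, n_samples = 100L,
                                 origin = NULL, replicate = 1L) {
  mode <- match.arg(mode)
  if (true_hardness < 0) stop("true_hardness must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_rng_seed(seed, {
    D <- if (mode == "penetration") 7 else 10
    d <- seq(0, D, length.out = n_samples)
    f <- true_hardness * (1 - exp(-5 * d / D)) / (1 - exp(-5))
    if (noise_sd > 0) f <- f + stats::rnorm(n_samples, 0, noise_sd)
    force_curve(d, f, mode = mode, origin = origin, replicate = replicate)
  })
}

#' Simulate one triangle-test session
#'
#' Each panelist is a discriminator with probability `p_discriminator`;
#' discriminators always answer correctly, the rest guess with success
#' probability 1/3, so each panelist is correct with probability
#' `p + (1 - p)/3`.
#'
#' @param n_panelists Panel size (>= 0).
#' @param p_discriminator Discriminator proportion in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Number of correct answers.
#' @export
generate_triangle_session <- function(n_panelists, p_discriminator = 0,
                                      seed = NULL) {
  if (p_discriminator < 0 || p_discriminator > 1)
    stop("p_discriminator must lie in [0, 1]", call. = FALSE)
  if (n_panelists == 0) return(0L)
  with_rng_seed(seed, {
    p <- p_discriminator + (1 - p_discriminator) / 3
    stats::rbinom(1L, n_panelists, p)
  })
}
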
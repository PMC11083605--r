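#' Dry-matter / water-content composition measure
#'
#' @param dry_matter,water_content Percentages of mass; must sum to 100
#'   within `tol`.
#' @param tol Closure tolerance in percentage points.
#' @return A list of class `composition`.
#' @export
composition <- function(dry_matter, water_content, tol = 0.5) {
  if (dry_matter < 0 || dry_matter > 100 || water_content < 0 || water_content > 100)
    stop("composition percentages must lie in [0, 100]", call. = FALSE)
  if (abs(dry_matter + water_content - 100) > tol)
    stop("dry matter and water content must sum to 100%", call. = FALSE)
  structure(list(dry_matter = dry_matter, water_content = water_content),
            class = "composition")
}

#' Chewing frequency
#'
#' Number of tongue--palate compressions per second of mastication.
#'
#' @param n_compressions Compression count (>= 0).
#' @param mastication_time Mastication time in seconds (> 0).
#' @return Frequency in compressions per second.
#' @examples
#' chewing_frequency(10, 5)  # 2
#' @export
chewing_frequency <- function(n_compressions, mastication_time) {
  if (any(mastication_time <= 0))
    stop("mastication_time must be positive", call. = FALSE)
  n_compressions / mastication_time
}

#' Saliva content of a bolus from moisture balance
#'
#' The saliva share of the bolus mass is inferred from the bolus and
#' cheese water/dry-matter fractions:
#' `(bolus WC / bolus DM) * cheese DM - cheese WC` (all in percent). The
#' identity assumes the dry matter of the bolus is all cheese dry matter,
#' so added water must be saliva. Slightly negative results (bolus drier
#' than the cheese, possible through evaporation or weighing error) are
#' clamped to zero with a warning, as a physical volume cannot be negative.
#'
#' @param bolus,cheese [composition()] objects (percent DM / WC).
#' @return Saliva content in percent of bolus mass.
#' @export
saliva_content <- function(bolus, cheese) {
  stopifnot(inherits(bolus, "composition"), inherits(cheese, "composition"))
  if (bolus$dry_matter <= 0)
    stop("bolus dry matter must be positive", call. = FALSE)
  sc <- (bolus$water_content / bolus$dry_matter) * cheese$dry_matter -
    cheese$water_content
  if (sc < 0) {
    warning("negative saliva content clamped to 0 (bolus drier than cheese)",
            call. = FALSE)
    sc <- 0
  }
  sc
}

#' Saliva volume from saliva content
#'
#' `saliva content x 10^-2 x consumed mass`; grams of saliva are
#' assimilated to millilitres since saliva is more than 99 percent water.
#' The default consumed mass of 4.5 g is the standard cheese piece served
#' to every panelist.
#'
#' @param content Saliva content in percent (>= 0).
#' @param consumed_mass Mass of cheese consumed, in grams.
#' @return Saliva volume in mL.
#' @export
saliva_volume <- function(content, consumed_mass = 4.5) {
  if (any(content < 0)) stop("saliva content must be nonnegative", call. = FALSE)
  content * 1e-2 * consumed_mass
}

#' Bolus-collection stage times
#'
#' Boli are sampled at 33 percent (early mastication), 66 percent (late
#' mastication) and 99 percent (moment of swallowing) of each subject's
#' own mastication time.
#'
#' @param mastication_time Total mastication time in seconds (> 0).
#' @return Named numeric vector of the three collection times (s).
#' @examples
#' stage_times(10)  # 3.3 6.6 9.9
#' @export
stage_times <- function(mastication_time) {
  if (any(mastication_time <= 0))
    stop("mastication_time must be positive", call. = FALSE)
  c(`33` = 0.33, `66` = 0.66, `99` = 0.99) * mastication_time
}

#' Derive per-subject masticatory parameters
#'
#' Appends the derived quantities to a panel table: chewing frequency,
#' saliva content (from bolus vs cheese composition), saliva volume and
#' rate, and the three transposition ratios (mouth volume / quantity
#' consumed, saliva volume / mouth volume, saliva volume / quantity
#' consumed).
#'
#' @param panel Data.frame with columns `id`, `group`, `mouth_volume`
#'   (mL), `quantity_consumed` (g), `mastication_time` (s),
#'   `n_compressions`, `bolus_dry_matter`, `bolus_water_content`,
#'   `cheese_dry_matter`, `cheese_water_content` (percent) and optionally
#'   `consumed_mass` (g, default 4.5).
#' @return The panel with derived columns `chewing_frequency`,
#'   `saliva_content`, `saliva_volume`, `saliva_rate`,
#'   `ratio_mouth_per_quantity`, `ratio_saliva_per_mouth`,
#'   `ratio_saliva_per_quantity`.
#' @export
derive_params <- function(panel) {
  need <- c("mouth_volume", "quantity_consumed", "mastication_time",
            "n_compressions", "bolus_dry_matter", "bolus_water_content",
            "cheese_dry_matter", "cheese_water_content")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(panel$mouth_volume <= 0) || any(panel$quantity_consumed <= 0) ||
      any(panel$mastication_time <= 0) || any(panel$n_compressions < 1))
    stop("mouth_volume, quantity_consumed, mastication_time must be positive and n_compressions >= 1",
         call. = FALSE)
  mass <- if ("consumed_mass" %in% names(panel)) panel$consumed_mass else 4.5
  sc <- mapply(function(bd, bw, cd, cw)
    saliva_content(composition(bd, bw), composition(cd, cw)),
    panel$bolus_dry_matter, panel$bolus_water_content,
    panel$cheese_dry_matter, panel$cheese_water_content)
  panel$chewing_frequency <- chewing_frequency(panel$n_compressions,
                                               panel$mastication_time)
  panel$saliva_content <- sc
  panel$saliva_volume <- saliva_volume(sc, mass)
  panel$saliva_rate <- panel$saliva_volume / panel$mastication_time
  panel$ratio_mouth_per_quantity <- panel$mouth_volume / panel$quantity_consumed
  panel$ratio_saliva_per_mouth <- panel$saliva_volume / panel$mouth_volume
  panel$ratio_saliva_per_quantity <- panel$saliva_volume / panel$quantity_consumed
  panel
}

panel_summary_vars <- c(
  "mouth_volume", "quantity_consumed", "ratio_mouth_per_quantity",
  "mastication_time", "n_compressions", "chewing_frequency",
  "saliva_volume", "saliva_rate", "ratio_saliva_per_mouth",
  "ratio_saliva_per_quantity")

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize a panel: per-group mean and population SD
#'
#' Replicate rows (triplicate measurements) are first averaged per
#' subject, then each masticatory variable is summarized per group as the
#' mean and the population ("Pearson") standard deviation (divide by N).
#' A pooled `overall` row across all subjects is included; with equal
#' group sizes its mean equals the mean of group means and it is the value
#' fed to the masticator transposition.
#'
#' @param panel Output of [derive_params()] (one row per subject per
#'   replicate; a `replicate` column is optional).
#' @param variables Variables to summarize (defaults to the standard
#'   masticatory parameter set present in the panel).
#' @return Long data.frame: `variable`, `group`, `n`, `mean`, `sd`.
#' @export
summarize_panel <- function(panel, variables = NULL) {
  if (is.null(variables))
    variables <- intersect(panel_summary_vars, names(panel))
  if (!"group" %in% names(panel) || !"id" %in% names(panel))
    stop("panel needs 'id' and 'group' columns", call. = FALSE)
  if (any(table(factor(panel$group)) == 0) || nrow(panel) == 0)
    stop("every group must contain at least one record", call. = FALSE)
  # average replicates per subject
  agg <- stats::aggregate(panel[variables],
                          by = list(id = panel$id, group = panel$group), mean)
  out <- do.call(rbind, lapply(variables, function(v) {
    per_group <- do.call(rbind, lapply(split(agg[[v]], agg$group), function(x)
      data.frame(n = length(x), mean = mean(x), sd = pop_sd(x))))
    per_group$group <- rownames(per_group)
    overall <- data.frame(n = nrow(agg), mean = mean(agg[[v]]),
                          sd = pop_sd(agg[[v]]), group = "overall")
    res <- rbind(per_group, overall)
    res$variable <- v
    res[, c("variable", "group", "n", "mean", "sd")]
  }))
  rownames(out) <- NULL
  out
}
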
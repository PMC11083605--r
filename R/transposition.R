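#' Masticator configuration constants
#'
#' Operating constants of the chewing simulator: a fixed-volume sample
#' container standing in for the mouth, a plunger-mounted artificial
#' palate over a sintered artificial tongue, loaded with cheese pieces and
#' artificial saliva and held at in-mouth temperature.
#'
#' @param container_volume Container ("mouth") volume in mL.
#' @param temperature Set temperature in deg C (metadata).
#' @param n_pieces Number of cheese pieces loaded.
#' @param piece_mass Mass of one piece in g.
#' @param palate_surface Artificial palate surface in cm^2 (metadata).
#' @return A list of class `masticator_config`.
#' @export
masticator_config <- function(container_volume = 375.00, temperature = 36,
                              n_pieces = 7L, piece_mass = 4.5,
                              palate_surface = 63.62) {
  if (container_volume <= 0) stop("container_volume must be positive", call. = FALSE)
  if (n_pieces < 1) stop("n_pieces must be at least 1", call. = FALSE)
  structure(list(container_volume = container_volume, temperature = temperature,
                 n_pieces = as.integer(n_pieces), piece_mass = piece_mass,
                 palate_surface = palate_surface),
            class = "masticator_config")
}

#' Cheese mass to load from the mouth-volume ratio
#'
#' The in vitro cheese quantity preserves the in vivo ratio of mouth
#' volume to quantity consumed: `container_volume / ratio`, reported to 2
#' decimals. With the 375 mL container and the pooled-panel ratio of
#' 11.47 mL/g this gives 32.69 g.
#'
#' @param config A [masticator_config()].
#' @param ratio_mouth_per_quantity Pooled mouth volume / quantity consumed
#'   ratio (mL/g, > 0).
#' @return Cheese mass in grams (2 decimals).
#' @export
in_vitro_cheese_mass <- function(config = masticator_config(),
                                 ratio_mouth_per_quantity) {
  if (ratio_mouth_per_quantity <= 0)
    stop("ratio_mouth_per_quantity must be positive", call. = FALSE)
  round(config$container_volume / ratio_mouth_per_quantity, 2)
}

#' Artificial saliva volume for a compression count
#'
#' Saliva secretion is taken as linear in both the number of cheese pieces
#' and the number of tongue--palate compressions:
#' `saliva rate x n_pieces x n_compressions`. The whole volume is loaded
#' into the container before the run starts (a precomputed total, not a
#' flow). With the pooled rate 0.05 mL/s and 7 pieces the schedule runs
#' from 0.35 mL (1 compression) to 6.30 mL (18 compressions).
#'
#' @param saliva_rate In vivo saliva rate (mL/s, >= 0).
#' @param n_pieces Number of cheese pieces (>= 0).
#' @param n_compressions Number of compressions (>= 0).
#' @return Saliva volume in mL.
#' @export
in_vitro_saliva_volume <- function(saliva_rate, n_pieces, n_compressions) {
  if (any(c(saliva_rate, n_pieces, n_compressions) < 0))
    stop("all arguments must be nonnegative", call. = FALSE)
  saliva_rate * n_pieces * n_compressions
}

#' Check loaded piece mass against the computed cheese mass
#'
#' The computed cheese mass (container volume / ratio) and the mass
#' actually loadable as whole pieces (`n_pieces x piece_mass`) need not
#' coincide; a warning is raised when they differ by more than `tol`
#' grams. Both masses are kept as separate fields throughout.
#'
#' @param config A [masticator_config()].
#' @param cheese_mass Computed cheese mass (g).
#' @param tol Tolerance in grams.
#' @return Absolute mass discrepancy (g), invisibly.
#' @export
check_piece_mass <- function(config, cheese_mass, tol = 1) {
  gap <- abs(config$n_pieces * config$piece_mass - cheese_mass)
  if (gap > tol)
    warning(sprintf(
      "loaded piece mass %.2f g differs from computed cheese mass %.2f g by %.2f g",
      config$n_pieces * config$piece_mass, cheese_mass, gap), call. = FALSE)
  invisible(gap)
}

#' Build the in vitro experimental grid
#'
#' Cartesian product of compression counts and rotation speeds, each
#' operating point carrying its saliva volume (see
#' [in_vitro_saliva_volume()]) and the shared cheese mass. Ordering is
#' deterministic: ascending compressions major, ascending speed minor.
#' The study grid is `{1, 2, 6, 8, 10, 14, 18}` compressions by
#' `{4, 15}` rpm, i.e. 14 settings.
#'
#' @param compressions Compression counts (positive integers, distinct).
#' @param speeds Rotation speeds in rpm (positive, distinct).
#' @param config A [masticator_config()].
#' @param saliva_rate Pooled in vivo saliva rate (mL/s).
#' @param ratio_mouth_per_quantity Pooled mouth/quantity ratio (mL/g).
#' @param piece_mass_tol Tolerance for [check_piece_mass()].
#' @return Data.frame of class `in_vitro_grid`: `n_compressions`,
#'   `rotation_speed`, `saliva_volume`, `cheese_mass`.
#' @export
build_grid <- function(compressions = c(1, 2, 6, 8, 10, 14, 18),
                       speeds = c(4, 15),
                       config = masticator_config(),
                       saliva_rate = 0.05,
                       ratio_mouth_per_quantity = 11.47,
                       piece_mass_tol = 2) {
  if (!length(compressions) || !length(speeds))
    stop("compressions and speeds must be nonempty", call. = FALSE)
  if (any(compressions < 1) || any(speeds <= 0))
    stop("compressions must be >= 1 and speeds positive", call. = FALSE)
  if (anyDuplicated(compressions) || anyDuplicated(speeds))
    stop("duplicate grid points are not allowed", call. = FALSE)
  grid <- expand.grid(rotation_speed = sort(speeds),
                      n_compressions = sort(compressions))
  grid <- grid[, c("n_compressions", "rotation_speed")]
  grid$saliva_volume <- in_vitro_saliva_volume(saliva_rate, config$n_pieces,
                                               grid$n_compressions)
  grid$cheese_mass <- in_vitro_cheese_mass(config, ratio_mouth_per_quantity)
  check_piece_mass(config, grid$cheese_mass[1], tol = piece_mass_tol)
  rownames(grid) <- NULL
  class(grid) <- c("in_vitro_grid", class(grid))
  grid
}

#' Transpose panel summaries to a masticator settings sheet
#'
#' Combines the pooled panel means with the masticator constants into the
#' transposition sheet: fixed parameters (container volume, cheese mass,
#' pooled ratio, pooled saliva rate) plus the variable grid.
#'
#' @param panel_summary Output of [summarize_panel()] containing
#'   `ratio_mouth_per_quantity` and `saliva_rate` rows.
#' @param config A [masticator_config()].
#' @param compressions,speeds Grid definition.
#' @return List with `fixed` (data.frame) and `grid` (see [build_grid()]).
#' @export
transpose_parameters <- function(panel_summary, config = masticator_config(),
                                 compressions = c(1, 2, 6, 8, 10, 14, 18),
                                 speeds = c(4, 15)) {
  pick <- function(v) {
    row <- panel_summary$variable == v & panel_summary$group == "overall"
    if (!any(row)) stop("panel summary lacks overall row for ", v, call. = FALSE)
    panel_summary$mean[row]
  }
  ratio <- pick("ratio_mouth_per_quantity")
  rate <- pick("saliva_rate")
  mass <- in_vitro_cheese_mass(config, ratio)
  grid <- build_grid(compressions, speeds, config, rate, ratio)
  fixed <- data.frame(
    parameter = c("container_volume_mL", "cheese_mass_g",
                  "ratio_mouth_per_quantity_mL_per_g", "saliva_rate_mL_per_s",
                  "n_pieces", "piece_mass_g", "temperature_C"),
    value = c(config$container_volume, mass, ratio, rate,
              config$n_pieces, config$piece_mass, config$temperature))
  list(fixed = fixed, grid = grid)
}
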
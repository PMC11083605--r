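#' Reference chromameter means for the uncoloured and coloured cheese
#'
#' Mean CIE L*a*b* surface colours of the initial (uncoloured) processed
#' cream cheese and of the purple surface-coloured cheese under the study
#' conditions this package emulates. Their colour difference
#' (`delta_e`) is 42.24 CIELAB units, far above the visual threshold of 5.
#'
#' @return Named list of two [lab_color()] objects, `uncolored` and
#'   `colored`.
#' @export
reference_lab_colors <- function() {
  list(uncolored = lab_color(90.81, -1.67, 11.38),
       colored = lab_color(57.01, 19.82, -2.04))
}

#' Reference cheese composition
#'
#' Dry matter / water content of the uncoloured processed cream cheese,
#' used as the default cheese composition by the panel generator and the
#' saliva-content computation.
#'
#' @return A [composition()].
#' @export
reference_cheese_composition <- function() composition(42.97, 57.03)

#' Reference panel generating parameters
#'
#' Group means and population SDs of the masticatory parameters of the
#' 30-child (5--12 y) / 30-adult (18--65 y) reference panel: mouth volume
#' (mL), quantity consumed (g), mastication time (s), number of
#' tongue--palate compressions, and saliva volume (mL). These are the
#' default generating parameters of [panel_spec()].
#'
#' @return Data.frame with columns `group`, `variable`, `mean`, `sd`.
#' @export
reference_panel_parameters <- function() {
  data.frame(
    group = rep(c("child", "adult"), each = 5),
    variable = rep(c("mouth_volume", "quantity_consumed", "mastication_time",
                     "n_compressions", "saliva_volume"), 2),
    mean = c(38.24, 4.52, 6.92, 8.62, 0.28,
             84.75, 7.39, 8.91, 10.08, 0.52),
    sd = c(14.19, 2.11, 3.25, 3.78, 0.23,
           17.71, 2.44, 3.31, 3.90, 0.41),
    stringsAsFactors = FALSE)
}

#' Reference in vivo stage measurements
#'
#' Mean in vivo bolus measurements per group and mastication stage under
#' the reference study conditions: red-channel variance (normalized
#' intensity scale) from image analysis and back-extrusion hardness (N)
#' from texture analysis.
#'
#' @return Data.frame: `group`, `stage`, `metric`, `value`.
#' @export
reference_invivo_measurements <- function() {
  data.frame(
    group = rep(rep(c("child", "adult"), each = 3), 2),
    stage = rep(c(33, 66, 99), 4),
    metric = rep(c("red_variance", "hardness"), each = 6),
    value = c(0.0034, 0.0024, 0.0018,
              0.0024, 0.0012, 0.0009,
              93.54, 81.50, 71.94,
              107.98, 75.57, 54.50),
    stringsAsFactors = FALSE)
}

#' Reference in vitro candidate measurements
#'
#' Measured bolus values of the masticator settings that were retained as
#' stage matches under the reference study conditions, per metric. These
#' are the candidate sets against which nearest-value matching reproduces
#' the reference stage selections.
#'
#' @return Data.frame: `metric`, `n_compressions`, `rotation_speed`,
#'   `value`.
#' @export
reference_invitro_measurements <- function() {
  data.frame(
    metric = c(rep("red_variance", 5), rep("hardness", 4)),
    n_compressions = c(1, 2, 6, 8, 14, 1, 2, 6, 8),
    rotation_speed = c(15, 15, 4, 15, 15, 15, 15, 4, 15),
    value = c(0.0028, 0.0026, 0.0022, 0.0012, 0.0008,
              112.24, 96.82, 71.30, 50.83),
    stringsAsFactors = FALSE)
}
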
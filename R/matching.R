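#' Match one in vivo stage measurement to the nearest in vitro setting
#'
#' Selects the candidate masticator setting whose bolus measurement is
#' nearest (smallest absolute difference) to the in vivo value. Ties are
#' broken by minimal intervention: fewer compressions first, then lower
#' rotation speed.
#'
#' @param in_vivo A one-row data.frame or list with fields `metric`
#'   (`"red_variance"` or `"hardness"`) and `value` (>= 0); optional
#'   `group` and `stage` fields are carried through.
#' @param candidates Data.frame with columns `n_compressions`,
#'   `rotation_speed`, `value` and optionally `metric` (must be uniform
#'   and equal to the in vivo metric).
#' @return One-row data.frame: `group`, `stage`, `metric`,
#'   `in_vivo_value`, `n_compressions`, `rotation_speed`,
#'   `in_vitro_value`, `absolute_gap`.
#' @examples
#' cand <- data.frame(n_compressions = c(2, 6), rotation_speed = c(15, 4),
#'                    value = c(0.0026, 0.0022))
#' match_stage(list(metric = "red_variance", value = 0.0024), cand)
#' @export
match_stage <- function(in_vivo, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("candidate list must be nonempty", call. = FALSE)
  metric <- in_vivo$metric
  if (!metric %in% c("red_variance", "hardness"))
    stop("metric must be 'red_variance' or 'hardness'", call. = FALSE)
  if ("metric" %in% names(candidates) &&
      !all(candidates$metric == metric))
    stop("mixed metrics: candidates must all share the in vivo metric",
         call. = FALSE)
  if (in_vivo$value < 0 || any(candidates$value < 0))
    stop("measurement values must be nonnegative", call. = FALSE)
  gap <- abs(candidates$value - in_vivo$value)
  # gaps equal up to floating-point representation are genuine ties and must
  # fall through to the minimal-intervention tie-break
  scale <- max(abs(c(candidates$value, in_vivo$value)), .Machine$double.eps)
  tied <- gap <= min(gap) + 1e-9 * scale
  pool <- candidates[tied, ]
  ord <- order(pool$n_compressions, pool$rotation_speed)
  best <- pool[ord[1], ]
  data.frame(
    group = if (is.null(in_vivo$group)) NA_character_ else in_vivo$group,
    stage = if (is.null(in_vivo$stage)) NA_real_ else in_vivo$stage,
    metric = metric,
    in_vivo_value = in_vivo$value,
    n_compressions = best$n_compressions,
    rotation_speed = best$rotation_speed,
    in_vitro_value = best$value,
    absolute_gap = abs(best$value - in_vivo$value),
    stringsAsFactors = FALSE)
}

#' Match the full in vivo table and recommend final settings
#'
#' Runs [match_stage()] for every group x stage x metric combination (2
#' groups x 3 stages x 2 metrics = 12 matches) and derives one final
#' recommended setting per group: the red-variance (image analysis) match
#' at the 99 percent stage. Image analysis takes priority over texture for
#' the final choice because the bolus mixing state is the more faithful
#' marker of in vivo chewing than hardness.
#'
#' @param in_vivo Data.frame with columns `group`, `stage` (33/66/99),
#'   `metric`, `value` covering every combination.
#' @param in_vitro Data.frame of candidate measurements with columns
#'   `metric`, `n_compressions`, `rotation_speed`, `value`.
#' @param stages Required stages (default 33, 66, 99).
#' @return List with `matches` (12-row data.frame) and `recommendation`
#'   (one row per group: `group`, `n_compressions`, `rotation_speed`).
#' @export
match_all <- function(in_vivo, in_vitro, stages = c(33, 66, 99)) {
  groups <- unique(in_vivo$group)
  metrics <- unique(in_vivo$metric)
  combos <- expand.grid(stage = stages, metric = metrics, group = groups,
                        stringsAsFactors = FALSE)
  matches <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    row <- in_vivo[in_vivo$group == cm$group & in_vivo$stage == cm$stage &
                     in_vivo$metric == cm$metric, ]
    if (nrow(row) != 1)
      stop(sprintf("missing or duplicated in vivo measurement: %s / %s%% / %s",
                   cm$group, cm$stage, cm$metric), call. = FALSE)
    cand <- in_vitro[in_vitro$metric == cm$metric, ]
    if (nrow(cand) == 0)
      stop("no in vitro candidates for metric ", cm$metric, call. = FALSE)
    match_stage(row, cand)
  }))
  rownames(matches) <- NULL
  final_stage <- max(stages)
  recommendation <- do.call(rbind, lapply(groups, function(g) {
    sel <- matches[matches$group == g & matches$stage == final_stage &
                     matches$metric == "red_variance", ]
    if (nrow(sel) != 1)
      stop("final recommendation needs a red_variance match at the swallowing stage",
           call. = FALSE)
    data.frame(group = g, n_compressions = sel$n_compressions,
               rotation_speed = sel$rotation_speed, stringsAsFactors = FALSE)
  }))
  rownames(recommendation) <- NULL
  list(matches = matches, recommendation = recommendation)
}

#' Format match results as a Markdown table
#'
#' @param matches Match table from [match_all()] (or one [match_stage()]
#'   row).
#' @return Character vector of Markdown lines.
#' @export
format_match_table <- function(matches) {
  header <- "| Group | Stage (%) | Metric | In vivo | In vitro | Setting |"
  sep <- "|---|---|---|---|---|---|"
  rows <- vapply(seq_len(nrow(matches)), function(i) {
    m <- matches[i, ]
    sprintf("| %s | %s | %s | %.4g | %.4g | %d compressions - %g rpm |",
            m$group, m$stage, m$metric, m$in_vivo_value, m$in_vitro_value,
            m$n_compressions, m$rotation_speed)
  }, character(1))
  c(header, sep, rows)
}
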
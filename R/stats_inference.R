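#' One-way fixed-effect ANOVA
#'
#' Standard between/within sum-of-squares decomposition via
#' [stats::lm()]. Degenerate inputs follow a fixed convention: zero
#' within-group variance with a nonzero group difference reports
#' `F = Inf, p = 0`; identical group means report `F = 0, p = 1`.
#'
#' @param values Numeric response.
#' @param group_labels Grouping factor (>= 2 groups, each nonempty).
#' @return One-row data.frame: `effect`, `F`, `df_num`, `df_den`, `p`.
#' @export
one_way_anova <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) == 0)) stop("every group must be nonempty", call. = FALSE)
  if (length(values) != length(g)) stop("length mismatch", call. = FALSE)
  if (length(values) <= nlevels(g))
    stop("need more observations than groups", call. = FALSE)
  fit <- stats::lm(values ~ g)
  # perfect-fit warnings are handled below by the explicit F conventions
  tab <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss_b <- tab$`Sum Sq`[1]; ss_w <- tab$`Sum Sq`[2]
  df1 <- tab$Df[1]; df2 <- tab$Df[2]
  scale <- max(ss_b + ss_w, .Machine$double.eps)
  if (ss_w / scale < 1e-12) {
    if (ss_b / scale < 1e-12) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ss_b / df1) / (ss_w / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  data.frame(effect = "group", F = f, df_num = df1, df_den = df2, p = p,
             stringsAsFactors = FALSE)
}

#' Mixed-design ANOVA with a random subject effect
#'
#' Fits the split-plot model used for repeated bolus measurements:
#' subjects are a random effect nested in the between-subject factor(s),
#' which are tested against the subject-within-group stratum; the
#' within-subject factor(s) and any interaction are tested against the
#' residual stratum. Factors are coded with sum-to-zero contrasts, so on
#' the balanced designs this package generates the partitioning coincides
#' with Type III sums of squares. The two-way model
#' (`subject` random + one between factor) and the three-way model
#' (+ mastication progress + interaction) are both expressed through this
#' interface.
#'
#' @param values Numeric response (e.g. red-channel variance or hardness).
#' @param subject_ids Subject identifier for each observation.
#' @param fixed_factors Data.frame (or named list) of fixed factors, one
#'   entry per observation; factors constant within subject are treated as
#'   between-subject.
#' @param interaction Include all fixed-factor interactions?
#' @return Data.frame with one row per effect: `effect`, `F`, `df_num`,
#'   `df_den`, `p`. Zero-residual strata report `F = Inf, p = 0`.
#' @export
mixed_anova <- function(values, subject_ids, fixed_factors,
                        interaction = TRUE) {
  fixed <- as.data.frame(fixed_factors, stringsAsFactors = FALSE)
  if (nrow(fixed) != length(values) || length(subject_ids) != length(values))
    stop("values, subject_ids and fixed_factors must align", call. = FALSE)
  subj <- factor(subject_ids)
  dat <- data.frame(.y = values, .subject = subj)
  for (nm in names(fixed)) {
    f <- factor(fixed[[nm]])
    if (nlevels(f) < 2L)
      stop("fixed factor '", nm, "' must have at least 2 levels", call. = FALSE)
    # a factor in 1-1 correspondence with subjects is confounded with the
    # random effect and cannot be tested
    cross <- table(subj, f)
    if (nlevels(f) == nlevels(subj) && all(rowSums(cross > 0) == 1L) &&
        all(colSums(cross > 0) == 1L))
      stop("fixed factor '", nm, "' is confounded with subject", call. = FALSE)
    stats::contrasts(f) <- stats::contr.sum(nlevels(f))
    dat[[nm]] <- f
  }
  within_f <- names(fixed)[vapply(names(fixed), function(nm)
    any(rowSums(table(subj, dat[[nm]]) > 0) > 1L), logical(1))]
  if (interaction && length(within_f)) {
    cells <- do.call(base::interaction,
                     c(list(subj), dat[within_f], list(drop = TRUE)))
    if (all(table(cells) <= 1L))
      stop("interaction requested with a single observation per subject cell; ",
           "replicate measurements are required", call. = FALSE)
  }
  op <- if (interaction && length(names(fixed)) > 1L) " * " else " + "
  rhs <- paste(names(fixed), collapse = op)
  form <- stats::as.formula(paste("`.y` ~", rhs, "+ Error(.subject)"))
  fit <- stats::aov(form, data = dat)
  out <- do.call(rbind, lapply(summary(fit), function(s) {
    tab <- s[[1]]
    terms <- trimws(rownames(tab))
    resid_row <- terms == "Residuals"
    if (!any(resid_row) || all(resid_row)) return(NULL)
    df_den <- tab$Df[resid_row]
    ms_den <- tab$`Mean Sq`[resid_row]
    eff <- which(!resid_row)
    do.call(rbind, lapply(eff, function(i) {
      ms_num <- tab$`Mean Sq`[i]
      if (ms_den <= ms_num * 1e-12) {
        f <- Inf; p <- 0
      } else {
        f <- ms_num / ms_den
        p <- stats::pf(f, tab$Df[i], df_den, lower.tail = FALSE)
      }
      data.frame(effect = gsub("`", "", terms[i]), F = f, df_num = tab$Df[i],
                 df_den = df_den, p = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# exact upper-tail binomial with p0 = 1/3
triangle_tail <- function(k, n) {
  if (k <= 0) return(1)
  stats::pbinom(k - 1, n, 1 / 3, lower.tail = FALSE)
}

#' Exact binomial triangle test
#'
#' Forced-choice discrimination test: each of three samples, one odd; a
#' non-discriminating panelist answers correctly with probability 1/3.
#' The p-value is the exact upper-tail binomial probability of observing
#' at least `n_correct` correct answers under p0 = 1/3, and
#' `min_correct_for_alpha` is the smallest correct count whose tail
#' probability does not exceed `alpha` (or `NA` when even a perfect score
#' is not significant).
#'
#' @param n_correct Observed correct answers (0..n_panelists).
#' @param n_panelists Panel size (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return List of class `triangle_test_result`: `n_panelists`,
#'   `n_correct`, `p_value`, `min_correct_for_alpha`, `significant`.
#' @examples
#' triangle_test(9, 30)   # not significant
#' @export
triangle_test <- function(n_correct, n_panelists, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_panelists < 1 || n_correct < 0 || n_correct > n_panelists)
    stop("need 0 <= n_correct <= n_panelists", call. = FALSE)
  p <- triangle_tail(n_correct, n_panelists)
  tails <- vapply(0:n_panelists, triangle_tail, numeric(1), n = n_panelists)
  ok <- which(tails <= alpha)
  min_correct <- if (length(ok)) (0:n_panelists)[ok[1]] else NA_integer_
  structure(list(n_panelists = n_panelists, n_correct = n_correct,
                 p_value = p, min_correct_for_alpha = min_correct,
                 significant = p <= alpha),
            class = "triangle_test_result")
}

#' @export
print.triangle_test_result <- function(x, ...) {
  cat(sprintf("Triangle test: %d/%d correct, exact p = %.4g (%ssignificant)\n",
              x$n_correct, x$n_panelists, x$p_value,
              if (x$significant) "" else "not "))
  if (is.na(x$min_correct_for_alpha)) {
    cat("minimum significant count: unattainable at this panel size\n")
  } else {
    cat(sprintf("minimum significant count: %d\n", x$min_correct_for_alpha))
  }
  invisible(x)
}
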
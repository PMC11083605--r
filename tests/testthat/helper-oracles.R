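# Independent oracles and small fixture builders used across the suite.

# brute-force one-way sum-of-squares decomposition
oracle_one_way_f <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(x)
    length(x) * (mean(x) - grand)^2))
  ss_within <- sum(unlist(tapply(values, groups, function(x)
    (x - mean(x))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ss_between / df1) / (ss_within / df2)
}

# exact binomial upper tail (p0 = 1/3) by recursive term ratio
oracle_triangle_tail <- function(k, n) {
  if (k <= 0) return(1)
  term <- (2 / 3)^n  # P(X = 0)
  total <- if (k == 0) term else 0
  for (j in 1:n) {
    term <- term * (n - j + 1) / j * (1 / 2)  # ratio p/(1-p) = 1/2
    if (j >= k) total <- total + term
  }
  total
}

# split-plot F ratios on a balanced two-group x s-stage x r-replicate design,
# from explicit expected-mean-square sums
oracle_split_plot <- function(y, subject, group, stage) {
  df <- data.frame(y = y, subject = factor(subject), group = factor(group),
                   stage = factor(stage))
  grand <- mean(df$y)
  n_subj <- nlevels(df$subject)
  g <- nlevels(df$group); s <- nlevels(df$stage)
  r <- nrow(df) / (n_subj * s)
  subj_means <- tapply(df$y, df$subject, mean)
  subj_group <- tapply(as.character(df$group), df$subject, `[`, 1)
  group_means <- tapply(df$y, df$group, mean)
  stage_means <- tapply(df$y, df$stage, mean)
  cell_means <- tapply(df$y, list(df$group, df$stage), mean)

  ss_group <- (n_subj / g) * s * r * sum((group_means - grand)^2)
  ss_subj <- s * r * sum((subj_means - group_means[subj_group])^2)
  ss_stage <- n_subj * r * sum((stage_means - grand)^2)
  ss_int <- (n_subj / g) * r *
    sum((sweep(sweep(cell_means, 1, group_means), 2, stage_means) + grand)^2)
  ss_tot <- sum((df$y - grand)^2)
  ss_res <- ss_tot - ss_group - ss_subj - ss_stage - ss_int

  df_subj <- n_subj - g
  df_res <- nrow(df) - n_subj - (s - 1) - (g - 1) * (s - 1)
  list(
    F_group = (ss_group / (g - 1)) / (ss_subj / df_subj),
    F_stage = (ss_stage / (s - 1)) / (ss_res / df_res),
    F_int = (ss_int / ((g - 1) * (s - 1))) / (ss_res / df_res))
}

# raw green-backdrop raster with a white disk (and optional speck)
make_disk_raster <- function(size = 40, radius = 12, speck = FALSE) {
  ctr <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  disk <- sqrt((xs - ctr)^2 + (ys - ctr)^2) <= radius
  px <- array(0, c(size, size, 3))
  px[, , 1] <- ifelse(disk, 0.95, 0.20)
  px[, , 2] <- ifelse(disk, 0.95, 0.70)
  px[, , 3] <- ifelse(disk, 0.95, 0.25)
  if (speck) for (k in 1:3) px[2, 2:4, k] <- 0.95
  list(pixels = px, disk = disk)
}

# image whose per-channel ROI variance is exactly (half at m-d, half at m+d)
make_variance_image <- function(red_d, green_d = 0.1, blue_d = 0.1, m = 0.5) {
  px <- array(m, c(2, 2, 3))
  for (k in 1:3) {
    d <- c(red_d, green_d, blue_d)[k]
    px[, , k] <- matrix(c(m - d, m - d, m + d, m + d), 2, 2)
  }
  bolus_image(px)
}
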
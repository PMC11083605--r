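test_that("nearest-value matching selects the minimal absolute gap", {
  cand <- data.frame(
    n_compressions = c(1, 2, 6, 8, 14),
    rotation_speed = c(15, 15, 4, 15, 15),
    value = c(0.0028, 0.0026, 0.0022, 0.0012, 0.0008))
  m <- match_stage(list(metric = "red_variance", value = 0.0018,
                        group = "child", stage = 99), cand)
  expect_equal(m$n_compressions, 6)
  expect_equal(m$rotation_speed, 4)
  expect_equal(m$absolute_gap, abs(0.0018 - 0.0022))

  hard <- data.frame(n_compressions = c(2, 6, 1, 8),
                     rotation_speed = c(15, 4, 15, 15),
                     value = c(96.82, 71.30, 112.24, 50.83))
  mh <- match_stage(list(metric = "hardness", value = 54.50), hard)
  expect_equal(mh$n_compressions, 8)
  expect_equal(mh$rotation_speed, 15)
})

test_that("equidistant candidates fall to the fewer-compressions tie-break", {
  cand <- data.frame(n_compressions = c(2, 6), rotation_speed = c(15, 4),
                     value = c(0.0026, 0.0022))
  m <- match_stage(list(metric = "red_variance", value = 0.0024), cand)
  expect_equal(m$n_compressions, 2)
  expect_equal(m$rotation_speed, 15)

  # all candidates equal: minimal compressions, then minimal rpm
  eq <- data.frame(n_compressions = c(6, 1, 1), rotation_speed = c(4, 15, 4),
                   value = 0.002)
  me <- match_stage(list(metric = "red_variance", value = 0.001), eq)
  expect_equal(c(me$n_compressions, me$rotation_speed), c(1, 4))
})

test_that("matching rejects empty or inconsistent candidate sets", {
  expect_error(match_stage(list(metric = "hardness", value = 1),
                           data.frame()), "nonempty")
  cand <- data.frame(n_compressions = 1, rotation_speed = 4, value = 1,
                     metric = "red_variance")
  expect_error(match_stage(list(metric = "hardness", value = 1), cand),
               "mixed metrics")
})

test_that("selection is order invariant and gaps shrink with more candidates", {
  set.seed(31)
  for (i in 1:20) {
    cand <- data.frame(n_compressions = sample(1:18, 6),
                       rotation_speed = sample(c(4, 15), 6, TRUE),
                       value = runif(6))
    target <- list(metric = "hardness", value = runif(1))
    m1 <- match_stage(target, cand)
    m2 <- match_stage(target, cand[sample(6), ])
    expect_equal(m1, m2)
    extra <- rbind(cand, data.frame(n_compressions = 3, rotation_speed = 4,
                                    value = runif(1)))
    expect_lte(match_stage(target, extra)$absolute_gap, m1$absolute_gap)
  }
})

test_that("the full reference table is reproduced row by row", {
  res <- match_all(reference_invivo_measurements(),
                   reference_invitro_measurements())
  expect_equal(nrow(res$matches), 12)

  expected <- data.frame(
    group = rep(rep(c("child", "adult"), each = 3), 2),
    stage = rep(c(33, 66, 99), 4),
    metric = rep(c("red_variance", "hardness"), each = 6),
    n_compressions = c(1, 2, 6, 2, 8, 14, 2, 6, 6, 1, 6, 8),
    rotation_speed = c(15, 15, 4, 15, 15, 15, 15, 4, 4, 15, 4, 15))
  for (i in seq_len(nrow(expected))) {
    got <- res$matches[res$matches$group == expected$group[i] &
                         res$matches$stage == expected$stage[i] &
                         res$matches$metric == expected$metric[i], ]
    expect_equal(got$n_compressions, expected$n_compressions[i],
                 label = sprintf("%s %d%% %s compressions", expected$group[i],
                                 expected$stage[i], expected$metric[i]))
    expect_equal(got$rotation_speed, expected$rotation_speed[i])
  }

  expect_equal(res$recommendation$n_compressions[
    res$recommendation$group == "child"], 6)
  expect_equal(res$recommendation$rotation_speed[
    res$recommendation$group == "child"], 4)
  expect_equal(res$recommendation$n_compressions[
    res$recommendation$group == "adult"], 14)
  expect_equal(res$recommendation$rotation_speed[
    res$recommendation$group == "adult"], 15)
})

test_that("identical in vitro values yield zero-gap exact matches", {
  iv <- reference_invivo_measurements()
  cand <- data.frame(metric = iv$metric, n_compressions = seq_len(nrow(iv)),
                     rotation_speed = 4, value = iv$value)
  for (i in seq_len(nrow(iv))) {
    m <- match_stage(iv[i, ], cand[cand$metric == iv$metric[i], ])
    expect_equal(m$absolute_gap, 0)
    expect_equal(m$in_vitro_value, iv$value[i])
  }
})

test_that("missing stages are rejected and reports render", {
  iv <- reference_invivo_measurements()
  expect_error(match_all(iv[iv$stage != 66, ],
                         reference_invitro_measurements()),
               "missing")
  res <- match_all(iv, reference_invitro_measurements())
  md <- format_match_table(res$matches)
  expect_length(md, 14)  # header + separator + 12 rows
  expect_match(md[3], "compressions")
})
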
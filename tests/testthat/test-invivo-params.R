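test_that("chewing frequency and stage times follow the per-subject definitions", {
  expect_equal(chewing_frequency(10, 5), 2)
  expect_equal(chewing_frequency(8, 8), 1)
  expect_equal(chewing_frequency(9, 6.92), 1.3006, tolerance = 1e-4)
  expect_error(chewing_frequency(5, 0), "positive")

  expect_equal(unname(stage_times(10)), c(3.3, 6.6, 9.9))
  expect_equal(unname(stage_times(6.92)), c(2.2836, 4.5672, 6.8508))
  expect_error(stage_times(0), "positive")
})

test_that("saliva content follows the moisture balance and clamps at zero", {
  cheese <- reference_cheese_composition()
  expect_equal(saliva_content(composition(40, 60), cheese), 7.425)
  expect_equal(saliva_content(cheese, cheese), 0)
  expect_equal(saliva_content(composition(50, 50), composition(50, 50)), 0)
  expect_warning(
    sc <- saliva_content(composition(60, 40), cheese), "clamped")
  expect_equal(sc, 0)
  expect_error(composition(120, -20), "\\[0, 100\\]")
  expect_error(composition(30, 60), "sum to 100")
})

test_that("saliva volume converts content to millilitres via the consumed mass", {
  expect_equal(saliva_volume(0), 0)
  expect_equal(saliva_volume(7.425), 0.334125)
  expect_equal(saliva_volume(11.56), 0.5202)
  expect_error(saliva_volume(-1), "nonnegative")
})

test_that("derived ratios are unit consistent per subject", {
  panel <- derive_params(generate_panel(
    panel_spec(group_sizes = c(child = 4L, adult = 4L)), seed = 2))
  expect_equal(panel$ratio_mouth_per_quantity * panel$quantity_consumed,
               panel$mouth_volume)
  expect_equal(panel$saliva_rate * panel$mastication_time, panel$saliva_volume)
  expect_equal(panel$ratio_saliva_per_mouth * panel$mouth_volume,
               panel$saliva_volume)
  expect_true(all(panel$saliva_content >= 0))
})

test_that("panel summaries use the population SD and are permutation invariant", {
  panel <- data.frame(
    id = c("a", "b"), group = "child",
    mouth_volume = c(30, 50), quantity_consumed = c(4, 5),
    mastication_time = c(6, 8), n_compressions = c(8, 9),
    bolus_dry_matter = c(40, 41), bolus_water_content = c(60, 59),
    cheese_dry_matter = 42.97, cheese_water_content = 57.03)
  s <- summarize_panel(derive_params(panel))
  mv <- s[s$variable == "mouth_volume" & s$group == "child", ]
  expect_equal(mv$mean, 40)
  expect_equal(mv$sd, 10)  # population SD of {30, 50}

  single <- summarize_panel(derive_params(panel[1, ]))
  expect_true(all(single$sd == 0))

  big <- derive_params(generate_panel(
    panel_spec(group_sizes = c(child = 5L, adult = 5L)), seed = 9))
  s1 <- summarize_panel(big)
  s2 <- summarize_panel(big[sample(nrow(big)), ])
  expect_equal(s1, s2)
})

test_that("replicates are averaged per subject before group summaries", {
  panel <- data.frame(
    id = rep("a", 3), group = "child", replicate = 1:3,
    mouth_volume = c(10, 20, 60), quantity_consumed = 5,
    mastication_time = 6, n_compressions = 8,
    bolus_dry_matter = 40, bolus_water_content = 60,
    cheese_dry_matter = 42.97, cheese_water_content = 57.03)
  s <- summarize_panel(derive_params(panel))
  expect_equal(s$mean[s$variable == "mouth_volume" & s$group == "child"], 30)
})

test_that("pooled overall mean equals the mean of group means at equal sizes", {
  panel <- derive_params(generate_panel(
    panel_spec(group_sizes = c(child = 6L, adult = 6L)), seed = 4))
  s <- summarize_panel(panel)
  for (v in unique(s$variable)) {
    rows <- s[s$variable == v, ]
    expect_equal(rows$mean[rows$group == "overall"],
                 mean(rows$mean[rows$group %in% c("child", "adult")]))
  }
})
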
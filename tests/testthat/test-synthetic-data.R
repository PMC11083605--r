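test_that("generators are bit-reproducible under a fixed seed", {
  p1 <- generate_panel(panel_spec(group_sizes = c(child = 3L, adult = 3L)), seed = 7)
  p2 <- generate_panel(panel_spec(group_sizes = c(child = 3L, adult = 3L)), seed = 7)
  expect_identical(p1, p2)

  i1 <- generate_bolus_image(mix_spec(), 4, 15, seed = 7)
  i2 <- generate_bolus_image(mix_spec(), 4, 15, seed = 7)
  expect_identical(i1$pixels, i2$pixels)

  c1 <- generate_force_curve(50, "back_extrusion", 0.5, seed = 7)
  c2 <- generate_force_curve(50, "back_extrusion", 0.5, seed = 7)
  expect_identical(c1$force, c2$force)
  expect_identical(generate_triangle_session(30, 0.2, seed = 7),
                   generate_triangle_session(30, 0.2, seed = 7))
})

test_that("zero-SD panel specs reproduce the group means exactly", {
  pars <- reference_panel_parameters()
  pars$sd <- 0
  spec <- panel_spec(pars, group_sizes = c(child = 2L, adult = 2L),
                     rep_noise_frac = 0)
  p <- generate_panel(spec, seed = 1)
  expect_equal(unique(p$mouth_volume[p$group == "child"]), 38.24)
  expect_equal(unique(p$n_compressions[p$group == "adult"]), 10L)
  expect_error(panel_spec(group_sizes = c(child = 0L)), ">= 1")
})

test_that("generated panels honour the generating moments", {
  p <- derive_params(generate_panel(panel_spec(), seed = 3))
  subj <- aggregate(p[c("mouth_volume", "saliva_volume")],
                    by = list(group = p$group), mean)
  expect_equal(subj$mouth_volume[subj$group == "child"], 38.24,
               tolerance = 2 * 14.19 / sqrt(30) / 38.24)
  expect_equal(subj$mouth_volume[subj$group == "adult"], 84.75,
               tolerance = 2 * 17.71 / sqrt(30) / 84.75)
  expect_true(all(p$n_compressions >= 1))
  expect_true(all(p$mastication_time > 0))
})

test_that("noise-free unmixed image has the closed two-point variance", {
  sp <- mix_spec(noise_sd = 0)
  img <- generate_bolus_image(sp, n_compressions = 0)
  f <- attr(img, "colored_fraction")
  expect_equal(f, sp$colored_fraction, tolerance = 0.05)
  for (ch in c("red", "green", "blue")) {
    k <- match(ch, c("red", "green", "blue"))
    expect_equal(channel_variance(img, ch)$variance,
                 f * (1 - f) * (sp$colored_rgb[k] - sp$base_rgb[k])^2)
  }
})

test_that("a vanishing coloured fraction leaves only the noise floor", {
  sp <- mix_spec(colored_fraction = 1e-6, noise_sd = 0.01)
  img <- generate_bolus_image(sp, n_compressions = 0, seed = 2)
  expect_lt(channel_variance(img)$variance, 3 * 0.01^2)
})

test_that("mixing variance decreases with compressions and rotation speed", {
  comps <- c(1, 2, 6, 10, 18)
  v4 <- v15 <- matrix(NA, 20, length(comps))
  for (s in 1:20) {
    v4[s, ] <- sapply(comps, function(n)
      channel_variance(generate_bolus_image(mix_spec(), n, 4, seed = s))$variance)
    v15[s, ] <- sapply(comps, function(n)
      channel_variance(generate_bolus_image(mix_spec(), n, 15, seed = s))$variance)
  }
  # per-seed monotone decay in compressions at fixed rpm
  expect_true(all(apply(v4, 1, function(v) all(diff(v) <= 0))))
  expect_true(all(apply(v15, 1, function(v) all(diff(v) <= 0))))
  # faster stirring mixes more: mean over seeds lower at 15 rpm everywhere
  expect_true(all(colMeans(v15) <= colMeans(v4)))
  # the deterministic field is strictly ordered even at one compression
  sp0 <- mix_spec(noise_sd = 0)
  expect_lt(channel_variance(generate_bolus_image(sp0, 1, 15))$variance,
            channel_variance(generate_bolus_image(sp0, 1, 4))$variance)
})

test_that("the in vivo image set has the designed structure and group ordering", {
  panel <- generate_panel(panel_spec(group_sizes = c(child = 6L, adult = 6L)),
                          seed = 5)
  imgs <- generate_invivo_image_set(panel, seed = 6)
  expect_length(imgs, 6 * 2 * 3 * 2)  # subjects x stages x duplicates
  one <- generate_invivo_image_set(panel[panel$id == "child_01", ], seed = 6)
  expect_length(one, 6)

  sc <- score_images(imgs)
  agg <- aggregate(sc["variance"], by = sc[c("group", "stage")], mean)
  for (st in c(33, 66, 99)) {
    expect_gt(agg$variance[agg$group == "child" & agg$stage == st],
              agg$variance[agg$group == "adult" & agg$stage == st])
  }
  for (g in c("child", "adult")) {
    v <- agg$variance[agg$group == g][order(agg$stage[agg$group == g])]
    expect_true(all(diff(v) < 0))
  }
  # duplicates at identical settings differ only through noise
  reps <- sc[sc$subject == "child_01" & sc$stage == 33, "variance"]
  expect_length(reps, 2)
  expect_lt(abs(diff(reps)), 0.005)
})

test_that("triangle sessions follow the discriminator mixture", {
  expect_identical(generate_triangle_session(0, 0.5), 0L)
  expect_identical(generate_triangle_session(12, 1, seed = 1), 12L)
  counts <- vapply(1:400, function(s)
    generate_triangle_session(30, 0, seed = s), integer(1))
  se <- sqrt(30 * (1 / 3) * (2 / 3) / 400)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  expect_error(generate_triangle_session(10, 1.5), "p_discriminator")
})
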
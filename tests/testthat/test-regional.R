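test_that("reference norms filter by age and recover generator parameters", {
  pop <- tiny_population(n = 600, seed = 21)
  # push 40 specimens outside the age window
  pop$age_yr[1:40] <- 1.5
  norms <- compute_reference_norms(pop)
  expect_s3_class(norms, "reference_norms")
  expect_equal(norms$n, sum(pop$age_yr >= 0.9 & pop$age_yr <= 1.1))
  expect_lte(norms$n, 560)

  cfg <- generator_config(n = 1, seed = 1)
  se <- cfg$clr_sd / sqrt(norms$n)
  # sampling-theory check: means land within 3 SE for most parts
  within <- abs(norms$mean - cfg$clr_mean) <= 3 * se
  expect_gte(sum(within), 10)

  expect_error(compute_reference_norms(pop[1:10, ]),
               "too few reference specimens")
})

test_that("degenerate (identical) reference specimens are rejected", {
  pop <- tiny_population(n = 40, seed = 3)
  pop[, nutrient_columns()] <-
    pop[rep(1, nrow(pop)), nutrient_columns()]
  expect_error(compute_reference_norms(pop), "degenerate norm standard deviation")
})

test_that("CND indices match hand-evaluated standardization on Site #1", {
  cl <- clr_transform(close_composition(site1_profile()))
  idx <- cnd_indices(cl, fx$norms)
  # hand-evaluated (clr_i - mean_i)/sd_i with the published norms
  expect_equal(unname(idx["Mn"]), 7.68, tolerance = 0.01)
  expect_equal(unname(idx["B"]), 4.54, tolerance = 0.01)
  expect_equal(unname(idx["N"]), 1.61, tolerance = 0.01)
  expect_equal(unname(idx["Fe"]), -5.04, tolerance = 0.01)
  expect_equal(unname(idx["Zn"]), -3.43, tolerance = 0.01)
  expect_equal(unname(idx["Cu"]), -3.04, tolerance = 0.01)

  # clr equal to the norm means -> all-zero indices
  m <- fx$norms$mean
  expect_equal(as.numeric(cnd_indices(m, fx$norms)), rep(0, 12))

  # doubling all SDs halves every index
  halved <- reference_norms(fx$norms$mean, fx$norms$sd * 2,
                            provenance = "doubled")
  expect_equal(as.numeric(cnd_indices(cl, halved)), as.numeric(idx) / 2,
               tolerance = 1e-12)
})

test_that("CND indices are affine-equivariant in the norm means", {
  cl <- clr_transform(close_composition(site2_profile()))
  idx <- cnd_indices(cl, fx$norms)
  delta <- stats::setNames(c(0.05, -0.05, rep(0, 10)), composition_parts())
  shifted <- reference_norms(fx$norms$mean + delta,
                             fx$norms$sd, provenance = "shifted")
  idx2 <- cnd_indices(cl, shifted)
  expect_equal(as.numeric(idx2 - idx), as.numeric(-delta / fx$norms$sd),
               tolerance = 1e-10)
})

test_that("global imbalance aggregates to an 11-df chi-squared probability", {
  zero <- stats::setNames(rep(0, 12), composition_parts())
  gi0 <- global_imbalance(zero)
  expect_equal(gi0$r2, 0)
  expect_equal(gi0$p_value, 1)
  expect_equal(gi0$df, 11)

  one <- zero; one["N"] <- sqrt(11)
  gi1 <- global_imbalance(one)
  expect_equal(gi1$r2, 11, tolerance = 1e-12)
  # frozen chi-squared CDF oracle value at r2 = 11, df = 11
  expect_equal(gi1$p_value, 0.44326327842647, tolerance = 1e-10)

  cl <- clr_transform(close_composition(site1_profile()))
  idx <- cnd_indices(cl, fx$norms)
  expect_equal(global_imbalance(idx)$r2, sum(as.numeric(idx)^2))
})

test_that("nutrient ranking orders shortage to excess with fixed tie-breaks", {
  cl <- clr_transform(close_composition(site1_profile()))
  idx <- cnd_indices(cl, fx$norms)
  rk <- rank_nutrients(idx)
  expect_equal(rk$part[1:3], c("Fe", "Zn", "Cu"))      # shortage order
  expect_equal(rev(rk$part)[1:3], c("Mn", "B", "N"))   # excess order
  expect_false("Fv" %in% rk$part)
  expect_true("Fv" %in% rank_nutrients(idx, exclude_fv = FALSE)$part)

  tied <- stats::setNames(rep(1, 12), composition_parts())
  expect_equal(rank_nutrients(tied)$part, nutrient_parts())

  rk_neg <- rank_nutrients(-idx)
  expect_equal(rk_neg$part, rev(rk$part))
})

test_that("quartile intervals use the linear-interpolation estimator", {
  pop <- tiny_population(n = 5, seed = 5)
  pop$n_g_kg <- c(1, 2, 3, 4, 5)
  iv <- quartile_intervals(pop)
  expect_equal(iv$lower[iv$nutrient == "N"], 2)
  expect_equal(iv$upper[iv$nutrient == "N"], 4)
  expect_match(attr(iv, "estimator"), "linear interpolation")

  pop$p_g_kg <- rep(1.3, 5)
  expect_error(quartile_intervals(pop), "zero-width interval")
  expect_error(quartile_intervals(tiny_population(n = 5, seed = 5)[1:3, ]),
               "too few specimens")
})

test_that("quartile intervals recover the generator's concentration quartiles", {
  pop <- tiny_population(n = 2000, seed = 31)
  iv <- quartile_intervals(pop)
  # compare to the quartiles implied by the generating distribution,
  # estimated from an independent larger draw
  big <- tiny_population(n = 8000, seed = 99)
  for (p in c("N", "K", "Ca")) {
    col <- nutrient_columns()[match(p, nutrient_parts())]
    qref <- stats::quantile(big[[col]], c(0.25, 0.75), names = FALSE)
    expect_equal(iv$lower[iv$nutrient == p], qref[1], tolerance = 0.05)
    expect_equal(iv$upper[iv$nutrient == p], qref[2], tolerance = 0.05)
  }
})

test_that("interval classification reproduces every printed site label", {
  for (site in c("site1", "site2")) {
    prof <- nutrient_profile(fx$sites[[site]])
    expect_identical(classify_against_intervals(prof, fx$intervals_state),
                     fx$site_labels[[site]]$state)
    expect_identical(classify_against_intervals(prof, fx$intervals_tn),
                     fx$site_labels[[site]]$tn)
  }
  # boundary inclusivity is what forces several of those labels:
  # P = 1.4 at the TN upper bound -> Normal; N = 15.0 at the state lower -> Normal
  lab1 <- classify_against_intervals(site1_profile(), fx$intervals_tn)
  expect_equal(unname(lab1["P"]), "Normal")
  lab2 <- classify_against_intervals(site2_profile(), fx$intervals_state)
  expect_equal(unname(lab2["N"]), "Normal")
})

test_that("agreement statistic counts identical labels cell by cell", {
  labs_state <- lapply(fx$sites, function(s)
    classify_against_intervals(nutrient_profile(s), fx$intervals_state))
  labs_tn <- lapply(fx$sites, function(s)
    classify_against_intervals(nutrient_profile(s), fx$intervals_tn))
  ag <- interval_agreement(labs_state, labs_tn)
  expect_equal(ag$agreements, 12)
  expect_equal(ag$attempts, 22)

  expect_equal(interval_agreement(labs_tn, labs_tn)$fraction, 1)
  flipped <- lapply(labs_tn, function(l)
    ifelse(l == "Low", "High", ifelse(l == "High", "Low", "Mid")))
  expect_equal(interval_agreement(labs_tn, flipped)$agreements, 0)
  expect_error(interval_agreement(labs_tn, labs_tn[[1]]), "misaligned")
})

test_that("joint interval survival collapses as nutrients stack", {
  pop <- tiny_population(n = 489, seed = 13)
  iv <- quartile_intervals(pop)
  surv <- joint_interval_survival(pop, iv)
  expect_equal(surv$n, 489)
  # independent margins: expected fraction 0.5^11 ~ 5e-4
  expect_lte(surv$fraction, 0.02)

  # monotone collapse: survival is non-increasing as nutrients are added
  fracs <- sapply(c(3, 6, 9, 11), function(k) {
    ok <- rep(TRUE, nrow(pop))
    for (i in seq_len(k)) {
      col <- nutrient_columns()[match(iv$nutrient[i], nutrient_parts())]
      ok <- ok & pop[[col]] >= iv$lower[i] & pop[[col]] <= iv$upper[i]
    }
    mean(ok)
  })
  expect_true(all(diff(fracs) <= 0))

  # specimens at the interval midpoints all survive
  mids <- pop[rep(1, 5), ]
  for (i in seq_len(nrow(iv))) {
    col <- nutrient_columns()[match(iv$nutrient[i], nutrient_parts())]
    mids[[col]] <- (iv$lower[i] + iv$upper[i]) / 2
  }
  expect_equal(joint_interval_survival(mids, iv)$survivors, 5)
  # one violation removes exactly one survivor
  mids$n_g_kg[1] <- iv$upper[iv$nutrient == "N"] * 2
  expect_equal(joint_interval_survival(mids, iv)$survivors, 4)
})
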
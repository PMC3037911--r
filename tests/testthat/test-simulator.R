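test_that("bulk digestion curves start at 100% and never increase", {
  cfg <- simulation_config(n_nucleoids = 400, seed = 11L)
  for (cond in c("G0", "PHx24", "PHx7D")) {
    curve <- simulate_bulk_digestion(condition_profile(cond), cfg)
    expect_equal(curve$pct_bound[1], 100)
    expect_true(all(diff(curve$pct_bound) <= 0))
    expect_true(all(curve$pct_bound >= 0 & curve$pct_bound <= 100))
  }
})

test_that("without nuclease all DNA stays bound", {
  cfg <- simulation_config(n_nucleoids = 50, dnase_rate = 0, seed = 2L)
  curve <- simulate_bulk_digestion(condition_profile("G0"), cfg)
  expect_equal(curve$pct_bound, rep(100, length(cfg$times)))
})

test_that("a fixed seed fixes every simulator output bit for bit", {
  arch <- albumin_architecture()
  cfg <- simulation_config(n_nucleoids = 300, seed = 5L)
  p <- condition_profile("G0")
  expect_identical(simulate_bulk_digestion(p, cfg),
                   simulate_bulk_digestion(p, cfg))
  s1 <- simulate_amplicon_survival(arch, p, cfg)
  s2 <- simulate_amplicon_survival(arch, p, cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  cfg2 <- simulation_config(n_nucleoids = 300, seed = 6L)
  expect_false(identical(simulate_bulk_digestion(p, cfg)$pct_bound,
                         simulate_bulk_digestion(p, cfg2)$pct_bound))
})

test_that("amplicon survival is 1 at t = 0, non-increasing, and ordered by NM distance", {
  p <- condition_profile("G0")
  for (seed in c(1L, 23L, 404L)) {
    cfg <- simulation_config(n_nucleoids = 250, seed = seed)
    arch <- tiny_arch(amp_centers = c(450, 100), ids = c("far", "near"))
    surv <- simulate_amplicon_survival(arch, p, cfg)
    expect_true(all(surv$intact_fraction[surv$time_min == 0] == 1))
    for (id in c("far", "near")) {
      expect_true(all(diff(surv$intact_fraction[surv$amplicon == id]) <= 0))
    }
    # nm_distance 0.9 vs 0.2 in the same loop: distal template dies first
    far <- surv$intact_fraction[surv$amplicon == "far"]
    near <- surv$intact_fraction[surv$amplicon == "near"]
    expect_true(all(far <= near))
  }
})

test_that("with acceleration off, survival matches the exponential closed form", {
  arch <- tiny_arch(amp_centers = c(500, 300, 150), ids = c("x", "y", "z"))
  cfg <- simulation_config(n_nucleoids = 4000, seed = 9L, acceleration = 0)
  p <- condition_profile("G0")
  surv <- simulate_amplicon_survival(arch, p, cfg)
  d <- nm_distance(arch)
  for (i in seq_len(nrow(d))) {
    lambda <- cfg$dnase_rate * p$rate_multiplier *
      exp(-cfg$supercoil_steepness * (1 - d$nm_distance[i]))
    for (t in c(5, 15, 30)) {
      expected <- exp(-lambda * t)
      got <- surv$intact_fraction[surv$amplicon == d$amplicon[i] &
                                    surv$time_min == t]
      se <- sqrt(expected * (1 - expected) / cfg$n_nucleoids)
      expect_lt(abs(got - expected), 3 * se + 1e-12)
    }
  }
})

test_that("call_matrix applies the detection threshold with an always-present control", {
  mk_survival <- function(frac) {
    structure(
      tibble::tibble(
        amplicon = "a", nm_distance = 0.5,
        time_min = c(0, 5, 15, 30, 60), intact_fraction = frac
      ),
      class = c("amplicon_survival", class(tibble::tibble())),
      detection_threshold = 0.1
    )
  }
  cm <- call_matrix(mk_survival(c(1.0, 0.6, 0.2, 0.05, 0.01)))
  expect_equal(unlist(cm[1, c("C", "D", "P", "VC", "E")], use.names = FALSE),
               c("+", "+", "+", "-", "-"))
  cm0 <- call_matrix(mk_survival(c(1, 0, 0, 0, 0)))
  expect_equal(unlist(cm0[1, c("C", "D", "P", "VC", "E")], use.names = FALSE),
               c("+", "-", "-", "-", "-"))
  # a schedule time missing from the grid is an error
  bad <- mk_survival(c(1, .5, .3, .2, .1))
  bad$time_min <- c(0, 4, 15, 30, 60)
  expect_error(call_matrix(bad), "Missing time point")
})

test_that("template boosting lowers the threshold and never moves zones away", {
  arch <- albumin_architecture()
  cfg <- simulation_config(n_nucleoids = 2000, seed = 3L)
  surv <- simulate_amplicon_survival(arch, condition_profile("G0"), cfg)
  cm <- call_matrix(surv, condition = "G0")
  expect_identical(as.data.frame(boost_template(cm, 1)), as.data.frame(cm))
  expect_error(boost_template(cm, 0.5), ">= 1")
  z0 <- assign_zones(cm)
  z6 <- assign_zones(boost_template(cm, 6))
  expect_true(all(z6$ordinal >= z0$ordinal))
  # the six-fold boost uncovers template in the NM-embedded fraction
  expect_true(any(z6$ordinal == 4 & z0$ordinal < 4))
  # equivalent to re-calling at threshold / 6
  direct <- call_matrix(surv, detection_threshold = cfg$detection_threshold / 6,
                        condition = "G0")
  expect_identical(as.data.frame(boost_template(cm, 6)), as.data.frame(direct))
})

test_that("condition profiles enforce their invariants", {
  expect_error(
    new_condition_profile("x", c(distal = .5, proximal = .2,
                                 very_close = .2, embedded = .2)),
    "summing to 1"
  )
  expect_error(
    new_condition_profile("x", c(distal = .6, proximal = .1,
                                 very_close = .1, embedded = .2),
                          rate_multiplier = 0),
    "rate_multiplier"
  )
  # restored quiescence is modelled as identical to G0
  g0 <- condition_profile("G0")
  p7 <- condition_profile("PHx7D")
  expect_equal(p7$zone_mass, g0$zone_mass)
  expect_equal(p7$rate_multiplier, g0$rate_multiplier)
  expect_equal(p7$loop_contraction, g0$loop_contraction)
  # PHx-24: halved embedded mass, faster digestion
  phx <- condition_profile("PHx24")
  expect_equal(phx$zone_mass[["embedded"]], g0$zone_mass[["embedded"]] / 2)
  expect_gt(phx$rate_multiplier, 1)
  expect_error(simulation_config(times = c(1, 2)), "start at 0")
  expect_error(simulation_config(detection_threshold = 0), "0, 1")
})

test_that("caption-slope calibration carries the slope-implied masses", {
  p <- condition_profile("G0", calibration = "caption_slopes")
  # piecewise-linear removal at the printed slopes: 49% / 17% / 12.15%
  expect_equal(unname(p$zone_mass),
               c(0.490, 0.170, 0.1215, 0.2185), tolerance = 1e-12)
  expect_equal(sum(p$zone_mass), 1)
})
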
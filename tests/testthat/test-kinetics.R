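# Exact piecewise-linear curve with the given per-window slopes,
# independent of segment_phases (the oracle the fit must recover).
piecewise_curve <- function(slopes, breakpoints = c(0, 5, 15, 30, 60),
                            times = NULL) {
  times <- times %||% sort(unique(c(breakpoints,
                                    seq(0, max(breakpoints), by = 2.5))))
  knots_y <- 100 + cumsum(c(0, slopes * diff(breakpoints)))
  pct <- stats::approx(breakpoints, knots_y, xout = times)$y
  as_digestion_curve(
    tibble::tibble(condition = "piecewise", time_min = times, pct_bound = pct)
  )
}

test_that("segmentation recovers generating slopes on exact piecewise input", {
  slopes <- c(-9.80, -1.70, -0.47, -0.17)  # published G0 phase slopes
  curve <- piecewise_curve(slopes)
  seg <- segment_phases(curve)
  expect_equal(tidy(seg)$slope, slopes, tolerance = 1e-10)
  expect_equal(seg$residual,
               100 + sum(slopes * diff(c(0, 5, 15, 30, 60))),
               tolerance = 1e-10)
  # the PHx-24 and PHx-7D published slope sets are recovered just as exactly
  for (s in list(c(-12.52, -1.04, -0.38, -0.31),
                 c(-10.50, -1.21, -0.55, -0.15))) {
    expect_equal(tidy(segment_phases(piecewise_curve(s)))$slope, s,
                 tolerance = 1e-10)
  }
})

test_that("a constant curve yields zero slopes and residual 100", {
  curve <- as_digestion_curve(tibble::tibble(
    condition = "flat", time_min = c(0, 5, 10, 15, 20, 30, 45, 60),
    pct_bound = 100
  ))
  seg <- segment_phases(curve)
  expect_equal(tidy(seg)$slope, rep(0, 4))
  expect_equal(seg$residual, 100)
})

test_that("simulated G0 kinetics give the expected first-phase slope", {
  cfg <- simulation_config(n_nucleoids = 2000, seed = 1L,
                           times = c(0:15, seq(17.5, 60, by = 2.5)))
  curve <- simulate_bulk_digestion(condition_profile("G0"), cfg)
  seg <- segment_phases(curve)
  # ~60% removed over the first 5 min corresponds to a ~-12 %/min OLS slope
  expect_equal(tidy(seg)$slope[1], -12, tolerance = 1 / 12)
  # fitted slopes are non-positive with non-increasing magnitude
  expect_true(all(tidy(seg)$slope <= 0))
  expect_true(all(diff(abs(tidy(seg)$slope)) <= 0))
})

test_that("segmentation rejects under-sampled windows and mixed conditions", {
  sparse <- as_digestion_curve(tibble::tibble(
    time_min = c(0, 20, 40, 60), pct_bound = c(100, 50, 30, 20)
  ))
  expect_error(segment_phases(sparse), "fewer than 2 points")
  two <- dplyr::bind_rows(
    tibble::tibble(condition = "A", time_min = c(0, 60), pct_bound = c(100, 20)),
    tibble::tibble(condition = "B", time_min = c(0, 60), pct_bound = c(100, 10))
  )
  expect_error(segment_phases(two), "several conditions")
  expect_error(
    as_digestion_curve(tibble::tibble(time_min = c(0, 5),
                                      pct_bound = c(90, 80))),
    "100 at t = 0"
  )
})

test_that("zone schedules use window right endpoints as sampling times", {
  sched <- zone_schedule()
  expect_equal(sched$rep_time, c(5, 15, 30, 60))
  expect_equal(sched$zone, c("distal", "proximal", "very_close", "embedded"))
  expect_equal(sched$ordinal, 1:4)
  expect_equal(zone_schedule(c(0, 4, 12, 25, 50))$rep_time, c(4, 12, 25, 50))
  expect_true(all(sched$rep_time >= sched$t_start &
                    sched$rep_time <= sched$t_end))

  curve <- piecewise_curve(c(-9.8, -1.7, -0.47, -0.17))
  sched2 <- derive_zone_schedule(segment_phases(curve))
  expect_equal(sched2$rep_time, c(5, 15, 30, 60))
  expect_equal(attr(sched2, "residual_pct"),
               100 - 49 - 17 - 7.05 - 5.1, tolerance = 1e-9)
  seg3 <- segment_phases(curve, breakpoints = c(0, 15, 30, 60))
  expect_error(derive_zone_schedule(seg3), "four kinetic windows")
})

test_that("data-driven breakpoint search recovers true changepoints", {
  curve <- piecewise_curve(c(-9.8, -1.7, -0.47, -0.17),
                           times = sort(unique(c(
                             seq(0, 60, by = 2.5), 5, 15, 30
                           ))))
  expect_equal(find_breakpoints(curve), c(0, 5, 15, 30, 60))
})

test_that("condition comparison captures removal and residual contrasts", {
  cfg <- simulation_config(seed = 4L)
  g0 <- simulate_bulk_digestion(condition_profile("G0"), cfg)
  cmp_same <- compare_conditions(g0, g0)
  expect_equal(cmp_same$residual_ratio, 1.0)
  expect_equal(cmp_same$removal_difference, 0)

  phx24 <- simulate_bulk_digestion(condition_profile("PHx24"), cfg)
  cmp <- compare_conditions(g0, phx24)
  # the NM-embedded residual of replicating cells is about half the G0 value
  expect_equal(cmp$residual_ratio, 0.5, tolerance = 0.1 / 0.5)
  expect_gt(cmp$removal_difference, 0)

  phx7d <- simulate_bulk_digestion(condition_profile("PHx7D"), cfg)
  cmp7 <- compare_conditions(g0, phx7d)
  expect_equal(cmp7$residual_ratio, 1.0, tolerance = 0.1)

  short <- as_digestion_curve(tibble::tibble(time_min = c(0, 30),
                                             pct_bound = c(100, 50)))
  expect_error(compare_conditions(g0, short), "60 minutes")
})

test_that("digestion curves round-trip through TSV", {
  cfg <- simulation_config(n_nucleoids = 100, seed = 8L)
  curve <- simulate_bulk_digestion(condition_profile("G0"), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_digestion_curve(curve, path)
  expect_equal(as.data.frame(read_digestion_curve(path)),
               as.data.frame(curve))
})
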
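test_that("single-row zone assignment follows the rightmost-present rule", {
  expect_equal(assign_zone(c("+", "+", "-", "-", "-"))$zone, "distal")
  expect_equal(assign_zone(c("+", "+", "+", "+", "-"))$zone, "very_close")
  expect_equal(assign_zone(c("+", "-", "-", "-", "-"))$zone, "hypersensitive")
  expect_equal(assign_zone(c("+", "+", "+", "+", "+"))$zone, "embedded")
  # replicate-variability annotations never change the sign
  expect_equal(assign_zone(c("+", "+", "+", "-*", "-"))$ordinal, 2L)
  expect_true(assign_zone(c("+", "+", "+", "-*", "-"))$variable)
  # non-monotone rows resolve to the rightmost "+" with a warning
  expect_warning(z <- assign_zone(c("+", "-", "+", "-", "-")), "Non-monotone")
  expect_equal(z$ordinal, 2L)
  expect_true(z$non_monotone)
  # malformed rows
  expect_error(assign_zone(c("-", "+", "-", "-", "-")), "must be '\\+'")
  expect_error(assign_zone(c("+", "?", "-", "-", "-")), "Malformed")
  expect_error(assign_zone(c("+", "+", "-")), "exactly 5")
})

test_that("assignment ordinals are monotone in the calls", {
  # adding a "+" in a deeper column never decreases the ordinal
  base_rows <- list(
    c("+", "-", "-", "-", "-"), c("+", "+", "-", "-", "-"),
    c("+", "+", "+", "-", "-"), c("+", "+", "+", "+", "-")
  )
  for (row in base_rows) {
    o <- assign_zone(row)$ordinal
    for (k in 2:5) {
      deeper <- row
      deeper[k] <- "+"
      o2 <- suppressWarnings(assign_zone(deeper)$ordinal)
      expect_gte(o2, o)
    }
  }
})

test_that("encoded sample-specific table reproduces the published control map", {
  z <- fixture_zones("table3", "G0")
  expected <- c(a = 2, b = 1, c = 1, d = 2, e = 1, f = 1, g = 1, h = 2,
                i = 1, j = 1, k = 2, l = 1, m = 2, n = 1, o = 2)
  expect_equal(setNames(z$ordinal, z$amplicon), expected)
  z6 <- fixture_zones("table6", "G0")
  expect_equal(setNames(z6$ordinal, z6$amplicon),
               c(Fyn = 1, CD23 = 1, GFAP = 1, MPZ = 2))
  expect_equal(nrow(assign_zones(tibble::tibble(
    amplicon = character(), C = character(), D = character(),
    P = character(), VC = character(), E = character()
  ))), 0)
})

test_that("shift analysis reproduces the published 11-shifted pattern", {
  g0 <- fixture_zones("table3", "G0")
  phx24 <- fixture_zones("table3", "PHx24")
  shift <- shift_analysis(g0, phx24)
  g <- glance(shift)
  expect_equal(g$shifted_closer_by_one, 11)
  expect_equal(g$fixed, 4)
  expect_equal(g$moved_away, 0)
  expect_equal(sum(g$shifted_closer_total, g$fixed, g$moved_away), 15)
  # identical assignments: everything fixed
  same <- glance(shift_analysis(g0, g0))
  expect_equal(same$fixed, 15)
  expect_equal(same$shifted_closer_total + same$moved_away, 0)
  # mismatched amplicon sets are rejected
  expect_error(shift_analysis(g0, fixture_zones("table6", "G0")),
               "Mismatched")
})

test_that("G0-calibrated table shift counts match an independent manual tally", {
  # hand tally of the encoded G0-calibration matrix (control vs PHx-24):
  # +1: a, c, d, g, h, k, m, o; +2: b, e, f, i, j, l, n
  g0 <- fixture_zones("table2", "G0")
  phx24 <- fixture_zones("table2", "PHx24")
  shift <- shift_analysis(g0, phx24)
  expect_equal(sort(shift$amplicon[shift$delta == 1]),
               c("a", "c", "d", "g", "h", "k", "m", "o"))
  expect_equal(sort(shift$amplicon[shift$delta == 2]),
               c("b", "e", "f", "i", "j", "l", "n"))
  g <- glance(shift)
  expect_equal(g$shifted_closer_total, 15)
  expect_equal(g$fixed, 0)
  expect_equal(g$moved_away, 0)
})

test_that("trajectory classification recovers the published groups", {
  traj <- classify_trajectories(
    fixture_zones("table3", "G0"),
    fixture_zones("table3", "PHx24"),
    fixture_zones("table3", "PHx7D")
  )
  expect_equal(sort(traj$amplicon[traj$class == "fixed_proximal"]),
               c("a", "m"))
  expect_equal(sort(traj$amplicon[traj$class == "fixed_distal"]),
               c("c", "g"))
  expect_equal(sum(traj$class == "shifted_returned"), 8)
  expect_equal(sort(traj$amplicon[traj$class == "shifted_not_returned"]),
               c("e", "h", "k"))
  # e drops to hypersensitive at PHx-7D, which is not a return
  expect_equal(traj$ordinal_phx7d[traj$amplicon == "e"], 0L)

  # all three assignments identical: every amplicon is a fixed class/other
  g0 <- fixture_zones("table3", "G0")
  same <- classify_trajectories(g0, g0, g0)
  expect_true(all(same$class %in% c("fixed_proximal", "fixed_distal", "other")))
  expect_equal(sum(same$delta_phx24 != 0), 0)

  # the four unrelated genes all shift closer and return
  traj6 <- classify_trajectories(
    fixture_zones("table6", "G0"),
    fixture_zones("table6", "PHx24"),
    fixture_zones("table6", "PHx7D")
  )
  expect_equal(traj6$class, rep("shifted_returned", 4))
})

test_that("boosted-template fixture scores exactly five amplicons embedded", {
  z4 <- assign_zones(mapping_fixture("table4"))
  expect_equal(sort(z4$amplicon[z4$ordinal == 4]),
               c("a", "d", "h", "i", "k"))
  # drifting "+/-" entries are conservative absences but flagged variable
  expect_true(all(z4$variable[z4$amplicon %in% c("b", "c", "e", "j", "l")]))
  # relative to the standard-template G0 map, nothing moves away from the NM
  z2 <- fixture_zones("table2", "G0")
  shared <- intersect(z2$amplicon, z4$amplicon)
  d <- z4$ordinal[match(shared, z4$amplicon)] -
    z2$ordinal[match(shared, z2$amplicon)]
  expect_true(all(d >= 0))
})

test_that("simulated zone maps are consistent with NM distance", {
  arch <- albumin_architecture()
  for (seed in c(1L, 77L)) {
    cfg <- simulation_config(n_nucleoids = 1200, seed = seed)
    surv <- simulate_amplicon_survival(arch, condition_profile("G0"), cfg)
    z <- assign_zones(call_matrix(surv))
    d <- nm_distance(arch)
    ord <- z$ordinal[match(d$amplicon, z$amplicon)]
    idx <- order(d$nm_distance)
    expect_true(all(diff(ord[idx]) <= 0))
  }
})

test_that("call matrices round-trip through CSV", {
  fx <- mapping_fixture("table3")
  path <- withr::local_tempfile(fileext = ".csv")
  write_call_matrix(fx, path)
  expect_equal(as.data.frame(read_call_matrix(path)), as.data.frame(fx))
  expect_error(read_call_matrix(withr::local_tempfile(fileext = ".csv")),
               "not found")
})
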
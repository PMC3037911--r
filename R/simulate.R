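#' Condition profiles for nucleoid digestion
#'
#' A condition profile captures how the DNA of a nucleoid population is
#' distributed over the four topological zones and how fast it is cleaved,
#' for one proliferation state of the hepatocytes:
#'
#' * `G0` — quiescent cells. Default (`text_percentages` calibration) zone
#'   DNA-mass fractions 0.60 / 0.10 / 0.10 / 0.20 for distal / proximal /
#'   very close / embedded, reproducing the published digestion phases
#'   (~60% of total DNA removed in the first 5 min, ~10% in 5-15 min,
#'   ~10% in 15-60 min, ~20% residual).
#' * `PHx24` — 24 h after partial hepatectomy, the peak of DNA synthesis.
#'   Digestion is faster (`rate_multiplier` 1.3: ~70% removed by 5 min so
#'   ~30% remains NM-bound) and the nuclease-resistant NM-embedded mass is
#'   halved to 0.10 (active replication forks expose single-stranded DNA).
#'   `loop_contraction` 0.5 models the reel-in of the template towards the
#'   NM: the effective NM distance of every loop sequence is halved, which
#'   is what makes individual amplicons *more* persistent at PHx-24 even
#'   though bulk digestion is faster.
#' * `PHx7D` — 7 days after partial hepatectomy, regeneration complete and
#'   cells re-quiescent: identical to the `G0` profile.
#'
#' The alternative `caption_slopes` calibration derives zone masses from
#' the published per-phase slopes instead of the phase percentages (the two
#' are arithmetically inconsistent: a -9.80 %/min slope over 0-5 min
#' removes 49%, not 60%). Neither is "corrected"; `text_percentages` is the
#' default because the percentages define the zone masses used by the whole
#' analysis.
#'
#' @param condition One of `"G0"`, `"PHx24"`, `"PHx7D"`.
#' @param calibration `"text_percentages"` (default) or `"caption_slopes"`.
#' @return An object of class `condition_profile`: list with `name`,
#'   `zone_mass` (named fractions summing to 1), `rate_multiplier`,
#'   `embedded_resistance`, `loop_contraction`, `calibration`.
#' @export
condition_profile <- function(condition = c("G0", "PHx24", "PHx7D"),
                              calibration = c("text_percentages",
                                              "caption_slopes")) {
  condition <- match.arg(condition)
  calibration <- match.arg(calibration)
  masses <- list(
    text_percentages = list(
      G0    = c(distal = 0.60, proximal = 0.10, very_close = 0.10, embedded = 0.20),
      PHx24 = c(distal = 0.65, proximal = 0.125, very_close = 0.125, embedded = 0.10),
      PHx7D = c(distal = 0.60, proximal = 0.10, very_close = 0.10, embedded = 0.20)
    ),
    # Masses implied by piecewise-linear decay at the printed slopes:
    # phase removals are slope * window length, residual the remainder.
    caption_slopes = list(
      G0    = c(distal = 0.490, proximal = 0.170, very_close = 0.1215, embedded = 0.2185),
      PHx24 = c(distal = 0.626, proximal = 0.104, very_close = 0.150, embedded = 0.120),
      PHx7D = c(distal = 0.525, proximal = 0.121, very_close = 0.1275, embedded = 0.2265)
    )
  )
  new_condition_profile(
    name = condition,
    zone_mass = masses[[calibration]][[condition]],
    rate_multiplier = if (condition == "PHx24") 1.3 else 1.0,
    embedded_resistance = 0.0019,
    loop_contraction = if (condition == "PHx24") 0.5 else 0.0,
    calibration = calibration
  )
}

#' @rdname condition_profile
#' @param name Condition label.
#' @param zone_mass Named fractions of total DNA in the
#'   distal/proximal/very_close/embedded zones; must sum to 1.
#' @param rate_multiplier Dimensionless scaling of the base cleavage hazard
#'   (> 0).
#' @param embedded_resistance Hazard attenuation factor for NM-embedded DNA
#'   (near 0: embedded DNA is nearly nuclease-inaccessible).
#' @param loop_contraction Fraction by which effective amplicon NM
#'   distances shrink (0 = loops in their quiescent configuration).
#' @export
new_condition_profile <- function(name, zone_mass, rate_multiplier = 1,
                                  embedded_resistance = 0.0019,
                                  loop_contraction = 0,
                                  calibration = "custom") {
  zones <- c("distal", "proximal", "very_close", "embedded")
  if (!identical(sort(names(zone_mass)), sort(zones))) {
    abort("`zone_mass` must be named distal, proximal, very_close, embedded.")
  }
  zone_mass <- zone_mass[zones]
  if (any(zone_mass < 0 | zone_mass > 1) ||
      abs(sum(zone_mass) - 1) > 1e-9) {
    abort("Invariant violated: zone_mass components in [0,1] summing to 1.")
  }
  if (!is.numeric(rate_multiplier) || rate_multiplier <= 0) {
    abort("`rate_multiplier` must be > 0.")
  }
  if (loop_contraction < 0 || loop_contraction >= 1) {
    abort("`loop_contraction` must be in [0, 1).")
  }
  structure(
    list(
      name = name, zone_mass = zone_mass, rate_multiplier = rate_multiplier,
      embedded_resistance = embedded_resistance,
      loop_contraction = loop_contraction, calibration = calibration
    ),
    class = "condition_profile"
  )
}

#' Simulation settings for nucleoid digestion
#'
#' @param n_nucleoids Number of nucleoids in the simulated population
#'   (>= 1).
#' @param dnase_rate Base cleavage hazard at the loop tip, per minute.  The
#'   default 0.46 is calibrated so that, together with
#'   `supercoil_steepness` and `acceleration`, the G0 bulk curve reproduces
#'   the published digestion phases for 0.5 U/ml DNase I.
#' @param times Sampling grid in minutes, starting at 0.
#' @param detection_threshold Fraction of nucleoids with an intact template
#'   below which an amplicon is scored absent ("-"); the published
#'   "non-amplifiable level" is not quantified, default 0.1.
#' @param seed Integer seed; all stochastic draws derive from it, and a
#'   fixed seed fixes all outputs bit for bit.
#' @param supercoil_steepness Shape of the hazard-versus-NM-distance curve:
#'   hazard at relative distance `d` is
#'   `dnase_rate * exp(-supercoil_steepness * (1 - d))`, encoding the
#'   supercoiling/steric-protection gradient from tip to anchor.
#' @param acceleration Supercoil-loss acceleration: the cleavage hazard is
#'   inflated by `(1 + acceleration * cleaved_fraction)` as nicks unwind
#'   the loop; 0 recovers pure exponential survival.
#' @param embedding_cutoff Relative NM distance below which a sequence is
#'   treated as NM-embedded (uses the attenuated embedded hazard, no
#'   supercoil acceleration).
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_nucleoids = 2000,
                              dnase_rate = 0.46,
                              times = c(0:5, 7.5, 10, 12.5, 15, 20, 25, 30,
                                        40, 50, 60),
                              detection_threshold = 0.1,
                              seed = 1L,
                              supercoil_steepness = 4,
                              acceleration = 3,
                              embedding_cutoff = 0.05) {
  if (n_nucleoids < 1) abort("`n_nucleoids` must be >= 1.")
  if (length(times) < 1 || times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing and start at 0.")
  }
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    abort("`detection_threshold` must be in (0, 1).")
  }
  if (dnase_rate < 0) abort("`dnase_rate` must be >= 0.")
  structure(
    list(
      n_nucleoids = as.integer(n_nucleoids), dnase_rate = dnase_rate,
      times = as.numeric(times), detection_threshold = detection_threshold,
      seed = as.integer(seed), supercoil_steepness = supercoil_steepness,
      acceleration = acceleration, embedding_cutoff = embedding_cutoff
    ),
    class = "simulation_config"
  )
}

# Survival fraction at time t under hazard h inflated by supercoil loss:
# dS/dt = -h * (1 + a * (1 - S)) * S.  Closed form (b = 1 + a):
#   S(t) = b exp(-b h t) / (1 + a exp(-b h t)),
# reducing to exp(-h t) when a = 0.
survival_fraction <- function(t, hazard, acceleration = 0) {
  if (hazard == 0) return(rep(1, length(t)))
  b <- 1 + acceleration
  e <- exp(-b * hazard * t)
  b * e / (1 + acceleration * e)
}

# Inverse of survival_fraction in t: cleavage time at survival quantile u,
# used for inverse-transform sampling (u ~ Unif(0,1)).
cleavage_time <- function(u, hazard, acceleration = 0) {
  if (hazard == 0) return(rep(Inf, length(u)))
  b <- 1 + acceleration
  -log(u / (b - acceleration * u)) / (b * hazard)
}

# Cleavage hazard (per minute) at relative NM distance d.  Supercoiling and
# steric protection attenuate the hazard exponentially towards the anchor;
# below the embedding cutoff the sequence sits inside the NM and only the
# strongly attenuated embedded hazard applies.
hazard_at_distance <- function(d, config, profile) {
  base <- config$dnase_rate * profile$rate_multiplier
  ifelse(
    d < config$embedding_cutoff,
    base * profile$embedded_resistance,
    base * exp(-config$supercoil_steepness * (1 - d))
  )
}

# Representative NM distances of the three loop zones used for the bulk
# mass-fraction model; calibrated once, together with dnase_rate = 0.46,
# supercoil_steepness = 4 and acceleration = 3, against the published G0
# phase percentages (closed-form survival, no fitting to simulation output).
bulk_zone_distances <- function() {
  c(distal = 0.80, proximal = 0.45, very_close = 0.15)
}

#' Simulate bulk digestion of a nucleoid population
#'
#' Monte Carlo simulation of the % of total DNA still bound to the NM as a
#' limited concentration of DNase I digests the naked loop DNA.  Each
#' nucleoid's DNA is partitioned over the four topological zones by the
#' profile's `zone_mass`; each zone is cleaved at an exponential-type
#' hazard that increases with distance from the NM and is inflated as
#' cumulative cleavage unwinds supercoils (see [simulation_config()]).
#' NM-embedded DNA uses the attenuated `embedded_resistance` hazard with no
#' acceleration.  Per-nucleoid, per-zone cleavage times are drawn by
#' inverse-transform sampling from the closed-form survival law.
#'
#' @param profile A [condition_profile()].
#' @param config A [simulation_config()].
#' @return A `digestion_curve` tibble with columns `condition`, `time_min`,
#'   `pct_bound`; starts at 100% and is non-increasing.
#' @examples
#' simulate_bulk_digestion(condition_profile("G0"),
#'                         simulation_config(n_nucleoids = 200))
#' @export
simulate_bulk_digestion <- function(profile, config = simulation_config()) {
  stopifnot(inherits(profile, "condition_profile"),
            inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_nucleoids
  zones <- names(profile$zone_mass)
  d_rep <- bulk_zone_distances()
  base <- config$dnase_rate * profile$rate_multiplier
  hazards <- c(
    base * exp(-config$supercoil_steepness * (1 - d_rep)),
    embedded = base * profile$embedded_resistance
  )
  accel <- c(rep(config$acceleration, 3), 0)

  # n x 4 cleavage times; column z holds the time at which nucleoid i's
  # zone-z DNA is lost.
  u <- matrix(runif(n * 4L), nrow = n)
  pct <- vapply(config$times, function(t) {
    surv <- vapply(1:4, function(z) {
      mean(cleavage_time(u[, z], hazards[z], accel[z]) > t)
    }, numeric(1))
    100 * sum(profile$zone_mass * surv)
  }, numeric(1))
  # t = 0: all DNA bound by construction (cleavage times are positive).
  out <- tibble(
    condition = profile$name,
    time_min = config$times,
    pct_bound = pct
  )
  as_digestion_curve(out)
}

#' Simulate per-amplicon template survival
#'
#' For every amplicon in the architecture, simulates the fraction of
#' nucleoids in which the template is still intact at each sampling time.
#' The cleavage hazard is a monotone increasing function of the amplicon's
#' relative NM distance (`exp(-supercoil_steepness * (1 - d))` times the
#' base rate); amplicons below the embedding cutoff use the attenuated
#' embedded hazard.  A condition's `loop_contraction` shrinks effective
#' distances (`d * (1 - loop_contraction)`), modelling the reel-in of the
#' template towards the NM during S phase.  One uniform draw per nucleoid
#' is shared across amplicons (a nucleoid's overall digestion progress), so
#' the ordering "larger NM distance implies pointwise smaller survival"
#' holds exactly for every seed.
#'
#' @param arch A [loop_architecture()].
#' @inheritParams simulate_bulk_digestion
#' @return An `amplicon_survival` tibble with columns `amplicon`,
#'   `nm_distance`, `time_min`, `intact_fraction`.
#' @export
simulate_amplicon_survival <- function(arch, profile,
                                       config = simulation_config()) {
  stopifnot(inherits(arch, "loop_architecture"),
            inherits(profile, "condition_profile"),
            inherits(config, "simulation_config"))
  set.seed(config$seed)
  amp <- arch$amplicons
  d_eff <- amp$nm_distance * (1 - profile$loop_contraction)
  hazards <- hazard_at_distance(d_eff, config, profile)
  accel <- ifelse(d_eff < config$embedding_cutoff, 0, config$acceleration)

  u <- runif(config$n_nucleoids)
  rows <- purrr::map(seq_len(nrow(amp)), function(i) {
    tt <- cleavage_time(u, hazards[i], accel[i])
    tibble(
      amplicon = amp$id[i],
      nm_distance = amp$nm_distance[i],
      time_min = config$times,
      intact_fraction = vapply(config$times, function(t) mean(tt > t),
                               numeric(1))
    )
  })
  out <- bind_rows(rows)
  structure(
    out,
    class = c("amplicon_survival", class(tibble())),
    detection_threshold = config$detection_threshold
  )
}

#' Threshold survival trajectories into a presence/absence call matrix
#'
#' An amplicon is scored "+" at a zone's representative sampling time if
#' its intact fraction there is at least `detection_threshold` (the
#' template has not fallen to a non-amplifiable level), "-" otherwise.
#' Column `C` is the undigested t = 0 control and is always "+".
#'
#' @param survival An `amplicon_survival` tibble from
#'   [simulate_amplicon_survival()].
#' @param schedule A zone schedule from [zone_schedule()] or
#'   [derive_zone_schedule()]; its representative times must be present in
#'   the survival time grid.
#' @param detection_threshold Detection threshold in (0, 1); defaults to
#'   the threshold recorded on `survival`.
#' @param condition Condition label attached to the matrix.
#' @return An `amplicon_calls` tibble with columns `amplicon`, `C`, `D`,
#'   `P`, `VC`, `E`; the survival input, schedule and threshold are kept as
#'   attributes so the matrix can be re-called (see [boost_template()]).
#' @export
call_matrix <- function(survival, schedule = zone_schedule(),
                        detection_threshold = NULL, condition = NULL) {
  stopifnot(inherits(survival, "amplicon_survival") ||
              all(c("amplicon", "time_min", "intact_fraction") %in%
                    names(survival)))
  if (is.null(detection_threshold)) {
    detection_threshold <- attr(survival, "detection_threshold") %||% 0.1
  }
  rep_times <- c(0, schedule$rep_time)
  missing_t <- setdiff(rep_times, unique(survival$time_min))
  if (length(missing_t) > 0L) {
    abort(paste0(
      "Missing time point(s) in survival grid: ",
      paste(missing_t, collapse = ", "), " min."
    ))
  }
  amps <- unique(survival$amplicon)
  wide <- purrr::map(rep_times, function(t) {
    s <- survival[survival$time_min == t, ]
    s <- s[match(amps, s$amplicon), ]
    ifelse(s$intact_fraction >= detection_threshold, "+", "-")
  })
  out <- tibble(amplicon = amps)
  for (k in seq_along(call_columns())) out[[call_columns()[k]]] <- wide[[k]]
  out$C <- "+"  # t = 0 control: undigested template always amplifiable
  new_amplicon_calls(
    out,
    condition = condition,
    survival = survival, schedule = schedule,
    detection_threshold = detection_threshold
  )
}

new_amplicon_calls <- function(x, condition = NULL, survival = NULL,
                               schedule = NULL, detection_threshold = NULL) {
  structure(
    as_tibble(x),
    class = c("amplicon_calls", class(tibble())),
    condition = condition,
    survival = survival,
    schedule = schedule,
    detection_threshold = detection_threshold
  )
}

#' Re-call a matrix at a higher template concentration
#'
#' Raising the template concentration `fold`-fold lowers the effective
#' detection threshold by the same factor (the experiment that detects
#' NM-embedded targets by using 60 instead of 10 ng of NM-bound DNA is a
#' six-fold boost).  Zone assignments can only move closer to (or stay at)
#' the NM, never farther.
#'
#' @param calls An `amplicon_calls` matrix produced by [call_matrix()] (its
#'   survival attribute is required).
#' @param fold Template fold-increase, >= 1; `fold = 1` leaves the matrix
#'   unchanged.
#' @return An `amplicon_calls` tibble re-called at
#'   `detection_threshold / fold`.
#' @export
boost_template <- function(calls, fold) {
  stopifnot(inherits(calls, "amplicon_calls"))
  if (!is.numeric(fold) || length(fold) != 1L || fold < 1) {
    abort("`fold` must be a single number >= 1.")
  }
  survival <- attr(calls, "survival")
  if (is.null(survival)) {
    abort("`calls` carries no survival trajectories; re-call from call_matrix().")
  }
  call_matrix(
    survival,
    schedule = attr(calls, "schedule"),
    detection_threshold = attr(calls, "detection_threshold") / fold,
    condition = attr(calls, "condition")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
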
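#' Distance-to-zone thresholds from zone DNA-mass fractions
#'
#' The four topological zones are operationally defined by how much DNA
#' each contains (the digestion-kinetics phases), not by fixed distances.
#' This converts the zone-mass fractions into relative-NM-distance
#' thresholds: the embedded zone is the closest `zone_mass["embedded"]`
#' fraction of loop DNA, then very close, proximal and distal bands in
#' order of increasing distance.  The distance distribution of loop DNA is
#' evaluated on a uniform arc-length grid over the architecture's loops,
#' so the thresholds are the zone-mass quantiles of that distribution and
#' the mapping is monotone (smaller distance, higher ordinal).
#'
#' @param arch A [loop_architecture()].
#' @param zone_mass Named zone-mass fractions (default: the G0 profile's).
#' @param n_grid Number of arc-length grid points.
#' @return A tibble with columns `zone`, `ordinal`, `d_max` (upper
#'   distance bound of the zone; distal has `d_max = Inf`).
#' @export
zone_thresholds <- function(arch,
                            zone_mass = condition_profile("G0")$zone_mass,
                            n_grid = 20000) {
  stopifnot(inherits(arch, "loop_architecture"))
  loops <- arch$loops
  span <- sum(loops$anchor_right - loops$anchor_left)
  pos <- unlist(purrr::map(seq_len(nrow(loops)), function(i) {
    n_i <- max(2L, round(n_grid * (loops$anchor_right[i] -
                                     loops$anchor_left[i]) / span))
    seq(loops$anchor_left[i], loops$anchor_right[i] - 1e-6,
        length.out = n_i)
  }))
  d <- nm_distance_at(arch, pos)
  q <- quantile(
    d,
    probs = cumsum(c(zone_mass[["embedded"]], zone_mass[["very_close"]],
                     zone_mass[["proximal"]])),
    names = FALSE
  )
  tibble(
    zone = c("embedded", "very_close", "proximal", "distal"),
    ordinal = c(4L, 3L, 2L, 1L),
    d_max = c(q, Inf)
  )
}

# Map effective relative distances to zone ordinals given thresholds.
map_distance_to_zone <- function(d, thresholds) {
  vapply(d, function(x) {
    thresholds$ordinal[which(x <= thresholds$d_max)[1]]
  }, integer(1))
}

new_model_prediction <- function(model, s, amplicon, ordinal) {
  structure(
    tibble(model = model, s = s, amplicon = amplicon,
           ordinal = as.integer(ordinal)),
    class = c("model_prediction", class(tibble()))
  )
}

check_baseline_coverage <- function(arch, baseline) {
  missing <- setdiff(arch$amplicons$id, baseline$amplicon)
  if (length(missing) > 0L) {
    abort(paste0("Baseline does not cover amplicon(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

baseline_ordinals <- function(arch, baseline) {
  baseline$ordinal[match(arch$amplicons$id, baseline$amplicon)]
}

#' Tracking model of loop replication
#'
#' A replication complex that moves along a static template leaves every
#' loop sequence at its original position relative to the NM at all times,
#' so the prediction equals the baseline assignment for every S-phase
#' progress `s`.
#'
#' @param arch A [loop_architecture()].
#' @param baseline A `zone_assignment` covering all amplicons of `arch`
#'   (the quiescent-state observation).
#' @param s S-phase progress, fraction of loop DNA replicated in `[0, 1]`.
#' @param ... Unused; kept for a common signature across models.
#' @return A `model_prediction` tibble (`model`, `s`, `amplicon`,
#'   `ordinal`).
#' @export
predict_tracking <- function(arch, baseline, s = 0, ...) {
  stopifnot(inherits(arch, "loop_architecture"), s >= 0, s <= 1)
  check_baseline_coverage(arch, baseline)
  new_model_prediction("tracking", s, arch$amplicons$id,
                       baseline_ordinals(arch, baseline))
}

#' Tip reel-in model of loop replication
#'
#' The replication origin sits at the loop tip and binds the NM in late
#' G1, splitting each loop into two half-sized loops.  For any `s > 0`
#' every amplicon's effective NM distance is recomputed on its half-loop
#' (arc distance to the nearest of the original anchors and the newly
#' anchored tip, normalised by the half-loop's quarter span) and mapped to
#' a zone by the zone-mass quantile thresholds of the quiescent
#' architecture.  Anchoring the tip can only bring DNA closer to the NM,
#' so the predicted ordinal is floored at the baseline ordinal; at `s = 0`
#' the model coincides with tracking.  Under this model LAR-adjacent
#' sequences are the last to be replicated.
#'
#' @inheritParams predict_tracking
#' @param zone_mass Zone-mass fractions used for the distance-to-zone
#'   quantile mapping.
#' @export
predict_tip_reel_in <- function(arch, baseline, s = 0,
                                zone_mass = condition_profile("G0")$zone_mass,
                                ...) {
  stopifnot(inherits(arch, "loop_architecture"), s >= 0, s <= 1)
  check_baseline_coverage(arch, baseline)
  base_ord <- baseline_ordinals(arch, baseline)
  if (s == 0) {
    return(new_model_prediction("tip_reel_in", s, arch$amplicons$id, base_ord))
  }
  thr <- zone_thresholds(arch, zone_mass)
  amp <- arch$amplicons
  loops <- arch$loops
  li <- match(amp$loop, loops$id)
  p <- amp$center - loops$anchor_left[li]
  L <- loops$anchor_right[li] - loops$anchor_left[li]
  dist_bp <- pmin(p, abs(p - L / 2), L - p)
  d_eff <- pmin(1, dist_bp / (L / 4))
  ord <- pmax(map_distance_to_zone(d_eff, thr), base_ord)
  new_model_prediction("tip_reel_in", s, amp$id, ord)
}

#' LAR reel-in model of loop replication
#'
#' Replication origins sit next to the LAR anchors; the forks stay fixed
#' on the NM while the template is pulled symmetrically through them.  At
#' progress `s`, the forks of a loop of span `L` have consumed the
#' outermost `s*L/2` of template on each side.  An amplicon at arc
#' position `p` is:
#'
#' * already replicated (`p < s*L/2` or `p > L - s*L/2`): its daughter
#'   duplex has been extruded from the replication factory, restoring its
#'   original position — the prediction reverts to the baseline zone
#'   (variant `replicated = "embedded"` keeps it NM-embedded instead, for
#'   sensitivity analysis);
#' * not yet replicated: its effective NM distance is the arc distance to
#'   the nearest fork (normalised by the half-loop span), mapped to a zone
#'   by the zone-mass quantile thresholds — unreplicated sequences shift
#'   closer to the NM as `s` grows.
#'
#' At `s = 0` (no forks active) and `s = 1` (everything replicated and
#' extruded) the prediction equals the baseline.
#'
#' @inheritParams predict_tip_reel_in
#' @param replicated How already-replicated sequences are placed:
#'   `"revert"` (default, extrusion restores the original position) or
#'   `"embedded"`.
#' @export
predict_lar_reel_in <- function(arch, baseline, s = 0,
                                zone_mass = condition_profile("G0")$zone_mass,
                                replicated = c("revert", "embedded"),
                                ...) {
  stopifnot(inherits(arch, "loop_architecture"), s >= 0, s <= 1)
  replicated <- match.arg(replicated)
  check_baseline_coverage(arch, baseline)
  base_ord <- baseline_ordinals(arch, baseline)
  if (s == 0 || s == 1) {
    return(new_model_prediction("lar_reel_in", s, arch$amplicons$id, base_ord))
  }
  thr <- zone_thresholds(arch, zone_mass)
  amp <- arch$amplicons
  loops <- arch$loops
  li <- match(amp$loop, loops$id)
  p <- amp$center - loops$anchor_left[li]
  L <- loops$anchor_right[li] - loops$anchor_left[li]
  f1 <- s * L / 2
  f2 <- L - s * L / 2
  done <- p < f1 | p > f2
  d_eff <- pmin(p - f1, f2 - p) / (L / 2)
  ord <- integer(nrow(amp))
  ord[done] <- if (replicated == "revert") base_ord[done] else 4L
  ord[!done] <- map_distance_to_zone(d_eff[!done], thr)
  new_model_prediction("lar_reel_in", s, amp$id, ord)
}

#' Concordance between a model prediction and observed zones
#'
#' @param prediction A `model_prediction`.
#' @param observed A `zone_assignment` over the same amplicons.
#' @return Fraction in `[0, 1]` of amplicons whose predicted ordinal
#'   equals the observed ordinal.
#' @export
concordance <- function(prediction, observed) {
  check_same_amplicons(prediction, observed)
  obs <- observed$ordinal[match(prediction$amplicon, observed$amplicon)]
  mean(prediction$ordinal == obs)
}

#' Discriminate among loop-replication mechanisms
#'
#' Evaluates the concordance of the tracking, tip reel-in and LAR reel-in
#' models with an observed S-phase zone assignment over a grid of S-phase
#' progress values (the observation is an unknown population average over
#' S phase), and reports each model's best concordance and the overall
#' winner.  Ties are broken in model order (tracking, tip_reel_in,
#' lar_reel_in) and flagged.
#'
#' @param arch A [loop_architecture()].
#' @param baseline Quiescent-state `zone_assignment` (model input).
#' @param observed S-phase `zone_assignment` to score against.
#' @param s_grid Non-empty grid of progress values in `[0, 1]`; default 21
#'   evenly spaced points.
#' @param zone_mass Zone-mass fractions for the distance-to-zone mapping.
#' @return An object of class `model_verdict`: list with `scores` (tibble
#'   model x s x concordance; also via [tidy()]), `best` (per-model max,
#'   via [glance()]), `winner` and `tie`.
#' @examples
#' fx <- mapping_fixture("table3")
#' g0 <- assign_zones(dplyr::filter(fx, condition == "G0"))
#' phx <- assign_zones(dplyr::filter(fx, condition == "PHx24"))
#' discriminate(albumin_architecture(), g0, phx)
#' @export
discriminate <- function(arch, baseline, observed,
                         s_grid = seq(0, 1, length.out = 21),
                         zone_mass = condition_profile("G0")$zone_mass) {
  if (length(s_grid) == 0L) abort("`s_grid` must be non-empty.")
  if (any(s_grid < 0 | s_grid > 1)) abort("`s_grid` values must lie in [0, 1].")
  models <- list(
    tracking = predict_tracking,
    tip_reel_in = predict_tip_reel_in,
    lar_reel_in = predict_lar_reel_in
  )
  scores <- bind_rows(purrr::imap(models, function(fn, nm) {
    bind_rows(purrr::map(s_grid, function(s) {
      pred <- fn(arch, baseline, s = s, zone_mass = zone_mass)
      tibble(model = nm, s = s, concordance = concordance(pred, observed))
    }))
  }))
  best <- scores %>%
    group_by(.data$model) %>%
    summarise(
      s_best = .data$s[which.max(.data$concordance)],
      concordance_max = max(.data$concordance),
      .groups = "drop"
    )
  best <- best[match(names(models), best$model), ]
  top <- max(best$concordance_max)
  winners <- best$model[best$concordance_max == top]
  structure(
    list(
      scores = scores,
      best = best,
      winner = winners[1],
      tie = length(winners) > 1L
    ),
    class = "model_verdict"
  )
}

#' @export
print.model_verdict <- function(x, ...) {
  cat("<model_verdict> winner:", x$winner,
      if (x$tie) "(tie, broken by model order)" else "", "\n")
  print(x$best)
  invisible(x)
}

#' @export
tidy.model_verdict <- function(x, ...) x$scores

#' @export
glance.model_verdict <- function(x, ...) {
  mutate(x$best, winner = .data$model == x$winner, tie = x$tie)
}

#' Serialise a model verdict to JSON
#'
#' @param verdict A [discriminate()] result.
#' @param path Output `.json` path.
#' @export
write_verdict <- function(verdict, path) {
  stopifnot(inherits(verdict, "model_verdict"))
  jsonlite::write_json(
    list(winner = verdict$winner, tie = verdict$tie, best = verdict$best),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
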
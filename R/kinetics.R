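#' Digestion curve constructor / validator
#'
#' A digestion curve records the percentage of total DNA still bound to
#' the NM over digestion time for one condition.  Times must be strictly
#' increasing starting at 0, the curve must start at 100%, and all values
#' must lie in `[0, 100]`.
#'
#' @param df Data frame with columns `time_min`, `pct_bound` and
#'   optionally `condition`.
#' @return A `digestion_curve` tibble.
#' @export
as_digestion_curve <- function(df) {
  df <- as_tibble(df)
  if (!all(c("time_min", "pct_bound") %in% names(df))) {
    abort("A digestion curve needs columns `time_min` and `pct_bound`.")
  }
  if (!"condition" %in% names(df)) df$condition <- "unknown"
  for (cc in unique(df$condition)) {
    sub <- df[df$condition == cc, ]
    if (sub$time_min[1] != 0 || is.unsorted(sub$time_min, strictly = TRUE)) {
      abort("Invariant violated: times strictly increasing, starting at 0.")
    }
    if (abs(sub$pct_bound[1] - 100) > 1e-6) {
      abort("Invariant violated: pct_bound must be 100 at t = 0.")
    }
  }
  if (any(df$pct_bound < -1e-9 | df$pct_bound > 100 + 1e-9)) {
    abort("Invariant violated: pct_bound within [0, 100].")
  }
  structure(df[, c("condition", "time_min", "pct_bound")],
            class = c("digestion_curve", class(tibble())))
}

#' Read / write digestion curves as TSV
#'
#' Curves are stored as tab-separated text with columns `time_min`,
#' `pct_bound`, `condition`.
#'
#' @param path File path.
#' @export
read_digestion_curve <- function(path) {
  as_digestion_curve(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_digestion_curve
#' @param curve A `digestion_curve`.
#' @export
write_digestion_curve <- function(curve, path) {
  readr::write_tsv(curve, path)
  invisible(path)
}

#' Segment a digestion curve into kinetic phases
#'
#' Fits an ordinary least-squares slope to the points of each breakpoint
#' window.  Windows are closed on both ends, so a point on a shared
#' boundary contributes to both adjacent windows (the published windows
#' "0 - 5", "5 - 15", ... are closed).  The residual is the percentage
#' still bound at the final breakpoint time (linearly interpolated if not
#' sampled).  Default breakpoints `(0, 5, 15, 30, 60)` reproduce the
#' published phase windows; see [find_breakpoints()] for a data-driven
#' alternative.
#'
#' @param curve A `digestion_curve` (see [as_digestion_curve()]).
#' @param breakpoints Increasing numeric vector starting at 0; each window
#'   must contain at least two curve points.
#' @return An object of class `phase_segmentation` with a per-window slope
#'   table (`tidy()`), residual (`glance()`), and the breakpoints used.
#' @examples
#' curve <- simulate_bulk_digestion(condition_profile("G0"),
#'                                  simulation_config(n_nucleoids = 500))
#' tidy(segment_phases(curve))
#' @export
segment_phases <- function(curve, breakpoints = c(0, 5, 15, 30, 60)) {
  curve <- as_digestion_curve(curve)
  if (length(unique(curve$condition)) > 1L) {
    abort("`curve` holds several conditions; filter to one before segmenting.")
  }
  if (length(breakpoints) < 2L || breakpoints[1] != 0 ||
      is.unsorted(breakpoints, strictly = TRUE)) {
    abort("`breakpoints` must be strictly increasing and start at 0.")
  }
  if (max(breakpoints) > max(curve$time_min) + 1e-9) {
    abort("`breakpoints` extend beyond the sampled times.")
  }
  eps <- 1e-9
  windows <- purrr::map(seq_len(length(breakpoints) - 1L), function(k) {
    t0 <- breakpoints[k]
    t1 <- breakpoints[k + 1L]
    pts <- curve[curve$time_min >= t0 - eps & curve$time_min <= t1 + eps, ]
    if (nrow(pts) < 2L) {
      abort(paste0("Window [", t0, ", ", t1, "] contains fewer than 2 points."))
    }
    fit <- lm(pct_bound ~ time_min, data = pts)
    tibble(
      phase = k, t_start = t0, t_end = t1,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      n_points = nrow(pts)
    )
  })
  residual <- approx(curve$time_min, curve$pct_bound,
                     xout = max(breakpoints))$y
  structure(
    list(
      condition = curve$condition[1],
      breakpoints = breakpoints,
      windows = bind_rows(windows),
      residual = residual
    ),
    class = "phase_segmentation"
  )
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation> condition:", x$condition,
      "| residual:", round(x$residual, 2), "%\n")
  print(x$windows)
  invisible(x)
}

#' @export
tidy.phase_segmentation <- function(x, ...) x$windows

#' @export
glance.phase_segmentation <- function(x, ...) {
  tibble(
    condition = x$condition,
    n_phases = nrow(x$windows),
    residual_pct = x$residual,
    final_time = max(x$breakpoints)
  )
}

#' Serialise a phase segmentation to JSON
#'
#' @param seg A [segment_phases()] result.
#' @param path Output `.json` path.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "phase_segmentation"))
  jsonlite::write_json(
    list(
      condition = seg$condition,
      breakpoints = seg$breakpoints,
      windows = seg$windows,
      residual = seg$residual
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Data-driven breakpoint search
#'
#' Chooses the interior breakpoints (over the observed sampling times)
#' that minimise the summed squared residuals of the per-window OLS fits.
#' Off by default in the rest of the package: the published analysis fixes
#' the windows at (0, 5, 15, 30, 60) minutes.
#'
#' @param curve A `digestion_curve`.
#' @param n_phases Number of kinetic windows (default 4).
#' @return Numeric breakpoint vector of length `n_phases + 1`.
#' @export
find_breakpoints <- function(curve, n_phases = 4) {
  curve <- as_digestion_curve(curve)
  times <- curve$time_min
  t_end <- max(times)
  interior <- times[times > 0 & times < t_end]
  if (length(interior) < n_phases - 1L) {
    abort("Too few sampled times for the requested number of phases.")
  }
  cands <- combn(interior, n_phases - 1L)
  sse_of <- function(bp) {
    tryCatch({
      seg <- segment_phases(curve, bp)
      sum(vapply(seq_len(nrow(seg$windows)), function(k) {
        w <- seg$windows[k, ]
        pts <- curve[curve$time_min >= w$t_start & curve$time_min <= w$t_end, ]
        sum((pts$pct_bound - (w$intercept + w$slope * pts$time_min))^2)
      }, numeric(1)))
    }, error = function(e) Inf)
  }
  scores <- apply(cands, 2, function(b) sse_of(c(0, b, t_end)))
  best <- cands[, which.min(scores)]
  c(0, best, t_end)
}

#' Topological-zone schedule
#'
#' Maps the four kinetic windows of a digestion curve to the four
#' topological zones relative to the NM: window 1 is the distal zone
#' (ordinal 1), then proximal (2), very close (3) and embedded (4); larger
#' ordinals are closer to the NM, and ordinal 0 is reserved for sequences
#' already lost at the distal sampling time.  The representative sampling
#' time of each zone is the right endpoint of its window, i.e.
#' `(5, 15, 30, 60)` minutes by default.
#'
#' @param breakpoints Window breakpoints, length 5, starting at 0.
#' @return A tibble with columns `zone`, `ordinal`, `t_start`, `t_end`,
#'   `rep_time`.
#' @export
zone_schedule <- function(breakpoints = c(0, 5, 15, 30, 60)) {
  if (length(breakpoints) != 5L || breakpoints[1] != 0 ||
      is.unsorted(breakpoints, strictly = TRUE)) {
    abort("`breakpoints` must be five increasing values starting at 0.")
  }
  tibble(
    zone = zone_levels()[-1L],
    ordinal = 1:4,
    t_start = breakpoints[1:4],
    t_end = breakpoints[2:5],
    rep_time = breakpoints[2:5]
  )
}

#' @rdname zone_schedule
#' @param seg A four-window [segment_phases()] result; the embedded zone is
#'   tagged with the curve's residual percentage (attribute
#'   `residual_pct`).
#' @export
derive_zone_schedule <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  if (nrow(seg$windows) != 4L) {
    abort("A zone schedule needs exactly four kinetic windows.")
  }
  out <- zone_schedule(seg$breakpoints)
  attr(out, "residual_pct") <- seg$residual
  attr(out, "condition") <- seg$condition
  out
}

#' Compare digestion kinetics between two conditions
#'
#' Summarises the two headline contrasts of the assay: how much DNA is
#' removed within the first 5 minutes, and the ratio of the 60-minute
#' NM-embedded residuals (test over reference).  Values off the sampling
#' grid are linearly interpolated.
#'
#' @param curve_a Reference `digestion_curve` (e.g. G0).
#' @param curve_b Test `digestion_curve` (e.g. PHx-24).
#' @return A one-row tibble with removal-at-5-min for each curve, their
#'   difference (`b - a`), the 60-min residuals and `residual_ratio`
#'   (`b / a`).
#' @export
compare_conditions <- function(curve_a, curve_b) {
  curve_a <- as_digestion_curve(curve_a)
  curve_b <- as_digestion_curve(curve_b)
  if (length(unique(curve_a$condition)) > 1L ||
      length(unique(curve_b$condition)) > 1L) {
    abort("Each curve must hold a single condition.")
  }
  if (max(curve_a$time_min) < 60 || max(curve_b$time_min) < 60) {
    abort("Both curves must extend to at least 60 minutes.")
  }
  at <- function(curve, t) approx(curve$time_min, curve$pct_bound, xout = t)$y
  removed_a <- 100 - at(curve_a, 5)
  removed_b <- 100 - at(curve_b, 5)
  res_a <- at(curve_a, 60)
  res_b <- at(curve_b, 60)
  tibble(
    condition_a = curve_a$condition[1],
    condition_b = curve_b$condition[1],
    removed_by_5min_a = removed_a,
    removed_by_5min_b = removed_b,
    removal_difference = removed_b - removed_a,
    residual_60min_a = res_a,
    residual_60min_b = res_b,
    residual_ratio = res_b / res_a
  )
}
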
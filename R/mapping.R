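#' Parse a presence/absence call token
#'
#' Call matrices use "+" / "-" with two annotations carried over from the
#' source tables: a trailing "*" marks entries that varied between
#' replicate animals, and "+/-" marks entries that drifted between
#' experiments.  The annotation never changes the sign used for zone
#' assignment: "+*" counts as present, "-*" as absent, and "+/-" as absent
#' (a drifting signal is not a reproducible detection) — this convention
#' exactly reproduces the published shift counts, which are the only
#' available validation.
#'
#' @param x Character vector of call tokens.
#' @return A list with character `sign` ("+" or "-") and logical
#'   `variable`.
#' @keywords internal
parse_calls <- function(x) {
  x <- trimws(x)
  ok <- x %in% c("+", "-", "+*", "-*", "+/-")
  if (any(!ok)) {
    abort(paste0("Malformed call token(s): ",
                 paste(unique(x[!ok]), collapse = ", ")))
  }
  list(
    sign = ifelse(x %in% c("+", "+*"), "+", "-"),
    variable = x %in% c("+*", "-*", "+/-")
  )
}

#' Assign a topological zone from one row of calls
#'
#' The zone ordinal is the index of the deepest (rightmost) column scored
#' present among D, P, VC, E — a template that stays amplifiable at longer
#' digestion times lies closer to the NM.  The t = 0 control column C must
#' be present and does not count towards the ordinal; a row that is absent
#' in every post-control column is "hypersensitive" (ordinal 0, lost
#' before the distal sampling time).  A "+" after a "-" (never seen in the
#' source tables) is resolved by the rightmost "+" and flagged
#' `non_monotone` with a warning.
#'
#' @param calls Character vector of 5 call tokens in column order C, D, P,
#'   VC, E.
#' @return A one-row tibble with `ordinal`, `zone`, `non_monotone`,
#'   `variable` (any replicate-variability annotation in the row).
#' @examples
#' assign_zone(c("+", "+", "-", "-", "-"))   # distal
#' assign_zone(c("+", "+", "+", "+", "-"))   # very close
#' @export
assign_zone <- function(calls) {
  if (length(calls) != 5L) {
    abort("A call row has exactly 5 entries (C, D, P, VC, E).")
  }
  parsed <- parse_calls(calls)
  if (parsed$sign[1] != "+") {
    abort("Malformed row: control column C must be '+'.")
  }
  post <- parsed$sign[-1L] == "+"
  ordinal <- if (any(post)) max(which(post)) else 0L
  non_monotone <- any(post) && any(!post[seq_len(ordinal)])
  if (non_monotone) {
    warn("Non-monotone call row (a '+' after a '-'); using the rightmost '+'.")
  }
  tibble(
    ordinal = as.integer(ordinal),
    zone = zone_label(ordinal),
    non_monotone = non_monotone,
    variable = any(parsed$variable)
  )
}

#' Assign zones to every amplicon of a call matrix
#'
#' Row-wise [assign_zone()] preserving amplicon order.  If the matrix
#' carries several conditions (a `condition` column), each condition is
#' assigned separately.
#'
#' @param calls An `amplicon_calls` tibble, or any data frame with an
#'   `amplicon` column, optional `condition` column, and call columns C,
#'   D, P, VC, E.
#' @return A `zone_assignment` tibble with columns `condition` (if
#'   present), `amplicon`, `ordinal`, `zone`, `non_monotone`, `variable`.
#' @export
assign_zones <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0L) {
    return(structure(
      tibble(amplicon = character(), ordinal = integer(), zone = character(),
             non_monotone = logical(), variable = logical()),
      class = c("zone_assignment", class(tibble()))
    ))
  }
  if (!all(call_columns() %in% names(calls))) {
    abort("Call matrix must have columns C, D, P, VC, E.")
  }
  rows <- purrr::map(seq_len(nrow(calls)), function(i) {
    row <- tryCatch(
      assign_zone(unlist(calls[i, call_columns()], use.names = FALSE)),
      error = function(e) {
        abort(paste0("Row '", calls$amplicon[i], "': ", conditionMessage(e)))
      }
    )
    row$amplicon <- calls$amplicon[i]
    if ("condition" %in% names(calls)) row$condition <- calls$condition[i]
    row
  })
  out <- bind_rows(rows)
  front <- intersect(c("condition", "amplicon"), names(out))
  out <- out[, c(front, setdiff(names(out), front))]
  structure(out, class = c("zone_assignment", class(tibble())))
}

#' Shift analysis between two zone assignments
#'
#' Computes the per-amplicon zone change between a control and a test
#' condition.  `delta = ordinal_test - ordinal_control`, so positive
#' values mean the sequence moved closer to the NM.  "Closer" is strictly
#' ordinal (no fractional zones), and a sequence that drops to ordinal 0
#' (hypersensitive) has moved away from its control zone.
#'
#' @param control,test `zone_assignment` tibbles over the same amplicons.
#' @return A `zone_shift` tibble with columns `amplicon`,
#'   `ordinal_control`, `ordinal_test`, `delta`, `status`; summary counts
#'   via [glance()].
#' @examples
#' fx <- mapping_fixture("table3")
#' g0 <- assign_zones(dplyr::filter(fx, condition == "G0"))
#' phx <- assign_zones(dplyr::filter(fx, condition == "PHx24"))
#' glance(shift_analysis(g0, phx))
#' @export
shift_analysis <- function(control, test) {
  check_same_amplicons(control, test)
  out <- tibble(
    amplicon = control$amplicon,
    ordinal_control = control$ordinal,
    ordinal_test = test$ordinal[match(control$amplicon, test$amplicon)]
  )
  out$delta <- out$ordinal_test - out$ordinal_control
  out$status <- case_when(
    out$delta > 0 ~ "shifted_closer",
    out$delta == 0 ~ "fixed",
    TRUE ~ "moved_away"
  )
  structure(out, class = c("zone_shift", class(tibble())))
}

check_same_amplicons <- function(a, b, c = NULL) {
  sets <- list(a$amplicon, b$amplicon, if (!is.null(c)) c$amplicon)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  ref <- sort(sets[[1]])
  same <- all(vapply(sets, function(s) identical(sort(s), ref), logical(1)))
  if (!same) abort("Mismatched amplicon sets between assignments.")
  invisible(TRUE)
}

#' @export
glance.zone_shift <- function(x, ...) {
  tibble(
    n = nrow(x),
    shifted_closer_by_one = sum(x$delta == 1),
    shifted_closer_total = sum(x$delta > 0),
    fixed = sum(x$delta == 0),
    moved_away = sum(x$delta < 0),
    mean_delta = mean(x$delta)
  )
}

#' @export
tidy.zone_shift <- function(x, ...) as_tibble(x)

#' Classify amplicon trajectories across the proliferation cycle
#'
#' Given assignments for quiescent (control), peak-S-phase (PHx-24) and
#' re-quiescent (PHx-7D) samples, classifies each amplicon:
#'
#' * `fixed_proximal` — proximal (ordinal 2) at both control and PHx-24;
#' * `fixed_distal` — distal (ordinal 1) at both;
#' * `shifted_returned` — moved closer at PHx-24 and back to exactly its
#'   control ordinal at PHx-7D;
#' * `shifted_not_returned` — moved closer but did not return (a return to
#'   ordinal 0 when the control was 1 is *not* a return);
#' * `other` — anything else.
#'
#' @param control,phx24,phx7d `zone_assignment` tibbles over the same
#'   amplicons.
#' @return A `trajectory_classification` tibble with per-amplicon ordinals,
#'   `delta_phx24`, `returned` and `class`; counts via [glance()].
#' @export
classify_trajectories <- function(control, phx24, phx7d) {
  check_same_amplicons(control, phx24, phx7d)
  out <- tibble(
    amplicon = control$amplicon,
    ordinal_control = control$ordinal,
    ordinal_phx24 = phx24$ordinal[match(control$amplicon, phx24$amplicon)],
    ordinal_phx7d = phx7d$ordinal[match(control$amplicon, phx7d$amplicon)]
  )
  out$delta_phx24 <- out$ordinal_phx24 - out$ordinal_control
  out$returned <- out$delta_phx24 > 0 &
    out$ordinal_phx7d == out$ordinal_control
  out$class <- case_when(
    out$ordinal_control == 2 & out$ordinal_phx24 == 2 ~ "fixed_proximal",
    out$ordinal_control == 1 & out$ordinal_phx24 == 1 ~ "fixed_distal",
    out$delta_phx24 > 0 & out$returned ~ "shifted_returned",
    out$delta_phx24 > 0 & !out$returned ~ "shifted_not_returned",
    TRUE ~ "other"
  )
  structure(out, class = c("trajectory_classification", class(tibble())))
}

#' @export
glance.trajectory_classification <- function(x, ...) {
  tibble(
    n = nrow(x),
    fixed_proximal = sum(x$class == "fixed_proximal"),
    fixed_distal = sum(x$class == "fixed_distal"),
    shifted_returned = sum(x$class == "shifted_returned"),
    shifted_not_returned = sum(x$class == "shifted_not_returned"),
    other = sum(x$class == "other")
  )
}

#' @export
tidy.trajectory_classification <- function(x, ...) as_tibble(x)

#' Read / write a call-matrix CSV
#'
#' CSV with columns `condition` (optional), `amplicon`, `C`, `D`, `P`,
#' `VC`, `E`; cells are "+", "-", "+*", "-*" or "+/-" (see
#' [parse_calls()]).  Extra columns are preserved.
#'
#' @param path File path.
#' @return An `amplicon_calls` tibble (long over conditions if a
#'   `condition` column is present).
#' @export
read_call_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("amplicon", call_columns()) %in% names(df))) {
    abort("Call-matrix CSV must have columns amplicon, C, D, P, VC, E.")
  }
  parse_calls(unlist(df[, call_columns()]))  # validate tokens early
  new_amplicon_calls(df)
}

#' @rdname read_call_matrix
#' @param calls An `amplicon_calls` tibble.
#' @export
write_call_matrix <- function(calls, path) {
  readr::write_csv(as_tibble(calls), path)
  invisible(path)
}

#' Encoded published call-matrix fixtures
#'
#' Returns one of the call matrices shipped with the package, encoded
#' verbatim from the source tables:
#'
#' * `"table2"` — 15 albumin-region amplicons, zones calibrated on the G0
#'   digestion kinetics for all three conditions.
#' * `"table3"` — same amplicons, zones calibrated on each sample's own
#'   kinetics (the primary analysis).
#' * `"table4"` — G0 samples re-amplified with a six-fold template boost
#'   (12 amplicons, extra column `n_experiments`).
#' * `"table6"` — four unrelated genes, sample-specific calibration.
#' * `"table6_g0"` — four unrelated genes, G0 calibration.
#'
#' @param name Fixture name.
#' @return An `amplicon_calls` tibble with a `condition` column.
#' @export
mapping_fixture <- function(name = c("table2", "table3", "table4",
                                     "table6", "table6_g0")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "loopmapr",
                      mustWork = TRUE)
  read_call_matrix(path)
}
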
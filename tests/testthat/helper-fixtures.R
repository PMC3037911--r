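# Minimal single-loop architecture: one 1000 bp loop, tip at 500.
tiny_arch <- function(amp_centers = 500, amp_len = 100, ids = NULL) {
  ids <- ids %||% letters[seq_along(amp_centers)]
  loopmapr::loop_architecture(
    loops = tibble::tibble(id = "L1", anchor_left = 0, anchor_right = 1000),
    amplicons = tibble::tibble(
      id = ids,
      start = amp_centers - amp_len / 2,
      end = amp_centers + amp_len / 2
    ),
    region_length = 1000
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zone assignments for one condition of a shipped fixture matrix.
fixture_zones <- function(name, condition) {
  fx <- loopmapr::mapping_fixture(name)
  loopmapr::assign_zones(fx[fx$condition == condition, ])
}
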
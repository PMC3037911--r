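#' Loop architecture of a genomic region
#'
#' A `loop_architecture` describes how a genomic region is organised into
#' structural DNA loops anchored to the nuclear matrix (NM), and where the
#' PCR target amplicons sit along those loops.  Loops are defined by their
#' two loop anchorage regions (LARs, the `anchor_left`/`anchor_right`
#' midpoints on the NM) and a `tip`, the point of maximal NM distance
#' (default: the loop midpoint).  All coordinates are 0-based half-open
#' base pairs relative to the region start; strand is ignored because the
#' digestion assay is strand-agnostic.
#'
#' Validation enforces: `anchor_left < tip < anchor_right`; loops ordered
#' and non-overlapping (adjacent loops may share an anchor); every amplicon
#' midpoint falling within exactly one loop's `[anchor_left, anchor_right)`;
#' `0 <= start < end <= region_length` for every amplicon.
#'
#' @param loops Data frame with columns `id`, `anchor_left`, `anchor_right`
#'   and optionally `tip` (defaults to the loop midpoint).
#' @param amplicons Data frame with columns `id`, `start`, `end` and
#'   optionally `chromosome`.
#' @param region_length Length of the region in base pairs.
#'
#' @return An object of class `loop_architecture`: a list with elements
#'   `region_length`, `loops` (tibble) and `amplicons` (tibble; gains
#'   `length`, `center`, `loop` and `nm_distance` columns).
#' @seealso [albumin_architecture()], [read_architecture()], [nm_distance()]
#' @export
loop_architecture <- function(loops, amplicons, region_length) {
  if (!is.numeric(region_length) || length(region_length) != 1L ||
      region_length <= 0) {
    abort("`region_length` must be a single positive number.")
  }
  loops <- as_tibble(loops)
  amplicons <- as_tibble(amplicons)
  for (col in c("id", "anchor_left", "anchor_right")) {
    if (!col %in% names(loops)) {
      abort(paste0("`loops` is missing required column `", col, "`."))
    }
  }
  for (col in c("id", "start", "end")) {
    if (!col %in% names(amplicons)) {
      abort(paste0("`amplicons` is missing required column `", col, "`."))
    }
  }
  if (!"tip" %in% names(loops)) {
    loops$tip <- (loops$anchor_left + loops$anchor_right) / 2
  }
  if (!"chromosome" %in% names(amplicons)) amplicons$chromosome <- "chrUn"
  loops <- loops[, c("id", "anchor_left", "anchor_right", "tip")]
  loops <- arrange(loops, .data$anchor_left)

  if (anyDuplicated(loops$id)) abort("Loop ids must be unique.")
  if (any(!(loops$anchor_left < loops$tip & loops$tip < loops$anchor_right))) {
    abort("Invariant violated: each loop needs anchor_left < tip < anchor_right.")
  }
  if (nrow(loops) > 1L) {
    gap <- loops$anchor_left[-1L] - loops$anchor_right[-nrow(loops)]
    if (any(gap < 0)) {
      abort("Invariant violated: loops overlap; loops must be ordered and non-overlapping.")
    }
  }
  if (any(loops$anchor_left < 0) || any(loops$anchor_right > region_length)) {
    abort("Invariant violated: loop anchors must lie within [0, region_length].")
  }

  if (anyDuplicated(amplicons$id)) abort("Amplicon ids must be unique.")
  if (any(!(amplicons$start >= 0 & amplicons$start < amplicons$end))) {
    abort("Invariant violated: amplicons need 0 <= start < end.")
  }
  if (any(amplicons$end > region_length)) {
    abort("Invariant violated: amplicon end exceeds region_length.")
  }
  amplicons$length <- amplicons$end - amplicons$start
  amplicons$center <- (amplicons$start + amplicons$end) / 2

  loop_of <- vapply(amplicons$center, function(p) {
    hit <- which(p >= loops$anchor_left & p < loops$anchor_right)
    if (length(hit) != 1L) NA_integer_ else hit
  }, integer(1))
  if (anyNA(loop_of)) {
    orphans <- amplicons$id[is.na(loop_of)]
    abort(paste0(
      "Invariant violated: amplicon(s) outside all loops: ",
      paste(orphans, collapse = ", "), "."
    ))
  }
  amplicons$loop <- loops$id[loop_of]

  arch <- structure(
    list(
      region_length = as.numeric(region_length),
      loops = loops,
      amplicons = amplicons[, c(
        "id", "start", "end", "length", "center", "chromosome", "loop"
      )]
    ),
    class = "loop_architecture"
  )
  arch$amplicons$nm_distance <- nm_distance_at(arch, arch$amplicons$center)
  arch
}

#' @export
print.loop_architecture <- function(x, ...) {
  cat(
    "<loop_architecture> ", x$region_length, " bp, ",
    nrow(x$loops), " loops, ", nrow(x$amplicons), " amplicons\n",
    sep = ""
  )
  print(x$amplicons, n = 6)
  invisible(x)
}

#' Relative NM distance at arbitrary positions
#'
#' Computes the relative distance to the nuclear matrix at base-pair
#' positions: 0 at a loop anchor (LAR), 1 at the loop tip, linear in arc
#' distance in between (arc distance to the nearest anchor divided by the
#' arc distance from that anchor to the tip).
#'
#' @param arch A [loop_architecture()].
#' @param position Numeric vector of base-pair positions within the region.
#' @return Numeric vector of fractions in `[0, 1]`; `NA` for positions
#'   outside every loop.
#' @export
nm_distance_at <- function(arch, position) {
  stopifnot(inherits(arch, "loop_architecture"))
  loops <- arch$loops
  vapply(position, function(p) {
    hit <- which(p >= loops$anchor_left & p < loops$anchor_right)
    if (length(hit) != 1L) return(NA_real_)
    l <- loops$anchor_left[hit]
    r <- loops$anchor_right[hit]
    tp <- loops$tip[hit]
    if (p <= tp) (p - l) / (tp - l) else (r - p) / (r - tp)
  }, numeric(1))
}

#' Relative NM distance of amplicons
#'
#' @param arch A [loop_architecture()].
#' @param amplicon_id Optional character vector of amplicon ids; defaults to
#'   all amplicons.
#' @return A tibble with columns `amplicon`, `loop`, `nm_distance`.
#' @examples
#' nm_distance(albumin_architecture())
#' @export
nm_distance <- function(arch, amplicon_id = NULL) {
  stopifnot(inherits(arch, "loop_architecture"))
  amp <- arch$amplicons
  if (!is.null(amplicon_id)) {
    missing <- setdiff(amplicon_id, amp$id)
    if (length(missing) > 0L) {
      abort(paste0("Unknown amplicon id(s): ", paste(missing, collapse = ", ")))
    }
    amp <- amp[match(amplicon_id, amp$id), ]
  }
  tibble(
    amplicon = amp$id,
    loop = amp$loop,
    nm_distance = amp$nm_distance
  )
}

#' Built-in architecture of the 162 kbp albumin gene-family region
#'
#' The rat chromosome 14 region carrying the albumin gene family (Alb, Afp,
#' Afm, Afp-L) spans 162 kbp and is organised into five structural DNA
#' loops.  Fifteen target amplicons (a-o, each under 550 bp) are spaced
#' about every 10 kb along the region.  The published source does not print
#' exact LAR coordinates, so by default the five loops are placed with
#' equal spans (anchors every 32.4 kbp); pass `loops` to override with
#' measured boundaries.
#'
#' @param loops Optional data frame of loop boundaries (columns `id`,
#'   `anchor_left`, `anchor_right`, optional `tip`) overriding the
#'   equal-span default.
#' @return A [loop_architecture()] with 5 loops and 15 amplicons.
#' @examples
#' arch <- albumin_architecture()
#' arch$amplicons
#' @export
albumin_architecture <- function(loops = NULL) {
  region_length <- 162000
  if (is.null(loops)) {
    anchors <- seq(0, region_length, length.out = 6)
    loops <- tibble(
      id = paste0("L", 1:5),
      anchor_left = anchors[1:5],
      anchor_right = anchors[2:6]
    )
  }
  # Amplicon lengths as published for primer sets a-o.
  lengths <- c(
    a = 275, b = 547, c = 374, d = 305, e = 382, f = 393, g = 504,
    h = 263, i = 465, j = 392, k = 252, l = 373, m = 234, n = 355, o = 272
  )
  centers <- 6000 + 10000 * (seq_along(lengths) - 1)
  amplicons <- tibble(
    id = names(lengths),
    start = unname(centers - floor(lengths / 2)),
    end = unname(centers - floor(lengths / 2) + lengths),
    chromosome = "chr14"
  )
  loop_architecture(loops, amplicons, region_length)
}

#' Amplicon metadata for four unrelated genes
#'
#' Target amplicons at the 5' ends of four genes on separate rat
#' chromosomes (Fyn, CD23/Fcer2, GFAP, MPZ), used to test whether movement
#' towards the NM during replication is a genome-wide phenomenon.  Only
#' amplicon metadata is known (no loop architecture for these loci).
#'
#' @return A tibble with columns `amplicon`, `chromosome`, `length`.
#' @export
unrelated_gene_amplicons <- function() {
  tibble(
    amplicon = c("GFAP", "CD23", "MPZ", "Fyn"),
    chromosome = c("chr10", "chr12", "chr13", "chr20"),
    length = c(418, 284, 184, 340)
  )
}

#' Read / write a loop architecture file
#'
#' Architectures are stored as YAML (or JSON, by file extension) with keys
#' `region_length`, `loops` (list of `id`, `anchor_left`, `anchor_right`,
#' optional `tip`) and `amplicons` (list of `id`, `start`, `end`,
#' `chromosome`).  `write_architecture()` followed by `read_architecture()`
#' round-trips to an identical structure.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_architecture()` returns a validated [loop_architecture()];
#'   `write_architecture()` returns `path` invisibly.
#' @export
read_architecture <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!all(c("region_length", "loops", "amplicons") %in% names(raw))) {
    abort("Architecture file must define region_length, loops and amplicons.")
  }
  to_tbl <- function(x) {
    if (is.data.frame(x)) as_tibble(x) else bind_rows(lapply(x, as_tibble))
  }
  loop_architecture(
    loops = to_tbl(raw$loops),
    amplicons = to_tbl(raw$amplicons),
    region_length = raw$region_length
  )
}

#' @rdname read_architecture
#' @param arch A [loop_architecture()] to serialise.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "loop_architecture"))
  payload <- list(
    region_length = arch$region_length,
    loops = purrr::transpose(as.list(
      arch$loops[, c("id", "anchor_left", "anchor_right", "tip")]
    )),
    amplicons = purrr::transpose(as.list(
      arch$amplicons[, c("id", "start", "end", "chromosome")]
    ))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' Export amplicons to BED
#'
#' Writes the amplicon intervals as a BED file (chrom, start, end, name)
#' via `rtracklayer`.  Coordinates are kept relative to the region start,
#' matching the architecture's coordinate system.
#'
#' @param arch A [loop_architecture()].
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_amplicon_bed <- function(arch, path) {
  stopifnot(inherits(arch, "loop_architecture"))
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Packages GenomicRanges and rtracklayer are required for BED export.")
  }
  amp <- arch$amplicons
  gr <- GenomicRanges::GRanges(
    seqnames = amp$chromosome,
    ranges = IRanges::IRanges(start = amp$start + 1L, end = amp$end),
    name = amp$id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
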
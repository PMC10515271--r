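# Repeat-unit coordinate system and element annotation.
#
# All coordinates are 0-based, half-open (BED convention). Strand is recorded
# but ignored by coverage and classification: the browser tracks this package
# reproduces are unstranded.

#' Feature kinds recognised in a histone-array annotation
#' @keywords internal
.feature_kinds <- c("gene", "promoter", "tata_box", "ga_repeat", "tata_less_motif")

#' Default promoter-to-gene map for the histone repeat unit
#' @keywords internal
.default_promoter_map <- list(
  H1_promoter      = "H1",
  H2A_H2B_promoter = c("H2A", "H2B"),
  H3_H4_promoter   = c("H3", "H4")
)

#' Build the default histone repeat-unit annotation
#'
#' Returns the annotation of a single ~5 kb *Drosophila* replication-dependent
#' histone repeat unit: the five canonical histone genes (`H1`, `H2A`, `H2B`,
#' `H3`, `H4`), the two divergent TATA-containing core promoters
#' (`H3_H4_promoter`, flanked by `H4` and `H3`; `H2A_H2B_promoter`, flanked by
#' `H2A` and `H2B`), the TATA-less `H1_promoter` upstream of `H1`, TATA boxes
#' inside the two core promoters, a TATA-less motif inside the `H1` promoter,
#' and two GA-repeat elements (the CLAMP-binding cis elements) inside the
#' ~300 bp `H3/H4` promoter.
#'
#' The real array's internal coordinates are not published at base resolution;
#' the layout below is an invented but fixed stand-in chosen so every gene
#' body and promoter is at least 200 bp wide (unambiguous peak assignment at
#' typical fragment sizes) and so the longer GA element (50 bp) accommodates a
#' 50 bp read while a 100 bp read cannot lie inside it. Users with the real
#' annotation can supply their own via [read_annotation_bed()].
#'
#' @param unit_length Length of the repeat unit in bp (default 5000).
#' @return A tibble of class `histone_annotation` with columns `name`, `kind`,
#'   `start`, `end`, `strand`, carrying attributes `unit_length` and
#'   `promoter_map`.
#' @examples
#' ann <- histone_annotation()
#' dplyr::filter(ann, kind == "promoter")
#' @export
histone_annotation <- function(unit_length = 5000) {
  stopifnot(is.numeric(unit_length), unit_length >= 5000)
  features <- tibble::tribble(
    ~name,               ~kind,             ~start, ~end,  ~strand,
    "H4",                "gene",            300L,   610L,  "-",
    "H3_H4_promoter",    "promoter",        610L,   910L,  ".",
    "H3_H4_tata_H4",     "tata_box",        625L,   650L,  ".",
    "ga_repeat_1",       "ga_repeat",       700L,   750L,  ".",
    "ga_repeat_2",       "ga_repeat",       770L,   794L,  ".",
    "H3_H4_tata_H3",     "tata_box",        860L,   885L,  ".",
    "H3",                "gene",            910L,   1320L, "+",
    "H2A",               "gene",            1820L,  2210L, "-",
    "H2A_H2B_promoter",  "promoter",        2210L,  2460L, ".",
    "H2A_H2B_tata_H2A",  "tata_box",        2240L,  2265L, ".",
    "H2A_H2B_tata_H2B",  "tata_box",        2405L,  2430L, ".",
    "H2B",               "gene",            2460L,  2840L, "+",
    "H1_promoter",       "promoter",        3500L,  3750L, ".",
    "H1_tata_less",      "tata_less_motif", 3600L,  3630L, ".",
    "H1",                "gene",            3750L,  4530L, "+"
  )
  new_histone_annotation(features, unit_length = as.integer(unit_length),
                         promoter_map = .default_promoter_map)
}

#' Construct and validate a histone-array annotation
#'
#' @param features Tibble with columns `name`, `kind`, `start`, `end`, `strand`.
#' @param unit_length Repeat-unit length in bp.
#' @param promoter_map Named list mapping promoter names to the gene names they
#'   drive.
#' @return Validated `histone_annotation` tibble.
#' @export
new_histone_annotation <- function(features, unit_length,
                                   promoter_map = .default_promoter_map) {
  features <- tibble::as_tibble(features)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  ann <- structure(
    features,
    unit_length = as.integer(unit_length),
    promoter_map = promoter_map,
    class = c("histone_annotation", class(tibble::tibble()))
  )
  validate_annotation(ann)
  ann
}

#' Repeat-unit length of an annotation
#' @param annotation A `histone_annotation`.
#' @return Integer unit length (bp).
#' @export
unit_length <- function(annotation) {
  attr(annotation, "unit_length")
}

#' Validate a histone-array annotation
#'
#' Checks the structural invariants: coordinates within `[0, unit_length)`
#' half-open with `start < end`, unique feature names, the five canonical
#' histone genes each present exactly once, the three named promoters present,
#' GA repeats inside the `H3/H4` promoter, a TATA-less motif (and no TATA box)
#' in the `H1` promoter, at least one TATA box in each core promoter, and
#' mutually non-overlapping gene bodies.
#'
#' @param annotation A `histone_annotation`.
#' @return The annotation, invisibly; signals an error on violation.
#' @export
validate_annotation <- function(annotation) {
  u <- attr(annotation, "unit_length")
  f <- annotation
  required <- c("name", "kind", "start", "end", "strand")
  if (!all(required %in% names(f))) {
    abort(paste0("annotation must have columns: ", paste(required, collapse = ", ")))
  }
  if (!all(f$kind %in% .feature_kinds)) {
    abort(paste0("unknown feature kind(s): ",
                 paste(setdiff(unique(f$kind), .feature_kinds), collapse = ", ")))
  }
  if (anyDuplicated(f$name)) {
    abort(paste0("duplicate feature name(s): ",
                 paste(unique(f$name[duplicated(f$name)]), collapse = ", ")))
  }
  if (any(f$start < 0L) || any(f$end > u) || any(f$start >= f$end)) {
    abort("features must satisfy 0 <= start < end <= unit_length")
  }
  genes <- f[f$kind == "gene", ]
  for (g in c("H1", "H2A", "H2B", "H3", "H4")) {
    if (sum(genes$name == g) != 1L) abort(paste0("gene ", g, " must be present exactly once"))
  }
  proms <- f[f$kind == "promoter", ]
  for (p in c("H1_promoter", "H2A_H2B_promoter", "H3_H4_promoter")) {
    if (!p %in% proms$name) abort(paste0("promoter ", p, " missing"))
  }
  contains <- function(outer, inner) {
    outer$start <= inner$start & inner$end <= outer$end
  }
  h34 <- proms[proms$name == "H3_H4_promoter", ]
  ga <- f[f$kind == "ga_repeat", ]
  if (nrow(ga) < 1L || !all(contains(h34, ga))) {
    abort("H3_H4_promoter must contain at least one ga_repeat feature")
  }
  h1p <- proms[proms$name == "H1_promoter", ]
  tless <- f[f$kind == "tata_less_motif", ]
  if (nrow(tless) < 1L || !any(contains(h1p, tless))) {
    abort("H1_promoter must contain a tata_less_motif")
  }
  tata <- f[f$kind == "tata_box", ]
  if (nrow(tata) > 0L && any(contains(h1p, tata))) {
    abort("H1_promoter must not contain a tata_box")
  }
  for (p in c("H2A_H2B_promoter", "H3_H4_promoter")) {
    pr <- proms[proms$name == p, ]
    if (nrow(tata) < 1L || !any(contains(pr, tata))) {
      abort(paste0(p, " must contain at least one tata_box"))
    }
  }
  if (nrow(genes) > 1L) {
    g <- genes[order(genes$start), ]
    if (any(g$start[-1L] < g$end[-nrow(g)])) abort("gene bodies must not overlap")
  }
  invisible(annotation)
}

#' Features overlapping a position
#'
#' Returns every feature whose half-open interval `[start, end)` contains
#' `pos`. An empty result means the position is intergenic.
#'
#' @param annotation A `histone_annotation`.
#' @param pos 0-based position within the unit.
#' @return Tibble of the containing features (possibly zero rows).
#' @examples
#' ann <- histone_annotation()
#' elements_at(ann, 760)  # inside the H3/H4 promoter
#' @export
elements_at <- function(annotation, pos) {
  u <- unit_length(annotation)
  if (length(pos) != 1L || is.na(pos) || pos < 0 || pos >= u) {
    abort(sprintf("pos must lie in [0, %d)", u))
  }
  annotation[annotation$start <= pos & pos < annotation$end, ]
}

#' Intergenic intervals of an annotation
#'
#' The complement, within `[0, unit_length)`, of the union of gene and
#' promoter features — the region set used by the intergenic-depletion
#' false-positive rule. Sub-features (TATA boxes, GA repeats, the TATA-less
#' motif) do not count: they lie inside promoters.
#'
#' @param annotation A `histone_annotation`.
#' @return Tibble with columns `start`, `end`: disjoint, sorted, half-open.
#' @export
intergenic_intervals <- function(annotation) {
  u <- unit_length(annotation)
  f <- annotation[annotation$kind %in% c("gene", "promoter"), ]
  if (nrow(f) == 0L) {
    return(tibble::tibble(start = 0L, end = u))
  }
  f <- f[order(f$start), ]
  # merge the union of covered intervals
  merged_start <- integer(0)
  merged_end <- integer(0)
  cur_s <- f$start[1L]
  cur_e <- f$end[1L]
  for (i in seq_len(nrow(f))[-1L]) {
    if (f$start[i] <= cur_e) {
      cur_e <- max(cur_e, f$end[i])
    } else {
      merged_start <- c(merged_start, cur_s)
      merged_end <- c(merged_end, cur_e)
      cur_s <- f$start[i]
      cur_e <- f$end[i]
    }
  }
  merged_start <- c(merged_start, cur_s)
  merged_end <- c(merged_end, cur_e)
  gap_start <- c(0L, merged_end)
  gap_end <- c(merged_start, u)
  keep <- gap_start < gap_end
  tibble::tibble(start = as.integer(gap_start[keep]), end = as.integer(gap_end[keep]))
}

#' Logical per-base membership masks
#'
#' @param annotation A `histone_annotation`.
#' @param kinds Feature kinds to include.
#' @return Logical vector of length `unit_length`; `TRUE` where any feature of
#'   the requested kinds covers the base.
#' @keywords internal
feature_mask <- function(annotation, kinds) {
  u <- unit_length(annotation)
  mask <- logical(u)
  f <- annotation[annotation$kind %in% kinds, ]
  for (i in seq_len(nrow(f))) {
    mask[(f$start[i] + 1L):f$end[i]] <- TRUE
  }
  mask
}

# ---- BED6 interchange ------------------------------------------------------
#
# One line per feature; the feature kind is encoded in the BED name field as
# "name|kind"; score 0; the chrom field carries an arbitrary unit name.

#' Read a histone-array annotation from BED6
#'
#' Expects one line per feature with the feature kind encoded in the name
#' field as `"name|kind"`. The unit length is `max(end)` unless supplied.
#' Malformed lines, `start >= end`, and duplicate names are errors that name
#' the offending line.
#'
#' @param path BED6 file path.
#' @param unit_length Repeat-unit length; defaults to the maximum feature end.
#' @param promoter_map Promoter-to-gene map; defaults to the canonical one.
#' @return A validated `histone_annotation`.
#' @export
read_annotation_bed <- function(path, unit_length = NULL,
                                promoter_map = .default_promoter_map) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) abort("BED file has no feature lines")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 6L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d: expected 6 tab-separated fields, got %d",
                  bad[1L], n_fields[bad[1L]]))
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates",
                  which(is.na(start) | is.na(end))[1L]))
  }
  if (any(start >= end)) {
    abort(sprintf("malformed BED line %d: start >= end", which(start >= end)[1L]))
  }
  name_kind <- vapply(parts, `[[`, "", 4L)
  pieces <- stringr::str_split_fixed(name_kind, stringr::fixed("|"), 2L)
  if (any(!nzchar(pieces[, 2L]))) {
    abort(sprintf("malformed BED line %d: name field must be 'name|kind'",
                  which(!nzchar(pieces[, 2L]))[1L]))
  }
  if (anyDuplicated(pieces[, 1L])) {
    abort(sprintf("malformed BED line %d: duplicate feature name '%s'",
                  which(duplicated(pieces[, 1L]))[1L], pieces[duplicated(pieces[, 1L]), 1L][1L]))
  }
  features <- tibble::tibble(
    name = pieces[, 1L],
    kind = pieces[, 2L],
    start = start,
    end = end,
    strand = vapply(parts, `[[`, "", 6L)
  )
  u <- unit_length %||% max(features$end)
  new_histone_annotation(features, unit_length = u, promoter_map = promoter_map)
}

#' Write a histone-array annotation as BED6
#'
#' Inverse of [read_annotation_bed()]: round-trips `name`, `kind`, `start`,
#' `end` and `strand` losslessly.
#'
#' @param annotation A `histone_annotation`.
#' @param path Output path.
#' @param unit_name Value for the BED chrom column.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path, unit_name = "histone_unit") {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   unit_name, annotation$start, annotation$end,
                   annotation$name, annotation$kind, annotation$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' @export
print.histone_annotation <- function(x, ...) {
  cat(sprintf("<histone_annotation> unit_length = %d bp, %d features\n",
              unit_length(x), nrow(x)))
  NextMethod()
}
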
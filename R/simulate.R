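# Synthetic tandem-repeat reference and seeded ChIP/input read simulation.
#
# The generator stands in for the public ChIP datasets a real screen would
# consume: it emulates the ~100-copy tandem histone array embedded in
# background sequence and produces ChIP/input read pairs under the enrichment
# and false-positive modes the classifier distinguishes, with per-read ground
# truth attached.

.sim_modes <- c("NONE", "TRUE_PROMOTER", "GENE_BODY_BIAS",
                "INTERGENIC_DEPLETION", "INPUT_IDENTICAL", "GA_ARTIFACT")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic ChIP/input generator. Defaults are the
#' package's study conditions: a 100-copy array (the locus carries ~100
#' tandem repeats), 10 kb of background flank per side, 50,000 reads per role,
#' 75 bp reads, 8-fold enrichment on the target element, gene-body bias weight
#' 3, intergenic depletion weight 0.2, and a 5% GA-artifact read fraction.
#'
#' @param mode One of `"NONE"` (no enrichment), `"TRUE_PROMOTER"` (ChIP
#'   enriched on `target_element`, input uniform), `"GENE_BODY_BIAS"`
#'   (gene bodies overweighted in both roles), `"INTERGENIC_DEPLETION"`
#'   (intergenic bases underweighted in both roles), `"INPUT_IDENTICAL"`
#'   (the ChIP enrichment profile applied to both roles), `"GA_ARTIFACT"`
#'   (uniform background plus injected pure-GA reads in the ChIP role).
#' @param n_copies Tandem copies of the repeat unit (>= 1).
#' @param flank_length Background sequence per side, bp.
#' @param n_reads_chip,n_reads_input Read counts per role.
#' @param read_length Read length, bp (>= 20).
#' @param enrichment_fold Fold weight on `target_element` bases (>= 1).
#' @param bias_weight Weight on gene-body bases (`GENE_BODY_BIAS`, > 1
#'   sensible) or intergenic bases (`INTERGENIC_DEPLETION`, < 1 sensible).
#'   Defaults to 3 or 0.2 respectively.
#' @param target_element Feature name receiving enrichment.
#' @param artifact_read_fraction Fraction of ChIP reads that are pure (GA)n
#'   sequence in `GA_ARTIFACT` mode.
#' @param flank_read_fraction Fraction of reads per role drawn from the
#'   background flanks (exercises the mapper's rejection path).
#' @param error_rate Per-base uniform substitution error rate (default 0:
#'   the classification rules do not depend on sequencing error).
#' @param seed Integer RNG seed; fixes every random draw downstream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = "NONE",
                       n_copies = 100L,
                       flank_length = 10000L,
                       n_reads_chip = 50000L,
                       n_reads_input = 50000L,
                       read_length = 75L,
                       enrichment_fold = 8,
                       bias_weight = NULL,
                       target_element = "H3_H4_promoter",
                       artifact_read_fraction = 0.05,
                       flank_read_fraction = 0.02,
                       error_rate = 0,
                       seed = 1L) {
  mode <- match.arg(mode, .sim_modes)
  if (is.null(bias_weight)) {
    bias_weight <- switch(mode, GENE_BODY_BIAS = 3, INTERGENIC_DEPLETION = 0.2, 1)
  }
  cfg <- list(
    mode = mode,
    n_copies = as.integer(n_copies),
    flank_length = as.integer(flank_length),
    n_reads_chip = as.integer(n_reads_chip),
    n_reads_input = as.integer(n_reads_input),
    read_length = as.integer(read_length),
    enrichment_fold = enrichment_fold,
    bias_weight = bias_weight,
    target_element = target_element,
    artifact_read_fraction = artifact_read_fraction,
    flank_read_fraction = flank_read_fraction,
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_copies < 1L) abort("n_copies must be >= 1")
  if (cfg$read_length < 20L) abort("read_length must be >= 20")
  if (cfg$enrichment_fold < 1) abort("enrichment_fold must be >= 1")
  if (cfg$bias_weight <= 0) abort("bias_weight must be > 0")
  if (cfg$artifact_read_fraction < 0 || cfg$artifact_read_fraction > 1) {
    abort("artifact_read_fraction must lie in [0, 1]")
  }
  if (cfg$flank_read_fraction < 0 || cfg$flank_read_fraction > 1) {
    abort("flank_read_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Build a tandem-repeat reference genome
#'
#' Constructs `n_copies` identical copies of a random repeat-unit sequence,
#' embedded between two random background flanks. Bases covered by
#' `ga_repeat` features are perfect (GA)n dinucleotide repeats (phase fixed so
#' each element starts with `G`); every other unit and flank base is i.i.d.
#' uniform over A/C/G/T from the seeded RNG. Deterministic for a fixed seed.
#'
#' @param annotation A `histone_annotation`.
#' @param n_copies Number of tandem copies.
#' @param flank_length Flank length per side, bp.
#' @param seed Integer RNG seed.
#' @return A list of class `array_reference` with elements `sequence` (the
#'   full genome string), `unit_sequence` (one copy), `unit_offsets` (0-based
#'   starts of each copy), `annotation`, `n_copies`, `flank_length`.
#' @export
build_reference <- function(annotation, n_copies = 100L, flank_length = 10000L,
                            seed = 1L) {
  validate_annotation(annotation)
  u <- unit_length(annotation)
  n_copies <- as.integer(n_copies)
  flank_length <- as.integer(flank_length)
  withr::local_seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  unit <- sample(bases, u, replace = TRUE)
  ga <- annotation[annotation$kind == "ga_repeat", ]
  for (i in seq_len(nrow(ga))) {
    idx <- (ga$start[i] + 1L):ga$end[i]
    unit[idx] <- rep_len(c("G", "A"), length(idx))
  }
  unit_seq <- paste(unit, collapse = "")
  left <- paste(sample(bases, flank_length, replace = TRUE), collapse = "")
  right <- paste(sample(bases, flank_length, replace = TRUE), collapse = "")
  sequence <- paste0(left, strrep(unit_seq, n_copies), right)
  structure(
    list(
      sequence = sequence,
      unit_sequence = unit_seq,
      unit_offsets = flank_length + u * (seq_len(n_copies) - 1L),
      annotation = annotation,
      n_copies = n_copies,
      flank_length = flank_length
    ),
    class = "array_reference"
  )
}

#' @export
print.array_reference <- function(x, ...) {
  cat(sprintf("<array_reference> %d x %d bp unit + 2 x %d bp flank (total %d bp)\n",
              x$n_copies, nchar(x$unit_sequence), x$flank_length, nchar(x$sequence)))
  invisible(x)
}

#' Per-base read-start sampling weights for one repeat unit
#'
#' Quantifies the enrichment and bias regimes the classifier must tell apart.
#' All vectors are normalized to sum to 1.
#'
#' * `NONE` and `GA_ARTIFACT`: uniform (GA-artifact reads are injected
#'   separately by [simulate_pair()]).
#' * `TRUE_PROMOTER`: weight `enrichment_fold` on `target_element` bases for
#'   the ChIP role; the input stays uniform.
#' * `INPUT_IDENTICAL`: the `TRUE_PROMOTER` ChIP vector applied to both roles.
#' * `GENE_BODY_BIAS`: weight `bias_weight` on gene-body bases, both roles.
#' * `INTERGENIC_DEPLETION`: weight `bias_weight` on intergenic bases, both
#'   roles.
#'
#' @param annotation A `histone_annotation`.
#' @param mode Simulation mode (see [sim_config()]).
#' @param role `"chip"` or `"input"`.
#' @param enrichment_fold,bias_weight,target_element See [sim_config()].
#' @return Numeric vector of length `unit_length`, nonnegative, summing to 1.
#' @export
position_weights <- function(annotation, mode, role = c("chip", "input"),
                             enrichment_fold = 8, bias_weight = 1,
                             target_element = "H3_H4_promoter") {
  mode <- match.arg(mode, .sim_modes)
  role <- match.arg(role)
  if (bias_weight <= 0) abort("bias_weight must be > 0")
  u <- unit_length(annotation)
  w <- rep(1, u)
  enrich_target <- function(w) {
    feat <- annotation[annotation$name == target_element, ]
    if (nrow(feat) != 1L) abort(paste0("target element not found: ", target_element))
    w[(feat$start + 1L):feat$end] <- enrichment_fold
    w
  }
  if (mode == "TRUE_PROMOTER" && role == "chip") w <- enrich_target(w)
  if (mode == "INPUT_IDENTICAL") w <- enrich_target(w)
  if (mode == "GENE_BODY_BIAS") w[feature_mask(annotation, "gene")] <- bias_weight
  if (mode == "INTERGENIC_DEPLETION") {
    ig <- intergenic_intervals(annotation)
    for (i in seq_len(nrow(ig))) w[(ig$start[i] + 1L):ig$end[i]] <- bias_weight
  }
  w / sum(w)
}

#' Simulate a matched ChIP/input read pair
#'
#' Draws read start positions from the role-appropriate [position_weights()]
#' vector, assigns each read a uniformly chosen copy of the tandem array, and
#' copies its sequence from the reference. Reads whose unit offset spans the
#' copy junction are assigned to one of the first `n_copies - 1` copies so
#' the junction sequence is the identical-copy wrap, never array-to-flank.
#' A configured fraction of reads per role originates in the background
#' flanks (truth origin `"flank"`). In `GA_ARTIFACT` mode, exactly
#' `round(artifact_read_fraction * n_reads_chip)` ChIP reads are pure (GA)n
#' sequence (truth origin `"ga_synthetic"`); this emulates the short-read
#' multimapping pileup over GA-repeat cis elements. Reads are error-free
#' unless `error_rate > 0`. Deterministic for a fixed config (seed included).
#'
#' @param reference An `array_reference` from [build_reference()].
#' @param config A [sim_config()].
#' @return A list with elements `chip` and `input`, each a tibble of class
#'   `read_set` with columns `read_id`, `sequence`, `copy_index`, `offset`,
#'   `origin` and attributes `role` and `config`.
#' @export
simulate_pair <- function(reference, config) {
  stopifnot(inherits(reference, "array_reference"), inherits(config, "sim_config"))
  ann <- reference$annotation
  u <- unit_length(ann)
  L <- config$read_length
  if (L > u) abort("read_length must not exceed unit_length")
  withr::local_seed(config$seed)
  chip <- simulate_role(reference, config, "chip")
  input <- simulate_role(reference, config, "input")
  list(chip = chip, input = input)
}

#' @keywords internal
simulate_role <- function(reference, config, role) {
  ann <- reference$annotation
  u <- unit_length(ann)
  L <- config$read_length
  n <- if (role == "chip") config$n_reads_chip else config$n_reads_input
  n_ga <- if (role == "chip" && config$mode == "GA_ARTIFACT") {
    as.integer(round(config$artifact_read_fraction * n))
  } else 0L
  n_flank <- as.integer(round(config$flank_read_fraction * (n - n_ga)))
  n_unit <- n - n_ga - n_flank

  w <- position_weights(ann, config$mode, role,
                        enrichment_fold = config$enrichment_fold,
                        bias_weight = config$bias_weight,
                        target_element = config$target_element)

  offset <- sample.int(u, n_unit, replace = TRUE, prob = w) - 1L
  copy <- sample.int(reference$n_copies, n_unit, replace = TRUE)
  spans_junction <- offset > (u - L)
  if (reference$n_copies > 1L && any(spans_junction)) {
    # junction reads must come from a copy followed by another identical copy
    copy[spans_junction] <- sample.int(reference$n_copies - 1L,
                                       sum(spans_junction), replace = TRUE)
  }
  gstart <- reference$unit_offsets[copy] + offset
  unit_seq <- substring(reference$sequence, gstart + 1L, gstart + L)

  flank_seq <- character(0)
  if (n_flank > 0L) {
    total <- nchar(reference$sequence)
    fl <- reference$flank_length
    side <- sample(c(0L, 1L), n_flank, replace = TRUE)
    fstart <- ifelse(side == 0L,
                     sample.int(fl - L + 1L, n_flank, replace = TRUE) - 1L,
                     total - fl + sample.int(fl - L + 1L, n_flank, replace = TRUE) - 1L)
    flank_seq <- substring(reference$sequence, fstart + 1L, fstart + L)
  }

  ga_seq <- if (n_ga > 0L) {
    rep(substr(strrep("GA", ceiling(L / 2) + 1L), 1L, L), n_ga)
  } else character(0)

  sequence <- c(unit_seq, flank_seq, ga_seq)
  if (config$error_rate > 0) {
    sequence <- add_substitution_errors(sequence, config$error_rate)
  }
  reads <- tibble::tibble(
    read_id = sprintf("%s_%07d", role, seq_along(sequence)),
    sequence = sequence,
    copy_index = c(copy, rep(NA_integer_, n_flank + n_ga)),
    offset = c(offset, rep(NA_integer_, n_flank + n_ga)),
    origin = c(rep("unit", n_unit), rep("flank", n_flank), rep("ga_synthetic", n_ga))
  )
  structure(reads,
            role = role, config = config,
            class = c("read_set", class(tibble::tibble())))
}

#' @keywords internal
add_substitution_errors <- function(sequence, error_rate) {
  bases <- c("A", "C", "G", "T")
  vapply(sequence, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- runif(length(ch)) < error_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L), "")
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# ---- FASTQ / FASTA / truth-table interchange -------------------------------

#' Write a read set as FASTQ
#'
#' Standard 4-line records with constant quality `"I"`. The truth origin is
#' serialized into the read id after a `|` (`copy=<i>;offset=<bp>;origin=<o>`)
#' and recovered by [read_fastq()]. Byte-identical output for identical read
#' sets.
#'
#' @param readset A `read_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path) {
  n <- nrow(readset)
  if (n == 0L) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  truth <- sprintf("copy=%s;offset=%s;origin=%s",
                   ifelse(is.na(readset$copy_index), ".", readset$copy_index),
                   ifelse(is.na(readset$offset), ".", readset$offset),
                   readset$origin)
  qual <- strrep("I", nchar(readset$sequence))
  lines <- as.vector(rbind(
    paste0("@", readset$read_id, "|", truth),
    readset$sequence,
    rep("+", n),
    qual
  ))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTQ file as a read set
#'
#' Strict 4-line-per-record parser; recovers truth tags written by
#' [write_fastq()] when present (reads without a truth suffix get `NA`
#' truth fields and origin `"unknown"`). Malformed records are errors naming
#' the record index.
#'
#' @param path FASTQ path.
#' @return A `read_set` tibble.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) {
    return(structure(
      tibble::tibble(read_id = character(0), sequence = character(0),
                     copy_index = integer(0), offset = integer(0),
                     origin = character(0)),
      class = c("read_set", class(tibble::tibble()))
    ))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record %d: file has %d lines (not a multiple of 4)",
                  length(lines) %/% 4L + 1L, length(lines)))
  }
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(headers, "@"))
  if (length(bad) > 0L) abort(sprintf("malformed FASTQ record %d: header does not start with '@'", bad[1L]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) abort(sprintf("malformed FASTQ record %d: separator line does not start with '+'", bad[1L]))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    abort(sprintf("malformed FASTQ record %d: sequence length %d != quality length %d",
                  bad[1L], nchar(seqs[bad[1L]]), nchar(quals[bad[1L]])))
  }
  ids <- sub("^@", "", headers)
  has_truth <- grepl("|", ids, fixed = TRUE)
  bare <- sub("\\|.*$", "", ids)
  truth <- sub("^[^|]*\\|", "", ids)
  parse_field <- function(key) {
    v <- stringr::str_match(truth, paste0(key, "=([^;]+)"))[, 2L]
    v[!has_truth] <- NA_character_
    v
  }
  copy_chr <- parse_field("copy")
  offset_chr <- parse_field("offset")
  origin <- parse_field("origin")
  origin[is.na(origin)] <- "unknown"
  structure(
    tibble::tibble(
      read_id = bare,
      sequence = seqs,
      copy_index = suppressWarnings(as.integer(ifelse(copy_chr == ".", NA, copy_chr))),
      offset = suppressWarnings(as.integer(ifelse(offset_chr == ".", NA, offset_chr))),
      origin = origin
    ),
    class = c("read_set", class(tibble::tibble()))
  )
}

#' Write the reference (or its repeat unit) as FASTA
#'
#' Sequence lines are wrapped at 80 characters, matching the NormalizeFasta
#' dialect the screen's reference genomes use.
#'
#' @param reference An `array_reference`, or a plain character sequence.
#' @param path Output path.
#' @param what `"genome"` (full tandem sequence) or `"unit"` (single copy).
#' @param name Sequence name for the FASTA header.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path, what = c("genome", "unit"),
                                  name = NULL) {
  what <- match.arg(what)
  if (inherits(reference, "array_reference")) {
    seqchr <- if (what == "genome") reference$sequence else reference$unit_sequence
    name <- name %||% if (what == "genome") "histone_array_genome" else "histone_unit"
  } else {
    seqchr <- as.character(reference)
    name <- name %||% "sequence"
  }
  x <- Biostrings::DNAStringSet(seqchr)
  names(x) <- name
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a single-sequence FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of length 1 (the sequence, named by its
#'   header).
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) < 1L) abort("FASTA file contains no sequences")
  out <- as.character(x[[1L]])
  names(out) <- names(x)[1L]
  out
}

#' Write the per-read truth table as TSV
#'
#' @param readset A `read_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(readset, path) {
  readr::write_tsv(
    tibble::tibble(read_id = readset$read_id, copy_index = readset$copy_index,
                   offset = readset$offset, origin = readset$origin),
    path
  )
  invisible(path)
}
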
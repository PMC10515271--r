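# Screen-level orchestration: many candidate ChIP/input FASTQ pairs in, one
# tabulated report out. Accession identifiers in a manifest are inert
# metadata; no downloading happens anywhere in this package.

#' Build a screen manifest
#'
#' One row per replicate of a candidate. Rows sharing `candidate` are
#' combined by [classify_replicates()]. `input_fastq` may be `NA` for
#' entries with no control; such entries are classified on ChIP coverage
#' alone and labelled as a no-input comparison in the report rather than
#' silently skipped.
#'
#' @param candidate Character vector of candidate names.
#' @param chip_fastq Paths to ChIP FASTQ files (one per row).
#' @param input_fastq Paths to matched input FASTQ files, or `NA`.
#' @param read_length Read length per row, bp.
#' @param accession Optional free-text dataset identifiers (metadata only).
#' @return A tibble of class `screen_manifest`.
#' @export
screen_manifest <- function(candidate, chip_fastq, input_fastq = NA_character_,
                            read_length, accession = NA_character_) {
  m <- tibble::tibble(candidate = candidate, chip_fastq = chip_fastq,
                      input_fastq = input_fastq,
                      read_length = as.integer(read_length),
                      accession = accession)
  if (nrow(m) == 0L) abort("manifest must have at least one entry")
  if (any(is.na(m$chip_fastq) | !nzchar(m$chip_fastq))) {
    abort("every manifest entry needs a chip_fastq path")
  }
  structure(m, class = c("screen_manifest", class(tibble::tibble())))
}

#' Read / write a screen manifest as TSV
#' @param path TSV path.
#' @return For the reader, a `screen_manifest`; the writer returns `path`
#'   invisibly.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  screen_manifest(m$candidate, m$chip_fastq, m$input_fastq, m$read_length,
                  m$accession %||% NA_character_)
}

#' @rdname read_manifest
#' @param manifest A `screen_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' @keywords internal
classify_fastq_pair <- function(chip_path, input_path, index, unit_seq,
                                annotation, read_length, config) {
  u <- unit_length(annotation)
  chip_reads <- read_fastq(chip_path)
  chip_aln <- map_reads(chip_reads, index, unit_seq)
  chip_cov <- coverage(chip_aln, u, read_length)
  if (is.na(input_path)) {
    # no-input comparison: peaks on ChIP coverage, GA rule only
    called <- call_peaks(chip_cov, config)
    called <- detect_ga_artifact(called, annotation, read_length, config)
    called <- assign_elements(called, annotation)
    clean <- nrow(called) > 0L && any(!called$ga_artifact)
    flags <- if (any(called$ga_artifact)) "GA_ARTIFACT" else character(0)
    top <- if (nrow(called) > 0L) called$elements[[which.max(called$max_ratio)]] else character(0)
    return(structure(
      list(label = if (clean) "positive" else "negative",
           flags = flags, emergent_peaks = called, called_peaks = called,
           localization = top,
           diagnostics = list(comparison = "no-input",
                              n_called_peaks = nrow(called),
                              n_emergent_peaks = nrow(called),
                              read_length = read_length),
           ratio = NULL, config = config),
      class = "candidate_call"
    ))
  }
  input_reads <- read_fastq(input_path)
  input_aln <- map_reads(input_reads, index, unit_seq)
  input_cov <- coverage(input_aln, u, read_length)
  classify_candidate(chip_cov, input_cov, annotation,
                     read_length = read_length, config = config)
}

#' Run the candidate screen over a manifest
#'
#' For each manifest entry: map the FASTQ reads onto the repeat unit, build
#' 1 bp coverage, normalize ChIP to input, classify, then combine replicate
#' rows per candidate. Per-entry failures are recorded in the report (label
#' `"error"`) and do not abort the remaining entries. Deterministic given
#' the files and config.
#'
#' @param manifest A [screen_manifest()] (or plain tibble with its columns).
#' @param unit Repeat-unit sequence: a character scalar or a FASTA path.
#' @param annotation A `histone_annotation` or a BED path.
#' @param config A [classifier_config()].
#' @return A list of class `screen_report`: per-candidate `calls`, the
#'   tabulated `table` (one row per candidate), `summary` counts
#'   (`n_candidates`, `n_positive`, `n_rejected`), `config`, and `version`.
#' @export
run_screen <- function(manifest, unit, annotation = histone_annotation(),
                       config = classifier_config()) {
  if (nrow(manifest) == 0L) abort("manifest must have at least one entry")
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read_annotation_bed(annotation)
  }
  unit_seq <- if (file.exists(unit)) unname(read_reference_fasta(unit)) else unit
  index <- build_index(unit_seq)
  calls <- list()
  errors <- list()
  for (cand in unique(manifest$candidate)) {
    rows <- manifest[manifest$candidate == cand, ]
    res <- tryCatch({
      reps <- purrr::map(seq_len(nrow(rows)), function(i) {
        classify_fastq_pair(rows$chip_fastq[i], rows$input_fastq[i], index,
                            unit_seq, annotation, rows$read_length[i], config)
      })
      if (length(reps) == 1L) reps[[1L]] else classify_replicates(reps)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[cand]] <- conditionMessage(res)
    } else {
      calls[[cand]] <- res
    }
  }
  table <- dplyr::bind_rows(c(
    purrr::imap(calls, function(cl, nm) {
      tibble::tibble(
        candidate = nm,
        label = cl$label,
        flags = paste(cl$flags, collapse = ","),
        n_emergent_peaks = nrow(cl$emergent_peaks),
        localization = paste(cl$localization, collapse = ",")
      )
    }),
    purrr::imap(errors, function(msg, nm) {
      tibble::tibble(candidate = nm, label = "error", flags = "",
                     n_emergent_peaks = 0L, localization = msg)
    })
  ))
  table <- table[match(unique(manifest$candidate), table$candidate), ]
  n_cand <- length(unique(manifest$candidate))
  n_pos <- sum(table$label == "positive")
  structure(
    list(
      calls = calls,
      errors = errors,
      table = table,
      summary = list(n_candidates = n_cand, n_positive = n_pos,
                     n_rejected = n_cand - n_pos),
      config = unclass(config),
      version = as.character(utils::packageVersion("hlbscreen"))
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d candidates: %d positive, %d rejected\n",
              x$summary$n_candidates, x$summary$n_positive, x$summary$n_rejected))
  print(x$table)
  invisible(x)
}

#' @keywords internal
call_to_json_list <- function(cl) {
  peaks <- cl$emergent_peaks
  list(
    label = cl$label,
    flags = as.list(cl$flags),
    localization = as.list(cl$localization),
    diagnostics = cl$diagnostics[!purrr::map_lgl(cl$diagnostics, is.null)],
    emergent_peaks = purrr::map(seq_len(nrow(peaks)), function(i) {
      list(start = peaks$start[i], end = peaks$end[i], width = peaks$width[i],
           summit = peaks$summit[i], max_ratio = peaks$max_ratio[i],
           mean_ratio = peaks$mean_ratio[i],
           ga_artifact = isTRUE(peaks$ga_artifact[i]),
           elements = as.list(peaks$elements[[i]]))
    })
  )
}

#' Serialize / read back a screen report as JSON
#'
#' The JSON embeds the effective config and package version; writing the
#' same report twice is byte-identical, and write-read-write round-trips
#' byte-identically.
#'
#' @param report A `screen_report`.
#' @param path Output path.
#' @return The writer returns `path` invisibly; the reader returns the
#'   parsed report structure (a `screen_report` without track-level
#'   objects).
#' @export
write_screen_report <- function(report, path) {
  obj <- list(
    version = report$version,
    summary = report$summary,
    config = report$config,
    candidates = purrr::map(report$calls, call_to_json_list),
    errors = report$errors
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_screen_report
#' @export
read_screen_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  calls <- purrr::map(obj$candidates, function(c0) {
    peaks <- dplyr::bind_rows(purrr::map(c0$emergent_peaks, function(p) {
      tibble::tibble(start = as.integer(p$start), end = as.integer(p$end),
                     width = as.integer(p$width), summit = as.integer(p$summit),
                     max_ratio = as.numeric(p$max_ratio),
                     mean_ratio = as.numeric(p$mean_ratio),
                     ga_artifact = isTRUE(p$ga_artifact),
                     elements = list(as.character(unlist(p$elements))))
    }))
    structure(
      list(label = c0$label, flags = as.character(unlist(c0$flags)),
           emergent_peaks = peaks, called_peaks = NULL,
           localization = as.character(unlist(c0$localization)),
           diagnostics = c0$diagnostics, ratio = NULL, config = NULL),
      class = "candidate_call"
    )
  })
  table <- dplyr::bind_rows(purrr::imap(calls, function(cl, nm) {
    tibble::tibble(candidate = nm, label = cl$label,
                   flags = paste(cl$flags, collapse = ","),
                   n_emergent_peaks = nrow(cl$emergent_peaks),
                   localization = paste(cl$localization, collapse = ","))
  }))
  structure(
    list(calls = calls, errors = obj$errors, table = table,
         summary = obj$summary, config = obj$config, version = obj$version),
    class = "screen_report"
  )
}

#' Write the screen tabulation as TSV
#'
#' One row per candidate: label, flags, peak count, localization.
#'
#' @param report A `screen_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(report, path) {
  readr::write_tsv(report$table, path)
  invisible(path)
}
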
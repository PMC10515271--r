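# Collapse mapping onto a single circular repeat unit.
#
# Because the tandem copies of the histone array are (modelled as) identical,
# a read from any copy can be mapped to the single 5 kb unit: the mapper
# reports the position within the unit, collapsing the whole locus onto one
# coordinate system. The unit is treated as circular for both indexing and
# coverage so junction-spanning reads from interior copies stay mappable.
#
# The external aligner of a conventional pipeline is replaced by an internal
# exact-k-mer seed-and-verify mapper: on a 5 kb reference, seed lookup plus
# full-length mismatch counting is sufficient, removes a binary dependency,
# and makes the multimap tie-break (leftmost best placement, which is what
# concentrates GA-repeat reads into a single pileup) explicit and
# deterministic. BAM import remains available as an interchange point.

#' Build an exact k-mer index over the circularized repeat unit
#'
#' Positions are taken modulo the unit length, so k-mers spanning the
#' copy-junction exist in the index.
#'
#' @param unit_sequence Repeat-unit sequence (character scalar).
#' @param k Seed length (>= 12).
#' @return A list of class `kmer_index` with the lookup environment, `k`, and
#'   `unit_length`.
#' @export
build_index <- function(unit_sequence, k = 16L) {
  k <- as.integer(k)
  u <- nchar(unit_sequence)
  if (k < 12L) abort("k must be >= 12")
  if (u < k) abort("unit sequence must be at least k long")
  ext <- paste0(unit_sequence, substr(unit_sequence, 1L, k - 1L))
  kmers <- substring(ext, seq_len(u), seq_len(u) + k - 1L)
  lookup <- list2env(split(0:(u - 1L), kmers), hash = TRUE)
  structure(list(lookup = lookup, k = k, unit_length = u), class = "kmer_index")
}

#' Reverse complement of DNA strings
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

#' @keywords internal
lookup_kmers <- function(index, kmers) {
  mget(kmers, envir = index$lookup, ifnotfound = list(NULL))
}

#' Count mismatches between two equal-length strings
#' @keywords internal
count_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Map reads onto the circular repeat unit
#'
#' Seed-and-verify: candidate placements are circular-unit positions where
#' the read's leading k-mer (or, as a fallback, its trailing k-mer) matches
#' exactly, on either strand; each candidate is verified by full-length
#' comparison against the circularized unit and kept if it has at most
#' `max_mismatches` mismatches. The reported placement is the best-scoring
#' one, with ties broken by the leftmost unit position (forward strand
#' preferred on an exact position tie); `multimap_count` is the number of
#' equally best placements. Reads with no acceptable placement are returned
#' unmapped — unmapped is a value, not an error.
#'
#' Reads simulated from any copy of the tandem array therefore report
#' `unit_pos` equal to their offset within the unit, regardless of copy.
#'
#' @param reads A `read_set` tibble (or any tibble with `read_id` and
#'   `sequence` columns).
#' @param index A `kmer_index` from [build_index()].
#' @param unit_sequence The repeat-unit sequence the index was built from.
#' @param max_mismatches Maximum mismatches for an acceptable placement.
#' @return A tibble with columns `read_id`, `mapped`, `unit_pos` (0-based,
#'   `NA` when unmapped), `strand`, `mismatches`, `multimap_count`.
#' @export
map_reads <- function(reads, index, unit_sequence, max_mismatches = 2L) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- reads$sequence
  n <- length(seqs)
  lens <- nchar(seqs)
  u <- index$unit_length
  k <- index$k
  if (any(lens > u)) abort("read length must not exceed unit_length")
  if (any(lens < k)) abort("reads shorter than the seed length cannot be mapped")

  out_pos <- rep(NA_integer_, n)
  out_strand <- rep(NA_character_, n)
  out_mm <- rep(NA_integer_, n)
  out_multi <- rep(0L, n)

  if (n == 0L) {
    return(tibble::tibble(read_id = character(0), mapped = logical(0),
                          unit_pos = integer(0), strand = character(0),
                          mismatches = integer(0), multimap_count = integer(0)))
  }

  Lmax <- max(lens)
  ext <- paste0(unit_sequence, substr(unit_sequence, 1L, Lmax))
  rc <- revcomp(seqs)
  cand_f <- lookup_kmers(index, substr(seqs, 1L, k))
  cand_r <- lookup_kmers(index, substr(rc, 1L, k))
  nf <- lengths(cand_f)
  nr <- lengths(cand_r)

  # fast path: single forward candidate, no reverse candidate, exact match
  fast <- which(nf == 1L & nr == 0L)
  if (length(fast) > 0L) {
    p <- unlist(cand_f[fast], use.names = FALSE)
    hit <- substring(ext, p + 1L, p + lens[fast]) == seqs[fast]
    ok <- fast[hit]
    out_pos[ok] <- p[hit]
    out_strand[ok] <- "+"
    out_mm[ok] <- 0L
    out_multi[ok] <- 1L
    fast <- fast[!hit]  # re-examine mismatched ones in the slow path
  }
  # symmetric fast path on the reverse strand
  fastr <- which(nr == 1L & nf == 0L)
  if (length(fastr) > 0L) {
    p <- unlist(cand_r[fastr], use.names = FALSE)
    hit <- substring(ext, p + 1L, p + lens[fastr]) == rc[fastr]
    ok <- fastr[hit]
    out_pos[ok] <- p[hit]
    out_strand[ok] <- "-"
    out_mm[ok] <- 0L
    out_multi[ok] <- 1L
    fastr <- fastr[!hit]
  }

  todo <- c(which(!(nf == 1L & nr == 0L) & !(nr == 1L & nf == 0L)), fast, fastr)
  for (i in todo) {
    L <- lens[i]
    pf <- cand_f[[i]]
    pr <- cand_r[[i]]
    if (length(pf) == 0L && length(pr) == 0L) {
      # fallback seed at the read's tail (helps reads with a 5' error)
      pf2 <- lookup_kmers(index, substr(seqs[i], L - k + 1L, L))[[1L]]
      if (!is.null(pf2)) pf <- (pf2 - (L - k)) %% u
      pr2 <- lookup_kmers(index, substr(rc[i], L - k + 1L, L))[[1L]]
      if (!is.null(pr2)) pr <- (pr2 - (L - k)) %% u
    }
    if (length(pf) == 0L && length(pr) == 0L) next
    cand <- rbind(
      if (length(pf) > 0L) cbind(pos = pf, fwd = 1L),
      if (length(pr) > 0L) cbind(pos = pr, fwd = 0L)
    )
    cand <- cand[!duplicated(cand), , drop = FALSE]
    mm <- integer(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      q <- if (cand[j, "fwd"] == 1L) seqs[i] else rc[i]
      mm[j] <- count_mismatches(substr(ext, cand[j, "pos"] + 1L, cand[j, "pos"] + L), q)
    }
    keep <- mm <= max_mismatches
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    mm <- mm[keep]
    best <- mm == min(mm)
    bpos <- cand[best, "pos"]
    bfwd <- cand[best, "fwd"]
    ord <- order(bpos, -bfwd)  # leftmost; forward wins an exact position tie
    out_pos[i] <- bpos[ord[1L]]
    out_strand[i] <- if (bfwd[ord[1L]] == 1L) "+" else "-"
    out_mm[i] <- min(mm)
    out_multi[i] <- sum(best)
  }

  tibble::tibble(
    read_id = reads$read_id,
    mapped = !is.na(out_pos),
    unit_pos = out_pos,
    strand = out_strand,
    mismatches = out_mm,
    multimap_count = out_multi
  )
}

#' Map a single read
#'
#' Convenience wrapper around [map_reads()] for one sequence.
#'
#' @param sequence Read sequence (character scalar).
#' @param index A `kmer_index`.
#' @param unit_sequence Repeat-unit sequence.
#' @param max_mismatches Maximum acceptable mismatches.
#' @return One-row tibble as from [map_reads()].
#' @export
map_read <- function(sequence, index, unit_sequence, max_mismatches = 2L) {
  map_reads(tibble::tibble(read_id = "read", sequence = sequence),
            index, unit_sequence, max_mismatches)
}

#' Per-base (1 bp bin) coverage over the circular unit
#'
#' Each mapped alignment increments `read_length` consecutive bases starting
#' at `unit_pos`, wrapping across the origin. The conservation invariant
#' `sum(count) == n_mapped * read_length` holds exactly. Implemented with a
#' difference array + prefix sum; a naive per-read loop serves as the test
#' oracle.
#'
#' @param alignments Tibble from [map_reads()] (unmapped rows are dropped).
#' @param unit_len Unit length, bp.
#' @param read_length Read length, bp.
#' @return A tibble of class `coverage_track` with columns `position`
#'   (0-based) and `count`, and attributes `n_mapped`, `read_length`,
#'   `unit_length`.
#' @export
coverage <- function(alignments, unit_len, read_length) {
  unit_len <- as.integer(unit_len)
  L <- as.integer(read_length)
  starts <- alignments$unit_pos[alignments$mapped]
  if (anyNA(starts)) abort("alignments contain mapped = TRUE rows with NA unit_pos")
  n_mapped <- length(starts)
  d <- tabulate(starts + 1L, nbins = unit_len + L) -
    tabulate(starts + 1L + L, nbins = unit_len + L)
  cum <- cumsum(d)
  values <- cum[seq_len(unit_len)]
  overflow <- cum[(unit_len + 1L):(unit_len + L)]
  values[seq_len(L)] <- values[seq_len(L)] + overflow
  new_coverage_track(values, n_mapped = n_mapped, read_length = L)
}

#' @keywords internal
new_coverage_track <- function(values, n_mapped, read_length) {
  structure(
    tibble::tibble(position = seq_along(values) - 1L, count = as.numeric(values)),
    n_mapped = as.integer(n_mapped),
    read_length = as.integer(read_length),
    unit_length = length(values),
    class = c("coverage_track", class(tibble::tibble()))
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d bp unit, %d mapped reads of %d bp (mean %.1fx)\n",
              attr(x, "unit_length"), attr(x, "n_mapped"), attr(x, "read_length"),
              mean(x$count)))
  NextMethod()
}

# ---- interchange: SAM out, BAM in, bedGraph out ----------------------------

#' Write mapped reads as SAM
#'
#' One record per mapped read against the single repeat-unit reference. A
#' read crossing the circular origin is wrap-split into two records (the
#' wrapped tail is soft-clipped in the first record and emitted as a
#' secondary record at position 1).
#'
#' @param alignments Tibble from [map_reads()].
#' @param reads The `read_set` supplying sequences (matched by `read_id`).
#' @param path Output path.
#' @param unit_name Reference sequence name.
#' @param unit_len Unit length, bp.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, path, unit_name = "histone_unit",
                      unit_len = NULL) {
  seqs <- reads$sequence[match(alignments$read_id, reads$read_id)]
  u <- unit_len %||% max(nchar(seqs))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", unit_name, u))
  recs <- character(0)
  m <- which(alignments$mapped)
  for (i in m) {
    L <- nchar(seqs[i])
    pos <- alignments$unit_pos[i]
    flag <- if (identical(alignments$strand[i], "-")) 16L else 0L
    seq_out <- if (flag == 16L) revcomp(seqs[i]) else seqs[i]
    qual <- strrep("I", L)
    if (pos + L <= u) {
      recs <- c(recs, sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                              alignments$read_id[i], flag, unit_name, pos + 1L,
                              L, seq_out, qual))
    } else {
      head_len <- u - pos
      tail_len <- L - head_len
      recs <- c(recs,
                sprintf("%s\t%d\t%s\t%d\t255\t%dM%dS\t*\t0\t0\t%s\t%s",
                        alignments$read_id[i], flag, unit_name, pos + 1L,
                        head_len, tail_len, seq_out, qual),
                sprintf("%s\t%d\t%s\t1\t255\t%dS%dM\t*\t0\t0\t%s\t%s",
                        alignments$read_id[i], flag + 256L, unit_name,
                        head_len, tail_len, seq_out, qual))
    }
  }
  readr::write_lines(c(hdr, recs), path)
  invisible(path)
}

#' Import alignments from a BAM file
#'
#' Bypasses the internal mapper and takes placements as given: each primary
#' mapped record contributes its leftmost position on the single repeat-unit
#' reference. Requires the Rsamtools package.
#'
#' @param path BAM path.
#' @return Alignment tibble in the [map_reads()] layout (`mismatches` and
#'   `multimap_count` are `NA`/1: the BAM is trusted as-is).
#' @export
read_bam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("BAM import requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  tibble::tibble(
    read_id = b$qname,
    mapped = TRUE,
    unit_pos = as.integer(b$pos) - 1L,
    strand = as.character(b$strand),
    mismatches = NA_integer_,
    multimap_count = 1L
  )
}

#' Export a track as bedGraph
#'
#' Adjacent equal-valued bases are merged into intervals. Uses rtracklayer
#' when available; otherwise writes the four-column text directly.
#'
#' @param track A `coverage_track` or `ratio_track`.
#' @param path Output path.
#' @param unit_name Reference sequence name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, unit_name = "histone_unit") {
  vals <- track_values(track)
  r <- rle(vals)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  if (requireNamespace("rtracklayer", quietly = TRUE) &&
      requireNamespace("GenomicRanges", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = unit_name,
      ranges = IRanges::IRanges(start = starts + 1L, end = ends),
      score = r$values
    )
    rtracklayer::export.bedGraph(gr, path)
  } else {
    readr::write_lines(
      sprintf("%s\t%d\t%d\t%s", unit_name, starts, ends,
              format(r$values, trim = TRUE, scientific = FALSE)),
      path
    )
  }
  invisible(path)
}
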
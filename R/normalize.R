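# Input normalization: depth scaling and the per-base log2(ChIP/input) track.
#
# Depth scaling is simple total-count (CPM-style) scaling to a common target:
# on a single 5 kb reference, signal-extraction style scaling is undefined
# and unnecessary, and the scaling label travels with the track for
# provenance.

#' Extract the value column of a track
#' @param track A `coverage_track` or `ratio_track` (or numeric vector).
#' @return Numeric vector of per-base values.
#' @export
track_values <- function(track) {
  if (is.numeric(track)) return(track)
  if (inherits(track, "coverage_track")) return(track$count)
  if (inherits(track, "ratio_track")) return(track$log2_ratio)
  if (is.data.frame(track) && "count" %in% names(track)) return(track$count)
  if (is.data.frame(track) && "log2_ratio" %in% names(track)) return(track$log2_ratio)
  abort("cannot extract values from this track")
}

#' Depth-scale a coverage track to a target total
#'
#' Multiplies every base by `target_total / sum(count)`, so the scaled track
#' sums to `target_total`. Shape-preserving and invariant to entrywise
#' rescaling of the input counts.
#'
#' @param track A `coverage_track`.
#' @param target_total Target sum of the scaled track (default 1e6).
#' @return The track with `count` replaced by scaled values.
#' @export
depth_scale <- function(track, target_total = 1e6) {
  vals <- track_values(track)
  total <- sum(vals)
  if (total <= 0) abort("cannot depth-scale an empty track (no mapped reads)")
  out <- track
  out$count <- vals * (target_total / total)
  out
}

#' Per-base log2(ChIP/input) ratio track
#'
#' Both tracks are depth-scaled to a common `target_total`, then
#' `log2((chip + pseudocount) / (input + pseudocount))` is taken per base.
#' The pseudocount (> 0) keeps the track finite everywhere. Identical tracks
#' give an all-zero ratio, and multiplying either track's counts by a
#' constant changes nothing (depth-scaling invariance).
#'
#' @param chip,input `coverage_track`s over the same unit.
#' @param pseudocount Added to both scaled tracks before the ratio (> 0;
#'   default 1, the conventional bigwig-comparison default).
#' @param target_total Common scaled total (default 1e6).
#' @return A tibble of class `ratio_track` with columns `position`,
#'   `log2_ratio` and attributes `pseudocount`, `scaling`, `read_length`
#'   (ChIP's), `unit_length`.
#' @export
log2_ratio <- function(chip, input, pseudocount = 1, target_total = 1e6) {
  cu <- attr(chip, "unit_length") %||% nrow(chip)
  iu <- attr(input, "unit_length") %||% nrow(input)
  if (cu != iu) {
    abort(sprintf("unit length mismatch: chip %d bp vs input %d bp", cu, iu))
  }
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  c_s <- track_values(depth_scale(chip, target_total))
  i_s <- track_values(depth_scale(input, target_total))
  structure(
    tibble::tibble(
      position = seq_len(cu) - 1L,
      log2_ratio = log2((c_s + pseudocount) / (i_s + pseudocount))
    ),
    pseudocount = pseudocount,
    scaling = sprintf("total_count_to_%g", target_total),
    read_length = attr(chip, "read_length"),
    unit_length = cu,
    class = c("ratio_track", class(tibble::tibble()))
  )
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %d bp unit, pseudocount %g, scaling %s\n",
              attr(x, "unit_length"), attr(x, "pseudocount"), attr(x, "scaling")))
  NextMethod()
}

#' Circular centered moving average
#'
#' Smooths a per-base track with an odd centered window, wrapping across the
#' unit origin; `window = 1` is the identity. Preserves the track mean
#' exactly (circular average).
#'
#' @param x A track or numeric vector.
#' @param window Odd window width in bp (>= 1).
#' @return Numeric vector of smoothed values.
#' @export
smooth_track <- function(x, window = 31L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("window must be an odd integer >= 1")
  v <- track_values(x)
  if (window == 1L) return(v)
  h <- (window - 1L) %/% 2L
  padded <- c(tail(v, h), v, head(v, h))
  as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2L))[(h + 1L):(h + length(v))]
}
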
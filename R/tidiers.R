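# broom-style accessors for call and report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a candidate call into its emergent-peak table
#'
#' One row per emergent peak: coordinates, summit, smoothed signal, GA flag,
#' and assigned elements (collapsed to a `+`-separated string).
#'
#' @param x A `candidate_call`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy candidate_call
#' @export
tidy.candidate_call <- function(x, ...) {
  p <- x$emergent_peaks
  if (nrow(p) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          width = integer(0), summit = integer(0),
                          max_ratio = numeric(0), mean_ratio = numeric(0),
                          ga_artifact = logical(0), elements = character(0)))
  }
  tibble::tibble(
    start = p$start, end = p$end, width = p$width, summit = p$summit,
    max_ratio = p$max_ratio, mean_ratio = p$mean_ratio,
    ga_artifact = p$ga_artifact %||% rep(NA, nrow(p)),
    elements = purrr::map_chr(p$elements, paste, collapse = "+")
  )
}

#' One-row summary of a candidate call
#'
#' @param x A `candidate_call`.
#' @param ... Unused.
#' @return A one-row tibble: label, flags, peak count, top localization, and
#'   the dataset-level diagnostic scores.
#' @method glance candidate_call
#' @export
glance.candidate_call <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    label = x$label,
    flags = paste(x$flags, collapse = ","),
    n_emergent_peaks = nrow(x$emergent_peaks),
    localization = paste(x$localization, collapse = "+"),
    genebody_score = d$genebody_score %||% NA_real_,
    intergenic_score = d$intergenic_score %||% NA_real_,
    identity_correlation = d$identity_correlation %||% NA_real_,
    read_length = d$read_length %||% NA_integer_
  )
}

#' Tidy a screen report into its per-candidate table
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return The per-candidate tibble (candidate, label, flags, peak count,
#'   localization).
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' One-row summary of a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A one-row tibble with `n_candidates`, `n_positive`, `n_rejected`.
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = x$summary$n_candidates,
    n_positive = x$summary$n_positive,
    n_rejected = x$summary$n_rejected
  )
}
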
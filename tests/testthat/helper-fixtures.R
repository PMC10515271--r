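# Shared fixtures and independent oracles.
#
# Fixtures are generated in code (no stored data); the small reference is
# cached per test run because several files reuse it.

.fixture_env <- new.env(parent = emptyenv())

default_ann <- function() {
  if (is.null(.fixture_env$ann)) .fixture_env$ann <- histone_annotation()
  .fixture_env$ann
}

# small tandem reference: 5 copies, 1 kb flanks (fast to build and map)
small_ref <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- build_reference(default_ann(), n_copies = 5,
                                        flank_length = 1000, seed = 42)
  }
  .fixture_env$ref
}

small_index <- function() {
  if (is.null(.fixture_env$idx)) {
    .fixture_env$idx <- build_index(small_ref()$unit_sequence)
  }
  .fixture_env$idx
}

# Simulate, map and classify one candidate at reduced depth (unit tests).
classify_sim <- function(mode, seed, n_reads = 20000L, read_length = 75L,
                         config = classifier_config(), ...) {
  ref <- small_ref()
  ann <- default_ann()
  cfg <- sim_config(mode = mode, n_copies = ref$n_copies,
                    flank_length = ref$flank_length,
                    n_reads_chip = n_reads, n_reads_input = n_reads,
                    read_length = read_length, seed = seed, ...)
  pair <- simulate_pair(ref, cfg)
  ca <- map_reads(pair$chip, small_index(), ref$unit_sequence)
  ia <- map_reads(pair$input, small_index(), ref$unit_sequence)
  u <- unit_length(ann)
  classify_candidate(coverage(ca, u, read_length),
                     coverage(ia, u, read_length),
                     ann, read_length = read_length, config = config)
}

# ---- oracles ---------------------------------------------------------------

# naive per-read per-base circular coverage (the oracle for coverage())
naive_coverage <- function(starts, unit_len, read_length) {
  v <- numeric(unit_len)
  for (s in starts) {
    for (i in 0:(read_length - 1L)) {
      p <- (s + i) %% unit_len
      v[p + 1L] <- v[p + 1L] + 1
    }
  }
  v
}

# brute-force circular placement scan: mismatch count of `read` at every
# position of the circularized unit, both strands
brute_force_placements <- function(read, unit_seq) {
  u <- nchar(unit_seq)
  L <- nchar(read)
  ext <- paste0(unit_seq, substr(unit_seq, 1L, L))
  rc <- hlbscreen::revcomp(read)
  ri <- utf8ToInt(read)
  rci <- utf8ToInt(rc)
  mm_f <- integer(u)
  mm_r <- integer(u)
  for (p in 0:(u - 1L)) {
    w <- utf8ToInt(substr(ext, p + 1L, p + L))
    mm_f[p + 1L] <- sum(w != ri)
    mm_r[p + 1L] <- sum(w != rci)
  }
  tibble::tibble(pos = rep(0:(u - 1L), 2L),
                 strand = rep(c("+", "-"), each = u),
                 mismatches = c(mm_f, mm_r))
}

# naive per-feature containment scan (the oracle for elements_at)
naive_elements_at <- function(annotation, pos) {
  hits <- character(0)
  for (i in seq_len(nrow(annotation))) {
    if (annotation$start[i] <= pos && pos < annotation$end[i]) {
      hits <- c(hits, annotation$name[i])
    }
  }
  hits
}
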
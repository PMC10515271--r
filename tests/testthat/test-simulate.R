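test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_copies = 0), "n_copies")
  expect_error(sim_config(read_length = 10), "read_length")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(sim_config(artifact_read_fraction = 1.5), "artifact_read_fraction")
  expect_error(sim_config(mode = "GENE_BODY_BIAS", bias_weight = 0), "bias_weight")
  # mode-dependent bias defaults
  expect_equal(sim_config(mode = "GENE_BODY_BIAS")$bias_weight, 3)
  expect_equal(sim_config(mode = "INTERGENIC_DEPLETION")$bias_weight, 0.2)
})

test_that("build_reference has the right geometry, GA repeats, and determinism", {
  ann <- default_ann()
  ref <- build_reference(ann, n_copies = 3, flank_length = 1000, seed = 5)
  expect_equal(nchar(ref$sequence), 3L * 5000L + 2L * 1000L)
  expect_equal(ref$unit_offsets, 1000L + 5000L * (0:2))

  # each copy is the identical unit
  for (o in ref$unit_offsets) {
    expect_identical(substr(ref$sequence, o + 1, o + 5000), ref$unit_sequence)
  }

  # GA features are perfect (GA)n dinucleotide repeats
  ga <- dplyr::filter(ann, kind == "ga_repeat")
  for (i in seq_len(nrow(ga))) {
    len <- ga$end[i] - ga$start[i]
    expect_identical(substr(ref$unit_sequence, ga$start[i] + 1, ga$end[i]),
                     substr(strrep("GA", ceiling(len / 2) + 1), 1, len))
  }

  expect_identical(build_reference(ann, 3, 1000, seed = 5)$sequence, ref$sequence)
  expect_false(identical(build_reference(ann, 3, 1000, seed = 6)$sequence,
                         ref$sequence))
})

test_that("position_weights implements every mode and normalizes to 1", {
  ann <- default_ann()
  u <- unit_length(ann)
  h34 <- dplyr::filter(ann, name == "H3_H4_promoter")
  on_el <- (h34$start + 1):h34$end

  w <- position_weights(ann, "NONE", "chip")
  expect_equal(w, rep(1 / u, u))

  w <- position_weights(ann, "TRUE_PROMOTER", "chip", enrichment_fold = 8)
  expect_equal(w[on_el[1]] / w[1], 8)
  expect_equal(position_weights(ann, "TRUE_PROMOTER", "input"), rep(1 / u, u))

  # INPUT_IDENTICAL applies the ChIP vector to both roles
  expect_equal(position_weights(ann, "INPUT_IDENTICAL", "input", enrichment_fold = 8),
               position_weights(ann, "TRUE_PROMOTER", "chip", enrichment_fold = 8))

  w <- position_weights(ann, "GENE_BODY_BIAS", "input", bias_weight = 3)
  h3 <- dplyr::filter(ann, name == "H3")
  expect_equal(w[h3$start + 10] / w[1], 3)  # position 1 is intergenic

  w <- position_weights(ann, "INTERGENIC_DEPLETION", "input", bias_weight = 0.2)
  expect_equal(w[1] / w[h3$start + 10], 0.2)

  expect_equal(position_weights(ann, "GA_ARTIFACT", "chip"), rep(1 / u, u))

  for (m in c("NONE", "TRUE_PROMOTER", "GENE_BODY_BIAS", "INTERGENIC_DEPLETION",
              "INPUT_IDENTICAL", "GA_ARTIFACT")) {
    expect_equal(sum(position_weights(ann, m, "chip")), 1, tolerance = 1e-12)
  }
  expect_error(position_weights(ann, "GENE_BODY_BIAS", "chip", bias_weight = -1),
               "bias_weight")
})

test_that("simulated read positions follow the sampling weights (binomial check)", {
  ref <- small_ref()
  cfg <- sim_config(mode = "NONE", n_copies = 5, flank_length = 1000,
                    n_reads_chip = 1000, n_reads_input = 10000,
                    flank_read_fraction = 0, seed = 9)
  pair <- simulate_pair(ref, cfg)
  expect_equal(nrow(pair$input), 10000L)
  # fraction of truth offsets in a 500 bp window ~ Binomial(n, 0.1)
  inwin <- pair$input$offset >= 2000 & pair$input$offset < 2500
  p_hat <- mean(inwin)
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("TRUE_PROMOTER on/off read density converges to the enrichment fold", {
  ref <- small_ref()
  ann <- default_ann()
  cfg <- sim_config(mode = "TRUE_PROMOTER", n_copies = 5, flank_length = 1000,
                    n_reads_chip = 200000, n_reads_input = 1000,
                    enrichment_fold = 8, flank_read_fraction = 0, seed = 13)
  pair <- simulate_pair(ref, cfg)
  h34 <- dplyr::filter(ann, name == "H3_H4_promoter")
  on <- pair$chip$offset >= h34$start & pair$chip$offset < h34$end
  dens_ratio <- (sum(on) / (h34$end - h34$start)) /
    (sum(!on) / (5000 - (h34$end - h34$start)))
  expect_lt(abs(dens_ratio - 8) / 8, 0.10)
})

test_that("simulated reads carry exactly one truth origin and exact GA counts", {
  ref <- small_ref()
  cfg <- sim_config(mode = "GA_ARTIFACT", n_copies = 5, flank_length = 1000,
                    n_reads_chip = 20000, n_reads_input = 1000,
                    read_length = 36, artifact_read_fraction = 0.05, seed = 3)
  pair <- simulate_pair(ref, cfg)
  expect_equal(sum(pair$chip$origin == "ga_synthetic"), round(0.05 * 20000))
  expect_true(all(pair$chip$origin %in% c("unit", "flank", "ga_synthetic")))
  expect_equal(nrow(pair$chip), 20000L)
  # unit-origin reads have copy/offset truth; others don't
  expect_false(anyNA(pair$chip$offset[pair$chip$origin == "unit"]))
  expect_true(all(is.na(pair$chip$offset[pair$chip$origin != "unit"])))
  # ga reads are pure GA of the read length
  ga_seq <- pair$chip$sequence[pair$chip$origin == "ga_synthetic"]
  expect_true(all(ga_seq == substr(strrep("GA", 19), 1, 36)))
})

test_that("read sequences match the reference at their truth coordinates", {
  ref <- small_ref()
  cfg <- sim_config(mode = "NONE", n_copies = 5, flank_length = 1000,
                    n_reads_chip = 500, n_reads_input = 500, seed = 21)
  pair <- simulate_pair(ref, cfg)
  unit_reads <- dplyr::filter(pair$chip, origin == "unit")
  gstart <- ref$unit_offsets[unit_reads$copy_index] + unit_reads$offset
  expect_identical(unit_reads$sequence,
                   substring(ref$sequence, gstart + 1, gstart + 75))
})

test_that("identical configs give byte-identical FASTQ output", {
  ref <- small_ref()
  cfg <- sim_config(mode = "TRUE_PROMOTER", n_copies = 5, flank_length = 1000,
                    n_reads_chip = 2000, n_reads_input = 2000, seed = 17)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_pair(ref, cfg)$chip, f1)
  write_fastq(simulate_pair(ref, cfg)$chip, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("FASTQ round-trip preserves reads and truth tags; malformed records error", {
  ref <- small_ref()
  cfg <- sim_config(mode = "GA_ARTIFACT", n_copies = 5, flank_length = 1000,
                    n_reads_chip = 100, n_reads_input = 100, read_length = 36,
                    seed = 2)
  rs <- simulate_pair(ref, cfg)$chip
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs, path)
  back <- read_fastq(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(rs), ignore_attr = TRUE)

  # empty set round-trips as an empty file
  empty <- rs[0, ]
  write_fastq(empty, path)
  expect_equal(nrow(read_fastq(path)), 0L)

  writeLines(c("@r1", "ACGT", "+", "III"), path)   # qual length mismatch
  expect_error(read_fastq(path), "record 1.*length 4.*length 3")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(read_fastq(path), "truncated")
  writeLines(c("r1", "ACGT", "+", "IIII"), path)
  expect_error(read_fastq(path), "'@'")
})

test_that("reference FASTA is 80-column wrapped and round-trips", {
  ref <- small_ref()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(ref, path, what = "unit")
  lines <- readLines(path)
  expect_true(startsWith(lines[1], ">"))
  expect_true(all(nchar(lines[-1]) <= 80))
  expect_equal(max(nchar(lines[-1])), 80)
  expect_identical(unname(read_reference_fasta(path)), ref$unit_sequence)
})
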
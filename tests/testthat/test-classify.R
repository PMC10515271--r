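raw_cov <- function(counts, read_length = 75L) {
  structure(
    tibble::tibble(position = seq_along(counts) - 1L, count = as.numeric(counts)),
    n_mapped = as.integer(round(sum(counts) / read_length)),
    read_length = read_length, unit_length = length(counts),
    class = c("coverage_track", class(tibble::tibble()))
  )
}

test_that("peak calling: degenerate tracks, rectangular bumps, width filter", {
  cfg <- classifier_config()
  # constant track: SD 0, threshold = mean, no strict exceedance
  expect_equal(nrow(call_peaks(rep(2, 5000), cfg)), 0L)

  # rectangular bump of width 300, height far above noise: exactly one peak
  v <- withr::with_seed(10L, rnorm(5000, 0, 0.01))
  v[1001:1300] <- v[1001:1300] + 5
  pk <- call_peaks(v, cfg)
  expect_equal(nrow(pk), 1L)
  expect_lte(pk$start, 1050); expect_gte(pk$end, 1250)  # covers the bump core
  expect_true(pk$summit >= 1000 && pk$summit < 1300)
  expect_gte(pk$max_ratio, pk$mean_ratio)

  # bump of width 20 < min_peak_width 50: rejected
  v2 <- withr::with_seed(11L, rnorm(5000, 0, 0.01))
  v2[1001:1020] <- v2[1001:1020] + 5
  expect_equal(nrow(call_peaks(v2, cfg)), 0L)

  # a bump spanning the circular origin is reported as one wrapping peak
  v3 <- withr::with_seed(12L, rnorm(5000, 0, 0.01))
  v3[c(4901:5000, 1:100)] <- v3[c(4901:5000, 1:100)] + 5
  pk3 <- call_peaks(v3, cfg)
  expect_equal(nrow(pk3), 1L)
  expect_gt(pk3$end, 5000L)
})

test_that("emergence test removes peaks with a coincident input bump", {
  cfg <- classifier_config()
  peaks <- tibble::tibble(start = 1000L, end = 1300L, width = 300L,
                          summit = 1150L, max_ratio = 3, mean_ratio = 2.5)
  uniform_input <- raw_cov(withr::with_seed(13L, rpois(5000, 300)))
  expect_equal(nrow(emergence_test(peaks, uniform_input, cfg)), 1L)

  bumped <- track_values(uniform_input)
  bumped[1001:1300] <- bumped[1001:1300] * 4
  expect_equal(nrow(emergence_test(peaks, raw_cov(bumped), cfg)), 0L)
})

test_that("gene-body and intergenic input rules score 1.0 on uniform input", {
  ann <- default_ann()
  cfg <- classifier_config()
  uni <- raw_cov(rep(100, 5000))
  gb <- detect_gene_body_bias(uni, ann, cfg)
  expect_equal(gb$score, 1.0)
  expect_false(gb$flag)
  ig <- detect_intergenic_depletion(uni, ann, cfg)
  expect_equal(ig$score, 1.0)
  expect_false(ig$flag)

  # a score exactly at the cutoff does not flag (strict inequalities)
  ig_mask <- !hlbscreen:::feature_mask(ann, c("gene", "promoter"))
  v <- rep(1, 5000)
  # solve for intergenic value giving score exactly intergenic_ratio_min
  f <- mean(ig_mask)
  x <- cfg$intergenic_ratio_min * (1 - f) / (1 - cfg$intergenic_ratio_min * f)
  v[ig_mask] <- x
  ig2 <- detect_intergenic_depletion(raw_cov(v * 1000), ann, cfg)
  expect_equal(ig2$score, cfg$intergenic_ratio_min, tolerance = 1e-12)
  expect_false(ig2$flag)

  # gene-less annotation is a hard error for the gene-body rule
  toy <- structure(
    tibble::tibble(name = "p", kind = "promoter", start = 0L, end = 100L,
                   strand = "."),
    unit_length = 200L, class = c("histone_annotation", class(tibble::tibble()))
  )
  expect_error(detect_gene_body_bias(raw_cov(rep(1, 200)), toy, cfg), "gene-body")
  # ...while an intergenic-less annotation reports not-applicable, no flag
  tiled <- structure(
    tibble::tibble(name = "g", kind = "gene", start = 0L, end = 200L, strand = "+"),
    unit_length = 200L, class = c("histone_annotation", class(tibble::tibble()))
  )
  res <- detect_intergenic_depletion(raw_cov(rep(1, 200)), tiled, cfg)
  expect_false(res$flag)
  expect_false(res$applicable)
  expect_true(is.na(res$score))
})

test_that("input-identity rule needs both high correlation and real structure", {
  ann <- default_ann()
  cfg <- classifier_config()
  expect_equal(detect_input_identity(raw_cov(1:5000), raw_cov(1:5000), cfg)$correlation, 1.0)

  # independent flat-noise tracks: near-zero correlation, no flag
  a <- raw_cov(withr::with_seed(14L, rpois(5000, 500)))
  b <- raw_cov(withr::with_seed(15L, rpois(5000, 500)))
  res <- detect_input_identity(a, b, cfg)
  expect_lt(abs(res$correlation), 0.2)
  expect_false(res$flag)

  # identical structured tracks with a strong shared peak: flagged
  shape <- rep(100, 5000); shape[2001:2300] <- 800
  noisy <- function(seed) raw_cov(withr::with_seed(seed, rpois(5000, shape)))
  res2 <- detect_input_identity(noisy(16L), noisy(17L), cfg)
  expect_gt(res2$correlation, cfg$identity_corr_min)
  expect_true(res2$flag)

  # zero variance: undefined correlation, never flags
  res3 <- detect_input_identity(raw_cov(rep(5, 100)), raw_cov(rep(7, 100)), cfg)
  expect_true(is.na(res3$correlation))
  expect_false(res3$flag)

  expect_error(detect_input_identity(raw_cov(rep(1, 10)), raw_cov(rep(1, 20)), cfg),
               "mismatch")
})

test_that("GA-repeat rule is inclusive at 50 bp and off above it", {
  ann <- default_ann()
  cfg <- classifier_config()
  ga1 <- dplyr::filter(ann, name == "ga_repeat_1")
  over_ga <- tibble::tibble(start = ga1$start - 20L, end = ga1$end + 20L,
                            width = ga1$end - ga1$start + 40L,
                            summit = ga1$start + 10L, max_ratio = 3, mean_ratio = 2)
  away <- tibble::tibble(start = 3000L, end = 3100L, width = 100L,
                         summit = 3050L, max_ratio = 3, mean_ratio = 2)
  peaks <- dplyr::bind_rows(over_ga, away)
  expect_equal(detect_ga_artifact(peaks, ann, 36, cfg)$ga_artifact, c(TRUE, FALSE))
  expect_equal(detect_ga_artifact(peaks, ann, 50, cfg)$ga_artifact, c(TRUE, FALSE))
  expect_equal(detect_ga_artifact(peaks, ann, 51, cfg)$ga_artifact, c(FALSE, FALSE))
  expect_equal(detect_ga_artifact(peaks, ann, 100, cfg)$ga_artifact, c(FALSE, FALSE))
})

test_that("peaks are assigned to elements by summit and 25% overlap", {
  ann <- default_ann()
  h34 <- dplyr::filter(ann, name == "H3_H4_promoter")

  inside <- tibble::tibble(start = h34$start + 50L, end = h34$end - 50L,
                           width = h34$end - h34$start - 100L,
                           summit = h34$start + 100L, max_ratio = 2, mean_ratio = 1)
  expect_equal(assign_elements(inside, ann)$elements[[1]], "H3_H4_promoter")

  intergenic <- tibble::tibble(start = 1400L, end = 1600L, width = 200L,
                               summit = 1500L, max_ratio = 2, mean_ratio = 1)
  expect_length(assign_elements(intergenic, ann)$elements[[1]], 0L)

  # summit in H1_promoter, 30% tail overlap into the H1 gene body:
  # promoter listed first, gene second
  h1p <- dplyr::filter(ann, name == "H1_promoter")
  w <- 200L
  tail_in_gene <- 60L   # 30% of width
  pk <- tibble::tibble(start = h1p$end - (w - tail_in_gene),
                       end = h1p$end + tail_in_gene, width = w,
                       summit = h1p$end - 80L, max_ratio = 2, mean_ratio = 1)
  expect_equal(assign_elements(pk, ann)$elements[[1]], c("H1_promoter", "H1"))

  # 19% overlap without the summit is not enough
  pk2 <- tibble::tibble(start = h1p$end - 162L, end = h1p$end + 38L, width = 200L,
                        summit = h1p$end - 100L, max_ratio = 2, mean_ratio = 1)
  expect_equal(assign_elements(pk2, ann)$elements[[1]], "H1_promoter")
})

test_that("end-to-end: TRUE_PROMOTER positive with correct localization, NONE negative", {
  call <- classify_sim("TRUE_PROMOTER", seed = 11)
  expect_equal(call$label, "positive")
  expect_length(call$flags, 0L)
  expect_true("H3_H4_promoter" %in% call$localization)

  call0 <- classify_sim("NONE", seed = 11)
  expect_equal(call0$label, "negative")
  expect_length(call0$flags, 0L)
  expect_equal(nrow(call0$emergent_peaks), 0L)
})

test_that("end-to-end: INPUT_IDENTICAL yields zero emergent peaks and the identity flag", {
  call <- classify_sim("INPUT_IDENTICAL", seed = 19)
  expect_equal(call$label, "negative")
  expect_equal(nrow(call$emergent_peaks), 0L)
  expect_true("INPUT_IDENTICAL" %in% call$flags)
  expect_gt(call$diagnostics$identity_correlation, 0.95)
})

test_that("end-to-end: bias modes are rejected with the matching input-bias flag", {
  gb <- classify_sim("GENE_BODY_BIAS", seed = 23)
  expect_equal(gb$label, "negative")
  expect_true("GENE_BODY_BIAS" %in% gb$flags)
  expect_gt(gb$diagnostics$genebody_score, gb$config$genebody_ratio_max)

  ig <- classify_sim("INTERGENIC_DEPLETION", seed = 23)
  expect_equal(ig$label, "negative")
  expect_true("INTERGENIC_DEPLETION" %in% ig$flags)
  expect_lt(ig$diagnostics$intergenic_score, ig$config$intergenic_ratio_min)
})

test_that("end-to-end: GA_ARTIFACT at 36 bp is rejected with the GA flag", {
  call <- classify_sim("GA_ARTIFACT", seed = 29, read_length = 36L)
  expect_equal(call$label, "negative")
  expect_true("GA_ARTIFACT" %in% call$flags)
  # the flagged pileup sits over a GA-repeat element
  flagged <- dplyr::filter(call$called_peaks, ga_artifact)
  expect_gte(nrow(flagged), 1L)
  ga <- dplyr::filter(default_ann(), kind == "ga_repeat")
  expect_true(any(flagged$start < max(ga$end) & flagged$end > min(ga$start)))
})

test_that("a call is never positive with an empty emergent-peak set", {
  for (m in c("NONE", "TRUE_PROMOTER", "INPUT_IDENTICAL", "GA_ARTIFACT")) {
    call <- classify_sim(m, seed = 37,
                         read_length = if (m == "GA_ARTIFACT") 36L else 75L)
    if (call$label == "positive") {
      expect_gt(nrow(call$emergent_peaks), 0L)
      expect_true(any(!call$emergent_peaks$ga_artifact))
    }
  }
})

test_that("replicate combination is conservative and unions the flags", {
  pos <- classify_sim("TRUE_PROMOTER", seed = 41)
  neg_ga <- classify_sim("GA_ARTIFACT", seed = 41, read_length = 36L)
  neg_id <- classify_sim("INPUT_IDENTICAL", seed = 41)

  both_pos <- classify_replicates(list(pos, pos))
  expect_equal(both_pos$label, "positive")
  expect_true("H3_H4_promoter" %in% both_pos$localization)

  mixed <- classify_replicates(list(pos, neg_ga))
  expect_equal(mixed$label, "negative")

  both_neg <- classify_replicates(list(neg_ga, neg_id))
  expect_equal(both_neg$label, "negative")
  expect_true(all(c("GA_ARTIFACT", "INPUT_IDENTICAL") %in% both_neg$flags))

  expect_error(classify_replicates(list()), "at least one")
})
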
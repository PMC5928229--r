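enr_row <- function(orf, score, fc_mfp = 1, pool = "P01", n_pairs = 5,
                    included = n_pairs >= 3) {
  tibble::tibble(pool_id = pool, orf_id = orf, n_pairs = as.integer(n_pairs),
                 mean_fc_mfp = fc_mfp, mean_lung_vs_mfp = score,
                 log2_lung_vs_mfp = log2(score), included = included)
}

test_that("the control cutoff is the mean GFP score across pools, with fallback 5", {
  enr <- dplyr::bind_rows(
    enr_row("GFP", 4, pool = "P01"),
    enr_row("GFP", 5, pool = "P02"),
    enr_row("GFP", 6, pool = "P03")
  )
  expect_equal(control_cutoff(enr), 5)
  expect_equal(control_cutoff(enr_row("GFP", 7)), 7)
  expect_warning(fb <- control_cutoff(enr_row("ORF01", 9)), "fall")
  expect_equal(fb, 5)
  # controls failing the matched-pair rule cannot define the threshold
  expect_warning(fb2 <- control_cutoff(enr_row("GFP", 50, n_pairs = 2)), "fall")
  expect_equal(fb2, 5)
  expect_error(control_cutoff(enr, fallback = -1),
               class = "metscreen_config_error")
})

test_that("quadrant classification follows the two axes with ties counting as enriched", {
  expect_equal(classify_quadrant(0.4, 6, lung_cutoff = 5), "lung_only")
  expect_equal(classify_quadrant(3, 6, lung_cutoff = 5), "lung_and_mfp")
  expect_equal(classify_quadrant(0.5, 2, lung_cutoff = 5), "neither")
  expect_equal(classify_quadrant(2, 2, lung_cutoff = 5), "mfp_only")
  expect_equal(classify_quadrant(1, 5, lung_cutoff = 5), "lung_and_mfp")
})

test_that("the mammary-depletion criterion is an at-least-two-fold rule", {
  expect_true(mammary_depletion_filter(0.5))
  expect_false(mammary_depletion_filter(0.51))
  expect_true(mammary_depletion_filter(0.25))
  expect_error(mammary_depletion_filter(0.5, fold_threshold = 0.5),
               class = "metscreen_argument_error")
})

test_that("hits are thresholded, densely ranked and deterministically tie-broken", {
  man <- tiny_manifest(4)
  enr <- dplyr::bind_rows(
    enr_row("ORF01", 7), enr_row("ORF02", 5.1), enr_row("ORF03", 4.9),
    enr_row("ORF04", 7),             # tie with ORF01
    enr_row("GFP", 5)
  )
  hits <- call_hits(enr, man, cutoff = 5)
  called <- hits[hits$is_hit, ]
  expect_equal(called$orf_id, c("ORF01", "ORF04", "ORF02"))
  expect_equal(called$rank, 1:3)
  expect_true(all(is.na(hits$rank[!hits$is_hit])))
})

test_that("excluded genes and control constructs are never hits", {
  man <- tiny_manifest(2)
  enr <- dplyr::bind_rows(
    enr_row("ORF01", 50, n_pairs = 2),   # huge score, too few pairs
    enr_row("ORF02", 6),
    enr_row("GFP", 40)                   # control beats every candidate
  )
  hits <- suppressWarnings(call_hits(enr, man, cutoff = 5))
  expect_false(hits$is_hit[hits$orf_id == "ORF01"])
  expect_false(hits$is_hit[hits$orf_id == "GFP"])
  expect_true(is.na(hits$rank[hits$orf_id == "GFP"]))
  expect_true(hits$is_hit[hits$orf_id == "ORF02"])
})

test_that("raising the cutoff never adds a hit and quadrants partition included genes", {
  man <- tiny_manifest(8)
  set.seed(31)
  enr <- dplyr::bind_rows(purrr::map(1:8, function(i) {
    enr_row(sprintf("ORF%02d", i), score = runif(1, 0.1, 10),
            fc_mfp = runif(1, 0.2, 3))
  }), enr_row("GFP", 2))
  cutoffs <- c(0.5, 1, 2, 4, 8)
  hit_sets <- purrr::map(cutoffs, function(ct) {
    h <- call_hits(enr, man, cutoff = ct)
    h$orf_id[h$is_hit]
  })
  for (i in seq_along(cutoffs)[-1]) {
    expect_true(all(hit_sets[[i]] %in% hit_sets[[i - 1]]))
  }
  h <- call_hits(enr, man, cutoff = 2)
  inc <- h[h$included, ]
  expect_true(all(inc$quadrant %in%
                    c("lung_and_mfp", "lung_only", "mfp_only", "neither")))
  expect_equal(sum(table(inc$quadrant)), nrow(inc))
})

test_that("alternative hit modes implement the depletion and conjunction rules", {
  man <- tiny_manifest(3)
  enr <- dplyr::bind_rows(
    enr_row("ORF01", 8, fc_mfp = 0.4),   # lung-enriched and depleted
    enr_row("ORF02", 8, fc_mfp = 1.2),   # lung-enriched only
    enr_row("ORF03", 1, fc_mfp = 0.3),   # depleted only
    enr_row("GFP", 5)
  )
  lung <- call_hits(enr, man, cutoff = 5, hit_mode = "lung")
  expect_setequal(lung$orf_id[lung$is_hit], c("ORF01", "ORF02"))
  dep <- call_hits(enr, man, cutoff = 5, hit_mode = "mfp_depletion")
  expect_setequal(dep$orf_id[dep$is_hit], c("ORF01", "ORF03"))
  both <- call_hits(enr, man, cutoff = 5, hit_mode = "both")
  expect_setequal(both$orf_id[both$is_hit], "ORF01")
  empty <- call_hits(enr[0, ], man, cutoff = 5)
  expect_equal(nrow(empty), 0)
})
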
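mini_cq <- function(rows) {
  tibble::tibble(
    sample_id = rows$s, mouse_id = rows$m %||% NA_character_,
    pool_id = "P01", compartment = rows$c, probe = rows$p,
    replicate = rows$r, cq = rows$q, censored = rows$x %||% FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("replicate collapsing averages uncensored wells and propagates censoring", {
  cq <- mini_cq(list(s = "S1", c = "mfp", m = "M1",
                     p = rep(c("ORF01", "ORF02", "ORF03", "DNA_REF"), each = 3),
                     r = rep(1:3, 4),
                     q = c(24.0, 24.2, 24.4, 25.0, 40, 40, 40, 40, 40, 18, 18, 18),
                     x = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                           TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  col <- collapse_replicates(cq)
  expect_equal(col$cq[col$probe == "ORF01"], 24.2)
  expect_equal(col$n_replicates_used[col$probe == "ORF01"], 3L)
  expect_equal(col$cq[col$probe == "ORF02"], 25.0)
  expect_equal(col$n_replicates_used[col$probe == "ORF02"], 1L)
  expect_true(col$censored[col$probe == "ORF03"])
  expect_equal(col$cq[col$probe == "ORF03"], 40)
  expect_error(collapse_replicates(cq, policy = "harmonic"),
               class = "metscreen_argument_error")
})

test_that("delta-Ct subtracts the DNA probe and errors name the offending sample", {
  cq <- mini_cq(list(s = "S1", c = "mfp", m = "M1",
                     p = c("ORF01", "ORF02", "DNA_REF"), r = 1,
                     q = c(25, 20, 20)))
  norm <- normalize_to_dna(collapse_replicates(cq))
  expect_equal(norm$delta_ct[norm$orf_id == "ORF01"], 5)
  expect_equal(norm$delta_ct[norm$orf_id == "ORF02"], 0)

  no_dna <- cq[cq$probe != "DNA_REF", ]
  expect_error(normalize_to_dna(collapse_replicates(no_dna)), regexp = "S1")
})

test_that("fold changes follow 2^-ddCt with the reference mapping to exactly 1", {
  man <- tiny_manifest(3)
  sim <- simulate_pool(partition_library(man), seed = 8)
  fc <- sim$cq %>% collapse_replicates() %>% normalize_to_dna() %>%
    fold_change_vs_reference()
  ref_rows <- fc[fc$compartment == "reference", ]
  expect_true(all(ref_rows$fold_change == 1))
  # a one-cycle lower delta Ct than the reference doubles representation
  norm <- tibble::tibble(sample_id = c("P01_ref", "S"), mouse_id = c(NA, "M1"),
                         pool_id = "P01", compartment = c("reference", "mfp"),
                         orf_id = "ORF01", delta_ct = c(6, 5), censored = FALSE)
  expect_equal(fold_change_vs_reference(norm)$fold_change[2], 2)
})

test_that("sample-wide Cq shifts cancel: DNA normalisation is the invariance that matters", {
  for (seed in 1:25) {
    cq <- random_cq_table(n_orfs = 4, n_mice = 3, seed = seed)
    base <- quantify_screen(cq, min_pairs = 1)
    shifted <- cq
    victim <- sample(unique(cq$sample_id), 1)
    shifted$cq[shifted$sample_id == victim] <-
      shifted$cq[shifted$sample_id == victim] + 1.3
    after <- quantify_screen(shifted, min_pairs = 1)
    expect_equal(after$mean_lung_vs_mfp, base$mean_lung_vs_mfp,
                 tolerance = 1e-12)
    expect_equal(after$mean_fc_mfp, base$mean_fc_mfp, tolerance = 1e-12)
  }
})

test_that("lowering one barcode's Cq raises exactly that fold change and no other", {
  cq <- random_cq_table(n_orfs = 4, n_mice = 2, seed = 99)
  fc0 <- cq %>% collapse_replicates() %>% normalize_to_dna() %>%
    fold_change_vs_reference()
  target_sample <- "P01_M01_MFP"; target_orf <- "ORF02"
  cq2 <- cq
  sel <- cq2$sample_id == target_sample & cq2$probe == target_orf
  cq2$cq[sel] <- cq2$cq[sel] - 0.7
  fc1 <- cq2 %>% collapse_replicates() %>% normalize_to_dna() %>%
    fold_change_vs_reference()
  key0 <- paste(fc0$sample_id, fc0$orf_id)
  key1 <- paste(fc1$sample_id, fc1$orf_id)
  fc1 <- fc1[match(key0, key1), ]
  moved <- fc1$fold_change != fc0$fold_change
  expect_equal(sum(moved), 1)
  expect_true(fc1$fold_change[moved] > fc0$fold_change[moved])
  expect_equal(paste(fc1$sample_id[moved], fc1$orf_id[moved]),
               paste(target_sample, target_orf))
})

test_that("matched pairs require both compartments and divide lung by MFP", {
  fc <- tibble::tibble(
    pool_id = "P01",
    mouse_id = c("M1", "M1", "M2"),
    compartment = c("mfp", "lung", "mfp"),
    orf_id = "ORF01",
    sample_id = c("a", "b", "c"),
    fold_change = c(2, 8, 3),
    censored = FALSE
  )
  pairs <- matched_pairs(fc)
  expect_equal(nrow(pairs), 1)            # M2 has no lung
  expect_equal(pairs$lung_vs_mfp, 4)
  dup <- rbind(fc, fc[1, ])
  expect_error(matched_pairs(dup), class = "metscreen_data_error")
})

test_that("gene aggregation applies the minimum matched-pair rule", {
  pairs <- tibble::tibble(
    pool_id = "P01",
    mouse_id = c("M1", "M2", "M3", "M1", "M2"),
    orf_id = c("A", "A", "A", "B", "B"),
    fc_mfp = c(1, 1, 1, 2, 2),
    fc_lung = c(6, 7, 8, 2, 2),
    lung_vs_mfp = c(6, 7, 8, 1, 1)
  )
  enr <- aggregate_genes(pairs, min_pairs = 3)
  a <- enr[enr$orf_id == "A", ]
  expect_equal(a$mean_lung_vs_mfp, 7)
  expect_true(a$included)
  b <- enr[enr$orf_id == "B", ]
  expect_false(b$included)
  expect_equal(b$n_pairs, 2L)
  geo <- aggregate_genes(pairs, min_pairs = 3, mean_type = "geometric")
  expect_equal(geo$mean_lung_vs_mfp[geo$orf_id == "A"],
               exp(mean(log(c(6, 7, 8)))))
})

test_that("the pipeline equals an independent brute-force ddCt recomputation", {
  for (seed in c(1, 2, 3, 4)) {
    cq <- random_cq_table(n_orfs = sample(2:5, 1), n_mice = sample(2:4, 1),
                          seed = seed, censor_prob = 0.05)
    got <- quantify_screen(cq)
    want <- oracle_ddct(cq)
    want <- want[order(want$pool_id, want$orf_id), ]
    got <- got[order(got$pool_id, got$orf_id), ]
    expect_equal(got$n_pairs, want$n_pairs)
    expect_true(all(abs(got$mean_lung_vs_mfp / want$mean_lung_vs_mfp - 1)
                    <= 1e-12))
    expect_true(all(abs(got$mean_fc_mfp / want$mean_fc_mfp - 1) <= 1e-12))
    expect_equal(got$included, want$included)
  }
})

test_that("the drop policy removes censored measurements and their pairs", {
  cq <- random_cq_table(n_orfs = 3, n_mice = 3, seed = 7, censor_prob = 0.3)
  imp <- quantify_screen(cq, min_pairs = 1, censor_policy = "impute")
  drp <- quantify_screen(cq, min_pairs = 1, censor_policy = "drop")
  expect_true(sum(drp$n_pairs) < sum(imp$n_pairs))
})
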
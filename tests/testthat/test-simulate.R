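test_that("neutral noiseless exact simulation gives fold change 1 at every stage", {
  man <- tiny_manifest(5)
  plan <- partition_library(man)
  sim <- simulate_pool(plan, exact_config(), neutral_effects(man), seed = 1)
  fc <- sim$cq %>%
    collapse_replicates() %>%
    normalize_to_dna() %>%
    fold_change_vs_reference()
  expect_true(all(abs(fc$fold_change - 1) < 1e-9))
  enr <- quantify_screen(sim$cq)
  expect_true(all(abs(enr$mean_lung_vs_mfp - 1) < 1e-9))
  expect_true(all(abs(enr$mean_fc_mfp - 1) < 1e-9))
})

test_that("a single driver's exact-mode lung share matches the closed form", {
  man <- tiny_manifest(7)
  eff <- neutral_effects(man)
  eff$m[eff$orf_id == "ORF01"] <- 3
  k <- nrow(man)
  sim <- simulate_pool(plan <- partition_library(man), exact_config(), eff, seed = 2)
  lung <- sim$truth[sim$truth$compartment == "lung", ]
  expected <- 2^3 / (2^3 + (k - 1))   # equal p cancels
  expect_equal(unique(lung$proportion[lung$orf_id == "ORF01"]), expected,
               tolerance = 1e-12)
  # and the enrichment score equals p_lung / p_mfp in the deterministic limit
  enr <- quantify_screen(sim$cq)
  expect_equal(enr$mean_lung_vs_mfp[enr$orf_id == "ORF01"],
               expected * k, tolerance = 1e-9)
})

test_that("zero take rate yields no lung samples but intact MFP and reference", {
  man <- tiny_manifest(4)
  sim <- simulate_pool(partition_library(man),
                       simulation_config(metastasis_take_rate = 0), seed = 3)
  expect_equal(sum(sim$cq$compartment == "lung"), 0)
  expect_equal(dplyr::n_distinct(sim$cq$sample_id[sim$cq$compartment == "mfp"]), 10)
  expect_true(any(sim$cq$compartment == "reference"))
  # and no pairs -> empty enrichment is handled downstream
  enr <- quantify_screen(sim$cq)
  expect_equal(nrow(enr), 0)
})

test_that("true proportions are conserved and Cq never exceeds the detection limit", {
  man <- tiny_manifest(6)
  cfg <- simulation_config(lung_seeding_rate = 3)
  sim <- simulate_pool(partition_library(man), cfg, seed = 4)
  sums <- sim$truth %>%
    dplyr::group_by(mouse_id, compartment) %>%
    dplyr::summarise(s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(sim$cq$cq <= cfg$detection_limit + 1e-12))
  expect_true(all(sim$cq$cq[sim$cq$censored] == cfg$detection_limit))
})

test_that("simulation is byte-identical for a fixed seed and differs across seeds", {
  man <- tiny_manifest(5)
  plan <- partition_library(man)
  a <- simulate_pool(plan, seed = 11)
  b <- simulate_pool(plan, seed = 11)
  c <- simulate_pool(plan, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$cq$cq, c$cq$cq))
  # distinct substreams: noise draws differ between pools of a screen
  scr <- simulate_screen(rbind(plan, within(plan, pool_id <- "P02")), seed = 13)
  ref_cq <- scr$cq[scr$cq$compartment == "reference" & scr$cq$probe == "GFP", ]
  expect_false(identical(ref_cq$cq[ref_cq$pool_id == "P01"],
                         ref_cq$cq[ref_cq$pool_id == "P02"]))
})

test_that("with noise off and a large engraftment the MFP matches the expansion formula", {
  man <- tiny_manifest(4)
  eff <- neutral_effects(man)
  eff$g <- c(0.1, 0, 0, -0.05, 0)   # per-unit-time log2 growth offsets
  cfg <- simulation_config(n_engraft = 1e6, cq_noise_sd = 0, dna_probe_sd = 0,
                           primary_doublings = 10)
  sim <- simulate_pool(partition_library(man), cfg, eff, seed = 6)
  k <- nrow(man)
  w <- 2^(eff$g[match(man$orf_id, eff$orf_id)] * 10)
  expected <- w / sum(w)
  mfp <- sim$truth[sim$truth$compartment == "mfp", ]
  for (orf in man$orf_id) {
    obs <- mfp$proportion[mfp$orf_id == orf]
    expect_true(all(abs(obs / expected[man$orf_id == orf] - 1) < 0.01),
                info = orf)
  }
})

test_that("a 20-pool screen emits one reference per pool and bounded sample counts", {
  man <- make_manifest(230, barcode_seed = NULL)
  plan <- partition_library(man)
  sim <- simulate_screen(plan, seed = 21)
  by_comp <- table(unique(sim$cq[c("sample_id", "compartment")])$compartment)
  expect_equal(unname(by_comp["reference"]), 20)
  expect_equal(unname(by_comp["mfp"]), 200)
  expect_lte(unname(by_comp["lung"]), 200)
  expect_equal(anyDuplicated(unique(sim$cq$sample_id)), 0L)
  expect_error(
    simulate_screen(dplyr::mutate(plan, pool_id = "P01")[1:26, ]),
    class = "metscreen_config_error")
})
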
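#' Driver-recovery benchmark on a fully simulated screen
#'
#' Simulates complete screens in the published format (candidate library
#' partitioned into pools with a GFP control, 10 mice per pool), plants a
#' known set of metastasis drivers, runs the delta-delta-Ct quantification
#' and empirical-control hit calling, and scores how well the known
#' drivers are recovered.
#'
#' Recall is the fraction of planted drivers called as hits; the
#' false-positive rate is the fraction of eligible (included) neutral
#' candidates called as hits.
#'
#' @param seeds Integer vector; one full screen is simulated per seed.
#' @param n_candidates Candidate library size.
#' @param n_drivers Number of planted drivers.
#' @param driver_m Log2 metastasis advantage of each driver.
#' @param driver_g Log2 primary-growth offset of each driver.
#' @param config A [screen_config()]; its seed is overridden per run.
#' @return Tibble with one row per seed: `seed`, `cutoff`, `n_drivers`,
#'   `drivers_detected`, `recall`, `n_neutral_included`,
#'   `false_positives`, `fpr`.
#' @examples
#' \donttest{
#' driver_recovery(seeds = 1, n_candidates = 60, n_drivers = 4)
#' }
#' @export
driver_recovery <- function(seeds, n_candidates = 230L, n_drivers = 10L,
                            driver_m = 3, driver_g = 0,
                            config = screen_config()) {
  n_drivers <- check_count(n_drivers, "n_drivers")
  purrr::map_dfr(seeds, function(seed) {
    cfg <- config
    cfg$seed <- check_count(seed, "seed", min = 0L)
    cfg$n_candidates <- check_count(n_candidates, "n_candidates")
    manifest <- make_manifest(cfg$n_candidates, control = cfg$controls[1],
                              barcode_seed = NULL, config = cfg$design)
    cand_ids <- manifest$orf_id[manifest$role == "candidate"]
    drivers <- withr::with_seed(derive_seed(seed, 101L),
                                sample(cand_ids, n_drivers))
    effects <- set_drivers(default_effects(manifest, cfg$sim), drivers,
                           m = driver_m, g = driver_g)
    screen <- run_screen(cfg, manifest = manifest, effects = effects)
    hits <- screen$hits
    is_driver <- hits$orf_id %in% drivers
    neutral <- hits$role == "candidate" & !is_driver & hits$included
    tibble(
      seed = seed,
      cutoff = screen$cutoff,
      n_drivers = n_drivers,
      drivers_detected = sum(hits$is_hit & is_driver),
      recall = sum(hits$is_hit & is_driver) / n_drivers,
      n_neutral_included = sum(neutral),
      false_positives = sum(hits$is_hit & neutral),
      fpr = sum(hits$is_hit & neutral) / sum(neutral)
    )
  })
}
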
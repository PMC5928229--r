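# Monte-Carlo detection power of the pooled screen format.

# One simulated complexity pool: a single driver, n_neutral neutral ORFs and
# the GFP control, run through the full quantification + hit-calling chain.
# Returns TRUE when the driver is called a hit under the default
# (control-derived, fallback) cutoff.
simulate_detection <- function(n_neutral, driver_m, config, seed, mice,
                               min_pairs = 3L, fallback = 5) {
  manifest <- tibble(
    orf_id = c("DRIVER", sprintf("NEUT%03d", seq_len(n_neutral)), "GFP"),
    gene_symbol = c("DRIVER", sprintf("NEUT%03d", seq_len(n_neutral)), "GFP"),
    role = c(rep("candidate", n_neutral + 1L), "negative_control"),
    barcode = NA_character_
  )
  effects <- set_drivers(default_effects(manifest, config), "DRIVER", m = driver_m)
  sim <- simulate_pool(manifest, config, effects, seed = seed,
                       pool_id = "P01", mice = mice)
  enr <- quantify_screen(sim$cq, min_pairs = min_pairs)
  hits <- suppressWarnings(
    call_hits(enr, manifest, fallback = fallback, hit_mode = "lung")
  )
  isTRUE(any(hits$is_hit & hits$orf_id == "DRIVER"))
}

#' Monte-Carlo power of driver detection versus pool size
#'
#' For each pool size, simulates `reps` screens of one driver, `size - 1`
#' neutral ORFs and the GFP control, and reports the fraction in which the
#' driver is called a hit under the default control-derived cutoff. The
#' same per-rep seeds are reused across pool sizes (a paired design), so
#' the size comparison is not diluted by between-rep noise.
#'
#' This is the analysis behind the choice of a maximum pool size: a driver
#' diluted 1:9 remains detectable while dilution towards 1:19 erodes
#' detection through the lung-seeding bottleneck.
#'
#' @param sizes Integer vector of total candidate counts per pool
#'   (driver + neutrals); each must be at least 2.
#' @param driver_effect Log2 metastasis advantage of the driver (default
#'   3, the package's driver scale).
#' @param config A [simulation_config()].
#' @param reps Monte-Carlo replicates per size.
#' @param seed Root seed.
#' @param mice Mice per simulated pool.
#' @param min_pairs Minimum matched pairs for inclusion.
#' @return Tibble `pool_size`, `reps`, `detected`, `power`, `mc_se`
#'   (binomial Monte-Carlo standard error).
#' @examples
#' \donttest{
#' pool_size_power(c(5, 12), reps = 20, seed = 1)
#' }
#' @export
pool_size_power <- function(sizes, driver_effect = 3,
                            config = simulation_config(), reps = 200L,
                            seed = config$rng_seed, mice = 10L,
                            min_pairs = 3L) {
  reps <- check_count(reps, "reps")
  sizes <- vapply(sizes, check_count, integer(1), name = "sizes", min = 2L)
  purrr::map_dfr(sizes, function(size) {
    det <- vapply(seq_len(reps), function(r) {
      simulate_detection(size - 1L, driver_effect, config,
                         seed = derive_seed(seed, r), mice = mice,
                         min_pairs = min_pairs)
    }, logical(1))
    p <- mean(det)
    tibble(pool_size = size, reps = reps, detected = sum(det), power = p,
           mc_se = sqrt(p * (1 - p) / reps))
  })
}

#' Detection frequency of a diluted driver (complexity experiment)
#'
#' Emulates the pre-screen complexity test: one driver mixed with
#' `neutrals` non-driver ORFs (a driver:neutral ratio of `1:neutrals`),
#' implanted into `mice` mice, and scored for whether the driver is called
#' a hit. Comparing, e.g., 1:10 against 1:19 reproduces the
#' detectable-versus-masked contrast that motivated the pool-size limit.
#'
#' @param neutrals Number of neutral ORFs pooled with the single driver
#'   (the ratio denominator, >= 1).
#' @param driver_effect Log2 metastasis advantage of the driver.
#' @param config A [simulation_config()].
#' @param reps Monte-Carlo replicates (>= 1).
#' @param seed Root seed.
#' @param mice Mice per replicate.
#' @param min_pairs Minimum matched pairs for inclusion.
#' @return Tibble `ratio`, `neutrals`, `reps`, `detected`, `frequency`,
#'   `mc_se`.
#' @examples
#' \donttest{
#' complexity_experiment(10, reps = 20, seed = 1)
#' }
#' @export
complexity_experiment <- function(neutrals, driver_effect = 3,
                                  config = simulation_config(), reps = 200L,
                                  seed = config$rng_seed, mice = 10L,
                                  min_pairs = 3L) {
  neutrals <- check_count(neutrals, "neutrals")
  reps <- check_count(reps, "reps")
  det <- vapply(seq_len(reps), function(r) {
    simulate_detection(neutrals, driver_effect, config,
                       seed = derive_seed(seed, r), mice = mice,
                       min_pairs = min_pairs)
  }, logical(1))
  p <- mean(det)
  tibble(ratio = sprintf("1:%d", neutrals), neutrals = neutrals, reps = reps,
         detected = sum(det), frequency = p, mc_se = sqrt(p * (1 - p) / reps))
}
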
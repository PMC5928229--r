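#' Simulation configuration for the in vivo screen generative model
#'
#' Parameters of the stochastic model that stands in for the wet-lab
#' screen. Per mouse, the model runs the chain: equal-representation
#' reference pellet -> multinomial engraftment bottleneck -> exponential
#' primary expansion in the mammary fat pad (MFP) -> Poisson lung-seeding
#' bottleneck -> Cq emission with technical noise and censoring at the
#' detection limit.
#'
#' Per-ORF effects act in log2 units so simulator truth and
#' delta-delta-Ct output share a scale: an ORF with primary-growth offset
#' `g` multiplies its MFP count by `2^(g * primary_doublings)`, and one
#' with metastasis advantage `m` multiplies its expected lung seeding by
#' `2^m` (seeding and outgrowth are deliberately folded into the single
#' advantage `m`; endpoint genomic DNA cannot distinguish them).
#'
#' @param n_engraft Cells sampled per mouse at implantation (multinomial
#'   size of the engraftment bottleneck).
#' @param primary_doublings Dimensionless expansion time of the primary
#'   tumour; multiplies `g`.
#' @param lung_seeding_rate Expected number of cells seeding the lungs per
#'   mouse (Poisson mean at neutral effects); small values give the severe
#'   clonal bottleneck characteristic of metastasis.
#' @param cq_intercept Cq emitted at relative abundance 1 (cycles).
#' @param cq_noise_sd Technical Cq noise per replicate (cycles).
#' @param dna_probe_mu,dna_probe_sd Mean/SD of the total-DNA reference
#'   probe Cq (cycles).
#' @param detection_limit Maximum cycle; higher values are censored.
#' @param technical_replicates qPCR replicates per sample x probe.
#' @param metastasis_take_rate Probability that an implanted mouse yields
#'   any lung lesion (independently of all-zero seeding).
#' @param control_metastasis_advantage Intrinsic log2 lung advantage of the
#'   GFP negative control, emulating the baseline metastatic capacity of
#'   the host tumour model that the control is included to gauge.
#' @param positive_control_advantage Log2 lung advantage assigned to
#'   positive-control constructs (HOXA1-like drivers).
#' @param exact_proportions If `TRUE`, both bottlenecks are replaced by
#'   their expectations (no multinomial or Poisson draws; lungs are always
#'   sampled when the take rate is positive), enabling closed-form checks.
#' @param rng_seed Default seed.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_engraft = 2e5, primary_doublings = 10,
                              lung_seeding_rate = 4, cq_intercept = 21,
                              cq_noise_sd = 0.3, dna_probe_mu = 18,
                              dna_probe_sd = 0.2, detection_limit = 40,
                              technical_replicates = 3L,
                              metastasis_take_rate = 0.9,
                              control_metastasis_advantage = 1.5,
                              positive_control_advantage = 3,
                              exact_proportions = FALSE, rng_seed = 1L) {
  cfg <- list(
    n_engraft = check_count(n_engraft, "n_engraft"),
    primary_doublings = check_number(primary_doublings, "primary_doublings", min = 0),
    lung_seeding_rate = check_number(lung_seeding_rate, "lung_seeding_rate", min = 0),
    cq_intercept = check_number(cq_intercept, "cq_intercept"),
    cq_noise_sd = check_number(cq_noise_sd, "cq_noise_sd", min = 0),
    dna_probe_mu = check_number(dna_probe_mu, "dna_probe_mu"),
    dna_probe_sd = check_number(dna_probe_sd, "dna_probe_sd", min = 0),
    detection_limit = check_number(detection_limit, "detection_limit"),
    technical_replicates = check_count(technical_replicates, "technical_replicates"),
    metastasis_take_rate = check_number(metastasis_take_rate, "metastasis_take_rate", 0, 1),
    control_metastasis_advantage = check_number(control_metastasis_advantage,
                                                "control_metastasis_advantage"),
    positive_control_advantage = check_number(positive_control_advantage,
                                              "positive_control_advantage"),
    exact_proportions = isTRUE(exact_proportions),
    rng_seed = check_count(rng_seed, "rng_seed", min = 0L)
  )
  structure(cfg, class = "simulation_config")
}

#' Default per-ORF effect table
#'
#' Candidates are neutral (`g = m = 0`); the negative control carries the
#' configured intrinsic lung advantage; positive controls carry the
#' driver-scale advantage. Override rows to create true drivers.
#'
#' @param manifest Library manifest (needs `orf_id`, `role`).
#' @param config A [simulation_config()].
#' @return Tibble `orf_id`, `g`, `m`.
#' @export
default_effects <- function(manifest, config = simulation_config()) {
  validate_manifest(manifest)
  tibble(
    orf_id = manifest$orf_id,
    g = 0,
    m = dplyr::case_when(
      manifest$role == "negative_control" ~ config$control_metastasis_advantage,
      manifest$role == "positive_control" ~ config$positive_control_advantage,
      TRUE ~ 0
    )
  )
}

#' Mark a set of ORFs as metastasis drivers
#'
#' @param effects Effect table from [default_effects()].
#' @param driver_ids Character vector of ORF ids to promote.
#' @param m Log2 metastasis advantage given to each driver.
#' @param g Log2 primary-growth offset given to each driver.
#' @return The modified effect table.
#' @export
set_drivers <- function(effects, driver_ids, m = 3, g = 0) {
  check_columns(effects, c("orf_id", "g", "m"), "effects")
  missing <- setdiff(driver_ids, effects$orf_id)
  if (length(missing) > 0) {
    abort(sprintf("Unknown driver orf_id(s): %s.", paste(missing, collapse = ", ")),
          class = "metscreen_argument_error")
  }
  effects$m[effects$orf_id %in% driver_ids] <- m
  effects$g[effects$orf_id %in% driver_ids] <- g
  effects
}

# Cq emission for one sample: one row per probe x replicate, censored at the
# detection limit; zero proportions are emitted as censored rows at the limit.
emit_cq <- function(sample_id, mouse_id, pool_id, compartment, orf_ids,
                    proportions, config) {
  reps <- config$technical_replicates
  n <- length(orf_ids)
  base_cq <- ifelse(proportions > 0,
                    config$cq_intercept - log2(proportions), Inf)
  cq <- rep(base_cq, each = reps) +
    rnorm(n * reps, 0, config$cq_noise_sd) * is.finite(rep(base_cq, each = reps))
  dna <- rnorm(reps, config$dna_probe_mu, config$dna_probe_sd)
  all_cq <- c(cq, dna)
  censored <- all_cq > config$detection_limit
  tibble(
    sample_id = sample_id,
    mouse_id = mouse_id,
    pool_id = pool_id,
    compartment = compartment,
    probe = c(rep(orf_ids, each = reps), rep(DNA_REF, reps)),
    replicate = c(rep(seq_len(reps), n), seq_len(reps)),
    cq = pmin(all_cq, config$detection_limit),
    censored = censored
  )
}

#' Simulate one implantation pool
#'
#' Runs the generative chain for a single pool: a pooled reference pellet
#' with equal representation of every member, then for each mouse an
#' engraftment bottleneck, primary expansion in the MFP, and a Poisson
#' lung-seeding bottleneck, each compartment read out as a long-format qPCR
#' Cq table with a total-DNA reference probe (`DNA_REF`) per sample.
#'
#' A mouse is metastasis negative (no lung sample) with probability
#' `1 - metastasis_take_rate`, or when no cell seeds its lungs.
#'
#' @param members Tibble of pool members (`orf_id`, `role`), e.g. one pool
#'   of a [partition_library()] plan.
#' @param config A [simulation_config()].
#' @param effects Per-ORF effect table (`orf_id`, `g`, `m`); defaults to
#'   [default_effects()] on the members.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param pool_id Pool identifier used in sample ids.
#' @param mice Number of mice; defaults to 10 as in the published format.
#'
#' @return List with `cq` (long Cq tibble: `sample_id`, `mouse_id`,
#'   `pool_id`, `compartment`, `probe`, `replicate`, `cq`, `censored`) and
#'   `truth` (tibble `pool_id`, `orf_id`, `g`, `m`, `mouse_id`,
#'   `compartment`, `proportion`; per-compartment proportions sum to 1).
#' @examples
#' pool <- partition_library(make_manifest(12, barcode_seed = NULL))
#' sim <- simulate_pool(pool, simulation_config(), seed = 7)
#' head(sim$cq)
#' @export
simulate_pool <- function(members, config = simulation_config(), effects = NULL,
                          seed = config$rng_seed, pool_id = NULL, mice = 10L) {
  check_columns(members, "orf_id", "pool members")
  members <- as_tibble(members)
  if (nrow(members) == 0) {
    abort("Pool is empty.", class = "metscreen_empty_design")
  }
  if (!"role" %in% names(members)) members$role <- "candidate"
  if (anyDuplicated(members$orf_id)) {
    abort("Pool members must be unique; duplicated orf_id found (duplicate pool_id collapse?).",
          class = "metscreen_config_error")
  }
  if (is.null(pool_id)) {
    pool_id <- if ("pool_id" %in% names(members)) members$pool_id[[1]] else "P01"
  }
  mice <- check_count(mice, "mice")
  if (is.null(effects)) effects <- default_effects(members, config)
  check_columns(effects, c("orf_id", "g", "m"), "effects")
  eff <- effects[match(members$orf_id, effects$orf_id), ]
  if (anyNA(eff$orf_id)) {
    abort("`effects` must cover every pool member.", class = "metscreen_argument_error")
  }
  orf_ids <- members$orf_id
  k <- length(orf_ids)
  g <- eff$g
  m <- eff$m

  withr::with_seed(seed, {
    p_ref <- rep(1 / k, k)
    cq_rows <- list()
    truth_rows <- list(tibble(
      pool_id = pool_id, orf_id = orf_ids, g = g, m = m,
      mouse_id = NA_character_, compartment = "reference", proportion = p_ref
    ))
    cq_rows[[1]] <- emit_cq(paste0(pool_id, "_ref"), NA_character_, pool_id,
                            "reference", orf_ids, p_ref, config)
    for (mo in seq_len(mice)) {
      mouse_id <- sprintf("%s_M%02d", pool_id, mo)
      # engraftment bottleneck
      if (config$exact_proportions) {
        engrafted <- p_ref * config$n_engraft
      } else {
        engrafted <- rmultinom(1, config$n_engraft, p_ref)[, 1]
      }
      # primary expansion
      mfp_counts <- engrafted * 2^(g * config$primary_doublings)
      p_mfp <- mfp_counts / sum(mfp_counts)
      cq_rows[[length(cq_rows) + 1L]] <-
        emit_cq(paste0(mouse_id, "_MFP"), mouse_id, pool_id, "mfp",
                orf_ids, p_mfp, config)
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        pool_id = pool_id, orf_id = orf_ids, g = g, m = m,
        mouse_id = mouse_id, compartment = "mfp", proportion = p_mfp
      )
      # lung seeding bottleneck
      take <- if (config$exact_proportions) {
        config$metastasis_take_rate > 0
      } else {
        runif(1) < config$metastasis_take_rate
      }
      lambda <- config$lung_seeding_rate * p_mfp * 2^m
      seeded <- if (config$exact_proportions) lambda else rpois(k, lambda)
      if (take && sum(seeded) > 0) {
        p_lung <- seeded / sum(seeded)
        cq_rows[[length(cq_rows) + 1L]] <-
          emit_cq(paste0(mouse_id, "_LUNG"), mouse_id, pool_id, "lung",
                  orf_ids, p_lung, config)
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          pool_id = pool_id, orf_id = orf_ids, g = g, m = m,
          mouse_id = mouse_id, compartment = "lung", proportion = p_lung
        )
      }
    }
    list(cq = bind_rows(cq_rows), truth = bind_rows(truth_rows))
  })
}

#' Simulate a full multi-pool screen
#'
#' Concatenates independent per-pool simulations (one shared reference
#' pellet per pool), with per-pool seeds derived from the root seed so
#' pools can be re-simulated independently yet reproducibly.
#'
#' @param plan A pool plan from [partition_library()].
#' @param config A [simulation_config()].
#' @param effects Per-ORF effect table covering all plan members; defaults
#'   to [default_effects()].
#' @param seed Root seed.
#' @param mice Mice per pool.
#' @return List with concatenated `cq` and `truth` tibbles; sample ids are
#'   globally unique.
#' @export
simulate_screen <- function(plan, config = simulation_config(), effects = NULL,
                            seed = config$rng_seed, mice = 10L) {
  check_columns(plan, c("pool_id", "orf_id"), "pool plan")
  if (is.null(effects)) {
    roles <- if ("role" %in% names(plan)) plan$role else "candidate"
    effects <- default_effects(distinct(tibble(orf_id = plan$orf_id, role = roles)),
                               config)
  }
  pools <- split(as_tibble(plan), plan$pool_id)
  if (anyDuplicated(names(pools))) {
    abort("Duplicate pool_id values.", class = "metscreen_schema_error")
  }
  out <- purrr::imap(pools, function(members, pid) {
    simulate_pool(members, config, effects,
                  seed = derive_seed(seed, match(pid, names(pools))),
                  pool_id = pid, mice = mice)
  })
  list(
    cq = bind_rows(purrr::map(out, "cq")),
    truth = bind_rows(purrr::map(out, "truth"))
  )
}
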
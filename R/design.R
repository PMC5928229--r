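#' Screen design configuration
#'
#' Collects the constants that define the physical format of the screen.
#' The defaults reproduce the published format: candidate ORFs pooled in
#' groups of at most 12, one GFP negative control added to every pool, and
#' 10 mice implanted per pool.
#'
#' @param max_pool_size Maximum number of candidate ORFs per pool.
#' @param barcode_length Barcode length in bases.
#' @param min_hamming_distance Minimum pairwise barcode Hamming distance.
#' @param mice_per_pool Mice implanted with each pool.
#' @param pooling_policy `"chunk"` (fixed-size pools, last one smaller) or
#'   `"balanced"` (same pool count, sizes differing by at most one).
#' @param rng_seed Integer seed used when no explicit seed is given.
#'
#' @return A list of class `design_config`.
#' @export
design_config <- function(max_pool_size = 12L, barcode_length = 8L,
                          min_hamming_distance = 3L, mice_per_pool = 10L,
                          pooling_policy = c("chunk", "balanced"),
                          rng_seed = 1L) {
  pooling_policy <- match.arg(pooling_policy)
  cfg <- list(
    max_pool_size = check_count(max_pool_size, "max_pool_size"),
    barcode_length = check_count(barcode_length, "barcode_length"),
    min_hamming_distance = check_count(min_hamming_distance, "min_hamming_distance", min = 0L),
    mice_per_pool = check_count(mice_per_pool, "mice_per_pool"),
    pooling_policy = pooling_policy,
    rng_seed = check_count(rng_seed, "rng_seed", min = 0L)
  )
  if (cfg$min_hamming_distance > cfg$barcode_length) {
    abort("`min_hamming_distance` must not exceed `barcode_length`.",
          class = "metscreen_argument_error")
  }
  structure(cfg, class = "design_config")
}

#' Build a candidate library manifest
#'
#' Convenience constructor for a manifest tibble with `n_candidates`
#' candidate ORFs plus one GFP negative-control template, mirroring the
#' 230-gene candidate library of the original screen. Gene symbols are
#' synthetic placeholders (`GENE001`, ...).
#'
#' @param n_candidates Number of candidate ORFs (default 230).
#' @param control Identifier of the negative-control construct.
#' @param positive_controls Optional character vector of positive-control
#'   identifiers (e.g. a HOXA1-like driver); excluded from hit ranking by
#'   role.
#' @param barcode_seed Seed for barcode generation, or `NULL` to leave the
#'   barcode column empty.
#' @param config A [design_config()] supplying barcode length/distance.
#'
#' @return Tibble with columns `orf_id`, `gene_symbol`, `role`, `barcode`.
#' @examples
#' make_manifest(12)
#' @export
make_manifest <- function(n_candidates = 230L, control = "GFP",
                          positive_controls = character(0),
                          barcode_seed = 1L, config = design_config()) {
  n_candidates <- check_count(n_candidates, "n_candidates")
  ids <- sprintf("ORF%03d", seq_len(n_candidates))
  manifest <- tibble(
    orf_id = c(ids, control, positive_controls),
    gene_symbol = c(sprintf("GENE%03d", seq_len(n_candidates)), control,
                    positive_controls),
    role = c(rep("candidate", n_candidates), "negative_control",
             rep("positive_control", length(positive_controls))),
    barcode = NA_character_
  )
  if (!is.null(barcode_seed)) {
    manifest <- add_barcodes(manifest, length = config$barcode_length,
                             min_dist = config$min_hamming_distance,
                             seed = barcode_seed)
  }
  manifest
}

validate_manifest <- function(manifest) {
  check_columns(manifest, c("orf_id", "role"), "manifest")
  bad <- setdiff(unique(manifest$role),
                 c("candidate", "negative_control", "positive_control"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown role(s) in manifest: %s.", paste(bad, collapse = ", ")),
          class = "metscreen_schema_error")
  }
  if (anyDuplicated(manifest$orf_id)) {
    abort("Manifest `orf_id` values must be unique.",
          class = "metscreen_schema_error")
  }
  invisible(manifest)
}

#' Partition a candidate library into implantation pools
#'
#' Candidates are shuffled deterministically (seeded) and split into pools
#' of at most `max_pool_size`; the single negative-control construct is
#' added to every pool so each pool carries its own empirical null.
#' Positive-control constructs, if any, are distributed one per pool over
#' the first pools without counting against the pool size.
#'
#' @param manifest Library manifest with `orf_id` and `role` columns
#'   (at least one candidate and exactly one negative control).
#' @param config A [design_config()].
#' @param seed Integer seed for the shuffle; defaults to `config$rng_seed`.
#'
#' @return Tibble with one row per pool member: `pool_id`, `orf_id`,
#'   `gene_symbol` (if present in the manifest) and `role`. Candidates
#'   appear in exactly one pool; the negative control appears in all.
#' @examples
#' partition_library(make_manifest(25, barcode_seed = NULL))
#' @export
partition_library <- function(manifest, config = design_config(),
                              seed = config$rng_seed) {
  validate_manifest(manifest)
  manifest <- as_tibble(manifest)
  candidates <- manifest$orf_id[manifest$role == "candidate"]
  controls <- manifest$orf_id[manifest$role == "negative_control"]
  positives <- manifest$orf_id[manifest$role == "positive_control"]
  if (length(candidates) == 0) {
    abort("Empty design: the manifest contains no candidate ORFs.",
          class = "metscreen_empty_design")
  }
  if (length(controls) != 1) {
    abort(sprintf(
      "Configuration error: exactly one negative-control entry is required, found %d.",
      length(controls)), class = "metscreen_config_error")
  }
  n_pools <- ceiling(length(candidates) / config$max_pool_size)
  shuffled <- withr::with_seed(seed, sample(candidates))
  sizes <- switch(config$pooling_policy,
    chunk = {
      full <- rep(config$max_pool_size, n_pools)
      full[n_pools] <- length(candidates) - config$max_pool_size * (n_pools - 1)
      full
    },
    balanced = {
      base <- length(candidates) %/% n_pools
      extra <- length(candidates) %% n_pools
      c(rep(base + 1L, extra), rep(base, n_pools - extra))
    }
  )
  assignment <- rep(seq_len(n_pools), times = sizes)
  pool_ids <- sprintf("P%02d", seq_len(n_pools))
  plan <- tibble(
    pool_id = pool_ids[assignment],
    orf_id = shuffled
  )
  # one shared negative control per pool; positives spread one per pool
  plan <- bind_rows(
    plan,
    tibble(pool_id = pool_ids, orf_id = controls),
    if (length(positives) > 0) {
      tibble(pool_id = pool_ids[((seq_along(positives) - 1L) %% n_pools) + 1L],
             orf_id = positives)
    }
  )
  plan <- plan %>%
    left_join(manifest %>% select(any_of(c("orf_id", "gene_symbol", "role"))),
              by = "orf_id") %>%
    arrange(.data$pool_id, .data$role != "candidate", .data$orf_id)
  class(plan) <- c("pool_plan", class(plan))
  plan
}

#' @importFrom dplyr any_of
NULL

#' Summarise a pool plan
#'
#' @param plan A pool plan from [partition_library()].
#' @return Tibble with one row per pool: pool id, candidate count, member
#'   count and control presence.
#' @export
pool_sizes <- function(plan) {
  check_columns(plan, c("pool_id", "orf_id", "role"), "pool plan")
  plan %>%
    group_by(.data$pool_id) %>%
    summarise(
      n_candidates = sum(.data$role == "candidate"),
      n_members = n(),
      has_control = any(.data$role == "negative_control"),
      .groups = "drop"
    )
}
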
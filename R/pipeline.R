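#' Run the full screen pipeline
#'
#' Design -> simulate -> quantify -> call, as one seeded, reproducible run:
#' builds (or accepts) a library manifest, partitions it into pools,
#' simulates the in vivo screen, runs the delta-delta-Ct quantification
#' chain and calls hits against the empirical-control cutoff.
#'
#' @param config A [screen_config()].
#' @param manifest Optional library manifest; by default a synthetic
#'   `config$n_candidates`-gene manifest is generated.
#' @param effects Optional per-ORF effect table; defaults to
#'   [default_effects()] (all candidates neutral).
#'
#' @return An object of class `met_screen`: a list with `manifest`,
#'   `pools`, `cq`, `truth`, `enrichment`, `hits`, `cutoff`, `config` and a
#'   `report` list of per-stage counts. Methods: [print()], [tidy()],
#'   [glance()], [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' screen <- run_screen(screen_config(n_candidates = 24, seed = 7))
#' glance(screen)
#' }
#' @export
run_screen <- function(config = screen_config(), manifest = NULL,
                       effects = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(manifest)) {
    manifest <- make_manifest(config$n_candidates, control = config$controls[1],
                              barcode_seed = derive_seed(config$seed, 1L),
                              config = config$design)
  }
  validate_manifest(manifest)
  pools <- partition_library(manifest, config$design,
                             seed = derive_seed(config$seed, 2L))
  if (is.null(effects)) effects <- default_effects(manifest, config$sim)
  sim <- simulate_screen(pools, config$sim, effects,
                         seed = derive_seed(config$seed, 3L),
                         mice = config$design$mice_per_pool)
  enrichment <- quantify_screen(sim$cq, min_pairs = config$min_pairs,
                                censor_policy = config$censor_policy,
                                mean_type = config$mean_type,
                                collapse_policy = config$collapse_policy)
  hits <- call_hits(enrichment, manifest, fallback = config$fallback_cutoff,
                    hit_mode = config$hit_mode,
                    mfp_threshold = config$mfp_threshold,
                    depletion_fold = config$depletion_fold)
  report <- list(
    seed = config$seed,
    n_candidates = sum(manifest$role == "candidate"),
    n_pools = n_distinct(pools$pool_id),
    mice_per_pool = config$design$mice_per_pool,
    n_samples = n_distinct(sim$cq$sample_id),
    n_lung_samples = n_distinct(sim$cq$sample_id[sim$cq$compartment == "lung"]),
    n_genes_included = sum(hits$included & hits$role == "candidate"),
    cutoff = attr(hits, "cutoff"),
    n_hits = sum(hits$is_hit)
  )
  structure(list(manifest = manifest, pools = pools, cq = sim$cq,
                 truth = sim$truth, enrichment = enrichment, hits = hits,
                 cutoff = attr(hits, "cutoff"), config = config,
                 report = report),
            class = "met_screen")
}

#' @export
print.met_screen <- function(x, ...) {
  r <- x$report
  cat("Pooled in vivo metastasis screen (simulated)\n")
  cat(sprintf("  %d candidate ORFs in %d pools (max %d candidates/pool), %d mice/pool\n",
              r$n_candidates, r$n_pools, x$config$design$max_pool_size,
              r$mice_per_pool))
  cat(sprintf("  %d samples (%d lung); %d genes passed the >=%d matched-pair rule\n",
              r$n_samples, r$n_lung_samples, r$n_genes_included,
              x$config$min_pairs))
  cat(sprintf("  enrichment cutoff %.3f (%s mode): %d hits\n",
              r$cutoff, x$config$hit_mode, r$n_hits))
  invisible(x)
}

#' Tidy the hit table of a screen run
#'
#' @param x A `met_screen` object.
#' @param ... Unused.
#' @return The scored hit tibble (one row per gene x pool).
#' @export
tidy.met_screen <- function(x, ...) as_tibble(x$hits)

#' One-row summary of a screen run
#'
#' @param x A `met_screen` object.
#' @param ... Unused.
#' @return A one-row tibble with pool/sample/hit counts and the applied
#'   cutoff.
#' @export
glance.met_screen <- function(x, ...) {
  as_tibble(x$report[c("n_candidates", "n_pools", "mice_per_pool",
                       "n_samples", "n_lung_samples", "n_genes_included",
                       "cutoff", "n_hits")])
}

#' Write every artifact of a screen run to a directory
#'
#' @param screen A `met_screen` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths (manifest, pool
#'   plan, Cq table, enrichment, hits, config and a JSON run report).
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "met_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    manifest = file.path(dir, "manifest.tsv"),
    pools = file.path(dir, "pools.json"),
    cq = file.path(dir, "cq.csv"),
    enrichment = file.path(dir, "enrichment.tsv"),
    hits = file.path(dir, "hits.tsv"),
    config = file.path(dir, "config.yaml"),
    report = file.path(dir, "report.json")
  )
  write_manifest(screen$manifest, paths["manifest"])
  write_pool_plan(screen$pools, paths["pools"])
  write_cq_table(screen$cq, paths["cq"])
  write_enrichment(screen$enrichment, paths["enrichment"])
  write_hits(screen$hits, paths["hits"])
  write_screen_config(screen$config, paths["config"])
  jsonlite::write_json(screen$report, paths["report"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
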
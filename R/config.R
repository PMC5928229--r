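#' Full pipeline configuration
#'
#' Bundles the design, simulation, quantification and hit-calling options
#' of an end-to-end run. The defaults reproduce the published screen
#' format: a 230-candidate library in pools of at most 12 with one GFP
#' control each, 10 mice per pool, a minimum of 3 matched pairs, a
#' fallback lung-enrichment cutoff of 5 and a two-fold mammary-depletion
#' threshold.
#'
#' @param n_candidates Candidate library size.
#' @param design A [design_config()].
#' @param sim A [simulation_config()].
#' @param min_pairs Minimum matched pairs for inclusion.
#' @param censor_policy Censored-Cq policy (`"impute"` or `"drop"`).
#' @param mean_type Pair-averaging policy.
#' @param collapse_policy Replicate-collapsing policy.
#' @param controls Negative-control identifiers.
#' @param fallback_cutoff Cutoff used when controls yield no eligible rows.
#' @param hit_mode Hit definition (see [call_hits()]).
#' @param mfp_threshold MFP-axis quadrant threshold.
#' @param depletion_fold Mammary-depletion fold threshold.
#' @param seed Global root seed; stage seeds are derived from it.
#'
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_candidates = 230L, design = design_config(),
                          sim = simulation_config(), min_pairs = 3L,
                          censor_policy = "impute", mean_type = "arithmetic",
                          collapse_policy = "mean", controls = "GFP",
                          fallback_cutoff = 5,
                          hit_mode = "lung", mfp_threshold = 1,
                          depletion_fold = 2, seed = 1L) {
  stopifnot(inherits(design, "design_config"), inherits(sim, "simulation_config"))
  structure(list(
    n_candidates = check_count(n_candidates, "n_candidates"),
    design = design,
    sim = sim,
    min_pairs = check_count(min_pairs, "min_pairs"),
    censor_policy = match.arg(censor_policy, c("impute", "drop")),
    mean_type = match.arg(mean_type, c("arithmetic", "geometric")),
    collapse_policy = match.arg(collapse_policy, c("mean", "median")),
    controls = as.character(controls),
    fallback_cutoff = check_number(fallback_cutoff, "fallback_cutoff", min = 0),
    hit_mode = match.arg(hit_mode, c("lung", "mfp_depletion", "both")),
    mfp_threshold = check_number(mfp_threshold, "mfp_threshold"),
    depletion_fold = check_number(depletion_fold, "depletion_fold", min = 1),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "screen_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' Serialised configurations round-trip exactly through
#' `write_screen_config()` / `read_screen_config()`.
#'
#' @param path File path.
#' @return `read_screen_config()` returns a `screen_config`.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s.", path), class = "metscreen_io_error")
  }
  raw <- yaml::read_yaml(path)
  design <- do.call(design_config, raw$design %||% list())
  sim <- do.call(simulation_config, raw$sim %||% list())
  rest <- raw[setdiff(names(raw), c("design", "sim"))]
  do.call(screen_config, c(list(design = design, sim = sim), rest))
}

#' @rdname read_screen_config
#' @param config A `screen_config`.
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  out <- unclass(config)
  out$design <- unclass(config$design)
  out$sim <- unclass(config$sim)
  yaml::write_yaml(out, path)
  invisible(path)
}
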
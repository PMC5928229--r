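#' Empirical-control enrichment cutoff
#'
#' The hit threshold is the mean enrichment score of the negative-control
#' construct across pools (only control rows passing the minimum
#' matched-pair rule contribute). When no eligible control rows exist the
#' configured fallback is returned with a warning; the default fallback of
#' 5 is the published GFP-derived cutoff.
#'
#' @param enrichment Per-gene enrichment tibble ([aggregate_genes()]).
#' @param control_orf_ids Identifiers of negative-control constructs.
#' @param fallback Cutoff used when no eligible control rows exist.
#' @return A single numeric threshold.
#' @examples
#' enr <- tibble::tibble(pool_id = c("P01", "P02", "P03"), orf_id = "GFP",
#'                       n_pairs = 5, mean_fc_mfp = 1,
#'                       mean_lung_vs_mfp = c(4, 5, 6), included = TRUE)
#' control_cutoff(enr)  # 5
#' @export
control_cutoff <- function(enrichment, control_orf_ids = "GFP", fallback = 5) {
  fallback <- check_number(fallback, "fallback")
  if (fallback < 0) {
    abort("`fallback` cutoff must be non-negative.",
          class = "metscreen_config_error")
  }
  check_columns(enrichment, c("orf_id", "mean_lung_vs_mfp", "included"),
                "enrichment table")
  ctrl <- enrichment %>%
    filter(.data$orf_id %in% control_orf_ids, .data$included)
  if (nrow(ctrl) == 0) {
    warn(sprintf(
      "No eligible control rows; falling back to the configured cutoff %.3g.",
      fallback))
    return(fallback)
  }
  mean(ctrl$mean_lung_vs_mfp)
}

#' Quadrant classification on the MFP and lung axes
#'
#' Joint status of each gene on the two screen axes: enrichment in the MFP
#' relative to the reference pellet (x) and enrichment in the lung relative
#' to the MFP (y). Values equal to a threshold classify as enriched.
#'
#' @param mean_fc_mfp Numeric vector of MFP-versus-reference fold changes.
#' @param enrichment_score Numeric vector of lung-versus-MFP scores.
#' @param lung_cutoff Threshold on the lung axis.
#' @param mfp_threshold Threshold on the MFP axis (default 1: any
#'   enrichment over the reference representation).
#' @return Character vector over `lung_and_mfp`, `lung_only`, `mfp_only`,
#'   `neither`.
#' @export
classify_quadrant <- function(mean_fc_mfp, enrichment_score, lung_cutoff,
                              mfp_threshold = 1) {
  check_number(lung_cutoff, "lung_cutoff", min = .Machine$double.xmin)
  check_number(mfp_threshold, "mfp_threshold", min = .Machine$double.xmin)
  lung <- enrichment_score >= lung_cutoff
  mfp <- mean_fc_mfp >= mfp_threshold
  dplyr::case_when(
    lung & mfp ~ "lung_and_mfp",
    lung & !mfp ~ "lung_only",
    !lung & mfp ~ "mfp_only",
    TRUE ~ "neither"
  )
}

#' Mammary-depletion criterion
#'
#' The supplementary hit definition: a gene depleted at least
#' `fold_threshold`-fold in the mammary tumour relative to the reference
#' pool is a putative metastatic driver.
#'
#' @param mean_fc_mfp Numeric vector of MFP-versus-reference fold changes.
#' @param fold_threshold Depletion fold (default 2; must be >= 1).
#' @return Logical vector, `TRUE` where `mean_fc_mfp <= 1/fold_threshold`.
#' @export
mammary_depletion_filter <- function(mean_fc_mfp, fold_threshold = 2) {
  fold_threshold <- check_number(fold_threshold, "fold_threshold", min = 1)
  mean_fc_mfp <= 1 / fold_threshold
}

#' Call and rank screen hits
#'
#' Applies the empirical-control cutoff (or an explicit one), classifies
#' every included gene into a quadrant, evaluates the mammary-depletion
#' criterion, and ranks hits in descending order of enrichment score with
#' deterministic lexicographic tie-breaking. Control-role constructs are
#' never hits and never ranked; genes failing the minimum matched-pair
#' rule (`included = FALSE`) are never hits regardless of score.
#'
#' `hit_mode` selects the hit definition: `"lung"` (enrichment score at or
#' above the cutoff — the main-text rule), `"mfp_depletion"` (at least
#' `depletion_fold`-fold mammary depletion — the supplementary rule), or
#' `"both"` (conjunction).
#'
#' @param enrichment Per-gene enrichment tibble ([aggregate_genes()]).
#' @param manifest Library manifest supplying `role` (and `gene_symbol`).
#' @param cutoff Lung-axis cutoff; `NULL` derives it with
#'   [control_cutoff()] from the manifest's negative controls.
#' @param fallback Fallback cutoff when no eligible control rows exist.
#' @param hit_mode Hit definition (see above).
#' @param mfp_threshold MFP-axis threshold for quadrant classification.
#' @param depletion_fold Mammary-depletion fold threshold.
#' @return Tibble with one row per gene x pool: enrichment columns plus
#'   `gene_symbol`, `role`, `mfp_status`, `quadrant`, `mfp_depleted`,
#'   `is_hit`, `rank` (dense, 1 = strongest hit, `NA` for non-hits),
#'   sorted with ranked hits first. The applied cutoff is attached as the
#'   `cutoff` attribute.
#' @examples
#' pool <- partition_library(make_manifest(12, barcode_seed = NULL))
#' sim <- simulate_pool(pool, seed = 3)
#' call_hits(quantify_screen(sim$cq), make_manifest(12, barcode_seed = NULL))
#' @export
call_hits <- function(enrichment, manifest, cutoff = NULL, fallback = 5,
                      hit_mode = c("lung", "mfp_depletion", "both"),
                      mfp_threshold = 1, depletion_fold = 2) {
  hit_mode <- match.arg(hit_mode)
  validate_manifest(manifest)
  check_columns(enrichment, c("pool_id", "orf_id", "n_pairs", "mean_fc_mfp",
                              "mean_lung_vs_mfp", "included"),
                "enrichment table")
  if (nrow(enrichment) == 0) {
    out <- enrichment %>%
      mutate(gene_symbol = character(0), role = character(0),
             mfp_status = character(0), quadrant = character(0),
             mfp_depleted = logical(0), is_hit = logical(0),
             rank = integer(0))
    attr(out, "cutoff") <- cutoff %||% fallback
    return(out)
  }
  controls <- manifest$orf_id[manifest$role == "negative_control"]
  if (is.null(cutoff)) {
    cutoff <- control_cutoff(enrichment, control_orf_ids = controls,
                             fallback = fallback)
  }
  cutoff <- check_number(cutoff, "cutoff", min = .Machine$double.xmin)
  ann <- manifest %>% select(any_of(c("orf_id", "gene_symbol", "role")))
  scored <- enrichment %>%
    left_join(ann, by = "orf_id") %>%
    mutate(
      role = if_else(is.na(.data$role), "candidate", .data$role),
      mfp_depleted = mammary_depletion_filter(.data$mean_fc_mfp, depletion_fold),
      mfp_status = dplyr::case_when(
        .data$mfp_depleted ~ "depleted",
        .data$mean_fc_mfp >= mfp_threshold ~ "enriched",
        TRUE ~ "neutral"
      ),
      quadrant = classify_quadrant(.data$mean_fc_mfp, .data$mean_lung_vs_mfp,
                                   lung_cutoff = cutoff,
                                   mfp_threshold = mfp_threshold),
      lung_hit = .data$mean_lung_vs_mfp >= cutoff,
      is_hit = .data$included & .data$role == "candidate" &
        switch(hit_mode,
               lung = .data$lung_hit,
               mfp_depletion = .data$mfp_depleted,
               both = .data$lung_hit & .data$mfp_depleted)
    ) %>%
    select(-"lung_hit") %>%
    arrange(dplyr::desc(.data$is_hit), dplyr::desc(.data$mean_lung_vs_mfp),
            .data$orf_id)
  scored$rank <- ifelse(scored$is_hit, cumsum(scored$is_hit), NA_integer_)
  attr(scored, "cutoff") <- cutoff
  scored
}

`%||%` <- function(x, y) if (is.null(x)) y else x
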
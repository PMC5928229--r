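#' Collapse technical qPCR replicates
#'
#' Reduces a long Cq table to one row per sample x probe. The default
#' policy averages the uncensored replicates; a row whose replicates are
#' all censored stays censored at the detection-limit cycle, with
#' `n_replicates_used = 0`.
#'
#' @param cq Long Cq tibble (see [simulate_pool()] for the schema).
#' @param policy `"mean"` (arithmetic mean of uncensored Cq) or `"median"`.
#' @return Tibble with one row per sample x probe: the collapsed `cq`,
#'   `censored` flag and `n_replicates_used`.
#' @examples
#' sim <- simulate_pool(make_manifest(3, barcode_seed = NULL), seed = 1)
#' collapse_replicates(sim$cq)
#' @export
collapse_replicates <- function(cq, policy = c("mean", "median")) {
  if (is.character(policy) && length(policy) == 1 &&
      !policy %in% c("mean", "median")) {
    abort(sprintf("Unknown replicate-collapsing policy '%s'.", policy),
          class = "metscreen_argument_error")
  }
  policy <- match.arg(policy)
  check_columns(cq, c("sample_id", "pool_id", "compartment", "probe",
                      "cq", "censored"), "Cq table")
  agg <- if (policy == "mean") mean else stats::median
  cq %>%
    group_by(.data$sample_id, .data$mouse_id, .data$pool_id,
             .data$compartment, .data$probe) %>%
    summarise(
      n_replicates_used = sum(!.data$censored),
      cq = if (any(!.data$censored)) agg(.data$cq[!.data$censored]) else max(.data$cq),
      censored = !any(!.data$censored),
      .groups = "drop"
    ) %>%
    select("sample_id", "mouse_id", "pool_id", "compartment", "probe",
           "cq", "censored", "n_replicates_used")
}

#' Normalise barcode Cq to the total-DNA reference probe
#'
#' Computes the per-sample delta-Ct, `Cq_barcode - Cq_DNA_REF`, which
#' cancels sample-wide differences in DNA input: adding a constant to every
#' Cq of one sample leaves all downstream fold changes unchanged.
#'
#' Censored barcode rows keep the delta-Ct implied by the detection-limit
#' cycle (a conservative lower bound on abundance) under the default
#' `censor_policy = "impute"`, and are removed under `"drop"`.
#'
#' @param collapsed Output of [collapse_replicates()].
#' @param censor_policy `"impute"` or `"drop"`.
#' @return Tibble of normalised abundances: one row per sample x ORF with
#'   `delta_ct`, `censored` and `n_replicates_used`.
#' @export
normalize_to_dna <- function(collapsed, censor_policy = c("impute", "drop")) {
  censor_policy <- match.arg(censor_policy)
  check_columns(collapsed, c("sample_id", "pool_id", "compartment", "probe",
                             "cq", "censored"), "collapsed Cq table")
  dna <- collapsed %>%
    filter(.data$probe == DNA_REF) %>%
    select("sample_id", dna_cq = "cq", dna_censored = "censored")
  barcodes <- collapsed %>% filter(.data$probe != DNA_REF)
  missing <- setdiff(unique(barcodes$sample_id), dna$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Sample(s) without a %s row: %s.", DNA_REF,
                  paste(missing, collapse = ", ")),
          class = "metscreen_data_error")
  }
  if (any(dna$dna_censored)) {
    abort(sprintf("%s probe censored in sample(s): %s.", DNA_REF,
                  paste(dna$sample_id[dna$dna_censored], collapse = ", ")),
          class = "metscreen_data_error")
  }
  out <- barcodes %>%
    inner_join(dna, by = "sample_id") %>%
    mutate(delta_ct = .data$cq - .data$dna_cq) %>%
    select("sample_id", "mouse_id", "pool_id", "compartment",
           orf_id = "probe", "delta_ct", "censored",
           dplyr::any_of("n_replicates_used"))
  if (censor_policy == "drop") out <- filter(out, !.data$censored)
  out
}

#' Fold change of each sample relative to the pooled reference pellet
#'
#' Applies the delta-delta-Ct step: for each sample x ORF, the fold change
#' relative to the pool's reference sample is `2^-(delta_ct_sample -
#' delta_ct_reference)`, assuming 100% amplification efficiency (one
#' doubling per cycle). The reference sample compared with itself gives
#' exactly 1.
#'
#' @param normalized Output of [normalize_to_dna()].
#' @return The input with a `fold_change` column (and `log2_fold_change`).
#' @export
fold_change_vs_reference <- function(normalized) {
  check_columns(normalized, c("sample_id", "pool_id", "compartment", "orf_id",
                              "delta_ct"), "normalized abundance table")
  ref <- normalized %>%
    filter(.data$compartment == "reference") %>%
    select("pool_id", "orf_id", ref_delta_ct = "delta_ct")
  no_ref <- setdiff(unique(normalized$pool_id), unique(ref$pool_id))
  if (length(no_ref) > 0) {
    abort(sprintf("Pool(s) without a reference sample: %s.",
                  paste(no_ref, collapse = ", ")),
          class = "metscreen_data_error")
  }
  out <- normalized %>% inner_join(ref, by = c("pool_id", "orf_id"))
  dropped <- anti_join(normalized, ref, by = c("pool_id", "orf_id"))
  if (nrow(dropped) > 0) {
    abort(sprintf(
      "ORF(s) measured but absent from their pool's reference sample: %s.",
      paste(unique(paste0(dropped$pool_id, ":", dropped$orf_id)), collapse = ", ")),
      class = "metscreen_data_error")
  }
  out %>%
    mutate(log2_fold_change = -(.data$delta_ct - .data$ref_delta_ct),
           fold_change = 2^.data$log2_fold_change) %>%
    select(-"ref_delta_ct")
}

#' Matched lung-versus-mammary pairs
#'
#' One row per (mouse, ORF) for which the mouse has both an MFP tumour and
#' a lung measurement. The lung-versus-MFP enrichment is the ratio of the
#' two reference-normalised fold changes, equivalently `2^-ddCt` of lung
#' versus mammary. Mice without lung lesions contribute no pairs.
#'
#' @param fc Output of [fold_change_vs_reference()].
#' @return Tibble `pool_id`, `mouse_id`, `orf_id`, `fc_mfp`, `fc_lung`,
#'   `lung_vs_mfp`, plus per-compartment censoring flags.
#' @export
matched_pairs <- function(fc) {
  check_columns(fc, c("pool_id", "mouse_id", "compartment", "orf_id",
                      "fold_change"), "fold-change table")
  tumours <- fc %>% filter(.data$compartment %in% c("mfp", "lung"))
  dup <- tumours %>%
    count(.data$mouse_id, .data$compartment, .data$orf_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate (mouse, compartment, ORF) measurements, e.g. %s %s %s.",
                  dup$mouse_id[1], dup$compartment[1], dup$orf_id[1]),
          class = "metscreen_data_error")
  }
  wide <- tumours %>%
    select("pool_id", "mouse_id", "orf_id", "compartment",
           "fold_change", "censored") %>%
    tidyr::pivot_wider(names_from = "compartment",
                       values_from = c("fold_change", "censored"))
  for (col in c("fold_change_lung", "censored_lung")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  wide %>%
    filter(!is.na(.data$fold_change_mfp), !is.na(.data$fold_change_lung)) %>%
    mutate(lung_vs_mfp = .data$fold_change_lung / .data$fold_change_mfp) %>%
    select("pool_id", "mouse_id", "orf_id",
           fc_mfp = "fold_change_mfp", fc_lung = "fold_change_lung",
           "lung_vs_mfp",
           censored_mfp = "censored_mfp", censored_lung = "censored_lung")
}

#' Aggregate matched pairs into per-gene enrichment scores
#'
#' Averages each ORF's matched-pair values within its pool. ORFs with fewer
#' than `min_pairs` pairs are retained but flagged `included = FALSE` and
#' are never eligible as hits (the minimum matched-pair rule). The
#' enrichment score is the mean lung-versus-MFP fold change.
#'
#' @param pairs Output of [matched_pairs()].
#' @param min_pairs Minimum matched pairs for inclusion (default 3).
#' @param mean_type `"arithmetic"` (default, plain average of linear
#'   ratios) or `"geometric"`.
#' @return Tibble `pool_id`, `orf_id`, `n_pairs`, `mean_fc_mfp`,
#'   `mean_lung_vs_mfp`, `log2_lung_vs_mfp`, `included`.
#' @export
aggregate_genes <- function(pairs, min_pairs = 3L,
                            mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  min_pairs <- check_count(min_pairs, "min_pairs")
  check_columns(pairs, c("pool_id", "orf_id", "fc_mfp", "lung_vs_mfp"),
                "matched-pair table")
  avg <- switch(mean_type,
                arithmetic = function(x) mean(x),
                geometric = function(x) exp(mean(log(x))))
  pairs %>%
    group_by(.data$pool_id, .data$orf_id) %>%
    summarise(
      n_pairs = n(),
      mean_fc_mfp = avg(.data$fc_mfp),
      mean_lung_vs_mfp = avg(.data$lung_vs_mfp),
      .groups = "drop"
    ) %>%
    mutate(log2_lung_vs_mfp = log2(.data$mean_lung_vs_mfp),
           included = .data$n_pairs >= min_pairs)
}

#' Full delta-delta-Ct quantification chain
#'
#' Convenience wrapper running [collapse_replicates()],
#' [normalize_to_dna()], [fold_change_vs_reference()], [matched_pairs()]
#' and [aggregate_genes()] in order.
#'
#' @param cq Long Cq tibble.
#' @inheritParams aggregate_genes
#' @inheritParams normalize_to_dna
#' @param collapse_policy Replicate-collapsing policy.
#' @return Per-gene enrichment tibble (see [aggregate_genes()]).
#' @examples
#' pool <- partition_library(make_manifest(12, barcode_seed = NULL))
#' sim <- simulate_pool(pool, seed = 3)
#' quantify_screen(sim$cq)
#' @export
quantify_screen <- function(cq, min_pairs = 3L,
                            censor_policy = c("impute", "drop"),
                            mean_type = c("arithmetic", "geometric"),
                            collapse_policy = "mean") {
  cq %>%
    collapse_replicates(policy = collapse_policy) %>%
    normalize_to_dna(censor_policy = censor_policy) %>%
    fold_change_vs_reference() %>%
    matched_pairs() %>%
    aggregate_genes(min_pairs = min_pairs, mean_type = mean_type)
}
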
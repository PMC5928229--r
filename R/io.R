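# Readers and writers for the screen's plain-text artifacts. All round-trip
# losslessly; malformed inputs raise errors naming the file and column.

read_checked <- function(path, reader, cols, what) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s.", path), class = "metscreen_io_error")
  }
  df <- suppressWarnings(reader(path))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed %s file %s: row %d, column %d (%s).",
                  what, path, probs$row[1], probs$col[1], probs$expected[1]),
          class = "metscreen_io_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing column(s): %s.",
                  what, path, paste(missing, collapse = ", ")),
          class = "metscreen_io_error")
  }
  as_tibble(df)
}

#' Read / write a library manifest (TSV)
#'
#' Tab-separated with header `orf_id  gene_symbol  role  barcode`; the
#' `barcode` column may be absent on input and filled later with
#' [add_barcodes()].
#'
#' @param path File path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- read_checked(path, function(p) {
    readr::read_tsv(p, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }, c("orf_id", "gene_symbol", "role"), "manifest")
  if (!"barcode" %in% names(df)) df$barcode <- NA_character_
  validate_manifest(df)
  df
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' Read / write a pool plan (JSON)
#'
#' Serialised as an array of `{pool_id, member_orf_ids}` objects; reading
#' restores the long member-per-row tibble (roles are re-derived from a
#' manifest when supplied).
#'
#' @param path File path.
#' @param manifest Optional manifest used to restore `gene_symbol`/`role`.
#' @return `read_pool_plan()` returns a pool-plan tibble.
#' @export
read_pool_plan <- function(path, manifest = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s.", path), class = "metscreen_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0) {
    abort(sprintf("Pool-plan file %s contains no pools.", path),
          class = "metscreen_io_error")
  }
  plan <- purrr::map_dfr(raw, function(p) {
    if (is.null(p$pool_id) || is.null(p$member_orf_ids)) {
      abort(sprintf("Pool-plan file %s: every entry needs pool_id and member_orf_ids.",
                    path), class = "metscreen_io_error")
    }
    tibble(pool_id = p$pool_id,
           orf_id = unlist(p$member_orf_ids, use.names = FALSE))
  })
  if (!is.null(manifest)) {
    plan <- left_join(plan,
                      select(manifest, any_of(c("orf_id", "gene_symbol", "role"))),
                      by = "orf_id")
  }
  plan
}

#' @rdname read_pool_plan
#' @param plan Pool-plan tibble (`pool_id`, `orf_id`, member order kept).
#' @export
write_pool_plan <- function(plan, path) {
  check_columns(plan, c("pool_id", "orf_id"), "pool plan")
  pools <- plan %>%
    group_by(.data$pool_id) %>%
    summarise(member_orf_ids = list(.data$orf_id), .groups = "drop")
  jsonlite::write_json(
    purrr::map2(pools$pool_id, pools$member_orf_ids,
                function(id, members) list(pool_id = id, member_orf_ids = members)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write a long-format Cq table (CSV)
#'
#' Comma-separated with header
#' `sample_id,mouse_id,pool_id,compartment,probe,replicate,cq,censored`;
#' reference-pellet rows carry an empty `mouse_id`. Real qPCR exports with
#' the same columns are accepted. Unknown compartment tokens are rejected.
#'
#' @param path File path.
#' @return `read_cq_table()` returns the Cq tibble.
#' @export
read_cq_table <- function(path) {
  df <- read_checked(path, function(p) {
    readr::read_csv(p, show_col_types = FALSE, col_types = readr::cols(
      sample_id = readr::col_character(),
      mouse_id = readr::col_character(),
      pool_id = readr::col_character(),
      compartment = readr::col_character(),
      probe = readr::col_character(),
      replicate = readr::col_integer(),
      cq = readr::col_double(),
      censored = readr::col_logical()
    ))
  }, c("sample_id", "mouse_id", "pool_id", "compartment", "probe",
       "replicate", "cq", "censored"), "Cq table")
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad) > 0) {
    abort(sprintf("Cq table %s: unknown compartment token(s): %s.",
                  path, paste(bad, collapse = ", ")),
          class = "metscreen_io_error")
  }
  df
}

#' @rdname read_cq_table
#' @param cq Cq tibble.
#' @export
write_cq_table <- function(cq, path) {
  check_columns(cq, c("sample_id", "mouse_id", "pool_id", "compartment",
                      "probe", "replicate", "cq", "censored"), "Cq table")
  readr::write_csv(cq, path, na = "")
  invisible(path)
}

#' Read / write per-gene enrichment tables (TSV)
#'
#' @param path File path.
#' @return `read_enrichment()` returns the enrichment tibble.
#' @export
read_enrichment <- function(path) {
  read_checked(path, function(p) {
    readr::read_tsv(p, show_col_types = FALSE, col_types = readr::cols(
      pool_id = readr::col_character(), orf_id = readr::col_character(),
      n_pairs = readr::col_integer(), included = readr::col_logical(),
      .default = readr::col_double()
    ))
  }, c("pool_id", "orf_id", "n_pairs", "mean_fc_mfp", "mean_lung_vs_mfp",
       "log2_lung_vs_mfp", "included"), "enrichment")
}

#' @rdname read_enrichment
#' @param enrichment Enrichment tibble.
#' @export
write_enrichment <- function(enrichment, path) {
  check_columns(enrichment, c("pool_id", "orf_id", "n_pairs", "mean_fc_mfp",
                              "mean_lung_vs_mfp", "log2_lung_vs_mfp",
                              "included"), "enrichment")
  readr::write_tsv(enrichment, path)
  invisible(path)
}

#' Read / write hit tables (TSV)
#'
#' The full scored table is written (non-hits keep an empty rank).
#'
#' @param path File path.
#' @return `read_hits()` returns the hit tibble.
#' @export
read_hits <- function(path) {
  read_checked(path, function(p) {
    readr::read_tsv(p, show_col_types = FALSE, col_types = readr::cols(
      rank = readr::col_integer(), n_pairs = readr::col_integer(),
      is_hit = readr::col_logical(), included = readr::col_logical(),
      mfp_depleted = readr::col_logical(),
      mean_fc_mfp = readr::col_double(),
      mean_lung_vs_mfp = readr::col_double(),
      log2_lung_vs_mfp = readr::col_double(),
      .default = readr::col_character()
    ))
  }, c("rank", "orf_id", "gene_symbol", "mean_lung_vs_mfp", "mean_fc_mfp",
       "quadrant", "n_pairs", "is_hit"), "hits")
}

#' @rdname read_hits
#' @param hits Hit tibble from [call_hits()].
#' @export
write_hits <- function(hits, path) {
  check_columns(hits, c("rank", "orf_id", "gene_symbol", "mean_lung_vs_mfp",
                        "mean_fc_mfp", "quadrant", "n_pairs", "is_hit"),
                "hits")
  readr::write_tsv(
    select(hits, "rank", "orf_id", "gene_symbol", "mean_lung_vs_mfp",
           "mean_fc_mfp", "quadrant", "n_pairs", "is_hit",
           dplyr::everything()),
    path)
  invisible(path)
}
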
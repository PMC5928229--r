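#' Generate unique DNA barcodes at a minimum Hamming distance
#'
#' Each construct in a pooled screen carries a unique DNA barcode that is
#' later amplified from genomic DNA and quantified by qPCR. Barcodes are
#' drawn by rejection sampling: random sequences over `A/C/G/T` are accepted
#' only if they differ from every previously accepted barcode at no fewer
#' than `min_dist` positions, which guards against misassignment by
#' amplification or sequencing error.
#'
#' @param n Number of barcodes to generate.
#' @param length Barcode length in bases.
#' @param min_dist Minimum pairwise Hamming distance (0 disables the
#'   constraint beyond uniqueness). Must not exceed `length`.
#' @param seed Integer seed; the returned set is deterministic for a fixed
#'   seed.
#' @param max_attempts Rejection-sampling budget per barcode before the
#'   design is declared infeasible.
#'
#' @return Character vector of `n` distinct barcodes of the given length.
#' @examples
#' generate_barcodes(8, length = 8, min_dist = 3, seed = 1)
#' @export
generate_barcodes <- function(n, length = 8L, min_dist = 3L, seed = 1L,
                              max_attempts = 10000L) {
  n <- check_count(n, "n")
  length <- check_count(length, "length")
  min_dist <- check_count(min_dist, "min_dist", min = 0L)
  max_attempts <- check_count(max_attempts, "max_attempts")
  if (min_dist > length) {
    abort("`min_dist` must not exceed the barcode `length`.",
          class = "metscreen_argument_error")
  }
  if (4^length < n) {
    abort(sprintf("Cannot place %d distinct barcodes of length %d (alphabet size 4).",
                  n, length),
          class = "metscreen_design_infeasible")
  }
  alphabet <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    accepted <- matrix(character(0), nrow = 0, ncol = length)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- sample(alphabet, length, replace = TRUE)
        if (nrow(accepted) == 0) {
          ok <- TRUE
        } else {
          # Hamming distance of the candidate to every accepted codeword
          d <- rowSums(accepted != matrix(cand, nrow(accepted), length, byrow = TRUE))
          ok <- all(d >= max(min_dist, 1L))
        }
        if (ok) {
          accepted <- rbind(accepted, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "Barcode design infeasible: could not place codeword %d of %d at Hamming distance >= %d after %d attempts.",
          i, n, min_dist, max_attempts),
          class = "metscreen_design_infeasible")
      }
    }
    unname(apply(accepted, 1, paste0, collapse = ""))
  })
}

#' Pairwise Hamming distances of a barcode set
#'
#' @param barcodes Character vector of equal-length DNA barcodes.
#' @return Integer matrix of pairwise Hamming distances.
#' @export
barcode_distances <- function(barcodes) {
  stopifnot(is.character(barcodes))
  if (length(unique(nchar(barcodes))) > 1) {
    abort("All barcodes must share one length.", class = "metscreen_argument_error")
  }
  chars <- strsplit(barcodes, "", fixed = TRUE)
  m <- length(barcodes)
  d <- matrix(0L, m, m, dimnames = list(barcodes, barcodes))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j > i) d[i, j] <- d[j, i] <- sum(chars[[i]] != chars[[j]])
    }
  }
  d
}

#' Attach barcodes to a library manifest
#'
#' Fills the `barcode` column of a manifest (see [read_manifest()]) for rows
#' where it is missing, keeping any pre-existing barcodes fixed as long as
#' they satisfy the length constraint.
#'
#' @param manifest Tibble with at least `orf_id`; a `barcode` column is
#'   created or completed.
#' @inheritParams generate_barcodes
#' @return The manifest with a complete, unique `barcode` column.
#' @export
add_barcodes <- function(manifest, length = 8L, min_dist = 3L, seed = 1L) {
  check_columns(manifest, "orf_id", "manifest")
  manifest <- as_tibble(manifest)
  if (!"barcode" %in% names(manifest)) manifest$barcode <- NA_character_
  need <- is.na(manifest$barcode) | manifest$barcode == ""
  codes <- generate_barcodes(nrow(manifest), length = length, min_dist = min_dist,
                             seed = seed)
  # keep user-specified codes, take fresh ones (not colliding) for the rest
  fresh <- setdiff(codes, manifest$barcode[!need])
  manifest$barcode[need] <- fresh[seq_len(sum(need))]
  if (anyDuplicated(manifest$barcode)) {
    abort("Barcodes are not unique across the library.",
          class = "metscreen_design_infeasible")
  }
  manifest
}
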
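# Independent brute-force ddCt recomputation, written against the raw Cq
# table with base-R loops only. Deliberately shares no code with the
# package's dplyr pipeline so it can serve as an oracle for it.

oracle_collapse <- function(cq) {
  key <- paste(cq$sample_id, cq$probe, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- cq[key == k, ]
    usable <- !rows$censored
    out[[k]] <- data.frame(
      sample_id = rows$sample_id[1], mouse_id = rows$mouse_id[1],
      pool_id = rows$pool_id[1], compartment = rows$compartment[1],
      probe = rows$probe[1],
      cq = if (any(usable)) mean(rows$cq[usable]) else max(rows$cq),
      censored = !any(usable),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# full chain: collapsed Cq -> delta Ct -> fold change vs pooled reference ->
# matched lung/MFP pairs -> per-gene means. Returns a data.frame keyed by
# (pool_id, orf_id).
oracle_ddct <- function(cq, min_pairs = 3) {
  col <- oracle_collapse(cq)
  samples <- unique(col$sample_id)
  dct <- list()
  for (s in samples) {
    rows <- col[col$sample_id == s, ]
    dna <- rows$cq[rows$probe == "DNA_REF"]
    stopifnot(length(dna) == 1)
    bar <- rows[rows$probe != "DNA_REF", ]
    bar$delta_ct <- bar$cq - dna
    dct[[s]] <- bar
  }
  dct <- do.call(rbind, dct)

  fc <- dct
  fc$fold_change <- NA_real_
  for (i in seq_len(nrow(fc))) {
    ref <- dct[dct$pool_id == fc$pool_id[i] &
                 dct$compartment == "reference" &
                 dct$probe == fc$probe[i], ]
    stopifnot(nrow(ref) == 1)
    fc$fold_change[i] <- 2^-(fc$delta_ct[i] - ref$delta_ct)
  }

  res <- list()
  for (pool in unique(fc$pool_id)) {
    pf <- fc[fc$pool_id == pool, ]
    for (orf in unique(pf$probe)) {
      ratios <- c(); mfps <- c()
      for (mouse in unique(pf$mouse_id[!is.na(pf$mouse_id)])) {
        m_fc <- pf$fold_change[pf$mouse_id == mouse & pf$probe == orf &
                                 pf$compartment == "mfp"]
        l_fc <- pf$fold_change[pf$mouse_id == mouse & pf$probe == orf &
                                 pf$compartment == "lung"]
        if (length(m_fc) == 1 && length(l_fc) == 1) {
          ratios <- c(ratios, l_fc / m_fc)
          mfps <- c(mfps, m_fc)
        }
      }
      res[[paste(pool, orf)]] <- data.frame(
        pool_id = pool, orf_id = orf, n_pairs = length(ratios),
        mean_fc_mfp = if (length(mfps)) mean(mfps) else NaN,
        mean_lung_vs_mfp = if (length(ratios)) mean(ratios) else NaN,
        included = length(ratios) >= min_pairs,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}
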
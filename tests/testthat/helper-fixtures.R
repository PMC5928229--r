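# Programmatic fixtures used across test files.

# A random raw Cq table with reference, MFP and lung samples for every
# mouse, optional random censoring, built directly (not via the simulator).
random_cq_table <- function(n_orfs = 4, n_mice = 3, seed = 1,
                            replicates = 3, censor_prob = 0,
                            pool_id = "P01", detection_limit = 40) {
  withr::with_seed(seed, {
    orfs <- sprintf("ORF%02d", seq_len(n_orfs))
    probes <- c(orfs, "DNA_REF")
    samples <- data.frame(
      sample_id = c(paste0(pool_id, "_ref"),
                    sprintf("%s_M%02d_MFP", pool_id, seq_len(n_mice)),
                    sprintf("%s_M%02d_LUNG", pool_id, seq_len(n_mice))),
      mouse_id = c(NA_character_,
                   sprintf("%s_M%02d", pool_id, seq_len(n_mice)),
                   sprintf("%s_M%02d", pool_id, seq_len(n_mice))),
      compartment = c("reference", rep("mfp", n_mice), rep("lung", n_mice)),
      stringsAsFactors = FALSE
    )
    rows <- expand.grid(sample_id = samples$sample_id, probe = probes,
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    rows <- merge(rows, samples, by = "sample_id")
    rows$pool_id <- pool_id
    rows$cq <- ifelse(rows$probe == "DNA_REF",
                      rnorm(nrow(rows), 18, 0.3),
                      rnorm(nrow(rows), 26, 2))
    # censoring happens per (sample, probe): absent template fails all wells
    unit <- paste(rows$sample_id, rows$probe)
    censorable <- rows$probe != "DNA_REF" & rows$compartment != "reference"
    hit_units <- unique(unit[censorable])
    hit_units <- hit_units[runif(length(hit_units)) < censor_prob]
    rows$censored <- censorable & unit %in% hit_units
    rows$cq[rows$censored] <- detection_limit
    tibble::as_tibble(rows[, c("sample_id", "mouse_id", "pool_id",
                               "compartment", "probe", "replicate",
                               "cq", "censored")])
  })
}

# Minimal manifest for a handful of candidates plus GFP.
tiny_manifest <- function(n = 4) {
  tibble::tibble(
    orf_id = c(sprintf("ORF%02d", seq_len(n)), "GFP"),
    gene_symbol = c(sprintf("GENE%02d", seq_len(n)), "GFP"),
    role = c(rep("candidate", n), "negative_control"),
    barcode = NA_character_
  )
}

# Noise-free deterministic configuration in exact-proportion mode.
exact_config <- function(...) {
  simulation_config(cq_noise_sd = 0, dna_probe_sd = 0,
                    exact_proportions = TRUE, metastasis_take_rate = 1, ...)
}

# All-neutral effect table (control advantage off too).
neutral_effects <- function(manifest) {
  tibble::tibble(orf_id = manifest$orf_id, g = 0, m = 0)
}
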
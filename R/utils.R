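# internal helpers: argument checking and seed derivation

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(substitute(x))),
          class = "metscreen_argument_error")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
          class = "metscreen_argument_error")
  }
  as.numeric(x)
}

# Deterministic 31-bit substream seeds so stages and pools can be re-run
# independently. Park-Miller step keeps everything inside R's integer range.
derive_seed <- function(seed, index) {
  a <- 48271
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(2L)) s <- (a * s + as.numeric(index) * 7919 + 1) %% m
  as.integer(s)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "metscreen_schema_error")
  }
  invisible(df)
}

COMPARTMENTS <- c("reference", "mfp", "lung")
DNA_REF <- "DNA_REF"
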
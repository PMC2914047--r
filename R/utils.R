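# Internal helpers shared across modules.

# Deterministic 32-bit seed derived from a master seed and a string label.
# Used so each leave-one-out run is reproducible from one integer.
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h
}

check_columns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "samloo_format_error")
  }
  invisible(df)
}

# Normalized factor-ish recode with validation.
match_values <- function(x, allowed, what) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value(s): %s (allowed: %s)",
                  what, paste(bad, collapse = ", "),
                  paste(allowed, collapse = ", ")),
          class = "samloo_format_error")
  }
  x
}

# sample() treats a length-1 numeric x as 1:x; this always samples from
# the elements of x.
sample_from <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}
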
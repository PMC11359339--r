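# Internal helpers shared across modules.

# Deterministic sub-seed for a (region, year, vine) slice so generation does
# not depend on call order. Kept below 2^31 - 1.
sub_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    codes <- utf8ToInt(paste0(as.character(p), "|"))
    for (ch in codes) h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

`%||%` <- rlang::`%||%`

abort_phenocast <- function(msg, class) {
  rlang::abort(msg, class = c(class, "phenocast_error"))
}

# 1-based day of year
doy <- function(date) lubridate::yday(date)

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_phenocast(
      paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")),
      "phenocast_schema_error"
    )
  }
  invisible(df)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
mae <- function(obs, pred) mean(abs(obs - pred))
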
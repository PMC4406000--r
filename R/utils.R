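# Internal helpers shared across modules.

# Round to nearest integer. "half_up" breaks .5 ties upward (floor(x + 0.5));
# "half_even" is banker's rounding (base round()). Averages of three integer
# contributions have fractional parts in {0, 1/3, 2/3}, so the rule only
# matters for two-member averages and user-supplied non-integer levels.
apply_rounding <- function(x, rule = c("half_up", "half_even")) {
  rule <- match.arg(rule)
  switch(rule,
    half_up = floor(x + 0.5),
    half_even = round(x)
  )
}

# Deterministic per-stage sub-seed derivation: keeps every derived seed a
# valid 32-bit integer whatever small integer the caller supplies.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

stop_twinpgg <- function(msg, class = "twinpgg_error") {
  abort(msg, class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_data_frame <- function(x, cols, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    stop_twinpgg(sprintf("`%s` must be a data frame.", arg))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop_twinpgg(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}
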
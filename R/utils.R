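# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a master seed and a text label.
# Each task / simulation stage gets its own substream so that editing one
# task's configuration never perturbs the schedules of the others.
derive_seed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1; doubles stay exact well below 2^53 here
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  as.integer((abs(as.double(seed)) %% m * 69069 + h + 1) %% m)
}

# Inverse-CDF sampler for a normal truncated to [lower, upper].
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_config <- function(field, msg) {
  rlang::abort(
    sprintf("invalid `%s`: %s", field, msg),
    class = "tapbattery_config_error", field = field
  )
}

abort_input <- function(msg, class = "tapbattery_input_error") {
  rlang::abort(msg, class = class)
}
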
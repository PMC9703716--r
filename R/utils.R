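# round half away from zero; base round() is banker's rounding, which would
# make edge counts platform-stable but not match the documented rule
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# trapezoidal area under a metric-vs-density curve
metric_auc <- function(densities, values) {
  stopifnot(length(densities) == length(values))
  if (length(densities) < 2) {
    abort("AUC needs at least 2 grid points.")
  }
  pracma::trapz(densities, values)
}

# permutation p with the add-one estimator: p in (0, 1] always
perm_pvalue <- function(observed, null) {
  (sum(abs(null) >= abs(observed)) + 1) / (length(null) + 1)
}

is_binary01 <- function(x) {
  v <- unique(x[!is.na(x)])
  length(v) >= 1 && all(v %in% c(0, 1))
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}
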
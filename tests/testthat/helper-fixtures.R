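# shared miniature fixtures for the unit tests

unit_simplex <- function(q = 3L) {
  mixture_region(paste0("x", seq_len(q)), lower = rep(0, q),
                 upper = rep(1, q), total = 1)
}

study_region <- dcn_region()
study <- dcn_design()

# random in-region blends for the study region: free components uniform
# in their bounds, water by difference, rejection-sampled for feasibility
random_blends <- function(n, region = study_region, seed = 1L) {
  q <- length(region$names)
  filler <- which.max(region$upper - region$lower)
  free <- setdiff(seq_len(q), filler)
  out <- matrix(NA_real_, 0L, q)
  set.seed(seed)
  while (nrow(out) < n) {
    x <- matrix(NA_real_, 1L, q)
    x[, free] <- region$lower[free] +
      runif(length(free)) * (region$upper[free] - region$lower[free])
    x[, filler] <- region$total - sum(x[, free])
    if (x[, filler] >= region$lower[filler] &&
        x[, filler] <= region$upper[filler]) {
      out <- rbind(out, x)
    }
  }
  colnames(out) <- region$names
  out
}

# seed an expression without disturbing surrounding test RNG expectations
with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
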
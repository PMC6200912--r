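## Shared fixtures: all built in code, seeded, test-scale.

tiny_cfg <- function(...) {
  sim_config(n_regions = 60L, n_networks = 9L, regions_per_network = 5L,
             run_length = 480L, tr = 1, seed = 42L, ...)
}

## Best |correlation| matching of estimated to true maps over all
## permutations (small source counts only); returns per-source best |cor|
## under a one-to-one assignment.
perm_match_cor <- function(est, truth) {
  k <- nrow(truth)
  stopifnot(k <= 5)
  cors <- abs(stats::cor(t(est), t(truth)))   # est x truth
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- rep(-Inf, k)
  for (p in perms(seq_len(nrow(est)))[
         vapply(perms(seq_len(nrow(est))), function(p)
           anyDuplicated(p) == 0, logical(1))]) {
    val <- cors[cbind(p[seq_len(k)], seq_len(k))]
    if (sum(val) > sum(best)) best <- val
  }
  best
}

## Explicit 101-threshold oracle for the sweep (independent of the closed
## form in the package).
sweep_oracle <- function(w) {
  out <- 0
  for (t in 0:100 / 100) out <- out + ifelse(w >= t, w, 0)
  out / 101
}
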
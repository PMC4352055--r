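# Shared fixture builders. All fixtures are generated in code; no data files.

# small centered grid for toy maps and ROIs
toy_grid <- function(n = 16, vox = 4) {
  volume_grid(rep(n, 3), vox, origin = rep(-vox * (n - 1) / 2, 3))
}

# a random demand trace with n_int intervals per module (disjoint by design)
random_trace <- function(modules = c("visual", "declarative"), n_int = 5,
                         total = 60) {
  ints <- lapply(seq_along(modules), function(i) {
    on <- sort(runif(n_int, 0, total - 2))
    off <- on + runif(n_int, 0.1, 1)
    # enforce disjointness by clipping each offset to the next onset
    off <- pmin(off, c(on[-1] - 1e-3, total))
    cbind(on, off)
  })
  names(ints) <- modules
  demand_trace(ints)
}

# exact single-interval trace
interval_trace <- function(module, onset, offset) {
  demand_trace(setNames(list(cbind(onset, offset)), module))
}

# independent column-addition carry oracle: add digit by digit
carry_oracle <- function(a, b) {
  n <- 0L
  carry <- 0L
  while (a > 0 || b > 0 || carry > 0) {
    s <- a %% 10 + b %% 10 + carry
    if (s >= 10) n <- n + 1L
    carry <- s %/% 10
    a <- a %/% 10
    b <- b %/% 10
  }
  n
}
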
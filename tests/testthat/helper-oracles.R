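# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and textbook formulas only.

# Sample-wise run scanner for suppression detection.
oracle_suppressions <- function(env, fs, threshold = 10, min_duration_s = 0.5,
                                start_time_s = 0) {
  runs <- list()
  in_run <- FALSE
  run_start <- NA
  for (i in seq_along(env)) {
    if (env[i] < threshold) {
      if (!in_run) {
        in_run <- TRUE
        run_start <- i
      }
    } else if (in_run) {
      runs[[length(runs) + 1]] <- c(run_start, i - 1)
      in_run <- FALSE
    }
  }
  if (in_run) runs[[length(runs) + 1]] <- c(run_start, length(env))
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  for (r in runs) {
    len_s <- (r[2] - r[1] + 1) / fs
    if (len_s > min_duration_s)
      out <- rbind(out, data.frame(start_s = start_time_s + (r[1] - 1) / fs,
                                   end_s = start_time_s + r[2] / fs))
  }
  out
}

# Exhaustive scan minimum of an envelope inside [interval[1], interval[2]).
oracle_min <- function(env, fs, interval, start_time_s = 0) {
  best <- Inf
  for (i in seq_along(env)) {
    t <- start_time_s + (i - 1) / fs
    if (t >= interval[1] && t < interval[2] && env[i] < best) best <- env[i]
  }
  best
}

# Classic tie-free Friedman statistic from the rank-sum formula.
oracle_friedman_stat <- function(grid) {
  n <- nrow(grid)
  k <- ncol(grid)
  R <- colSums(t(apply(grid, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# Exact two-sided signed-rank p-value by enumeration of all sign patterns
# (tie-free differences required).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1])
  }, 0)
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Spearman rho as the product-moment correlation of mid-ranks.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force occlusion count: walk each phase hour block by block and
# place onsets while a full onset-to-onset cycle fits before the pause.
oracle_occlusion_count <- function(phase_duration_s, pause_period_s,
                                   pause_duration_s, period_s,
                                   occlusion_duration_s) {
  count <- 0
  t_block <- 0
  while (t_block < phase_duration_s) {
    cycle_end <- t_block + pause_period_s - pause_duration_s
    t <- t_block
    while (t + period_s <= cycle_end) {
      count <- count + 1
      t <- t + period_s
    }
    t_block <- t_block + pause_period_s
  }
  count
}
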
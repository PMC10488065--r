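# Independent brute-force oracles used to check the package's statistical
# routines on small instances. These deliberately share no code with the
# implementation paths they verify.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (untied data only)
enum_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(sel) {
    x <- pooled[sel]; y <- pooled[-sel]
    sum(outer(x, y, ">"))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# two-sided Fisher exact p by direct hypergeometric summation over all
# tables with the observed margins
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# maximize the Bernoulli log-likelihood of an intercept+slope logistic
# model over a refined grid; returns c(intercept, slope)
grid_logistic <- function(x, y) {
  ll <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log1p(-p))
  }
  centre <- c(0, 0); half <- 8
  for (pass in 1:4) {
    b0s <- seq(centre[1] - half, centre[1] + half, length.out = 41)
    b1s <- seq(centre[2] - half, centre[2] + half, length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- mapply(ll, grid$b0, grid$b1)
    centre <- unlist(grid[which.max(vals), ])
    half <- half / 10
  }
  unname(centre)
}

# random short trace for property tests
random_trace <- function(n = 40, dt = 30, id = "r") {
  vital_trace(id, (seq_len(n) - 1) * dt,
              stats::runif(n, 40, 100))
}

# small fast simulator configuration used across tests
quick_config <- function(n = 120, seed = 1, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

# per-sample rectangle-rule TWA computed with an explicit loop, no reuse
# of the vectorized implementation
loop_twa <- function(trace, threshold) {
  dt <- trace$t[2] - trace$t[1]
  area <- 0
  for (m in trace$map_mmHg) {
    d <- threshold - m
    if (d > 0) area <- area + d * dt
  }
  area / (length(trace$map_mmHg) * dt)
}
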
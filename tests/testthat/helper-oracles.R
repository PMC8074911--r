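# Independent oracles used across the test files. These deliberately avoid
# the package's own vectorized implementations.

# Brute-force endpoint-sharing coupling: two links are coupled iff their
# species sets intersect.
brute_coupling <- function(web) {
  n <- nrow(web$links)
  g <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- c(web$links$consumer[i], web$links$resource[i])
      b <- c(web$links$consumer[j], web$links$resource[j])
      if (length(intersect(a, b)) > 0) g[i, j] <- 1
    }
  }
  dimnames(g) <- list(web$links$oscillator_id, web$links$oscillator_id)
  g
}

# A random small food web (no self-loops; duplicate species pairs allowed).
random_web <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(2:12, 1)
    pool <- paste0("sp", seq_len(sample(3:8, 1)))
    cons <- character(n)
    res <- character(n)
    for (i in seq_len(n)) {
      pair <- sample(pool, 2)
      cons[i] <- pair[1]
      res[i] <- pair[2]
    }
    foodweb(data.frame(oscillator_id = seq_len(n),
                       consumer = cons, resource = res))
  })
}

# Plain-R fixed-step RK4 over the package's phase_velocity(), as an
# independent check on the compiled integrator.
rk4_r <- function(net, config, initial) {
  n_steps <- round(config$t_end / config$dt)
  theta <- as.numeric(initial)
  out <- matrix(NA_real_, n_steps + 1, net$n)
  out[1, ] <- theta
  h <- config$dt
  for (s in seq_len(n_steps)) {
    k1 <- phase_velocity(theta, net, config)
    k2 <- phase_velocity(theta + h / 2 * k1, net, config)
    k3 <- phase_velocity(theta + h / 2 * k2, net, config)
    k4 <- phase_velocity(theta + h * k3, net, config)
    theta <- theta + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1, ] <- theta
  }
  out %% (2 * pi)
}

# Circular distance between two phase vectors, for comparisons that must
# ignore the 2*pi wrap.
circ_diff <- function(a, b) abs(2 * sin((a - b) / 2))

# A hand-built trajectory holding a prescribed final phase state, for testing
# classification functions in isolation from the integrator.
fake_traj <- function(theta, labels = seq_along(theta)) {
  phases <- rbind(rep(0, length(theta)), theta)
  colnames(phases) <- labels
  structure(list(times = c(0, 1), phases = phases,
                 config = sim_config(t_end = 1, dt = 1),
                 network = list(n = length(theta), labels = as.integer(labels))),
            class = "kuramoto_trajectory")
}

# Smallest grid K at which oscillators i and j are persistently co-grouped.
first_cogroup_K <- function(sweep, i, j) {
  hit <- vapply(sweep$partitions, function(p)
    any(vapply(p$groups, function(g) all(c(i, j) %in% g), logical(1))),
    logical(1))
  if (!any(hit)) return(NA_real_)
  min(sweep$spec$k_grid[hit])
}
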
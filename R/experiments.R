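#' Default coupling-strength grid
#'
#' A regular grid from 0 to 1.2 in steps of 0.05 augmented with the
#' specifically interesting low-coupling values at which small guild clusters
#' begin to synchronize.
#'
#' @return Increasing numeric vector.
#' @export
default_k_grid <- function() {
  sort(unique(c(seq(0, 1.2, by = 0.05), 0.01, 0.014, 0.015)))
}

#' Calibrated simulation settings for the coffee study network
#'
#' With identical winding numbers the phase dynamics depend on the coupling
#' `K` and time only through their product `tau = K * t`, so the harvest
#' time sets the scale on which the coupling axis of a sweep is read. For
#' the coffee fixture the package anchors that scale on complete
#' synchronization: the harvest time is chosen once (t_end = 110) so that
#' the persistent partition collapses to a single 22-oscillator group close
#' to coupling 1.0 on the sweep grid, which places the whole
#' group-formation-and-merging cascade inside the default grid. See the
#' methods vignette for the calibration rationale.
#'
#' @param seed Master seed.
#' @param ... Further arguments passed to [sim_config()] (e.g. `dt`).
#' @return A [sim_config] with `omega = 0.01` and `t_end = 110`.
#' @export
coffee_study_config <- function(seed = 1, ...) {
  sim_config(omega = 0.01, t_end = 110, seed = seed, ...)
}

#' Specification of a coupling-strength sweep
#'
#' @param k_grid Strictly increasing non-negative coupling values (on the
#'   per-neighbour scale).
#' @param config Base [sim_config]; `config$seed` is the master seed from
#'   which every replicate seed is derived.
#' @param criterion A [synchrony_criterion].
#' @param persistence A [persistence_config].
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(k_grid = default_k_grid(),
                       config = sim_config(seed = 1),
                       criterion = synchrony_criterion(),
                       persistence = persistence_config()) {
  k_grid <- as.numeric(k_grid)
  stopifnot(length(k_grid) > 0, all(k_grid >= 0),
            all(diff(k_grid) > 0) || length(k_grid) == 1)
  if (is.null(config$seed)) {
    stop("sweep_spec needs config$seed (a master seed)", call. = FALSE)
  }
  structure(list(k_grid = k_grid, config = config, criterion = criterion,
                 persistence = persistence),
            class = "sweep_spec")
}

#' Run a coupling-strength sweep
#'
#' For every grid coupling value, runs the replicate persistence analysis
#' (fresh random initializations per replicate, paired across sweep points by
#' the derived-seed scheme) and records order-parameter statistics at harvest
#' time together with the persistent partition. An onset table records, for
#' every distinct persistent group composition, the smallest grid coupling at
#' which it first appears.
#'
#' Replicate seeds depend only on (master seed, position of K in the grid,
#' replicate index), so running the same spec on a rescaled network yields
#' paired replicates, and shuffling the grid does not change per-K results.
#'
#' @param net An [oscillator_network].
#' @param spec A [sweep_spec].
#' @return An object of class `sweep_result`: list with `summary` (a tibble:
#'   `K`, `order_mean`, `order_sd`, `n_groups`, `n_chimeric`,
#'   `largest_group`), `partitions` (one `synchrony_partition` per K),
#'   `onset` (tibble of first appearances) and `spec`.
#' @export
run_sweep <- function(net, spec = sweep_spec()) {
  stopifnot(inherits(net, "oscillator_network"), inherits(spec, "sweep_spec"))
  ord <- order(spec$k_grid)
  rows <- vector("list", length(spec$k_grid))
  partitions <- vector("list", length(spec$k_grid))
  for (pos in seq_along(spec$k_grid)) {
    i <- ord[pos]
    K <- spec$k_grid[i]
    config <- spec$config
    config$K <- K
    # key replicate seeds by the K value itself: per-K results are then
    # invariant to grid composition and paired across networks
    part <- persistent_groups(net, config, spec$persistence, spec$criterion,
                              k_index = round(K * 1e4))
    rs <- part$replicate_order_parameters
    partitions[[i]] <- part
    g <- glance(part)
    rows[[i]] <- tibble::tibble(
      K = K, order_mean = mean(rs), order_sd = stats::sd(rs),
      n_groups = g$n_groups, n_chimeric = g$n_chimeric,
      largest_group = g$largest_group)
  }
  summary <- dplyr::bind_rows(rows)
  res <- structure(list(summary = summary, partitions = partitions,
                        onset = NULL, spec = spec),
                   class = "sweep_result")
  res$onset <- onset_table(res)
  res
}

# First grid K at which each persistent group composition appears.
onset_table <- function(result) {
  seen <- character(0)
  out <- list()
  for (i in seq_along(result$spec$k_grid)) {
    for (g in result$partitions[[i]]$groups) {
      key <- paste(g, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- tibble::tibble(
          first_K = result$spec$k_grid[i],
          size = length(g),
          members = key)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(first_K = numeric(0), size = integer(0),
                          members = character(0)))
  }
  dplyr::bind_rows(out)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", nrow(x$summary), " coupling values, ",
      x$spec$persistence$n_replicates, " replicates each\n", sep = "")
  print(x$summary, n = 8)
  invisible(x)
}

#' @export
tidy.sweep_result <- function(x, ...) x$summary

#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    n_k = nrow(x$summary),
    k_full_sync = k_full_sync(x),
    max_largest_group = max(x$summary$largest_group))
}

nrow_net <- function(x) length(x$partitions[[1]]$labels)

#' Smallest grid coupling achieving full persistent synchrony
#'
#' @param result A `sweep_result`.
#' @return The smallest grid K whose persistent partition is a single group
#'   containing every oscillator, or `NA` if none.
#' @export
k_full_sync <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  n <- nrow_net(result)
  hit <- result$summary$K[result$summary$n_groups == 1 &
                            result$summary$largest_group == n]
  if (length(hit) == 0) NA_real_ else min(hit)
}

#' Paired sweep on a baseline and a rescaled network
#'
#' Runs the identical sweep (same derived replicate seeds) on `net` and on
#' the network with one oscillator's couplings multiplied by `factor`, so any
#' difference in outcomes reflects network structure, not sampling noise.
#' Also extracts, for each condition, the "last two super-groups": the
#' persistent partition at the largest grid coupling that still has at least
#' two groups.
#'
#' @param net Baseline [oscillator_network].
#' @param oscillator_id Oscillator whose couplings are rescaled.
#' @param factor Non-negative multiplier (default 0.1, "a tenth of the
#'   others").
#' @param spec A [sweep_spec].
#' @return An object of class `weighted_comparison`: list with `baseline` and
#'   `scaled` sweep results, `factor`, `oscillator_id`, and `differences`, a
#'   per-K tibble flagging where the persistent partitions differ.
#' @export
compare_weighted <- function(net, oscillator_id, factor = 0.1,
                             spec = sweep_spec()) {
  baseline <- run_sweep(net, spec)
  scaled <- run_sweep(scale_oscillator_coupling(net, oscillator_id, factor),
                      spec)
  differences <- tibble::tibble(
    K = spec$k_grid,
    identical_partition = vapply(seq_along(spec$k_grid), function(i) {
      identical(baseline$partitions[[i]]$groups,
                scaled$partitions[[i]]$groups)
    }, logical(1)))
  structure(list(baseline = baseline, scaled = scaled,
                 factor = factor, oscillator_id = oscillator_id,
                 differences = differences),
            class = "weighted_comparison")
}

#' @export
print.weighted_comparison <- function(x, ...) {
  cat("<weighted_comparison> oscillator ", x$oscillator_id, " x ", x$factor,
      "; partitions differ at ",
      sum(!x$differences$identical_partition), "/",
      nrow(x$differences), " grid couplings\n", sep = "")
  invisible(x)
}

#' Last super-groups before full synchrony
#'
#' @param result A `sweep_result`.
#' @return The persistent `synchrony_partition` at the largest grid coupling
#'   with at least two groups, or `NULL` if there is none.
#' @export
last_supergroups <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  multi <- which(result$summary$n_groups >= 2)
  if (length(multi) == 0) return(NULL)
  result$partitions[[max(multi)]]
}

#' Earliest time a subset is fully co-grouped
#'
#' Scans the sampled trajectory times and returns the first at which all of
#' `subset` lies inside one connected component of the synchrony relation, or
#' `NA` if that never happens.
#'
#' @param traj A `kuramoto_trajectory`.
#' @param subset Oscillator ids.
#' @param criterion A [synchrony_criterion] (its `eval_time` is ignored).
#' @return A time, or `NA_real_`.
#' @export
time_to_group <- function(traj, subset, criterion = synchrony_criterion()) {
  stopifnot(inherits(traj, "kuramoto_trajectory"))
  idx <- match(as.integer(subset), traj$network$labels)
  if (anyNA(idx)) {
    stop("unknown oscillator id(s): ",
         paste(subset[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(traj$times)) {
    theta <- traj$phases[i, ]
    rel <- synchrony_graph(theta, criterion)
    memb <- sync_components(rel)
    if (length(unique(memb[idx])) == 1) return(traj$times[i])
  }
  NA_real_
}

#' Export a trajectory as tidy or matrix CSV
#'
#' @param traj A `kuramoto_trajectory`.
#' @param path Output path.
#' @param format `"tidy"` (`time,oscillator_id,theta`) or `"matrix"` (one
#'   column per oscillator).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("tidy", "matrix")) {
  format <- match.arg(format)
  if (format == "tidy") {
    readr::write_csv(tidy(traj), path)
  } else {
    df <- tibble::as_tibble(traj$phases)
    names(df) <- paste0("osc_", colnames(traj$phases))
    df <- dplyr::bind_cols(tibble::tibble(time = traj$times), df)
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read a tidy trajectory CSV back into a long tibble
#'
#' @param path Path written by [write_trajectory()] with `format = "tidy"`.
#' @return A tibble `time, oscillator_id, theta`.
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(time = "d", oscillator_id = "i",
                                          theta = "d"))
}

#' Long-format phases of a trajectory
#'
#' @param x A `kuramoto_trajectory`.
#' @param ... Unused.
#' @return A tibble `time, oscillator_id, theta`.
#' @export
tidy.kuramoto_trajectory <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = ncol(x$phases)),
    oscillator_id = rep(as.integer(colnames(x$phases)),
                        each = length(x$times)),
    theta = as.vector(x$phases))
}

#' One-row summary of a trajectory
#'
#' @param x A `kuramoto_trajectory`.
#' @param ... Unused.
#' @return A tibble with `n`, `t_end`, `dt`, `K` and the final order
#'   parameter `r_end`.
#' @export
glance.kuramoto_trajectory <- function(x, ...) {
  tibble::tibble(n = ncol(x$phases), t_end = max(x$times),
                 dt = x$config$dt, K = x$config$K,
                 r_end = order_parameter(final_phases(x)))
}
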
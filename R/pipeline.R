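# Pipeline entry points: each command resolves its inputs, runs the package
# functions, writes result files plus a run manifest, and returns the output
# paths invisibly. A thin command-line wrapper over these lives at
# inst/cli/ecosync.R.

resolve_network <- function(network = NULL, fixture = FALSE) {
  if (fixture) {
    fx <- coffee_fixture()
    list(net = fx$network, input = system.file("extdata",
                                               "coffee_foodweb.csv",
                                               package = "ecosync"))
  } else {
    if (is.null(network) || !file.exists(network)) {
      stop("network file not found: ", network %||% "<missing>",
           call. = FALSE)
    }
    net <- if (grepl("\\.tsv$", network)) {
      read_coupling_matrix(network)
    } else {
      derive_coupling(read_foodweb(network))
    }
    list(net = net, input = network)
  }
}

write_manifest <- function(out_dir, command, config, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    config = config,
    package_version = as.character(utils::packageVersion("ecosync")),
    master_seed = seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = basename(outputs),
    generated_at = format(Sys.time(), tz = "UTC")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a single simulation and write its outputs
#'
#' Writes `trajectory.csv` (tidy long format), `partition.json`,
#' `partition.csv` and `manifest.json` under `out`.
#'
#' @param out Output directory (created if needed).
#' @param network Path to an edge-list CSV (or coupling-matrix `.tsv`);
#'   ignored when `fixture = TRUE`.
#' @param fixture Use the packaged coffee network.
#' @param K,seed,t_end,dt,omega Simulation settings (see [sim_config()]).
#' @param C Chordal synchrony threshold.
#' @return Invisibly, the written file paths.
#' @export
ecosync_simulate <- function(out, network = NULL, fixture = is.null(network),
                             K = 0.8, seed = 1, t_end = 20, dt = 0.01,
                             omega = 0.01, C = 0.01) {
  src <- resolve_network(network, fixture)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  config <- sim_config(omega = omega, K = K, t_end = t_end, dt = dt,
                       seed = seed)
  traj <- integrate_kuramoto(src$net, config)
  part <- groups_from_run(traj, synchrony_criterion(C = C))
  paths <- file.path(out, c("trajectory.csv", "partition.json",
                            "partition.csv"))
  write_trajectory(traj, paths[1])
  write_partition(part, json = paths[2], csv = paths[3])
  manifest <- write_manifest(out, "simulate",
                             config = config[c("omega", "K", "sign", "t_end",
                                               "dt", "seed")],
                             seed = seed, inputs = list(src$input),
                             outputs = paths)
  invisible(c(paths, manifest))
}

#' Run a coupling sweep and write its outputs
#'
#' Writes `sweep_summary.csv` (one row per grid coupling), `onset.csv`,
#' per-coupling partition JSONs under `partitions/`, and `manifest.json`.
#'
#' @inheritParams ecosync_simulate
#' @param k_grid Coupling grid (defaults to [default_k_grid()]).
#' @param replicates,min_cooccurrence Persistence settings.
#' @return Invisibly, the main output paths.
#' @export
ecosync_sweep <- function(out, network = NULL, fixture = is.null(network),
                          k_grid = default_k_grid(), replicates = 20,
                          min_cooccurrence = ceiling(replicates * 19 / 20),
                          seed = 1, t_end = 20, dt = 0.01, omega = 0.01,
                          C = 0.01) {
  src <- resolve_network(network, fixture)
  dir.create(file.path(out, "partitions"), showWarnings = FALSE,
             recursive = TRUE)
  spec <- sweep_spec(
    k_grid = k_grid,
    config = sim_config(omega = omega, t_end = t_end, dt = dt, seed = seed),
    persistence = persistence_config(replicates, min_cooccurrence),
    criterion = synchrony_criterion(C = C))
  result <- run_sweep(src$net, spec)
  paths <- file.path(out, c("sweep_summary.csv", "onset.csv"))
  readr::write_csv(result$summary, paths[1])
  readr::write_csv(result$onset, paths[2])
  for (i in seq_along(spec$k_grid)) {
    write_partition(result$partitions[[i]],
                    json = file.path(out, "partitions",
                                     sprintf("K_%0.3f.json", spec$k_grid[i])))
  }
  manifest <- write_manifest(out, "sweep",
                             config = list(k_grid = k_grid,
                                           replicates = replicates,
                                           min_cooccurrence = min_cooccurrence,
                                           seed = seed, t_end = t_end,
                                           dt = dt, omega = omega, C = C),
                             seed = seed, inputs = list(src$input),
                             outputs = paths)
  invisible(c(paths, manifest))
}

#' Paired baseline / downweighted-oscillator sweep
#'
#' Runs the identical sweep on the baseline network and on the network with
#' one oscillator's couplings multiplied by `factor` (default: oscillator 22
#' of the coffee fixture at a tenth), and writes both summaries, a per-K
#' difference table, the last-super-group partitions, and a manifest.
#'
#' @inheritParams ecosync_sweep
#' @param oscillator_id Oscillator to downweight.
#' @param factor Coupling multiplier.
#' @return Invisibly, the main output paths.
#' @export
ecosync_weak22 <- function(out, network = NULL, fixture = is.null(network),
                           oscillator_id = 22, factor = 0.1,
                           k_grid = default_k_grid(), replicates = 20,
                           min_cooccurrence = ceiling(replicates * 19 / 20),
                           seed = 1, t_end = 20, dt = 0.01, omega = 0.01,
                           C = 0.01) {
  src <- resolve_network(network, fixture)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- sweep_spec(
    k_grid = k_grid,
    config = sim_config(omega = omega, t_end = t_end, dt = dt, seed = seed),
    persistence = persistence_config(replicates, min_cooccurrence),
    criterion = synchrony_criterion(C = C))
  cmp <- compare_weighted(src$net, oscillator_id, factor, spec)
  paths <- file.path(out, c("baseline_summary.csv", "scaled_summary.csv",
                            "differences.csv"))
  readr::write_csv(cmp$baseline$summary, paths[1])
  readr::write_csv(cmp$scaled$summary, paths[2])
  readr::write_csv(cmp$differences, paths[3])
  for (cond in c("baseline", "scaled")) {
    lsg <- last_supergroups(cmp[[cond]])
    if (!is.null(lsg)) {
      write_partition(lsg, json = file.path(
        out, sprintf("last_supergroups_%s.json", cond)))
    }
  }
  manifest <- write_manifest(out, "weak22",
                             config = list(oscillator_id = oscillator_id,
                                           factor = factor, k_grid = k_grid,
                                           replicates = replicates,
                                           min_cooccurrence = min_cooccurrence,
                                           seed = seed, t_end = t_end,
                                           dt = dt, omega = omega, C = C),
                             seed = seed, inputs = list(src$input),
                             outputs = paths)
  invisible(c(paths, manifest))
}

#' Generate a synthetic web and write it with its ground truth
#'
#' Writes `web.csv` (edge list), `ground_truth.csv`
#' (`oscillator_id,guild`) and `manifest.json`.
#'
#' @param out Output directory.
#' @param n_guilds,enemies_per_guild,n_bridges,n_cut_links,seed See
#'   [web_spec()].
#' @return Invisibly, the written paths.
#' @export
ecosync_generate <- function(out, n_guilds = 4, enemies_per_guild = c(4, 6),
                             n_bridges = 3, n_cut_links = 1, seed = 0) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- web_spec(n_guilds, enemies_per_guild, n_bridges, n_cut_links, seed)
  web <- generate_web(spec)
  paths <- file.path(out, c("web.csv", "ground_truth.csv"))
  write_foodweb(web, paths[1])
  readr::write_csv(ground_truth(spec, web), paths[2])
  manifest <- write_manifest(out, "generate", config = unclass(spec),
                             seed = seed, inputs = list(), outputs = paths)
  invisible(c(paths, manifest))
}
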
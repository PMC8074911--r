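#' Synchrony classification settings
#'
#' @param C Chordal threshold: two oscillators are judged synchronous when
#'   the Euclidean chord between their unit-circle points is below `C`
#'   (default 0.01; at this magnitude chord length and angular difference are
#'   indistinguishable to reporting precision).
#' @param eval_time Time at which phases are compared; `NULL` means the final
#'   time of the trajectory.
#' @return An object of class `synchrony_criterion`.
#' @export
synchrony_criterion <- function(C = 0.01, eval_time = NULL) {
  stopifnot(C > 0)
  structure(list(C = C, eval_time = eval_time), class = "synchrony_criterion")
}

#' Replicate persistence settings
#'
#' A pair of oscillators belongs to the same *persistent* synchrony group when
#' it co-occurs in a group in at least `min_cooccurrence` of `n_replicates`
#' randomly initialized runs (defaults 19 of 20).
#'
#' @param n_replicates Number of random-initialization replicates.
#' @param min_cooccurrence Minimum number of co-grouped replicates.
#' @return An object of class `persistence_config`.
#' @export
persistence_config <- function(n_replicates = 20, min_cooccurrence = 19) {
  stopifnot(n_replicates >= 1,
            min_cooccurrence >= 1, min_cooccurrence <= n_replicates)
  structure(list(n_replicates = n_replicates,
                 min_cooccurrence = min_cooccurrence),
            class = "persistence_config")
}

#' Chordal distance between two phases
#'
#' The Euclidean distance between the two phases' points on the unit circle,
#' `sqrt((sin a - sin b)^2 + (cos a - cos b)^2) = 2 |sin((a - b)/2)|`,
#' always in `[0, 2]`. Vectorized.
#'
#' @param theta_i,theta_j Phases in radians.
#' @return Non-negative chord length(s).
#' @examples
#' chordal_distance(0, pi)     # 2: antipodal
#' chordal_distance(0, 0.01)   # ~0.01: chord ~ angle for small differences
#' @export
chordal_distance <- function(theta_i, theta_j) {
  sqrt((sin(theta_i) - sin(theta_j))^2 + (cos(theta_i) - cos(theta_j))^2)
}

#' Pairwise synchrony relation of a phase state
#'
#' @param theta Named or unnamed numeric vector of phases.
#' @param criterion A [synchrony_criterion].
#' @return A symmetric logical matrix with `FALSE` diagonal: `TRUE` where the
#'   chordal distance is below the threshold `C`.
#' @export
synchrony_graph <- function(theta, criterion = synchrony_criterion()) {
  n <- length(theta)
  d <- chordal_distance(matrix(theta, n, n), matrix(theta, n, n, byrow = TRUE))
  rel <- d < criterion$C
  diag(rel) <- FALSE
  dimnames(rel) <- list(names(theta), names(theta))
  rel
}

# Connected components of a logical synchrony relation, as integer membership.
sync_components <- function(rel) {
  g <- igraph::graph_from_adjacency_matrix(rel, mode = "undirected")
  igraph::components(g)$membership
}

new_synchrony_partition <- function(membership, labels, source,
                                    pair_counts = NULL) {
  sizes <- table(membership)
  grouped <- membership %in% as.integer(names(sizes)[sizes >= 2])
  groups <- unname(split(labels[grouped], membership[grouped]))
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  structure(list(groups = groups,
                 chimerics = sort(labels[!grouped]),
                 labels = labels,
                 source = source,
                 pair_counts = pair_counts),
            class = "synchrony_partition")
}

#' @export
print.synchrony_partition <- function(x, ...) {
  cat("<synchrony_partition> (", x$source, ") ", length(x$groups),
      " group(s), ", length(x$chimerics), " chimeric element(s)\n", sep = "")
  for (g in x$groups) cat("  {", paste(g, collapse = ","), "}\n", sep = "")
  if (length(x$chimerics) > 0) {
    cat("  chimeric: ", paste(x$chimerics, collapse = ","), "\n", sep = "")
  }
  invisible(x)
}

#' Synchrony groups of a single run
#'
#' Groups are the connected components, of size at least two, of the pairwise
#' synchrony relation evaluated at the harvest time; chaining is intentional
#' (a group need not be a clique). Oscillators in no group are chimeric
#' elements.
#'
#' @param traj A `kuramoto_trajectory`.
#' @param criterion A [synchrony_criterion]; `eval_time = NULL` evaluates at
#'   the trajectory's final time.
#' @return A `synchrony_partition` with `source = "single-run"`.
#' @export
groups_from_run <- function(traj, criterion = synchrony_criterion()) {
  stopifnot(inherits(traj, "kuramoto_trajectory"))
  theta <- if (is.null(criterion$eval_time)) {
    final_phases(traj)
  } else {
    phases_at(traj, criterion$eval_time)
  }
  rel <- synchrony_graph(theta, criterion)
  new_synchrony_partition(sync_components(rel), traj$network$labels,
                          source = "single-run")
}

#' Persistent synchrony groups across replicates
#'
#' Runs `n_replicates` simulations with fresh random initial phases (replicate
#' seeds derived deterministically from `config$seed`), counts for every pair
#' of oscillators how often the two fell into the same synchrony group at the
#' harvest time, keeps the pairs co-grouped in at least `min_cooccurrence`
#' replicates, and closes that relation into connected components. Components
#' of size at least two are the persistent groups; the rest are chimeric.
#'
#' @param net An [oscillator_network].
#' @param config A [sim_config]; its `seed` is the master seed.
#' @param pconfig A [persistence_config].
#' @param criterion A [synchrony_criterion].
#' @param k_index Integer folded into replicate-seed derivation so sweep
#'   points get independent (but network-paired) replicates.
#' @return A `synchrony_partition` with `source = "persistent"` and the
#'   per-pair co-membership counts in `pair_counts`.
#' @export
persistent_groups <- function(net, config = sim_config(),
                              pconfig = persistence_config(),
                              criterion = synchrony_criterion(),
                              k_index = 0) {
  stopifnot(inherits(net, "oscillator_network"),
            inherits(pconfig, "persistence_config"))
  if (is.null(config$seed)) {
    stop("persistent_groups needs config$seed for reproducible replicates",
         call. = FALSE)
  }
  n <- net$n
  counts <- matrix(0L, n, n, dimnames = list(net$labels, net$labels))
  r_final <- numeric(pconfig$n_replicates)
  for (r in seq_len(pconfig$n_replicates)) {
    rconfig <- config
    rconfig$seed <- derive_seed(config$seed, k_index, r)
    theta <- simulate_final_phases(net, rconfig)
    r_final[r] <- order_parameter(theta)
    memb <- sync_components(synchrony_graph(theta, criterion))
    sizes <- table(memb)
    in_group <- memb %in% as.integer(names(sizes)[sizes >= 2])
    same <- outer(memb, memb, "==") & outer(in_group, in_group, "&")
    counts <- counts + same
  }
  diag(counts) <- 0L
  part <- partition_from_pair_counts(counts, pconfig$min_cooccurrence,
                                     labels = net$labels)
  part$replicate_order_parameters <- r_final
  part
}

#' Build a partition from pair co-membership counts
#'
#' Closes the relation `counts >= min_cooccurrence` into connected
#' components; components of size at least two become groups.
#'
#' @param counts Symmetric integer matrix of per-pair co-membership counts.
#' @param min_cooccurrence Persistence threshold.
#' @param labels Oscillator ids aligned to `counts` rows.
#' @return A `synchrony_partition` with `source = "persistent"`.
#' @export
partition_from_pair_counts <- function(counts, min_cooccurrence,
                                       labels = seq_len(nrow(counts))) {
  rel <- counts >= min_cooccurrence
  diag(rel) <- FALSE
  new_synchrony_partition(sync_components(rel), as.integer(labels),
                          source = "persistent", pair_counts = counts)
}

#' Size of the largest synchronized cluster within a subset
#'
#' Restricts the synchrony relation at harvest time to `subset` and returns
#' the size of its largest connected component (1 when no pair in the subset
#' is synchronized). Mirrors counting "how many of the five are in synchrony"
#' for a guild.
#'
#' @param traj A `kuramoto_trajectory`.
#' @param subset Non-empty vector of oscillator ids.
#' @param criterion A [synchrony_criterion].
#' @return An integer in `1..length(subset)`.
#' @export
count_in_synchrony <- function(traj, subset, criterion = synchrony_criterion()) {
  stopifnot(inherits(traj, "kuramoto_trajectory"), length(subset) > 0)
  idx <- match(as.integer(subset), traj$network$labels)
  if (anyNA(idx)) {
    stop("unknown oscillator id(s): ",
         paste(subset[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  theta <- if (is.null(criterion$eval_time)) {
    final_phases(traj)
  } else {
    phases_at(traj, criterion$eval_time)
  }
  rel <- synchrony_graph(theta[idx], criterion)
  max(table(sync_components(rel)))
}

#' Oscillator group membership as a tibble
#'
#' @param x A `synchrony_partition`.
#' @param ... Unused.
#' @return A tibble with `oscillator_id` and `group_id` (0 denotes a chimeric
#'   element; groups are numbered by their smallest member).
#' @export
tidy.synchrony_partition <- function(x, ...) {
  group_id <- stats::setNames(rep(0L, length(x$labels)), x$labels)
  for (i in seq_along(x$groups)) {
    group_id[as.character(x$groups[[i]])] <- i
  }
  tibble::tibble(oscillator_id = x$labels,
                 group_id = unname(group_id[as.character(x$labels)]))
}

#' One-row summary of a synchrony partition
#'
#' @param x A `synchrony_partition`.
#' @param ... Unused.
#' @return A tibble with `n_groups`, `n_chimeric`, `largest_group` (0 when no
#'   group exists) and `source`.
#' @export
glance.synchrony_partition <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$groups),
    n_chimeric = length(x$chimerics),
    largest_group = if (length(x$groups) == 0) 0L else
      max(vapply(x$groups, length, integer(1))),
    source = x$source
  )
}

#' Write a synchrony partition report
#'
#' Writes a JSON report (groups as sorted id lists, chimerics, pair counts if
#' present) and/or a flat CSV (`oscillator_id,group_id`, `group_id` 0 meaning
#' chimeric).
#'
#' @param partition A `synchrony_partition`.
#' @param json,csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_partition <- function(partition, json = NULL, csv = NULL) {
  stopifnot(inherits(partition, "synchrony_partition"))
  if (!is.null(json)) {
    payload <- list(source = partition$source,
                    groups = lapply(partition$groups, as.integer),
                    chimerics = as.integer(partition$chimerics))
    if (!is.null(partition$pair_counts)) {
      pc <- partition$pair_counts
      pairs <- which(upper.tri(pc) & pc > 0, arr.ind = TRUE)
      payload$pair_counts <- data.frame(
        i = partition$labels[pairs[, 1]],
        j = partition$labels[pairs[, 2]],
        count = pc[pairs])
    }
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv)) {
    readr::write_csv(tidy(partition), csv)
  }
  invisible(c(json = json, csv = csv))
}
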
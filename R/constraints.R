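#' Structural constraints on an oscillator network
#'
#' A small declarative vocabulary for asserting load-bearing topology of a
#' coupling network, decidable in polynomial time:
#'
#' * `node_removal_components`: after deleting the oscillators in `remove`
#'   (possibly none), the remaining graph has exactly the connected components
#'   given in `components` (a list of oscillator-id vectors).
#' * `edge_removal_components`: as above after deleting the single coupling
#'   `edge = c(i, j)`.
#' * `edge_present` / `edge_absent`: the coupling `edge = c(i, j)` exists /
#'   does not exist.
#' * `block_complete`: the oscillators in `nodes` are pairwise coupled.
#'
#' @param kind One of the five kinds above.
#' @param ... Kind-specific parameters (`remove`, `edge`, `components`,
#'   `nodes`) plus an optional `label`.
#' @return An object of class `structural_constraint`.
#' @export
structural_constraint <- function(kind, ...) {
  kinds <- c("node_removal_components", "edge_removal_components",
             "edge_present", "edge_absent", "block_complete")
  kind <- match.arg(kind, kinds)
  structure(c(list(kind = kind), list(...)), class = "structural_constraint")
}

#' @export
print.structural_constraint <- function(x, ...) {
  cat("<structural_constraint> ", x$kind,
      if (!is.null(x$label)) paste0(": ", x$label), "\n", sep = "")
  invisible(x)
}

same_partition <- function(comps, expected) {
  canon <- function(sets) {
    sets <- lapply(unname(sets), function(s) sort(as.integer(s)))
    sets[order(vapply(sets, function(s) s[1], integer(1)))]
  }
  identical(canon(comps), canon(expected))
}

graph_components <- function(net, drop_nodes = integer(0), drop_edge = NULL) {
  g <- as_oscillator_graph(net)
  if (length(drop_nodes) > 0) {
    g <- igraph::delete_vertices(g, as.character(drop_nodes))
  }
  if (!is.null(drop_edge)) {
    e <- igraph::get_edge_ids(g, as.character(drop_edge))
    if (e == 0) stop("edge to remove is not present: ",
                     paste(drop_edge, collapse = "-"), call. = FALSE)
    g <- igraph::delete_edges(g, e)
  }
  memb <- igraph::components(g)$membership
  split(as.integer(names(memb)), memb)
}

check_one_constraint <- function(net, con) {
  has_edge <- function(i, j) {
    net$gamma[match(i, net$labels), match(j, net$labels)] > 0
  }
  switch(con$kind,
    node_removal_components = {
      comps <- graph_components(net, drop_nodes = con$remove %||% integer(0))
      same_partition(comps, con$components)
    },
    edge_removal_components = {
      comps <- graph_components(net, drop_edge = con$edge)
      same_partition(comps, con$components)
    },
    edge_present = has_edge(con$edge[1], con$edge[2]),
    edge_absent = !has_edge(con$edge[1], con$edge[2]),
    block_complete = {
      idx <- match(as.integer(con$nodes), net$labels)
      sub <- net$gamma[idx, idx, drop = FALSE]
      all(sub[upper.tri(sub)] > 0)
    },
    stop("unknown constraint kind: ", con$kind, call. = FALSE)
  )
}

#' Check structural constraints against a network
#'
#' @param net An [oscillator_network].
#' @param constraints A list of [structural_constraint] objects.
#' @return A tibble with one row per constraint: `id`, `kind`, `label`,
#'   `pass`. The network is not modified.
#' @export
check_constraints <- function(net, constraints) {
  stopifnot(inherits(net, "oscillator_network"))
  ids <- unlist(lapply(constraints, function(con) {
    c(con$remove, con$edge, con$nodes, unlist(con$components))
  }))
  if (!all(as.integer(ids) %in% net$labels)) {
    stop("constraint references oscillator ids absent from the network",
         call. = FALSE)
  }
  tibble::tibble(
    id = seq_along(constraints),
    kind = vapply(constraints, function(con) con$kind, character(1)),
    label = vapply(constraints, function(con) con$label %||% "", character(1)),
    pass = vapply(constraints, function(con) check_one_constraint(net, con),
                  logical(1))
  )
}

#' The coffee pest / natural-enemy oscillator network
#'
#' Returns the packaged edge list of the coffee agroecosystem study
#' network: 22 consumer-resource links over the four coffee pests (berry
#' borer, leaf miner, green scale, leaf rust), their natural enemies, and
#' enemies of those enemies, together with the list of structural constraints
#' the network must satisfy (cut vertex at the ant-borer oscillator 22,
#' bridge coupling 3-8, the guild blocks, the 8-5 non-coupling, ...).
#'
#' `coffee_fixture()` validates the derived coupling network against the
#' constraints and fails loudly on any violation, so a corrupted fixture can
#' never flow silently into an analysis.
#'
#' @return For `coffee_foodweb()`, a [foodweb]; for `coffee_constraints()`, a
#'   list of [structural_constraint]s; for `coffee_fixture()`, a list with
#'   elements `web`, `network` (the derived coupling), and `constraints`.
#' @export
coffee_foodweb <- function() {
  path <- system.file("extdata", "coffee_foodweb.csv", package = "ecosync",
                      mustWork = TRUE)
  read_foodweb(path)
}

#' @rdname coffee_foodweb
#' @export
coffee_constraints <- function() {
  list(
    structural_constraint("node_removal_components",
      remove = integer(0), components = list(1:22),
      label = "22 oscillators forming one connected network"),
    structural_constraint("node_removal_components",
      remove = 22L, components = list(1:13, 14:21),
      label = "removing the ant-borer oscillator 22 splits 1-13 from 14-21"),
    structural_constraint("edge_removal_components",
      edge = c(3L, 8L), components = list(c(1:4, 14:22), 5:13),
      label = "the 3-8 coupling alone joins {1-4,14-22} to {5-13}"),
    structural_constraint("edge_present", edge = c(3L, 2L),
      label = "spider oscillator 3 coupled to 2"),
    structural_constraint("edge_present", edge = c(3L, 4L),
      label = "spider oscillator 3 coupled to 4"),
    structural_constraint("edge_present", edge = c(3L, 8L),
      label = "spider oscillator 3 coupled to 8 (trophic triplet)"),
    structural_constraint("edge_absent", edge = c(8L, 5L),
      label = "8 and 5 share no species and are uncoupled"),
    structural_constraint("block_complete", nodes = 17:21,
      label = "berry borer enemies 17-21 form a complete block"),
    structural_constraint("block_complete", nodes = 10:13,
      label = "leaf rust antagonists 10-13 form a complete block"),
    structural_constraint("edge_present", edge = c(5L, 6L),
      label = "scale block connectivity 5-6"),
    structural_constraint("edge_present", edge = c(6L, 7L),
      label = "scale block connectivity 6-7"),
    structural_constraint("edge_present", edge = c(6L, 8L),
      label = "scale block connectivity 6-8"),
    structural_constraint("edge_present", edge = c(9L, 7L),
      label = "oscillator 9 couples into the scale block"),
    structural_constraint("edge_present", edge = c(9L, 10L),
      label = "oscillator 9 couples into the rust block")
  )
}

#' @rdname coffee_foodweb
#' @export
coffee_fixture <- function() {
  web <- coffee_foodweb()
  net <- derive_coupling(web)
  report <- check_constraints(net, coffee_constraints())
  if (!all(report$pass)) {
    bad <- report$label[!report$pass]
    stop("coffee fixture failed structural constraint(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  list(web = web, network = net, constraints = coffee_constraints())
}
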
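#' Construct a food web of consumer-resource links
#'
#' A food web here is a collection of numbered consumer->resource links.
#' Each link -- a predator, parasitoid or disease attacking a host -- is the
#' unit that later becomes a phase oscillator; species are only the glue that
#' decides which oscillators are coupled.
#'
#' @param links A data frame with columns `oscillator_id` (unique, contiguous
#'   integers starting at 1), `consumer` and `resource` (species identifiers).
#' @return An object of class `foodweb`: a list with `species` (character
#'   vector) and `links` (a tibble sorted by `oscillator_id`).
#' @examples
#' foodweb(data.frame(oscillator_id = 1:2,
#'                    consumer = c("A", "B"), resource = c("B", "C")))
#' @export
foodweb <- function(links) {
  links <- tibble::as_tibble(links)
  required <- c("oscillator_id", "consumer", "resource")
  missing_cols <- setdiff(required, names(links))
  if (length(missing_cols) > 0) {
    stop("food-web table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  links <- links[required]
  links$oscillator_id <- as.integer(links$oscillator_id)
  links$consumer <- as.character(links$consumer)
  links$resource <- as.character(links$resource)
  if (anyNA(links)) stop("food-web table contains missing values", call. = FALSE)
  if (anyDuplicated(links$oscillator_id)) {
    stop("duplicate oscillator_id in food-web table", call. = FALSE)
  }
  links <- dplyr::arrange(links, .data$oscillator_id)
  if (!identical(links$oscillator_id, seq_len(nrow(links)))) {
    stop("oscillator_id values must be contiguous 1..M", call. = FALSE)
  }
  if (any(links$consumer == links$resource)) {
    bad <- links$oscillator_id[links$consumer == links$resource]
    stop("self-consumption link(s) at oscillator_id ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(species = sort(unique(c(links$consumer, links$resource))),
         links = links),
    class = "foodweb"
  )
}

#' @export
print.foodweb <- function(x, ...) {
  cat("<foodweb> ", nrow(x$links), " links (oscillators), ",
      length(x$species), " species\n", sep = "")
  print(x$links, n = 6)
  invisible(x)
}

#' Read a food web from an edge-list CSV
#'
#' The file must have a header row and the three columns
#' `oscillator_id,consumer,resource`.
#'
#' @param path Path to a CSV file.
#' @return A validated [foodweb] object.
#' @export
read_foodweb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  links <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  foodweb(links)
}

#' Write a food web to an edge-list CSV
#'
#' @param web A [foodweb].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_foodweb <- function(web, path) {
  stopifnot(inherits(web, "foodweb"))
  readr::write_csv(web$links, path)
  invisible(path)
}

#' Construct an oscillator coupling network
#'
#' @param gamma Symmetric numeric matrix of non-negative coupling weights with
#'   zero diagonal.
#' @param labels Integer oscillator ids aligned to the rows of `gamma`
#'   (defaults to `1:n`).
#' @return An object of class `oscillator_network` with elements `n`, `gamma`
#'   and `labels`.
#' @export
oscillator_network <- function(gamma, labels = seq_len(nrow(gamma))) {
  gamma <- as.matrix(gamma)
  n <- nrow(gamma)
  labels <- as.integer(labels)
  stopifnot(ncol(gamma) == n, length(labels) == n, !anyDuplicated(labels))
  if (any(gamma < 0)) stop("coupling weights must be non-negative", call. = FALSE)
  if (any(abs(gamma - t(gamma)) > 1e-12)) {
    stop("coupling matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(gamma) != 0)) stop("coupling matrix must have zero diagonal", call. = FALSE)
  dimnames(gamma) <- list(labels, labels)
  structure(list(n = n, gamma = gamma, labels = labels),
            class = "oscillator_network")
}

#' @export
print.oscillator_network <- function(x, ...) {
  nz <- sum(x$gamma > 0) / 2
  cat("<oscillator_network> ", x$n, " oscillators, ", nz, " couplings",
      if (all(x$gamma %in% c(0, 1))) " (unweighted)" else " (weighted)",
      "\n", sep = "")
  invisible(x)
}

#' Derive oscillator couplings from a food web
#'
#' Two links are coupled whenever they share at least one species endpoint in
#' any role: two consumers attacking the same resource, two resources attacked
#' by the same consumer, or a trophic chain (A eats B, B eats C). This is the
#' line graph of the consumption network with direction ignored for the
#' sharing test.
#'
#' @param web A [foodweb].
#' @return An unweighted (0/1) [oscillator_network] whose rows follow the
#'   web's oscillator ids.
#' @examples
#' w <- foodweb(data.frame(oscillator_id = 1:2,
#'                         consumer = c("A", "B"), resource = c("B", "C")))
#' derive_coupling(w)$gamma  # coupled: the two links form a chain through B
#' @export
derive_coupling <- function(web) {
  stopifnot(inherits(web, "foodweb"))
  n <- nrow(web$links)
  cons <- web$links$consumer
  res <- web$links$resource
  gamma <- matrix(0, n, n)
  # incidence trick: links sharing a species are adjacent in the line graph
  species <- unique(c(cons, res))
  inc <- matrix(0L, n, length(species), dimnames = list(NULL, species))
  inc[cbind(seq_len(n), match(cons, species))] <- 1L
  inc[cbind(seq_len(n), match(res, species))] <- 1L
  shared <- inc %*% t(inc)
  gamma[shared > 0] <- 1
  diag(gamma) <- 0
  oscillator_network(gamma, labels = web$links$oscillator_id)
}

#' Convert an oscillator network to an igraph graph
#'
#' @param net An [oscillator_network].
#' @return An undirected weighted `igraph` graph with vertex names equal to
#'   the oscillator ids.
#' @export
as_oscillator_graph <- function(net) {
  stopifnot(inherits(net, "oscillator_network"))
  g <- igraph::graph_from_adjacency_matrix(net$gamma, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- as.character(net$labels)
  g
}

#' Rescale all couplings of one oscillator
#'
#' Multiplies the row and column of one oscillator by `factor`, leaving every
#' other entry untouched. Used for keystone downweighting experiments (e.g.
#' setting the ant-berry borer oscillator's couplings to a tenth of the rest).
#'
#' @param net An [oscillator_network].
#' @param oscillator_id The oscillator whose couplings are rescaled.
#' @param factor Non-negative multiplier; `0` isolates the oscillator,
#'   `1` is the identity.
#' @return A new [oscillator_network].
#' @export
scale_oscillator_coupling <- function(net, oscillator_id, factor) {
  stopifnot(inherits(net, "oscillator_network"), factor >= 0)
  i <- match(as.integer(oscillator_id), net$labels)
  if (is.na(i)) stop("unknown oscillator_id: ", oscillator_id, call. = FALSE)
  gamma <- net$gamma
  gamma[i, ] <- gamma[i, ] * factor
  gamma[, i] <- gamma[, i] * factor
  oscillator_network(gamma, labels = net$labels)
}

#' Extract the induced subnetwork on a set of oscillators
#'
#' @param net An [oscillator_network].
#' @param ids Oscillator ids to keep.
#' @return The induced [oscillator_network]; labels are preserved.
#' @export
extract_subnetwork <- function(net, ids) {
  stopifnot(inherits(net, "oscillator_network"), length(ids) > 0)
  idx <- match(as.integer(ids), net$labels)
  if (anyNA(idx)) {
    stop("unknown oscillator id(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  oscillator_network(net$gamma[idx, idx, drop = FALSE],
                     labels = net$labels[idx])
}

#' Write / read a coupling matrix as TSV
#'
#' The first row and first column carry oscillator labels; values are
#' non-negative reals (0/1 in the unweighted case). The pair round-trips
#' bit-exactly.
#'
#' @param net An [oscillator_network].
#' @param path File path.
#' @return `write_coupling_matrix()` returns `path` invisibly;
#'   `read_coupling_matrix()` returns an [oscillator_network].
#' @export
write_coupling_matrix <- function(net, path) {
  stopifnot(inherits(net, "oscillator_network"))
  df <- data.frame(oscillator_id = net$labels,
                   format(net$gamma, trim = TRUE, digits = 17),
                   check.names = FALSE)
  names(df) <- c("oscillator_id", net$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coupling_matrix
#' @export
read_coupling_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labels <- as.integer(df$oscillator_id)
  gamma <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(gamma) <- "double"
  oscillator_network(gamma, labels = labels)
}
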
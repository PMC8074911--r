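#' Specification for a synthetic guild-and-bridge food web
#'
#' The generator emulates the statistical structure of the coffee study
#' network: several "pest guilds" (many enemy links converging on one pest,
#' each yielding a complete coupling block), sparse bridge links joining
#' guilds through intraguild predation (trophic triplets), and optional cut
#' links whose removal disconnects the derived oscillator graph (mirroring
#' the keystone ant oscillator).
#'
#' @param n_guilds Number of pest guilds (at least 1).
#' @param enemies_per_guild Length-2 range (min, max) of enemy links per pest.
#' @param n_bridges Number of within-region cross-guild links. The first
#'   bridges deterministically chain consecutive guilds of a region so
#'   regions are internally connected when enough bridges are available;
#'   extras land on random guild pairs.
#' @param n_cut_links Number of links that are the sole connector between two
#'   regions of the web; requires `n_guilds > n_cut_links`.
#' @param seed Integer seed; generation is fully seed-deterministic.
#' @return An object of class `web_spec`.
#' @export
web_spec <- function(n_guilds = 4, enemies_per_guild = c(4, 6),
                     n_bridges = 3, n_cut_links = 1, seed = 0) {
  stopifnot(n_guilds >= 1, n_bridges >= 0, n_cut_links >= 0,
            length(enemies_per_guild) == 2,
            enemies_per_guild[1] >= 1,
            enemies_per_guild[2] >= enemies_per_guild[1])
  if (n_cut_links >= n_guilds) {
    stop("n_cut_links requires at least n_cut_links + 1 guilds", call. = FALSE)
  }
  structure(list(n_guilds = n_guilds,
                 enemies_per_guild = enemies_per_guild,
                 n_bridges = n_bridges, n_cut_links = n_cut_links,
                 seed = seed),
            class = "web_spec")
}

generate_web_impl <- function(spec) {
  n_regions <- spec$n_cut_links + 1
  region_of_guild <- sort(rep_len(seq_len(n_regions), spec$n_guilds))
  # index-based draw: sample(x, ...) misbehaves when the range has one value
  rng <- seq(spec$enemies_per_guild[1], spec$enemies_per_guild[2])
  k_enemies <- rng[sample.int(length(rng), spec$n_guilds, replace = TRUE)]
  links <- list()
  guild_of <- integer(0)
  enemy_species <- vector("list", spec$n_guilds)
  for (g in seq_len(spec$n_guilds)) {
    enemy_species[[g]] <- sprintf("enemy_%d_%d", g, seq_len(k_enemies[g]))
    for (e in enemy_species[[g]]) {
      links[[length(links) + 1]] <- c(e, sprintf("pest_%d", g))
      guild_of <- c(guild_of, g)
    }
  }
  # bridge: an enemy of guild g2 preys on an enemy of guild g1 (a trophic
  # triplet), coupling the two guild blocks through that single link
  add_bridge <- function(g1, g2) {
    resource <- sample(enemy_species[[g1]], 1)
    consumer <- sample(enemy_species[[g2]], 1)
    links[[length(links) + 1]] <<- c(consumer, resource)
    guild_of <<- c(guild_of, g2)
  }
  multi <- split(seq_len(spec$n_guilds), region_of_guild)
  spanning <- list()
  for (guilds in multi) {
    if (length(guilds) >= 2) {
      for (i in seq_len(length(guilds) - 1)) {
        spanning[[length(spanning) + 1]] <- c(guilds[i], guilds[i + 1])
      }
    }
  }
  n_span <- min(length(spanning), spec$n_bridges)
  for (i in seq_len(n_span)) add_bridge(spanning[[i]][1], spanning[[i]][2])
  extra <- spec$n_bridges - n_span
  eligible <- multi[vapply(multi, length, integer(1)) >= 2]
  if (extra > 0 && length(eligible) == 0) {
    stop("bridges requested but no region has two guilds", call. = FALSE)
  }
  for (i in seq_len(extra)) {
    guilds <- eligible[[sample.int(length(eligible), 1)]]
    pair <- sample(guilds, 2)
    add_bridge(pair[1], pair[2])
  }
  # cut links: exactly one connector between consecutive regions
  for (r in seq_len(spec$n_cut_links)) {
    g1 <- max(multi[[r]])
    g2 <- min(multi[[r + 1]])
    add_bridge(g1, g2)
  }
  df <- do.call(rbind, links)
  tibble::tibble(oscillator_id = seq_len(nrow(df)),
                 consumer = df[, 1], resource = df[, 2],
                 guild = guild_of)
}

#' Generate a synthetic food web
#'
#' @param spec A [web_spec].
#' @return A [foodweb] whose `links` follow the spec; the ground-truth guild
#'   labels are retrievable with [ground_truth()].
#' @examples
#' web <- generate_web(web_spec(n_guilds = 2, n_bridges = 0, n_cut_links = 0))
#' @export
generate_web <- function(spec) {
  stopifnot(inherits(spec, "web_spec"))
  tab <- withr::with_seed(spec$seed, generate_web_impl(spec))
  web <- foodweb(tab[c("oscillator_id", "consumer", "resource")])
  attr(web, "guilds") <- tibble::tibble(oscillator_id = tab$oscillator_id,
                                        guild = tab$guild)
  attr(web, "web_spec") <- spec
  web
}

#' Ground-truth guild membership of a generated web
#'
#' Guild links carry their own guild; bridge and cut links carry the guild of
#' their consumer species. The web is checked against a regeneration from
#' `spec` so a spec/web mismatch fails loudly.
#'
#' @param spec The [web_spec] used to generate `web`.
#' @param web The [foodweb] returned by [generate_web()].
#' @return A tibble `oscillator_id, guild`.
#' @export
ground_truth <- function(spec, web) {
  stopifnot(inherits(spec, "web_spec"), inherits(web, "foodweb"))
  regen <- generate_web(spec)
  if (!identical(regen$links, web$links)) {
    stop("web does not match a regeneration from spec", call. = FALSE)
  }
  attr(regen, "guilds")
}

#' Rand index between two labelings
#'
#' Fraction of unordered pairs on which two partitions agree (co-grouped in
#' both or separated in both).
#'
#' @param a,b Label vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  same_a <- outer(a, a, "==")[upper.tri(diag(length(a)))]
  same_b <- outer(b, b, "==")[upper.tri(diag(length(b)))]
  mean(same_a == same_b)
}
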
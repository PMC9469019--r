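#' Migration count matrix from parentage assignments
#'
#' Counts retained parent-offspring pairs by (destination, origin):
#' `counts[i, j]` is the number of offspring sampled in population `i`
#' whose assigned parent is in population `j`. The diagonal holds resident
#' assignments (kept, but excluded when building network edges).
#'
#' @param pairs A tibble of parentage pairs (from [assign_parentage()]).
#' @param populations Population codes of the slice (character vector, a
#'   population table, or a [msat_data]); fixes matrix order and keeps
#'   zero rows/columns for uninvolved populations.
#' @return A square integer matrix of class `migration_counts`
#'   (rows = destination, cols = origin).
#' @export
migration_counts <- function(pairs, populations) {
  if (inherits(populations, "msat_data")) {
    populations <- populations$populations$population
  } else if (is.data.frame(populations)) {
    populations <- populations$population
  }
  bad <- setdiff(unique(c(pairs$offspring_pop, pairs$parent_pop)),
                 populations)
  if (length(bad) > 0) {
    stop("pairs reference unknown population(s): ",
         paste(bad, collapse = ", "))
  }
  m <- matrix(0L, length(populations), length(populations),
              dimnames = list(destination = populations,
                              origin = populations))
  if (nrow(pairs) > 0) {
    tab <- table(factor(pairs$offspring_pop, levels = populations),
                 factor(pairs$parent_pop, levels = populations))
    m[] <- m + as.integer(tab)
  }
  class(m) <- c("migration_counts", class(m))
  m
}

#' Contemporary migration rates from assignment counts
#'
#' Row-wise multinomial maximum-likelihood rates
#' `m[i, j] = n[i, j] / sum_j n[i, j]` (the fraction of assigned offspring
#' in destination `i` whose parent was in `j`), with a Wilson 95% score
#' interval per cell (cell versus rest as a binomial). Rows with zero
#' assignments are flagged undefined (`NA` rates).
#'
#' @param counts A `migration_counts` matrix.
#' @param conf Confidence level (default 0.95).
#' @return A tibble of class `migration_rates`: `destination`, `origin`,
#'   `count`, `n_assigned`, `m`, `ci_low`, `ci_high`.
#' @export
migration_rates <- function(counts, conf = 0.95) {
  m <- unclass(counts)
  labs <- rownames(m)
  row_n <- rowSums(m)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- tidyr::expand_grid(destination = labs, origin = labs)
  out$count <- as.integer(m[cbind(match(out$destination, labs),
                                  match(out$origin, labs))])
  out$n_assigned <- row_n[match(out$destination, labs)]
  out$m <- ifelse(out$n_assigned > 0, out$count / out$n_assigned, NA_real_)
  wil <- wilson_interval(out$count, out$n_assigned, z)
  out$ci_low <- wil$low; out$ci_high <- wil$high
  class(out) <- c("migration_rates", class(out))
  out
}

wilson_interval <- function(x, n, z) {
  phat <- x / n
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Build the directed migration network
#'
#' One directed edge origin -> destination for every off-diagonal
#' assignment count >= 1 (edges are unweighted: presence of contemporary
#' gene flow). Node attributes carry coordinates when supplied; degrees
#' are total directed degrees (in + out).
#'
#' @param counts A `migration_counts` matrix.
#' @param coords Optional data frame with `population`, `latitude`,
#'   `longitude` (or a [msat_data]).
#' @return An igraph object of class `migration_network` with vertex
#'   attributes `latitude`/`longitude` (if given) and edge attribute
#'   `count`.
#' @export
build_network <- function(counts, coords = NULL) {
  m <- unclass(counts)
  labs <- rownames(m)
  off <- m; diag(off) <- 0L
  idx <- which(off >= 1, arr.ind = TRUE)
  # edge direction: origin (parent pop, column) -> destination (row)
  edges <- tibble::tibble(from = labs[idx[, 2]], to = labs[idx[, 1]],
                          count = off[idx])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = tibble::tibble(name = labs))
  if (!is.null(coords)) {
    if (inherits(coords, "msat_data")) coords <- coords$populations
    i <- match(labs, coords$population)
    igraph::V(g)$latitude <- coords$latitude[i]
    igraph::V(g)$longitude <- coords$longitude[i]
  }
  class(g) <- c("migration_network", class(g))
  g
}

as_igraph <- function(x) {
  class(x) <- setdiff(class(x), "migration_network")
  x
}

#' Node degrees of a migration network
#'
#' @param network A `migration_network`.
#' @return A tibble `population`, `in_degree`, `out_degree`, `degree`
#'   (in + out, over directed edges).
#' @export
network_degrees <- function(network) {
  g <- as_igraph(network)
  tibble::tibble(
    population = igraph::V(g)$name,
    in_degree = igraph::degree(g, mode = "in"),
    out_degree = igraph::degree(g, mode = "out"),
    degree = igraph::degree(g, mode = "all"))
}

#' Edge betweenness on the undirected projection
#'
#' Shortest-path edge betweenness (Brandes) on the undirected, unweighted
#' projection of the migration network (reciprocal edges collapse to one).
#' Each unordered node pair contributes once, endpoints included, so an
#' isolated edge a--b has betweenness 1 and either edge of a path a--b--c
#' has betweenness 2.
#'
#' @param network A `migration_network` (>= 1 edge).
#' @return A tibble `from`, `to`, `betweenness` over undirected edges.
#' @export
edge_betweenness_undirected <- function(network) {
  u <- undirected_projection(network)
  if (igraph::ecount(u) == 0) stop("network has no edges")
  eb <- igraph::edge_betweenness(u, directed = FALSE)
  ends <- igraph::as_edgelist(u)
  tibble::tibble(from = ends[, 1], to = ends[, 2], betweenness = eb)
}

undirected_projection <- function(network) {
  igraph::as_undirected(as_igraph(network), mode = "collapse",
                        edge.attr.comb = list(count = "sum", "ignore"))
}

#' Fast-greedy modularity clustering of the migration network
#'
#' Agglomerative greedy maximisation of Newman modularity Q on the
#' undirected projection, by default weighted by shortest-path edge
#' betweenness (computed on the unweighted projection first). Components
#' are handled independently; isolated nodes form singleton clusters; an
#' edgeless graph puts every node in its own cluster with Q = 0.
#'
#' @param network A `migration_network`.
#' @param weights `"betweenness"` (default), `"none"` (unweighted), or a
#'   numeric vector over undirected edges.
#' @return An object of class `migration_clustering`: `membership`
#'   (tibble `population`, `cluster`), `Q`, `n_clusters`, `weighted`,
#'   and the undirected `graph` with its edge `weight`s.
#' @export
cluster_migration <- function(network, weights = "betweenness") {
  u <- undirected_projection(network)
  n <- igraph::vcount(u)
  if (igraph::ecount(u) == 0) {
    memb <- seq_len(n)
    out <- list(membership = tibble::tibble(
      population = igraph::V(u)$name, cluster = memb),
      Q = 0, n_clusters = n, weighted = FALSE, graph = u)
    return(structure(out, class = "migration_clustering"))
  }
  w <- NULL
  weighted <- FALSE
  if (is.numeric(weights)) {
    w <- weights; weighted <- TRUE
  } else if (identical(weights, "betweenness")) {
    w <- igraph::edge_betweenness(u, directed = FALSE)
    weighted <- TRUE
  } else if (!identical(weights, "none")) {
    stop("unknown `weights`")
  }
  if (!is.null(w)) igraph::E(u)$weight <- w
  fit <- igraph::cluster_fast_greedy(u, weights = w)
  # pick the cut along the merge path with maximal recomputed Q (the
  # hierarchy's own argmax misbehaves on tiny graphs); ties go to fewer
  # clusters, i.e. the later merge
  n_comp <- igraph::count_components(u)
  cuts <- seq(n, n_comp)
  best_q <- -Inf; memb <- seq_len(n)
  for (no in cuts) {
    mb <- tryCatch(igraph::cut_at(fit, no = no), error = function(e) NULL)
    if (is.null(mb)) next
    q <- igraph::modularity(u, mb, weights = w)
    if (q > best_q + 1e-12 || abs(q - best_q) <= 1e-12) {
      best_q <- max(q, best_q); memb <- mb
    }
  }
  Q <- igraph::modularity(u, memb, weights = w)
  structure(list(
    membership = tibble::tibble(population = igraph::V(u)$name,
                                cluster = as.integer(memb)),
    Q = Q, n_clusters = max(memb), weighted = weighted, graph = u),
    class = "migration_clustering")
}

#' @export
print.migration_clustering <- function(x, ...) {
  cat("<migration_clustering> ", x$n_clusters, " cluster(s), Q = ",
      round(x$Q, 4), if (x$weighted) " (betweenness-weighted)", "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.migration_clustering <- function(x, ...) x$membership

#' @export
glance.migration_clustering <- function(x, ...) {
  singles <- sum(table(x$membership$cluster) == 1)
  tibble::tibble(n_clusters = x$n_clusters, Q = x$Q,
                 n_nodes = nrow(x$membership), n_singletons = singles,
                 weighted = x$weighted)
}

#' Source/sink classification from directed-degree asymmetry
#'
#' A population is a `sink` when it receives more gene-flow edges than it
#' sends (`in_degree > out_degree`), a `source` when the reverse holds,
#' and `mixed` when equal (including isolated nodes).
#'
#' @param network A `migration_network`.
#' @return A tibble `population`, `in_degree`, `out_degree`, `role`.
#' @export
classify_source_sink <- function(network) {
  d <- network_degrees(network)
  d$role <- dplyr::case_when(
    d$in_degree > d$out_degree ~ "sink",
    d$out_degree > d$in_degree ~ "source",
    TRUE ~ "mixed")
  d
}

#' Persistence of source/sink roles across time slices
#'
#' @param labels_by_slice Named list of tibbles from
#'   [classify_source_sink()], one per time slice.
#' @param strip_time If `TRUE` (default), the trailing digits of
#'   population codes are dropped so the same site is matched across
#'   slices (e.g. `FJ1`/`FJ2` -> `FJ`).
#' @return A tibble `site`, `n_slices`, `roles` (per-slice labels,
#'   "/"-separated), `persistent` (same role in every slice present).
#' @export
source_sink_persistence <- function(labels_by_slice, strip_time = TRUE) {
  all <- purrr::imap_dfr(labels_by_slice, function(d, nm)
    dplyr::mutate(d, slice = nm))
  all$site <- if (strip_time)
    stringr::str_remove(all$population, "[0-9]+$") else all$population
  dplyr::summarise(dplyr::group_by(all, .data$site),
                   n_slices = dplyr::n(),
                   roles = paste(.data$role, collapse = "/"),
                   persistent = dplyr::n_distinct(.data$role) == 1,
                   .groups = "drop")
}

#' Key nodes of a clustered migration network
#'
#' Reports, per cluster and globally, the maximum-degree node(s) (all
#' ties listed) and the bridge nodes (endpoints of edges joining two
#' clusters), combined with source/sink labels.
#'
#' @param network A `migration_network`.
#' @param clustering A `migration_clustering` computed on the same
#'   network.
#' @return A list of class `key_node_report`: `per_cluster` (tibble
#'   `cluster`, `population`, `degree`), `global` (max-degree nodes),
#'   `bridges` (tibble `population`, `clusters_touched`), `roles`.
#' @export
key_nodes <- function(network, clustering) {
  deg <- network_degrees(network)
  memb <- clustering$membership
  if (!setequal(deg$population, memb$population)) {
    stop("clustering does not match the network's node set")
  }
  d <- dplyr::left_join(deg, memb, by = "population")
  with_edges <- dplyr::filter(d, .data$degree > 0)
  per_cluster <- if (nrow(with_edges) == 0) {
    tibble::tibble(cluster = integer(), population = character(),
                   degree = numeric())
  } else {
    dplyr::select(
      dplyr::filter(dplyr::group_by(with_edges, .data$cluster),
                    .data$degree == max(.data$degree)),
      "cluster", "population", "degree") |> dplyr::ungroup()
  }
  global <- if (nrow(with_edges) == 0) with_edges else
    dplyr::filter(with_edges, .data$degree == max(.data$degree))

  u <- undirected_projection(network)
  bridges <- tibble::tibble(population = character(),
                            clusters_touched = integer())
  if (igraph::ecount(u) > 0) {
    ends <- igraph::as_edgelist(u)
    cl <- memb$cluster[match(ends, memb$population)]
    cl <- matrix(cl, ncol = 2)
    inter <- cl[, 1] != cl[, 2]
    if (any(inter)) {
      nodes <- unique(as.vector(ends[inter, , drop = FALSE]))
      touched <- vapply(nodes, function(v) {
        nb <- igraph::neighbors(u, v)$name
        length(unique(memb$cluster[match(c(v, nb), memb$population)]))
      }, integer(1))
      bridges <- tibble::tibble(population = nodes,
                                clusters_touched = touched)
    }
  }
  structure(list(per_cluster = per_cluster,
                 global = dplyr::select(global, "population", "degree"),
                 bridges = bridges,
                 roles = classify_source_sink(network)),
            class = "key_node_report")
}

#' @export
print.key_node_report <- function(x, ...) {
  cat("Key nodes — global max degree: ",
      paste(x$global$population, collapse = ", "), "\n", sep = "")
  if (nrow(x$bridges) > 0) {
    cat("Bridge nodes: ", paste(x$bridges$population, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Geographic summary of migration edges
#'
#' Geodesic length of every directed migration edge, with mean, median,
#' quartiles, maximum and a Student-t 95% confidence interval for the
#' mean (undefined, with a flag, when there is a single edge).
#'
#' @param network A `migration_network` whose vertices carry
#'   `latitude`/`longitude`.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `migration_distance_summary`: `edges` (tibble
#'   `from`, `to`, `distance_km`) and `summary` (one-row tibble).
#' @export
migration_distance_summary <- function(network, conf = 0.95) {
  g <- as_igraph(network)
  lat <- igraph::V(g)$latitude; lon <- igraph::V(g)$longitude
  if (is.null(lat) || anyNA(lat) || is.null(lon) || anyNA(lon)) {
    miss <- igraph::V(g)$name[is.na(lat) | is.na(lon)]
    stop("missing coordinates for node(s): ",
         paste(if (length(miss)) miss else "all", collapse = ", "))
  }
  ends <- igraph::as_edgelist(g)
  i <- match(ends[, 1], igraph::V(g)$name)
  j <- match(ends[, 2], igraph::V(g)$name)
  d <- if (nrow(ends) == 0) numeric(0) else
    geodesic_km(lat[i], lon[i], lat[j], lon[j])
  edges <- tibble::tibble(from = ends[, 1], to = ends[, 2],
                          distance_km = d)
  n <- length(d)
  ci <- c(NA_real_, NA_real_)
  if (n >= 2) {
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) *
      stats::sd(d) / sqrt(n)
    ci <- mean(d) + c(-half, half)
  }
  smry <- tibble::tibble(
    n_edges = n,
    mean_km = if (n) mean(d) else NA_real_,
    median_km = if (n) stats::median(d) else NA_real_,
    q1_km = if (n) unname(stats::quantile(d, 0.25)) else NA_real_,
    q3_km = if (n) unname(stats::quantile(d, 0.75)) else NA_real_,
    max_km = if (n) max(d) else NA_real_,
    ci_low_km = ci[1], ci_high_km = ci[2],
    ci_defined = n >= 2)
  structure(list(edges = edges, summary = smry),
            class = "migration_distance_summary")
}

#' @export
print.migration_distance_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d migration edges, mean %.1f km (95%% CI %.1f-%.1f), max %.1f km\n",
              s$n_edges, s$mean_km, s$ci_low_km, s$ci_high_km, s$max_km))
  invisible(x)
}

#' @export
autoplot.migration_network <- function(object, ...) {
  g <- as_igraph(object)
  ends <- igraph::as_edgelist(g)
  labs <- igraph::V(g)$name
  lat <- igraph::V(g)$latitude; lon <- igraph::V(g)$longitude
  if (is.null(lat)) {
    set.seed(1)
    xy <- igraph::layout_with_fr(g)
    lon <- xy[, 1]; lat <- xy[, 2]
  }
  nodes <- tibble::tibble(population = labs, x = lon, y = lat,
                          degree = igraph::degree(g, mode = "all"))
  seg <- tibble::tibble(x = lon[match(ends[, 1], labs)],
                        y = lat[match(ends[, 1], labs)],
                        xend = lon[match(ends[, 2], labs)],
                        yend = lat[match(ends[, 2], labs)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50") +
    ggplot2::geom_point(data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree)) +
    ggplot2::geom_text(data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$population),
      vjust = -0.8, size = 3) +
    ggplot2::labs(x = "longitude", y = "latitude", size = "degree")
}
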
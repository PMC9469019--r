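# Small in-code fixtures and independent oracles used across test files.

# build a msat_data from a compact list: pops[[code]] = list of individuals,
# each a list of length-2 allele vectors (or NA for missing), one per locus
make_msat <- function(pops, loci = NULL, meta = NULL) {
  n_loci <- length(pops[[1]][[1]])
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(n_loci))
  rows <- list()
  i <- 0
  for (pc in names(pops)) {
    for (ind in seq_along(pops[[pc]])) {
      i <- i + 1
      id <- sprintf("%s_i%02d", pc, ind)
      for (l in seq_len(n_loci)) {
        g <- pops[[pc]][[ind]][[l]]
        if (length(g) == 1 && is.na(g)) g <- c(NA_integer_, NA_integer_)
        rows[[length(rows) + 1]] <- tibble::tibble(
          individual = id, population = pc, locus = loci[l],
          allele_1 = g[1], allele_2 = g[2])
      }
    }
  }
  msat_data(dplyr::bind_rows(rows), meta, loci = loci)
}

# msat_data holding identical copies of a genotype for quick frequency tests
table1_path <- function() {
  system.file("extdata", "table1_sites.csv", package = "kinflow")
}
table2_path <- function() {
  system.file("extdata", "table2_diversity.csv", package = "kinflow")
}

# ---- independent oracles -------------------------------------------------

# exhaustive rarefaction: mean distinct alleles over all g-subsets of the
# gene copies at one locus (counts = per-allele copy numbers)
enum_distinct <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(seq_along(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# exhaustive private-allele expectation for a focal group vs others
enum_private <- function(count_groups, focal, g) {
  pools <- lapply(count_groups, function(ct) rep(seq_along(ct), ct))
  subsets <- lapply(pools, function(pool) utils::combn(seq_along(pool), g))
  # iterate over the cartesian product of subsets of each group
  idx <- lapply(subsets, function(s) seq_len(ncol(s)))
  grid <- expand.grid(idx)
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    drawn <- lapply(seq_along(pools), function(k)
      unique(pools[[k]][subsets[[k]][, grid[r, k]]]))
    priv <- setdiff(drawn[[focal]], unlist(drawn[-focal]))
    tot <- tot + length(priv)
  }
  tot / nrow(grid)
}

# brute-force edge betweenness by BFS path counting over unordered pairs
brute_edge_betweenness <- function(adj) {
  n <- nrow(adj)
  labs <- rownames(adj)
  eb <- matrix(0, n, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_shortest_paths_bfs(adj, s, t)
    if (length(paths) == 0) next
    w <- 1 / length(paths)
    for (p in paths) {
      for (k in seq_len(length(p) - 1)) {
        eb[p[k], p[k + 1]] <- eb[p[k], p[k + 1]] + w
        eb[p[k + 1], p[k]] <- eb[p[k + 1], p[k]] + w
      }
    }
  }
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j] > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        from = labs[i], to = labs[j], betweenness = eb[i, j])
    }
  }
  dplyr::bind_rows(out)
}

all_shortest_paths_bfs <- function(adj, s, t) {
  n <- nrow(adj)
  dist <- rep(Inf, n); dist[s] <- 0
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in which(adj[v, ] > 0)) {
      if (dist[u] == Inf) { dist[u] <- dist[v] + 1; queue <- c(queue, u) }
    }
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  grow <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
    for (u in which(adj[v, ] > 0)) {
      if (dist[u] == dist[v] + 1) grow(c(path, u))
    }
  }
  grow(s)
  paths
}

# exhaustive modularity search over all partitions of <= 10 nodes
best_partition_modularity <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  best <- -Inf
  part <- rep(1L, n)
  # enumerate set partitions via restricted growth strings
  rgs <- rep(1L, n)
  repeat {
    q <- 0
    for (c in unique(rgs)) {
      inside <- which(rgs == c)
      ec <- sum(adj[inside, inside, drop = FALSE]) / 2
      dc <- sum(deg[inside])
      q <- q + ec / m - (dc / (2 * m))^2
    }
    if (q > best) { best <- q; part <- rgs }
    # next restricted growth string
    i <- n
    repeat {
      if (i == 1) return(list(Q = best, partition = part))
      if (rgs[i] <= max(rgs[1:(i - 1)])) break
      i <- i - 1
    }
    rgs[i] <- rgs[i] + 1L
    if (i < n) rgs[(i + 1):n] <- 1L
  }
}

# migration_counts matrix from an edge list (edges = list of c(origin, dest))
counts_from_edges <- function(n, edges, labs = NULL) {
  if (is.null(labs)) labs <- letters[seq_len(n)]
  m <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (e in edges) m[labs[e[2]], labs[e[1]]] <- 1L
  class(m) <- c("migration_counts", class(m))
  m
}

adj_from_counts <- function(counts) {
  m <- unclass(counts); diag(m) <- 0
  a <- (m + t(m)) > 0
  storage.mode(a) <- "double"
  a
}

setequal_multiset <- function(x, y) identical(sort(x), sort(y))
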
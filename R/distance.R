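#' Nei's standard genetic distance between populations
#'
#' Nei (1972) standard distance from allele frequencies. For each pair the
#' quantities Jx = sum(p^2), Jy = sum(q^2) and Jxy = sum(p q) are averaged
#' arithmetically across loci typed in both populations, then
#' I = Jxy / sqrt(Jx Jy) and D = -log(I). Populations sharing no alleles
#' at any locus get `Inf` (flagged, not fatal); a pair with zero shared
#' typed loci is an error.
#'
#' @param x A [msat_data] object with >= 2 populations.
#' @return A symmetric labeled matrix of class `c("genetic_dist","msat_dist")`
#'   with a zero diagonal; attribute `kind = "genetic"`. Infinite pairs are
#'   listed in attribute `infinite_pairs`.
#' @export
nei_distance_matrix <- function(x) {
  stopifnot(inherits(x, "msat_data"))
  pops <- x$populations$population
  if (length(pops) < 2) stop("need >= 2 populations")
  freqs <- allele_frequencies(x, by = "population")
  fl <- lapply(pops, function(p) freq_list(freqs, group = p))
  names(fl) <- pops

  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  inf_pairs <- list()
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      shared <- intersect(names(fl[[i]]), names(fl[[j]]))
      if (length(shared) == 0) {
        stop("populations ", pops[i], " and ", pops[j],
             " share no typed loci")
      }
      jx <- jy <- jxy <- numeric(length(shared))
      for (k in seq_along(shared)) {
        p <- fl[[i]][[shared[k]]]
        q <- fl[[j]][[shared[k]]]
        alleles <- union(names(p), names(q))
        pv <- ifelse(alleles %in% names(p), p[alleles], 0)
        qv <- ifelse(alleles %in% names(q), q[alleles], 0)
        jx[k] <- sum(pv^2); jy[k] <- sum(qv^2); jxy[k] <- sum(pv * qv)
      }
      I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
      d <- if (I <= 0) Inf else -log(I)
      if (!is.finite(d)) inf_pairs <- c(inf_pairs, list(c(pops[i], pops[j])))
      # clamp tiny negative rounding of identical profiles
      D[i, j] <- D[j, i] <- max(d, 0)
    }
  }
  attr(D, "kind") <- "genetic"
  attr(D, "infinite_pairs") <- inf_pairs
  class(D) <- c("genetic_dist", "msat_dist", class(D))
  D
}

#' Geodesic distance in kilometres
#'
#' Great-circle (haversine) distance on a sphere of mean Earth radius
#' 6371.0088 km. Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Geographic distance matrix between population sites
#'
#' @param populations A data frame with `population`, `latitude`,
#'   `longitude` (e.g. the population table of a [msat_data]), or a
#'   [msat_data] object.
#' @return A symmetric labeled matrix (km) of class
#'   `c("geographic_dist","msat_dist")`.
#' @export
geographic_distance_matrix <- function(populations) {
  if (inherits(populations, "msat_data")) populations <- populations$populations
  populations <- tibble::as_tibble(populations)
  if (anyNA(populations$latitude) || anyNA(populations$longitude)) {
    stop("missing coordinates for: ", paste(
      populations$population[is.na(populations$latitude) |
                               is.na(populations$longitude)], collapse = ", "))
  }
  n <- nrow(populations)
  labs <- populations$population
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    d <- geodesic_km(populations$latitude[i], populations$longitude[i],
                     populations$latitude[js], populations$longitude[js])
    D[i, js] <- d; D[js, i] <- d
  }
  attr(D, "kind") <- "geographic"
  class(D) <- c("geographic_dist", "msat_dist", class(D))
  D
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of -d^2/2 followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues are reported
#' but excluded from the percent-variance breakdown.
#'
#' @param dist A symmetric labeled distance matrix (finite entries).
#' @param n_axes Number of axes to return (default `min(n - 1, 3)`).
#' @return An object of class `msat_pcoa`: list with `coordinates`
#'   (tibble: label + Axis columns), `eigenvalues`, `percent_variance`.
#' @export
pcoa_ordination <- function(dist, n_axes = NULL) {
  m <- unclass(dist)
  attr(m, "kind") <- NULL; attr(m, "infinite_pairs") <- NULL
  if (any(!is.finite(m))) {
    stop("infinite or missing distances; drop or cap the offending pairs ",
         "before ordination")
  }
  n <- nrow(m)
  if (is.null(n_axes)) n_axes <- min(n - 1, 3)
  if (n_axes > n - 1) stop("n_axes must be <= n - 1")
  fit <- stats::cmdscale(m, k = n_axes, eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-9 * max(abs(eig))]
  pct <- 100 * pos / sum(pos)
  coords <- fit$points
  labs <- rownames(m)
  coord_tbl <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(coord_tbl) <- paste0("Axis", seq_len(ncol(coords)))
  coord_tbl <- dplyr::bind_cols(tibble::tibble(label = labs), coord_tbl)
  structure(list(coordinates = coord_tbl, eigenvalues = eig,
                 percent_variance = pct, n_axes = n_axes),
            class = "msat_pcoa")
}

#' @export
print.msat_pcoa <- function(x, ...) {
  cat("<msat_pcoa> ", nrow(x$coordinates), " points, ", x$n_axes, " axes; ",
      "axis 1-2 variance: ",
      paste0(round(x$percent_variance[seq_len(min(2,
        length(x$percent_variance)))], 1), "%", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.msat_pcoa <- function(x, ...) x$coordinates

#' @export
glance.msat_pcoa <- function(x, ...) {
  tibble::tibble(n = nrow(x$coordinates),
                 n_positive_axes = length(x$percent_variance),
                 pct_axis1 = x$percent_variance[1],
                 pct_axis2 = ifelse(length(x$percent_variance) > 1,
                                    x$percent_variance[2], NA_real_))
}

#' @export
autoplot.msat_pcoa <- function(object, ...) {
  pv <- object$percent_variance
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                               label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", pv[1]),
                  y = sprintf("Axis 2 (%.1f%%)", pv[2]))
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and a
#' geographic distance matrix, with a two-sided Mantel permutation p-value:
#' rows and columns of one matrix are permuted jointly `n_perm` times and
#' p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1). Infinite genetic
#' distances are excluded pairwise (with a message).
#'
#' @param genetic,geographic Symmetric labeled distance matrices with
#'   identical labels in identical order.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Integer seed (required: the test is permutation-based).
#' @return An object of class `ibd_test` with fields `r`, `p`, `n_pairs`,
#'   `n_perm`, `seed`, `n_excluded`.
#' @export
ibd_test <- function(genetic, geographic, n_perm = 9999, seed) {
  if (missing(seed)) stop("a seed is required for the permutation test")
  stopifnot(n_perm >= 99)
  A <- unclass(genetic); B <- unclass(geographic)
  if (!identical(rownames(A), rownames(B))) {
    stop("distance matrices must share labels in the same order")
  }
  n <- nrow(A)
  lower <- lower.tri(A)
  finite <- is.finite(A) | !lower
  n_excluded <- sum(!finite[lower])
  if (n_excluded > 0) {
    message("ibd_test: excluded ", n_excluded, " pair(s) with infinite ",
            "genetic distance")
  }
  use <- lower & is.finite(A)
  r_obs <- stats::cor(A[use], B[use])

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  perm_r <- withr_seed({
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      Ap <- A[idx, idx]
      usep <- lower & is.finite(Ap)
      stats::cor(Ap[usep], B[usep])
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_r) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_pairs = sum(use), n_perm = n_perm,
                 seed = seed, n_excluded = n_excluded),
            class = "ibd_test")
}

#' @export
print.ibd_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d pairs, %d permutations)\n",
              x$r, x$p, x$n_pairs, x$n_perm))
  invisible(x)
}

#' @export
tidy.ibd_test <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, method = "Mantel permutation")
}

#' @export
glance.ibd_test <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p, n_pairs = x$n_pairs,
                 n_perm = x$n_perm, n_excluded = x$n_excluded, seed = x$seed)
}

#' Long-format view of a distance matrix
#'
#' @param x A labeled distance matrix (`msat_dist`).
#' @param ... Unused.
#' @return A tibble `from`, `to`, `distance` over unordered pairs.
#' @export
tidy.msat_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(from = rownames(m)[idx[, 2]], to = rownames(m)[idx[, 1]],
                 distance = m[idx])
}
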
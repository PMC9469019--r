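#' Genotyping error model
#'
#' The class-II error model used throughout kinship inference: each
#' observed allele is, independently and with probability `e`, a
#' replacement drawn from the locus's population-wide allele frequency
#' distribution rather than the true transmitted allele. Allelic dropout
#' is not modelled.
#'
#' @param e Per-allele mistyping probability, `0 <= e < 0.5`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(e = 1e-4) {
  stopifnot(is.numeric(e), length(e) == 1, e >= 0, e < 0.5)
  structure(list(e = e), class = "error_model")
}

as_error <- function(error) {
  if (inherits(error, "error_model")) error$e else error_model(error)$e
}

# Per-locus likelihood machinery.
#
# With per-allele error e and background frequencies p, the probability
# that an observed allele is x given true allele t is
#   f(x | t) = (1 - e) [x == t] + e p_x,
# and the marginal of an observed allele drawn from the gene pool is p_x
# (the error redraws from the same pool). For a candidate parent with
# OBSERVED genotype G, let M(x | G) be the probability that the allele the
# true parent transmits is OBSERVED as x, integrating over the parent's
# true genotype (HWE prior x observation likelihood) and the error on the
# offspring side. Then
#   P(offspring observed {x,y} | parent observed G) =
#       M(x|G) p_y + M(y|G) p_x              (x != y)
#       M(x|G) p_x                           (x == y)
# and the unconditional probability is the HWE probability of the observed
# genotype (2 p_x p_y or p_x^2), so the single-locus likelihood ratio is
#   LR = (M(x|G)/p_x + M(y|G)/p_y) / 2       (x != y)
#   LR =  M(x|G)/p_x                         (x == y).
#
# locus_engine() precomputes, for one locus, the matrix M over all
# unordered observed genotypes.
locus_engine <- function(p, e) {
  k <- length(p)
  alleles <- names(p)
  p <- as.numeric(p)
  # F[x, t] = P(observe x | true t)
  F <- (1 - e) * diag(k) + e * matrix(p, k, k)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  A1 <- idx[, 1]; A2 <- idx[, 2]            # genotype g = {A1[g], A2[g]}
  G <- length(A1)
  hwe <- p[A1] * p[A2] * ifelse(A1 == A2, 1, 2)
  # P(observe genotype o | true genotype t), o and t unordered
  t1 <- F[A1, A1, drop = FALSE] * F[A2, A2, drop = FALSE]
  t2 <- F[A2, A1, drop = FALSE] * F[A1, A2, drop = FALSE]
  L <- (t1 + t2) / (1 + outer(A1 == A2, rep(TRUE, G)))
  # posterior over true genotype given observed (rows = observed)
  post <- L * rep(hwe, each = G)
  post <- post / rowSums(post)
  # m[t, x] = P(transmitted allele observed as x | true genotype t)
  m_true <- t(0.5 * (F[, A1, drop = FALSE] + F[, A2, drop = FALSE]))
  M <- post %*% m_true                       # G x k, rows sum to 1
  geno_key <- paste(alleles[A1], alleles[A2], sep = "/")
  list(alleles = alleles, p = p, A1 = A1, A2 = A2, M = M, hwe = hwe,
       geno_key = geno_key)
}

geno_index <- function(engine, a1, a2) {
  i <- match(as.character(pmin(a1, a2)), engine$alleles)
  j <- match(as.character(pmax(a1, a2)), engine$alleles)
  out <- match(paste(engine$alleles[i], engine$alleles[j], sep = "/"),
               engine$geno_key)
  out
}

#' Offspring genotype transition probability
#'
#' Probability of the offspring's observed single-locus genotype given
#' that one parent is the candidate (with its observed genotype) and the
#' other parent is an unknown random mate from the gene pool, integrating
#' the per-allele genotyping error model over both individuals' true
#' genotypes. With `e = 0` this reduces to Mendelian transmission times a
#' random allele draw.
#'
#' @param offspring,parent Length-2 vectors of observed allele lengths.
#' @param freqs Named numeric vector of background allele frequencies at
#'   the locus (must sum to 1).
#' @param error An [error_model] or a numeric error rate.
#' @return A probability.
#' @export
transition_prob <- function(offspring, parent, freqs, error = 0) {
  e <- as_error(error)
  stopifnot(abs(sum(freqs) - 1) < 1e-9, length(offspring) == 2,
            length(parent) == 2)
  eng <- locus_engine(freqs, e)
  gp <- geno_index(eng, parent[1], parent[2])
  xi <- match(as.character(offspring[1]), eng$alleles)
  yi <- match(as.character(offspring[2]), eng$alleles)
  if (anyNA(c(gp, xi, yi))) stop("genotype contains an allele absent from ",
                                 "`freqs`")
  Mrow <- eng$M[gp, ]
  if (xi == yi) Mrow[xi] * eng$p[xi]
  else Mrow[xi] * eng$p[yi] + Mrow[yi] * eng$p[xi]
}

#' Parent-offspring LOD score for one candidate pair
#'
#' Multi-locus log10 likelihood ratio that the candidate is a parent of
#' the offspring versus an unrelated member of the gene pool, summed over
#' loci typed in both individuals. Background frequencies should be pooled
#' over the whole time slice.
#'
#' @param offspring,candidate Individual ids present in `slice`.
#' @param slice A [msat_data] for one time slice.
#' @param error An [error_model] or numeric rate.
#' @param freqs Optional precomputed frequency table
#'   (`allele_frequencies(slice, by = "total")`).
#' @param min_shared_loci Minimum loci typed in both (default 10); fewer
#'   returns a zero-row tibble with a message.
#' @return A one-row tibble: `offspring`, `offspring_pop`, `parent`,
#'   `parent_pop`, `lod`, `n_loci_compared`, `n_mismatch` (loci that would
#'   be Mendelian exclusions at `e = 0`).
#' @export
po_lod <- function(offspring, candidate, slice, error = 1e-4, freqs = NULL,
                   min_shared_loci = 10) {
  lods <- lod_matrix(slice, error, freqs = freqs)
  i <- match(candidate, lods$ids); j <- match(offspring, lods$ids)
  if (anyNA(c(i, j))) stop("unknown individual id")
  if (lods$n_shared[i, j] < min_shared_loci) {
    message("pair skipped: only ", lods$n_shared[i, j], " shared typed loci")
    return(parentage_tibble()[0, ])
  }
  tibble::tibble(offspring = offspring, offspring_pop = lods$pop[j],
                 parent = candidate, parent_pop = lods$pop[i],
                 lod = lods$lod[i, j],
                 n_loci_compared = lods$n_shared[i, j],
                 n_mismatch = lods$n_mismatch[i, j])
}

parentage_tibble <- function() {
  tibble::tibble(offspring = character(), offspring_pop = character(),
                 parent = character(), parent_pop = character(),
                 lod = numeric(), n_loci_compared = integer(),
                 n_mismatch = integer())
}

# Full pairwise LOD machinery for a slice: returns ids, pops and n x n
# matrices lod (rows = candidate parent, cols = offspring), n_shared,
# n_mismatch.
lod_matrix <- function(slice, error = 1e-4, freqs = NULL) {
  e <- as_error(error)
  if (is.null(freqs)) freqs <- allele_frequencies(slice, by = "total")
  fl <- freq_list(freqs)
  wide <- genotype_wide(slice)
  ids <- wide$Ind; pop <- wide$Pop
  n <- length(ids)
  loci <- slice$loci
  lod <- matrix(0, n, n)
  n_shared <- matrix(0L, n, n)
  n_mismatch <- matrix(0L, n, n)
  for (li in seq_along(loci)) {
    p <- fl[[loci[li]]]
    if (is.null(p) || length(p) == 0) next
    eng <- locus_engine(p, e)
    a1 <- wide[[2 + 2 * li - 1]]; a2 <- wide[[2 + 2 * li]]
    typed <- !is.na(a1)
    g <- rep(NA_integer_, n)
    g[typed] <- geno_index(eng, a1[typed], a2[typed])
    xi <- match(as.character(a1), eng$alleles)
    yi <- match(as.character(a2), eng$alleles)
    # Mdiv[i, x] = M(x | parent i) / p_x ; LR[i, j] = mean over offspring
    # j's two alleles of Mdiv (collapses correctly for homozygotes)
    Mdiv <- eng$M[g, , drop = FALSE] / rep(eng$p, each = n)
    LR <- 0.5 * (Mdiv[, xi, drop = FALSE] + Mdiv[, yi, drop = FALSE])
    both <- outer(typed, typed, "&")
    contrib <- matrix(0, n, n)
    contrib[both] <- log10(LR[both])
    lod <- lod + contrib
    n_shared <- n_shared + both
    # Mendelian exclusion at e = 0: no shared observed allele
    share <- outer(a1, a1, "==") | outer(a1, a2, "==") |
      outer(a2, a1, "==") | outer(a2, a2, "==")
    excl <- both & !share
    n_mismatch <- n_mismatch + excl
  }
  list(ids = ids, pop = pop, lod = lod, n_shared = n_shared,
       n_mismatch = n_mismatch)
}

#' Monte-Carlo LOD acceptance threshold
#'
#' Simulates unrelated offspring-candidate configurations (independent
#' multilocus genotypes drawn from the background frequencies, passed
#' through the error model), scores each with the parent-offspring LOD,
#' and returns the requested upper quantile of the null distribution.
#'
#' With `n_candidates = 1` the null is the single unrelated pair, so a
#' score at or above the threshold has probability `1 - quantile` for one
#' arbitrary pair. In an assignment scan every offspring is compared
#' against many candidates and the relevant null is the *best* LOD among
#' `n_candidates` unrelated genotypes; setting `n_candidates` to the scan
#' size calibrates the threshold against that maximum (the convention of
#' simulation-calibrated parentage software), keeping the per-offspring
#' false-assignment rate at `1 - quantile` regardless of sample size.
#'
#' @param freqs Frequency table from [allele_frequencies()] (single group)
#'   or a named list `locus -> named frequency vector`.
#' @param error An [error_model] or numeric rate.
#' @param n_sim Number of simulated null trials (>= 1000).
#' @param quantile Upper quantile retained (default 0.999).
#' @param seed Integer seed (required).
#' @param n_candidates Unrelated candidates per trial whose maximum LOD
#'   forms the null (default 1: a single pair).
#' @return An object of class `lod_threshold`: `threshold`, `e`,
#'   `quantile`, `n_sim`, `n_candidates`, `seed`, and the simulated null
#'   `lods`.
#' @export
lod_threshold <- function(freqs, error = 1e-4, n_sim = 10000,
                          quantile = 0.999, seed, n_candidates = 1) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_sim >= 1000, quantile > 0, quantile < 1, n_candidates >= 1)
  e <- as_error(error)
  fl <- if (is.data.frame(freqs)) freq_list(freqs) else freqs
  fl <- fl[lengths(fl) > 0]
  if (all(lengths(fl) == 1)) {
    warning("all loci monomorphic: threshold uninformative")
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nc <- as.integer(n_candidates)
  npair <- n_sim * nc
  lods <- matrix(0, n_sim, nc)
  for (l in seq_along(fl)) {
    p <- fl[[l]]
    eng <- locus_engine(p, e)
    k <- length(p)
    draw <- function(m) matrix(sample.int(k, 2 * m, replace = TRUE,
                                          prob = eng$p), ncol = 2)
    # true allele indices from HWE, then per-allele error
    corrupt <- function(g) {
      flip <- matrix(stats::runif(length(g)) < e, ncol = 2)
      g[flip] <- sample.int(k, sum(flip), replace = TRUE, prob = eng$p)
      g
    }
    gp <- corrupt(draw(npair))             # candidates, one per pair
    go <- corrupt(draw(n_sim))             # one offspring per trial
    key <- paste(eng$A1, eng$A2)
    gidx <- match(paste(pmin(gp[, 1], gp[, 2]), pmax(gp[, 1], gp[, 2])), key)
    xi <- rep(go[, 1], times = nc); yi <- rep(go[, 2], times = nc)
    Minv <- eng$M / rep(eng$p, each = nrow(eng$M))
    LR <- 0.5 * (Minv[cbind(gidx, xi)] + Minv[cbind(gidx, yi)])
    lods <- lods + log10(LR)
  }
  best <- if (nc == 1) as.vector(lods) else
    apply(lods, 1, max)
  structure(list(threshold = unname(stats::quantile(best, quantile)),
                 e = e, quantile = quantile, n_sim = n_sim,
                 n_candidates = nc, seed = seed, lods = best),
            class = "lod_threshold")
}

#' @export
print.lod_threshold <- function(x, ...) {
  cat(sprintf("LOD threshold %.3f (quantile %.4g of %d simulated unrelated pairs, e = %g)\n",
              x$threshold, x$quantile, x$n_sim, x$e))
  invisible(x)
}

#' Assign a single best parent to every offspring in a time slice
#'
#' Every individual in the slice is evaluated as an offspring against every
#' other individual (any population, self excluded) as a candidate single
#' parent; the best-LOD candidate is retained when its LOD reaches the
#' Monte-Carlo threshold. Sex is ignored (one parent per offspring) and an
#' individual may be the best parent of many offspring. LOD ties are
#' broken toward the lexicographically smaller candidate id (with a
#' message). Background frequencies are pooled over the slice.
#'
#' @param slice A [msat_data] for one time slice (apply
#'   [filter_min_size()] first).
#' @param error An [error_model] or numeric rate (default 1e-4).
#' @param threshold A [lod_threshold], or `NULL` to compute one from the
#'   slice's pooled frequencies (using `seed`).
#' @param min_shared_loci Minimum loci typed in both members of a pair.
#' @param quantile,n_sim Passed to [lod_threshold()] when `threshold` is
#'   `NULL`.
#' @param seed Integer seed for the threshold simulation.
#' @return A tibble of retained pairs (class `parentage_pairs`):
#'   `offspring`, `offspring_pop`, `parent`, `parent_pop`, `lod`,
#'   `n_loci_compared`, `n_mismatch`. The threshold used is in attribute
#'   `threshold`.
#' @export
assign_parentage <- function(slice, error = 1e-4, threshold = NULL,
                             min_shared_loci = 10, quantile = 0.999,
                             n_sim = 10000, seed = NULL) {
  stopifnot(inherits(slice, "msat_data"))
  n_all <- n_individuals(slice)
  if (n_all == 0) stop("empty slice")
  freqs <- allele_frequencies(slice, by = "total")
  if (is.null(threshold)) {
    if (is.null(seed)) stop("supply `threshold` or `seed`")
    # null = best LOD among as many unrelated candidates as the scan
    # evaluates, so the per-offspring false-assignment rate is 1 - quantile
    threshold <- lod_threshold(freqs, error, n_sim = n_sim,
                               quantile = quantile, seed = seed,
                               n_candidates = max(n_all - 1L, 1L))
  }
  lods <- lod_matrix(slice, error, freqs = freqs)
  n <- length(lods$ids)
  L <- lods$lod
  diag(L) <- -Inf                       # self excluded
  L[lods$n_shared < min_shared_loci] <- -Inf

  # candidate order = lexicographic id order so which.max breaks ties
  # toward the smaller id
  ord <- order(lods$ids)
  rows <- purrr::map_dfr(seq_len(n), function(j) {
    col <- L[ord, j]
    if (all(!is.finite(col))) return(NULL)
    best <- which.max(col)
    if (col[best] < threshold$threshold) return(NULL)
    if (sum(col == col[best]) > 1) {
      message("assign_parentage: LOD tie for offspring ", lods$ids[j],
              "; kept ", lods$ids[ord[best]])
    }
    i <- ord[best]
    tibble::tibble(offspring = lods$ids[j], offspring_pop = lods$pop[j],
                   parent = lods$ids[i], parent_pop = lods$pop[i],
                   lod = L[ord, j][best],
                   n_loci_compared = lods$n_shared[i, j],
                   n_mismatch = lods$n_mismatch[i, j])
  })
  if (nrow(rows) == 0) rows <- parentage_tibble()
  attr(rows, "threshold") <- threshold
  class(rows) <- c("parentage_pairs", class(rows))
  rows
}

#' Concordance of parentage assignment across error rates
#'
#' Runs [assign_parentage()] under each assumed error rate and compares
#' the retained pair sets: pairwise Jaccard overlap, and the correlation
#' of per-population-pair counts. Markers are deemed informative when all
#' Jaccard overlaps reach `bar` (assignments essentially unchanged by the
#' assumed rate).
#'
#' @param slice A [msat_data] for one time slice.
#' @param rates Numeric vector of error rates (length >= 2); default the
#'   conventional grid 1e-4, 1e-3, 1e-2, 5e-2.
#' @param bar Jaccard bar for the "informative" verdict (default 0.8).
#' @param seed Seed for the threshold simulations (shared across rates).
#' @param ... Passed to [assign_parentage()].
#' @return A list of class `robustness_report`: `jaccard` (matrix),
#'   `count_correlation` (matrix), `informative` (flag), `assignments`
#'   (list of pair tibbles).
#' @export
error_rate_robustness <- function(slice, rates = c(1e-4, 1e-3, 1e-2, 5e-2),
                                  bar = 0.8, seed = 1, ...) {
  if (length(rates) < 2) stop("need at least 2 error rates")
  runs <- lapply(rates, function(e)
    assign_parentage(slice, error = e, seed = seed, ...))
  names(runs) <- paste0("e", rates)
  keys <- lapply(runs, function(d) paste(d$offspring, d$parent))
  k <- length(rates)
  jac <- matrix(1, k, k, dimnames = list(names(runs), names(runs)))
  ccor <- jac
  pair_counts <- lapply(runs, function(d)
    dplyr::count(d, .data$offspring_pop, .data$parent_pop))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    u <- union(keys[[a]], keys[[b]])
    jac[a, b] <- jac[b, a] <-
      if (length(u) == 0) 1 else
        length(intersect(keys[[a]], keys[[b]])) / length(u)
    merged <- dplyr::full_join(pair_counts[[a]], pair_counts[[b]],
                               by = c("offspring_pop", "parent_pop"))
    merged[is.na(merged)] <- 0
    ccor[a, b] <- ccor[b, a] <-
      if (nrow(merged) < 2) NA_real_ else
        suppressWarnings(stats::cor(merged$n.x, merged$n.y))
  }
  structure(list(jaccard = jac, count_correlation = ccor,
                 informative = all(jac >= bar), rates = rates,
                 assignments = runs),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Error-rate robustness: markers ",
      if (x$informative) "informative" else "NOT informative",
      " (min Jaccard ", round(min(x$jaccard), 3), ")\n", sep = "")
  print(round(x$jaccard, 3))
  invisible(x)
}
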
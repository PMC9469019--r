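#' Per-population diversity statistics
#'
#' For every population and locus with data, computes the observed allele
#' count (Na), effective allele number (Ne = 1/sum(p^2)), Shannon index
#' (I = -sum(p log p)), observed heterozygosity (Ho, heterozygote fraction
#' among non-missing individuals) and expected heterozygosity
#' (He = 1 - sum(p^2), the plug-in GenAlEx estimator), then averages over
#' loci with equal weight. Loci with no data in a population are excluded
#' from that population's mean. Optionally adds rarefied allelic richness
#' (Ar) at a standard number of gene copies.
#'
#' @param x A [msat_data] object.
#' @param ar_g Gene copies at which to rarefy allelic richness per
#'   population, or `NULL` (default) to skip the Ar column. Loci with fewer
#'   than `ar_g` copies in a population are skipped for that population.
#' @param unbiased If `TRUE`, multiply He by 2N/(2N-1) (small-sample
#'   correction); default `FALSE`, matching the plug-in convention.
#' @return A tibble of class `diversity_tbl`, one row per population with
#'   columns `population`, `n`, `n_loci`, `Na`, `Ne`, `I`, `Ho`, `He`
#'   (and `Ar` when `ar_g` is given).
#' @export
diversity_table <- function(x, ar_g = NULL, unbiased = FALSE) {
  stopifnot(inherits(x, "msat_data"))
  freqs <- allele_frequencies(x, by = "population")

  per_locus <- dplyr::summarise(
    dplyr::group_by(freqs, .data$group, .data$locus),
    Na = dplyr::n(),
    Ne = 1 / sum(.data$freq^2),
    I = -sum(.data$freq * log(.data$freq)),
    He = 1 - sum(.data$freq^2),
    copies = .data$copies_sampled[1],
    .groups = "drop")
  if (unbiased) {
    per_locus$He <- per_locus$He * per_locus$copies / (per_locus$copies - 1)
  }

  gt <- dplyr::filter(x$genotypes, !is.na(.data$allele_1))
  ho <- dplyr::summarise(
    dplyr::group_by(gt, group = .data$population, .data$locus),
    Ho = mean(.data$allele_1 != .data$allele_2), .groups = "drop")
  per_locus <- dplyr::left_join(per_locus, ho, by = c("group", "locus"))

  if (!is.null(ar_g)) {
    counts <- split(freqs, list(freqs$group, freqs$locus), drop = TRUE)
    per_locus$Ar <- purrr::map2_dbl(per_locus$group, per_locus$locus,
      function(g, l) {
        d <- counts[[paste(g, l, sep = ".")]]
        if (sum(d$count) < ar_g) return(NA_real_)
        expected_distinct(d$count, ar_g)
      })
  }

  typed <- dplyr::count(dplyr::distinct(freqs, .data$group, .data$locus),
                        .data$group, name = "n_loci")
  zero <- setdiff(x$populations$population, typed$group)
  if (length(zero) > 0) {
    stop("population(s) with zero typed loci: ", paste(zero, collapse = ", "))
  }
  skipped <- attr(allele_frequencies(x), "empty_cells")
  if (nrow(skipped) > 0) {
    message("diversity_table: ", nrow(skipped),
            " empty (population, locus) cell(s) excluded from means")
  }

  out <- dplyr::summarise(
    dplyr::group_by(per_locus, population = .data$group),
    n_loci = dplyr::n(),
    dplyr::across(dplyr::any_of(c("Na", "Ne", "I", "Ho", "He", "Ar")),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  out <- dplyr::left_join(
    dplyr::select(x$populations, "population", "n"), out, by = "population")
  class(out) <- c("diversity_tbl", class(out))
  out
}

#' Group mean rows of a diversity table
#'
#' Unweighted arithmetic mean of each metric across the supplied rows
#' (typically the populations of one sampling time). Values are kept at
#' full precision; round only when reporting.
#'
#' @param rows A data frame of per-population diversity rows (e.g. from
#'   [diversity_table()]), containing some of `Na`, `Ne`, `I`, `Ho`, `He`,
#'   `Ar`.
#' @param by Optional column name to group by (e.g. `"time_code"`); when
#'   `NULL` a single mean row is returned.
#' @return A tibble of mean rows.
#' @export
group_means <- function(rows, by = NULL) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) stop("no rows to average")
  metrics <- intersect(c("Na", "Ne", "I", "Ho", "He", "Ar"), names(rows))
  if (length(metrics) == 0) stop("no diversity metric columns found")
  if (is.null(by)) {
    dplyr::summarise(rows, n_populations = dplyr::n(),
                     dplyr::across(dplyr::all_of(metrics), mean))
  } else {
    dplyr::summarise(dplyr::group_by(rows, .data[[by]]),
                     n_populations = dplyr::n(),
                     dplyr::across(dplyr::all_of(metrics), mean),
                     .groups = "drop")
  }
}

# P(allele with n_a of N copies absent from a subsample of g copies),
# log-space hypergeometric tail: C(N - n_a, g) / C(N, g)
absent_prob <- function(n_a, N, g) {
  out <- numeric(length(n_a))
  ok <- (N - n_a) >= g
  out[ok] <- exp(lchoose(N - n_a[ok], g) - lchoose(N, g))
  out
}

# expected distinct alleles in a subsample of g copies at one locus
expected_distinct <- function(counts, g) {
  N <- sum(counts)
  if (g > N) return(NA_real_)
  sum(1 - absent_prob(counts, N, g))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles per locus in a standardized
#' subsample of `g` gene copies, averaged over loci (the rarefaction
#' estimator of allelic richness). Loci whose total copy count is below `g`
#' are unavailable at that `g` and are dropped from the average.
#'
#' @param counts Allele copy counts: either a frequency table as returned
#'   by [allele_frequencies()] restricted to one group, or a named list
#'   `locus -> integer copy counts`.
#' @param g Subsample size in gene copies (>= 2).
#' @return A tibble with one row per `g`: `g`, `richness` (mean expected
#'   distinct alleles per locus), `n_loci` available at that `g`.
#' @export
rarefied_richness <- function(counts, g) {
  stopifnot(all(g >= 2))
  cl <- as_count_list(counts)
  purrr::map_dfr(g, function(gi) {
    vals <- purrr::map_dbl(cl, expected_distinct, g = gi)
    tibble::tibble(g = gi, richness = mean(vals, na.rm = TRUE),
                   n_loci = sum(!is.na(vals)))
  })
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles per locus found in a `g`-copy subsample of
#' the focal group but in none of the equally sized subsamples of the other
#' groups (the multi-group private-allele rarefaction estimator).
#'
#' @param groups A list (length >= 2) of per-group allele counts; each
#'   element as accepted by [rarefied_richness()]. All groups must share
#'   locus names.
#' @param focal Index or name of the focal group.
#' @param g Subsample size in gene copies (>= 2); must be available in
#'   every group for a locus to contribute.
#' @return A tibble with one row per `g`: `g`, `private_richness`,
#'   `n_loci`.
#' @export
rarefied_private_richness <- function(groups, focal, g) {
  if (length(groups) < 2) stop("need at least 2 groups for private alleles")
  stopifnot(all(g >= 2))
  cls <- lapply(groups, as_count_list)
  if (is.character(focal)) focal <- match(focal, names(groups))
  loci <- names(cls[[focal]])
  purrr::map_dfr(g, function(gi) {
    vals <- purrr::map_dbl(loci, function(l) {
      per_group <- lapply(cls, function(cl) cl[[l]])
      if (any(vapply(per_group, is.null, logical(1)))) return(NA_real_)
      Ns <- vapply(per_group, sum, numeric(1))
      if (any(Ns < gi)) return(NA_real_)
      foc <- per_group[[focal]]
      alleles <- names(foc)
      present_focal <- 1 - absent_prob(unname(foc), Ns[focal], gi)
      absent_others <- rep(1, length(alleles))
      for (k in seq_along(per_group)) {
        if (k == focal) next
        oth <- per_group[[k]]
        n_in_k <- ifelse(alleles %in% names(oth), oth[alleles], 0)
        absent_others <- absent_others * absent_prob(unname(n_in_k), Ns[k], gi)
      }
      sum(present_focal * absent_others)
    })
    tibble::tibble(g = gi, private_richness = mean(vals, na.rm = TRUE),
                   n_loci = sum(!is.na(vals)))
  })
}

as_count_list <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    return(lapply(counts, function(v) {
      if (is.null(names(v))) names(v) <- seq_along(v)
      v
    }))
  }
  counts <- tibble::as_tibble(counts)
  if ("group" %in% names(counts) && dplyr::n_distinct(counts$group) > 1) {
    stop("frequency table spans multiple groups; filter to one group first")
  }
  lapply(split(counts, counts$locus),
         function(d) stats::setNames(d$count, d$allele))
}

#' Rarefaction curves for temporal metapopulation groups
#'
#' Pools populations by sampling time and sweeps the subsample size `g`
#' from 2 upward, computing expected distinct and private alleles per locus
#' for each time group (groups are compared at equal `g`).
#'
#' @param x A [msat_data] object with `time_code` metadata.
#' @param g_max Largest `g`; default the largest value available in every
#'   group (so private richness is defined throughout).
#' @param step Step of the `g` grid (default 2).
#' @return A tibble of class `rarefaction_tbl`: `group`, `g`, `richness`,
#'   `private_richness`.
#' @export
rarefaction_curves <- function(x, g_max = NULL, step = 2) {
  freqs <- allele_frequencies(x, by = "time")
  groups <- split(freqs, freqs$group)
  min_copies <- min(vapply(groups, function(d) {
    min(tapply(d$count, d$locus, sum))
  }, numeric(1)))
  if (is.null(g_max)) g_max <- min_copies
  gs <- seq(2, g_max, by = step)
  out <- purrr::imap_dfr(groups, function(d, nm) {
    rich <- rarefied_richness(d, gs)
    priv <- rarefied_private_richness(groups, focal = nm, g = gs)
    tibble::tibble(group = nm, g = gs, richness = rich$richness,
                   private_richness = priv$private_richness)
  })
  class(out) <- c("rarefaction_tbl", class(out))
  out
}

#' @export
autoplot.rarefaction_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("richness", "private_richness"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$g, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "gene copies (g)", y = "expected alleles per locus")
}

#' @export
autoplot.diversity_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, dplyr::any_of(c("Na", "Ne", "I", "Ho", "He", "Ar")),
    names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}
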
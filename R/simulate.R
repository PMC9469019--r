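#' Simulator configuration
#'
#' Parameters of the forward-time metapopulation simulator. Defaults
#' emulate the field study design this package targets: a dozen demes
#' typed at 15 microsatellite loci, four consecutive sampling episodes of
#' ~32 individuals per deme, an asymmetric directed migration matrix,
#' partial sampling of the parental cohort, and mild genotyping error and
#' missingness.
#'
#' Migration acts through parentage: an offspring born in deme `i` draws
#' its first parent from deme `i` and its second parent from deme `j`
#' with probability `migration[i, j]` (`j == i` is resident mating). This
#' is exactly the signal that kinship-based gene-flow inference detects.
#'
#' @param n_demes Number of demes (default 12).
#' @param deme_size Diploid adults per deme per generation (default 200).
#' @param n_loci Number of loci (default 15).
#' @param alleles_per_locus Alleles segregating per locus (default 10).
#' @param dirichlet_alpha Concentration of the Dirichlet draw of founding
#'   allele frequencies (default 1: broad, uneven spectra).
#' @param migration Row-stochastic `n_demes x n_demes` matrix; default
#'   0.85 resident with the remainder spread over other demes by a
#'   distance-decay kernel on the deme grid (scale `decay_km`).
#' @param resident_prob Diagonal mass of the default migration matrix.
#' @param decay_km e-folding scale (km) of the default kernel (1000 km,
#'   the distance scale typical of windborne moth migration).
#' @param n_generations Burn-in generations before the first sampled
#'   episode (default 2).
#' @param n_time_slices Sampled episodes (default 4).
#' @param sample_per_deme Offspring sampled per deme per slice (default 32).
#' @param parent_sampling_fraction Fraction of each parental cohort also
#'   sampled into the slice (default 0.25; 1 = complete parent sampling).
#' @param error_rate Per-allele mistyping probability applied to emitted
#'   genotypes (default 0.001).
#' @param missing_rate Per-genotype missing probability (default 0.02).
#' @param grid_spacing_km Spacing of the deme coordinate grid (default
#'   800 km).
#' @param seed Integer seed (required at simulation time).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 12, deme_size = 200, n_loci = 15,
                       alleles_per_locus = 10, dirichlet_alpha = 1,
                       migration = NULL, resident_prob = 0.85,
                       decay_km = 1000, n_generations = 2,
                       n_time_slices = 4, sample_per_deme = 32,
                       parent_sampling_fraction = 0.25,
                       error_rate = 0.001, missing_rate = 0.02,
                       grid_spacing_km = 800, seed = NULL) {
  stopifnot(n_demes >= 1, deme_size >= 2, n_loci >= 1,
            alleles_per_locus >= 1, n_time_slices >= 1,
            sample_per_deme >= 1,
            parent_sampling_fraction >= 0, parent_sampling_fraction <= 1,
            error_rate >= 0, error_rate < 0.5,
            missing_rate >= 0, missing_rate < 0.5)
  if (sample_per_deme > deme_size) {
    stop("deme_size too small for the requested sample_per_deme")
  }
  coords <- deme_grid(n_demes, grid_spacing_km)
  if (is.null(migration)) {
    migration <- default_migration(coords, resident_prob, decay_km)
  }
  migration <- as.matrix(migration)
  if (!all(dim(migration) == n_demes)) {
    stop("migration matrix must be ", n_demes, " x ", n_demes)
  }
  if (any(migration < 0) || any(abs(rowSums(migration) - 1) > 1e-12)) {
    stop("migration matrix rows must be non-negative and sum to 1")
  }
  structure(list(
    n_demes = n_demes, deme_size = deme_size, n_loci = n_loci,
    alleles_per_locus = alleles_per_locus,
    dirichlet_alpha = dirichlet_alpha, migration = migration,
    n_generations = n_generations, n_time_slices = n_time_slices,
    sample_per_deme = sample_per_deme,
    parent_sampling_fraction = parent_sampling_fraction,
    error_rate = error_rate, missing_rate = missing_rate,
    coords = coords, seed = seed), class = "sim_config")
}

deme_grid <- function(n_demes, spacing_km) {
  n_col <- ceiling(sqrt(n_demes))
  row <- (seq_len(n_demes) - 1) %/% n_col
  col <- (seq_len(n_demes) - 1) %% n_col
  lat0 <- 18; lon0 <- 100
  km_per_deg <- pi * 6371.0088 / 180
  lat <- lat0 + row * spacing_km / km_per_deg
  lon <- lon0 + col * spacing_km / (km_per_deg * cos(lat0 * pi / 180))
  tibble::tibble(deme = LETTERS[seq_len(n_demes)],
                 latitude = lat, longitude = lon)
}

default_migration <- function(coords, resident_prob, decay_km) {
  n <- nrow(coords)
  if (n == 1) return(matrix(1, 1, 1))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- geodesic_km(coords$latitude[i], coords$longitude[i],
                          coords$latitude, coords$longitude)
  }
  K <- exp(-D / decay_km); diag(K) <- 0
  M <- K / rowSums(K) * (1 - resident_prob)
  diag(M) <- resident_prob
  M
}

rdirichlet1 <- function(k, alpha) {
  x <- stats::rgamma(k, shape = alpha)
  x / sum(x)
}

#' Simulate a partially migrating microsatellite metapopulation
#'
#' Forward-time, non-overlapping generations. Each generation every deme
#' produces `deme_size` offspring; each offspring draws parent 1 from its
#' natal deme and parent 2 from the deme given by the migration matrix,
#' transmitting one allele per locus Mendelianly. After burn-in, each of
#' `n_time_slices` consecutive generations is a sampling episode: the
#' emitted populations contain `sample_per_deme` offspring plus a
#' `parent_sampling_fraction` sample of the parental cohort, coded
#' `<deme letter><slice>` (e.g. `"A1"`). Genotyping error and missingness
#' are then injected per the config. Ground truth (full pedigree and
#' per-slice migrant-parent origins) is returned alongside.
#'
#' @param config A [sim_config].
#' @param seed Integer seed; overrides `config$seed`.
#' @return A list with `data` (a [msat_data]) and `truth` (class
#'   `sim_truth`: `pedigree` tibble with `offspring`, `parent1`,
#'   `parent2`, `natal_deme`, `parent2_deme`, `slice`, `sampled`;
#'   `config`).
#' @export
simulate_metapopulation <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required (in `config` or `seed`)")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  nd <- config$n_demes; N <- config$deme_size
  L <- config$n_loci; k <- config$alleles_per_locus
  allele_lengths <- lapply(seq_len(L), function(l) 100L + 10L * l + 2L *
                             seq_len(k))
  base_freqs <- lapply(seq_len(L), function(l)
    rdirichlet1(k, config$dirichlet_alpha))

  # adults[[d]] : N x L x 2 integer array of allele values
  new_cohort <- function() {
    lapply(seq_len(nd), function(d) {
      arr <- array(NA_integer_, c(N, L, 2))
      for (l in seq_len(L)) {
        arr[, l, ] <- sample(allele_lengths[[l]], 2 * N, replace = TRUE,
                             prob = base_freqs[[l]])
      }
      arr
    })
  }
  adults <- new_cohort()
  adult_ids <- lapply(seq_len(nd), function(d)
    sprintf("G0_%s_%03d", LETTERS[d], seq_len(N)))

  pedigree <- list()
  samples <- list()
  pops <- list()
  emitted <- character(0)   # an individual can be sampled only once
  total_gens <- config$n_generations + config$n_time_slices

  for (gen in seq_len(total_gens)) {
    slice <- gen - config$n_generations        # > 0 once sampling starts
    offspring <- vector("list", nd)
    off_ids <- vector("list", nd)
    ped_gen <- vector("list", nd)
    for (d in seq_len(nd)) {
      p1 <- sample.int(N, N, replace = TRUE)
      origin <- sample.int(nd, N, replace = TRUE,
                           prob = config$migration[d, ])
      p2 <- sample.int(N, N, replace = TRUE)
      clash <- origin == d & p2 == p1
      while (any(clash)) {                      # no selfing
        p2[clash] <- sample.int(N, sum(clash), replace = TRUE)
        clash <- origin == d & p2 == p1
      }
      arr <- array(NA_integer_, c(N, L, 2))
      pick1 <- matrix(sample(c(1L, 2L), N * L, replace = TRUE), N, L)
      pick2 <- matrix(sample(c(1L, 2L), N * L, replace = TRUE), N, L)
      A <- adults[[d]]
      for (l in seq_len(L)) {
        arr[, l, 1] <- A[cbind(p1, l, pick1[, l])]
      }
      for (o in unique(origin)) {             # parent2 by origin deme
        idx <- which(origin == o)
        B <- adults[[o]]
        for (l in seq_len(L)) {
          arr[idx, l, 2] <- B[cbind(p2[idx], l, pick2[idx, l])]
        }
      }
      offspring[[d]] <- arr
      off_ids[[d]] <- sprintf("G%d_%s_%03d", gen, LETTERS[d], seq_len(N))
      ped_gen[[d]] <- tibble::tibble(
        offspring = off_ids[[d]],
        parent1 = adult_ids[[d]][p1],
        parent2 = vapply(seq_len(N), function(i)
          adult_ids[[origin[i]]][p2[i]], character(1)),
        natal_deme = LETTERS[d],
        parent2_deme = LETTERS[origin],
        slice = slice)
    }
    if (slice >= 1) {
      n_par <- round(config$parent_sampling_fraction * N)
      for (d in seq_len(nd)) {
        off_take <- sort(sample.int(N, config$sample_per_deme))
        par_pool <- which(!(adult_ids[[d]] %in% emitted))
        par_take <- if (n_par > 0 && length(par_pool) > 0)
          sort(sample(par_pool, min(n_par, length(par_pool))))
        else integer(0)
        ids <- c(off_ids[[d]][off_take], adult_ids[[d]][par_take])
        emitted <- c(emitted, ids)
        genos <- list(offspring[[d]][off_take, , , drop = FALSE],
                      adults[[d]][par_take, , , drop = FALSE])
        pop_code <- paste0(LETTERS[d], slice)
        samples[[length(samples) + 1]] <- tibble::tibble(
          individual = rep(ids, each = L),
          population = pop_code,
          locus = rep(sprintf("L%02d", seq_len(L)), length(ids)),
          allele_1 = c(aperm(genos[[1]][, , 1, drop = FALSE], c(2, 1, 3)),
                       aperm(genos[[2]][, , 1, drop = FALSE], c(2, 1, 3))),
          allele_2 = c(aperm(genos[[1]][, , 2, drop = FALSE], c(2, 1, 3)),
                       aperm(genos[[2]][, , 2, drop = FALSE], c(2, 1, 3))))
        ped_gen[[d]]$sampled <- off_ids[[d]] %in% ids
        pops[[length(pops) + 1]] <- tibble::tibble(
          population = pop_code, site = paste("deme", LETTERS[d]),
          latitude = config$coords$latitude[d],
          longitude = config$coords$longitude[d],
          time_code = slice,
          sampling_date = as.Date("2016-01-01") + 180 * (slice - 1))
      }
      pedigree[[length(pedigree) + 1]] <- dplyr::bind_rows(ped_gen)
    }
    adults <- offspring
    adult_ids <- off_ids
  }

  gt <- dplyr::bind_rows(samples)
  data <- msat_data(gt, dplyr::bind_rows(pops),
                    loci = sprintf("L%02d", seq_len(L)))
  if (config$error_rate > 0 || config$missing_rate > 0) {
    data <- inject_genotyping_error(data, e = config$error_rate,
                                    missing_rate = config$missing_rate,
                                    seed = seed + 10^6)
  }
  ped <- dplyr::bind_rows(pedigree)
  truth <- structure(list(pedigree = ped, config = config, seed = seed),
                     class = "sim_truth")
  list(data = data, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$pedigree), " offspring records, ",
      x$config$n_demes, " demes, ", x$config$n_time_slices, " slices\n",
      sep = "")
  invisible(x)
}

#' Inject genotyping error and missingness
#'
#' Each allele call is, independently with probability `e`, replaced by an
#' allele drawn from the locus's population-wide frequency distribution;
#' each genotype is set to missing with probability `missing_rate`.
#' Ground truth objects are unaffected.
#'
#' @param x A [msat_data].
#' @param e Per-allele replacement probability (`0 <= e < 0.5`).
#' @param missing_rate Per-genotype missing probability (`< 0.5`).
#' @param seed Integer seed.
#' @return A [msat_data] with perturbed genotypes.
#' @export
inject_genotyping_error <- function(x, e, missing_rate = 0, seed) {
  stopifnot(inherits(x, "msat_data"), e >= 0, e < 0.5,
            missing_rate >= 0, missing_rate < 0.5)
  if (e == 0 && missing_rate == 0) return(x)
  if (missing(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gt <- x$genotypes
  fl <- freq_list(allele_frequencies(x, by = "total"))
  for (l in x$loci) {
    rows <- which(gt$locus == l & !is.na(gt$allele_1))
    p <- fl[[l]]
    if (is.null(p) || length(rows) == 0) next
    vals <- as.integer(names(p))
    for (col in c("allele_1", "allele_2")) {
      flip <- rows[stats::runif(length(rows)) < e]
      if (length(flip) > 0) {
        gt[[col]][flip] <- sample(vals, length(flip), replace = TRUE,
                                  prob = p)
      }
    }
    drop <- rows[stats::runif(length(rows)) < missing_rate]
    gt$allele_1[drop] <- NA_integer_
    gt$allele_2[drop] <- NA_integer_
  }
  msat_data(gt, x$populations, loci = x$loci)
}

#' Realized migration counts from simulator truth
#'
#' Tallies offspring by natal deme (destination) and migrant-parent
#' origin. With `per_parent = TRUE` both parental gene draws are counted
#' (parent 1 is always resident), which is the scale estimated by
#' single-best-parent assignment; the default counts each offspring once
#' by its second parent's origin.
#'
#' @param truth A `sim_truth`.
#' @param sampled_only Restrict to offspring emitted in the dataset
#'   (default `TRUE`).
#' @param slice Optional slice number(s) to restrict to.
#' @param per_parent Count both parents instead of parent 2 only.
#' @return A `migration_counts` matrix (destination rows, origin columns)
#'   over deme letters.
#' @export
realized_migration <- function(truth, sampled_only = TRUE, slice = NULL,
                               per_parent = FALSE) {
  stopifnot(inherits(truth, "sim_truth"))
  ped <- truth$pedigree
  if (!is.null(slice)) ped <- dplyr::filter(ped, .data$slice %in% !!slice)
  if (sampled_only) ped <- dplyr::filter(ped, .data$sampled)
  demes <- LETTERS[seq_len(truth$config$n_demes)]
  dest <- factor(ped$natal_deme, levels = demes)
  m <- matrix(0L, length(demes), length(demes),
              dimnames = list(destination = demes, origin = demes))
  tab2 <- table(dest, factor(ped$parent2_deme, levels = demes))
  m[] <- as.integer(tab2)
  if (per_parent) {
    tab1 <- table(dest, factor(ped$natal_deme, levels = demes))
    m[] <- m + as.integer(tab1)
  }
  class(m) <- c("migration_counts", class(m))
  m
}
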
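#' Microsatellite datasets
#'
#' A `msat_data` object holds a temporally structured codominant
#' microsatellite dataset: one long genotype table (one row per individual
#' per locus, two integer allele-length columns) plus a population table
#' carrying site metadata (coordinates, sampling time code, date).
#' Missing genotypes have both alleles `NA`; half-calls are not allowed.
#'
#' @param genotypes A data frame with columns `individual`, `population`,
#'   `locus`, `allele_1`, `allele_2`. Allele calls are positive integers
#'   (fragment lengths in base pairs); a missing genotype has `NA` in both
#'   allele columns. Alleles are stored sorted so `allele_1 <= allele_2`.
#' @param populations A data frame with one row per population: `population`
#'   (unique code, e.g. `"FJ1"`), and optionally `site`, `latitude`,
#'   `longitude`, `time_code` (integer 1-4), `sampling_date`.
#' @param loci Optional character vector fixing the locus set and order;
#'   defaults to the loci present in `genotypes`.
#'
#' @return An object of class `msat_data`: a list with tibbles `genotypes`
#'   and `populations` and the character vector `loci`.
#' @export
msat_data <- function(genotypes, populations = NULL, loci = NULL) {
  genotypes <- tibble::as_tibble(genotypes)
  required <- c("individual", "population", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(required, names(genotypes))
  if (length(missing_cols) > 0) {
    stop("`genotypes` lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  half <- xor(is.na(genotypes$allele_1), is.na(genotypes$allele_2))
  if (any(half)) {
    stop("half-called genotypes (one allele missing) at ", sum(half), " row(s)")
  }
  # store alleles sorted ascending
  a1 <- pmin(genotypes$allele_1, genotypes$allele_2)
  a2 <- pmax(genotypes$allele_1, genotypes$allele_2)
  genotypes$allele_1 <- as.integer(a1)
  genotypes$allele_2 <- as.integer(a2)
  if (any(stats::na.omit(genotypes$allele_1) <= 0)) {
    stop("allele calls must be positive integers (0 is reserved for missing)")
  }

  if (is.null(loci)) loci <- unique(genotypes$locus)
  loci <- as.character(loci)

  if (is.null(populations)) {
    populations <- tibble::tibble(population = unique(genotypes$population))
  }
  populations <- tibble::as_tibble(populations)
  if (anyDuplicated(populations$population)) {
    stop("population codes must be unique")
  }
  extra <- setdiff(unique(genotypes$population), populations$population)
  if (length(extra) > 0) {
    stop("genotypes reference unknown population(s): ",
         paste(extra, collapse = ", "))
  }
  if ("latitude" %in% names(populations)) {
    bad <- !is.na(populations$latitude) & abs(populations$latitude) > 90
    if (any(bad)) stop("latitude out of [-90, 90] for: ",
                       paste(populations$population[bad], collapse = ", "))
  }
  if ("longitude" %in% names(populations)) {
    bad <- !is.na(populations$longitude) & abs(populations$longitude) > 180
    if (any(bad)) stop("longitude out of [-180, 180] for: ",
                       paste(populations$population[bad], collapse = ", "))
  }
  if ("time_code" %in% names(populations)) {
    populations$time_code <- as.integer(populations$time_code)
  }

  # complete the individual x locus grid so every locus has an entry
  ind_tbl <- dplyr::distinct(genotypes, .data$individual, .data$population)
  if (anyDuplicated(ind_tbl$individual)) {
    stop("individual ids must be unique across populations")
  }
  grid <- tidyr::expand_grid(ind_tbl, locus = loci)
  genotypes <- dplyr::left_join(grid, genotypes,
                                by = c("individual", "population", "locus"))

  n_tbl <- dplyr::count(ind_tbl, .data$population, name = "n")
  populations <- dplyr::left_join(
    dplyr::select(populations, -dplyr::any_of("n")), n_tbl, by = "population")
  populations$n[is.na(populations$n)] <- 0L

  structure(
    list(genotypes = genotypes, populations = populations, loci = loci),
    class = "msat_data")
}

#' @export
print.msat_data <- function(x, ...) {
  cat("<msat_data> ", nrow(x$populations), " populations, ",
      dplyr::n_distinct(x$genotypes$individual), " individuals, ",
      length(x$loci), " loci\n", sep = "")
  if ("time_code" %in% names(x$populations)) {
    tc <- table(x$populations$time_code)
    cat("time codes: ", paste(names(tc), tc, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

n_individuals <- function(x) dplyr::n_distinct(x$genotypes$individual)

#' Read a GenAlEx codominant genotype file
#'
#' Parses the GenAlEx codominant CSV layout: row 1 holds the counts
#' (`n_loci, n_individuals, n_populations, size_1, ..., size_k`), row 2 the
#' dataset title followed by population names aligned with the size columns,
#' row 3 the column header (individual, population, then two columns per
#' locus of which the first carries the locus name). Allele calls are
#' integers with `0` meaning missing.
#'
#' @param path Path to the CSV file.
#' @param sites Optional path to (or data frame of) a site metadata table
#'   with columns `population`, `site`, `latitude`, `longitude`,
#'   `time_code`, `sampling_date`; joined onto the population table.
#' @return A [msat_data] object with populations in file order.
#' @export
read_genalex <- function(path, sites = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(raw) < 4) stop("malformed GenAlEx file: fewer than 4 lines")

  hdr <- suppressWarnings(as.integer(raw[1, ]))
  n_loci <- hdr[1]; n_ind <- hdr[2]; n_pop <- hdr[3]
  if (any(is.na(c(n_loci, n_ind, n_pop)))) {
    stop("malformed GenAlEx header (line 1): expected integer counts ",
         "'n_loci, n_individuals, n_populations, sizes...'")
  }
  sizes <- hdr[seq(4, length.out = n_pop)]
  if (any(is.na(sizes))) {
    stop("malformed GenAlEx header (line 1): missing population sizes")
  }
  pop_names <- as.character(raw[2, seq(4, length.out = n_pop)])
  if (any(is.na(pop_names) | pop_names == "")) {
    stop("malformed GenAlEx header (line 2): missing population names")
  }
  header3 <- as.character(raw[3, ])
  n_allele_cols <- length(header3) - 2
  if (n_allele_cols < 2 * n_loci) {
    stop("malformed GenAlEx header (line 3): expected ", 2 * n_loci,
         " allele columns, found ", n_allele_cols)
  }
  locus_names <- header3[2 + 2 * seq_len(n_loci) - 1]
  if (any(is.na(locus_names) | locus_names == "")) {
    stop("malformed GenAlEx header (line 3): missing locus names")
  }

  data <- raw[-(1:3), , drop = FALSE]
  data <- data[!is.na(data[[1]]) & data[[1]] != "", , drop = FALSE]
  if (nrow(data) != n_ind) {
    stop("GenAlEx consistency error: header declares ", n_ind,
         " individuals but file has ", nrow(data), " data rows")
  }
  if (sum(sizes) != n_ind) {
    stop("GenAlEx consistency error: population sizes sum to ", sum(sizes),
         ", header declares ", n_ind, " individuals")
  }

  ind <- as.character(data[[1]])
  pop <- as.character(data[[2]])
  expected_pop <- rep(pop_names, times = sizes)
  if (!identical(pop, expected_pop)) {
    stop("GenAlEx consistency error: population column does not match ",
         "declared block sizes")
  }

  allele_mat <- suppressWarnings(
    vapply(seq_len(2 * n_loci),
           function(j) as.integer(data[[2 + j]]), integer(nrow(data))))
  allele_mat <- matrix(allele_mat, nrow = nrow(data))
  if (anyNA(allele_mat)) {
    stop("malformed GenAlEx file: non-integer allele call")
  }
  allele_mat[allele_mat == 0L] <- NA_integer_

  gt <- tibble::tibble(
    individual = rep(ind, each = n_loci),
    population = rep(pop, each = n_loci),
    locus = rep(locus_names, times = nrow(data)),
    allele_1 = as.vector(t(allele_mat[, 2 * seq_len(n_loci) - 1, drop = FALSE])),
    allele_2 = as.vector(t(allele_mat[, 2 * seq_len(n_loci), drop = FALSE])))

  pops <- tibble::tibble(population = pop_names)
  if (!is.null(sites)) {
    site_tbl <- if (is.data.frame(sites)) tibble::as_tibble(sites) else
      readr::read_csv(sites, show_col_types = FALSE, progress = FALSE)
    pops <- dplyr::left_join(pops,
      dplyr::select(site_tbl, -dplyr::any_of("sample_size")), by = "population")
  }
  msat_data(gt, pops, loci = locus_names)
}

#' Write a GenAlEx codominant genotype file
#'
#' @param x A [msat_data] object.
#' @param path Output path.
#' @param title Dataset title written on line 2.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(x, path, title = "kinflow export") {
  stopifnot(inherits(x, "msat_data"))
  loci <- x$loci
  wide <- genotype_wide(x)
  pops <- x$populations$population
  sizes <- x$populations$n
  n_ind <- sum(sizes)

  line1 <- c(length(loci), n_ind, length(pops), sizes)
  line2 <- c(title, "", "", pops)
  header3 <- c("Ind", "Pop", as.vector(rbind(loci, "")))
  width <- max(length(header3), length(line1), length(line2))
  pad <- function(v) c(as.character(v), rep("", width - length(v)))

  allele_cols <- wide[, -(1:2), drop = FALSE]
  allele_cols[is.na(allele_cols)] <- 0L
  body <- cbind(wide[, 1:2, drop = FALSE], allele_cols)

  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(pad(line1), collapse = ","), con)
  writeLines(paste(pad(line2), collapse = ","), con)
  writeLines(paste(pad(header3), collapse = ","), con)
  apply_rows <- apply(body, 1, function(r) paste(pad(r)[seq_len(width)],
                                                 collapse = ","))
  writeLines(apply_rows, con)
  invisible(path)
}

# wide individual x (2 per locus) allele matrix, populations in table order
genotype_wide <- function(x) {
  gt <- x$genotypes
  gt$population <- factor(gt$population, levels = x$populations$population)
  gt$locus <- factor(gt$locus, levels = x$loci)
  gt <- dplyr::arrange(gt, .data$population, .data$individual, .data$locus)
  ids <- unique(gt$individual)
  n_loci <- length(x$loci)
  m <- matrix(NA_integer_, nrow = length(ids), ncol = 2 * n_loci)
  m[, 2 * seq_len(n_loci) - 1] <- matrix(gt$allele_1, ncol = n_loci, byrow = TRUE)
  m[, 2 * seq_len(n_loci)] <- matrix(gt$allele_2, ncol = n_loci, byrow = TRUE)
  out <- data.frame(Ind = ids,
                    Pop = as.character(gt$population[seq(1, nrow(gt), n_loci)]),
                    m, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- as.vector(rbind(x$loci, paste0(x$loci, "_2")))
  out
}

#' Write a STRUCTURE two-row genotype file
#'
#' Two whitespace-separated rows per individual (one allele per row per
#' locus), an integer population column, missing data coded `-9`.
#'
#' @param x A [msat_data] object (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "msat_data"))
  if (n_individuals(x) == 0) stop("cannot write an empty dataset")
  wide <- genotype_wide(x)
  pop_code <- match(wide$Pop, x$populations$population)
  n_loci <- length(x$loci)
  a1 <- as.matrix(wide[, 2 + 2 * seq_len(n_loci) - 1, drop = FALSE])
  a2 <- as.matrix(wide[, 2 + 2 * seq_len(n_loci), drop = FALSE])
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  lines <- character(2 * nrow(wide))
  lines[2 * seq_len(nrow(wide)) - 1] <-
    paste(wide$Ind, pop_code, apply(a1, 1, paste, collapse = " "))
  lines[2 * seq_len(nrow(wide))] <-
    paste(wide$Ind, pop_code, apply(a2, 1, paste, collapse = " "))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a STRUCTURE two-row genotype file
#'
#' Counterpart of [write_structure()]; locus names are synthesised as
#' `L01, L02, ...` unless supplied.
#'
#' @param path Input path.
#' @param loci Optional locus names (length must match the file).
#' @return A [msat_data] object.
#' @export
read_structure <- function(path, loci = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2 != 0) {
    stop("malformed STRUCTURE file: odd number of data rows")
  }
  fields <- strsplit(trimws(lines), "\\s+")
  len <- lengths(fields)
  if (length(unique(len)) != 1) stop("malformed STRUCTURE file: ragged rows")
  n_loci <- len[1] - 2
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(n_loci))
  m <- do.call(rbind, fields)
  ids <- m[, 1]; pop <- m[, 2]
  odd <- seq(1, nrow(m), by = 2); even <- odd + 1
  if (!identical(ids[odd], ids[even])) {
    stop("malformed STRUCTURE file: row pairs disagree on individual id")
  }
  a1 <- matrix(as.integer(m[odd, -(1:2)]), nrow = length(odd))
  a2 <- matrix(as.integer(m[even, -(1:2)]), nrow = length(odd))
  a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
  gt <- tibble::tibble(
    individual = rep(ids[odd], each = n_loci),
    population = rep(pop[odd], each = n_loci),
    locus = rep(loci, times = length(odd)),
    allele_1 = as.vector(t(a1)),
    allele_2 = as.vector(t(a2)))
  msat_data(gt, loci = loci)
}

#' Per-population allele frequencies
#'
#' Counts non-missing gene copies per (group, locus) and converts to
#' frequencies. Cells with no non-missing calls are flagged empty (absent
#' from the table, listed in the `empty_cells` attribute).
#'
#' @param x A [msat_data] object.
#' @param by Grouping: `"population"` (default), `"time"` (pool populations
#'   sharing a `time_code`), or `"total"` (one pooled group).
#' @return A tibble with columns `group`, `locus`, `allele`, `count`,
#'   `copies_sampled`, `freq`. Frequencies sum to 1 within each
#'   (group, locus).
#' @export
allele_frequencies <- function(x, by = c("population", "time", "total")) {
  stopifnot(inherits(x, "msat_data"))
  by <- match.arg(by)
  gt <- x$genotypes
  gt$group <- switch(by,
    population = gt$population,
    time = {
      tc <- x$populations$time_code[match(gt$population,
                                          x$populations$population)]
      paste0("time", tc)
    },
    total = "total")
  long <- tidyr::pivot_longer(
    dplyr::select(gt, "group", "locus", "allele_1", "allele_2"),
    cols = c("allele_1", "allele_2"), values_to = "allele")
  long <- dplyr::filter(long, !is.na(.data$allele))
  counts <- dplyr::count(long, .data$group, .data$locus, .data$allele,
                         name = "count")
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$group, .data$locus),
    copies_sampled = sum(.data$count),
    freq = .data$count / .data$copies_sampled)
  counts <- dplyr::ungroup(counts)

  all_groups <- unique(gt$group)
  cells <- tidyr::expand_grid(group = all_groups, locus = x$loci)
  empty <- dplyr::anti_join(cells, counts, by = c("group", "locus"))
  attr(counts, "empty_cells") <- empty
  counts
}

# list: freqs[[locus]] = named numeric frequency vector, from pooled table
freq_list <- function(freq_tbl, group = NULL) {
  if (!is.null(group)) freq_tbl <- freq_tbl[freq_tbl$group == group, ]
  split_tbl <- split(freq_tbl, freq_tbl$locus)
  lapply(split_tbl, function(d) stats::setNames(d$freq, d$allele))
}

#' Drop populations below a minimum sample size
#'
#' Small samples bias kinship assignment, so populations with fewer than
#' `min_n` individuals are excluded before parentage analysis (the default
#' mirrors the 10-individual rule used with field microsatellite data).
#'
#' @param x A [msat_data] object.
#' @param min_n Minimum number of individuals (default 10).
#' @return A [msat_data] with only populations of size >= `min_n`, original
#'   order preserved. Removed population codes are in attribute `removed`.
#' @export
filter_min_size <- function(x, min_n = 10) {
  stopifnot(inherits(x, "msat_data"), min_n >= 1)
  keep <- x$populations$n >= min_n
  removed <- x$populations$population[!keep]
  if (!any(keep)) {
    stop("all populations removed by min_n = ", min_n)
  }
  if (length(removed) > 0) {
    message("filter_min_size: removed ", length(removed), " population(s): ",
            paste(removed, collapse = ", "))
  }
  out <- msat_data(
    dplyr::filter(x$genotypes, .data$population %in%
                    x$populations$population[keep]),
    x$populations[keep, , drop = FALSE], loci = x$loci)
  attr(out, "removed") <- removed
  out
}

#' Per-time-slice sample bookkeeping
#'
#' @param x A [msat_data] object whose population table has `time_code`,
#'   or a site metadata data frame with columns `population`,
#'   `sample_size` (or `n`) and `time_code`.
#' @return A tibble with one row per `time_code`: `n_populations`,
#'   `n_individuals`; grand totals in attributes `total_populations` and
#'   `total_individuals`.
#' @export
tabulate_by_time <- function(x) {
  if (inherits(x, "msat_data")) {
    pops <- x$populations
  } else {
    pops <- tibble::as_tibble(x)
    if (!"n" %in% names(pops)) {
      if (!"sample_size" %in% names(pops)) {
        stop("need a `sample_size` (or `n`) column")
      }
      pops$n <- pops$sample_size
    }
  }
  if (!"time_code" %in% names(pops) || anyNA(pops$time_code)) {
    stop("every population needs a valid time_code")
  }
  out <- dplyr::summarise(dplyr::group_by(pops, .data$time_code),
                          n_populations = dplyr::n(),
                          n_individuals = sum(.data$n), .groups = "drop")
  out <- dplyr::arrange(out, .data$time_code)
  attr(out, "total_populations") <- nrow(pops)
  attr(out, "total_individuals") <- sum(pops$n)
  out
}

#' Extract one time slice
#'
#' @param x A [msat_data] object.
#' @param time One `time_code` value.
#' @return A [msat_data] restricted to populations with that time code.
#' @export
time_slice <- function(x, time) {
  stopifnot(inherits(x, "msat_data"))
  keep <- x$populations$time_code == time
  if (!any(keep)) stop("no populations with time_code ", time)
  msat_data(
    dplyr::filter(x$genotypes, .data$population %in%
                    x$populations$population[keep]),
    x$populations[keep, , drop = FALSE], loci = x$loci)
}
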
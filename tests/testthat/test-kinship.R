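test_that("transition probabilities reduce to Mendelian rules at e = 0", {
  p <- c("100" = 0.6, "102" = 0.4)
  # parent AA transmits A; B is drawn from the pool with prob q
  expect_equal(transition_prob(c(100, 102), c(100, 100), p, 0), 0.4,
               tolerance = 1e-12)
  # Mendelian exclusion
  expect_equal(transition_prob(c(102, 102), c(100, 100), p, 0), 0)
  # with error the exclusion softens but stays below the unconditional
  tp <- transition_prob(c(102, 102), c(100, 100), p, error_model(0.05))
  expect_gt(tp, 0)
  expect_lt(tp, 0.4^2)
})

test_that("transition probabilities sum to one over offspring genotypes", {
  set.seed(11)
  for (k in 2:4) {
    p <- stats::setNames(rdir <- {
      x <- stats::rgamma(k, 1); x / sum(x)
    }, 100 + 2 * seq_len(k))
    alleles <- as.integer(names(p))
    genos <- list()
    for (i in seq_len(k)) for (j in i:k) {
      genos[[length(genos) + 1]] <- c(alleles[i], alleles[j])
    }
    parent <- genos[[sample(length(genos), 1)]]
    for (e in c(0, 0.03, 0.2)) {
      tot <- sum(vapply(genos, transition_prob, numeric(1),
                        parent = parent, freqs = p, error = e))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("single-locus LOD scores match hand likelihood ratios", {
  # parent AA, offspring AA, p_A = 0.25: LR = p/p^2 = 4
  x <- make_msat(list(P = list(list(c(100, 100)), list(c(100, 100)),
                               list(c(102, 102)), list(c(102, 102)),
                               list(c(102, 102)), list(c(102, 102)),
                               list(c(102, 100)), list(c(102, 100)))))
  # pooled freqs: A = 100 appears 2*2 + 2 = 6 of 16 copies
  fr <- allele_frequencies(x, by = "total")
  pa <- fr$freq[fr$allele == 100]
  pr <- po_lod("P_i01", "P_i02", x, error = 0, min_shared_loci = 1)
  expect_equal(pr$lod, log10(1 / pa), tolerance = 1e-9)

  # symmetric case p = q = 0.5: parent AA, offspring AB has LR = 1
  y <- make_msat(list(P = list(list(c(1, 1)), list(c(1, 2)),
                               list(c(2, 2)), list(c(1, 2)))))
  pr2 <- po_lod("P_i02", "P_i01", y, error = 0, min_shared_loci = 1)
  expect_equal(pr2$lod, 0, tolerance = 1e-12)

  # Mendelian-incompatible locus at e = 0 gives -Inf and counts a mismatch
  pr3 <- po_lod("P_i03", "P_i01", y, error = 0, min_shared_loci = 1)
  expect_true(is.infinite(pr3$lod) && pr3$lod < 0)
  expect_equal(pr3$n_mismatch, 1L)
  # with e > 0 the LOD is finite
  pr4 <- po_lod("P_i03", "P_i01", y, error = 1e-3, min_shared_loci = 1)
  expect_true(is.finite(pr4$lod))
})

test_that("LOD thresholds are deterministic and monotone in the quantile", {
  sim <- simulate_metapopulation(sim_config(
    n_demes = 2, deme_size = 50, sample_per_deme = 20,
    parent_sampling_fraction = 0, n_time_slices = 1, seed = 13))
  fr <- allele_frequencies(sim$data, by = "total")
  t1 <- lod_threshold(fr, 1e-4, n_sim = 2000, quantile = 0.99, seed = 5)
  t2 <- lod_threshold(fr, 1e-4, n_sim = 2000, quantile = 0.99, seed = 5)
  t3 <- lod_threshold(fr, 1e-4, n_sim = 2000, quantile = 0.999, seed = 5)
  expect_identical(t1$threshold, t2$threshold)
  expect_gte(t3$threshold, t1$threshold)
  expect_true(is.finite(t1$threshold))
})

test_that("threshold quantile matches the null LOD distribution", {
  # a symmetric two-allele locus has an enumerable unrelated-pair LOD
  # distribution; the median of simulated LODs must match the exact median
  p <- list(L1 = c("1" = 0.5, "2" = 0.5))
  thr <- lod_threshold(p, error = 0, n_sim = 20000, quantile = 0.5,
                       seed = 9)
  # enumerate all 3x3 unordered genotype pairs and their LODs
  genos <- list(c(1, 1), c(1, 2), c(2, 2))
  probs <- c(0.25, 0.5, 0.25)
  lods <- c(); ws <- c()
  for (i in 1:3) for (j in 1:3) {
    lr <- transition_prob(genos[[j]], genos[[i]], p$L1, 0) /
      probs[j]
    lods <- c(lods, log10(lr)); ws <- c(ws, probs[i] * probs[j])
  }
  ord <- order(lods)
  cdf <- cumsum(ws[ord])
  exact_median <- lods[ord][which(cdf >= 0.5)[1]]
  expect_equal(thr$threshold, exact_median, tolerance = 0.02)
})

test_that("true parents are recovered and dominate unrelated candidates", {
  sim <- simulate_metapopulation(sim_config(
    n_demes = 2, deme_size = 120, sample_per_deme = 30,
    parent_sampling_fraction = 1, n_time_slices = 1,
    error_rate = 0, missing_rate = 0,
    migration = matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE),
    seed = 19))
  sl <- time_slice(sim$data, 1)
  pairs <- assign_parentage(sl, error = 1e-4, seed = 23, n_sim = 2000)
  ped <- sim$truth$pedigree
  truth_key <- c(paste(ped$offspring, ped$parent1),
                 paste(ped$offspring, ped$parent2))
  off <- pairs[pairs$offspring %in% ped$offspring[ped$sampled], ]
  expect_gte(nrow(off), 0.9 * sum(ped$sampled))
  expect_gte(mean(paste(off$offspring, off$parent) %in% truth_key), 0.9)

  # true-parent LODs stochastically dominate unrelated LODs
  lods <- kinflow:::lod_matrix(sl, 1e-4)
  ids <- lods$ids
  ped_s <- ped[ped$sampled & ped$parent1 %in% ids, ]
  true_lod <- lods$lod[cbind(match(ped_s$parent1, ids),
                             match(ped_s$offspring, ids))]
  set.seed(1)
  unrel <- replicate(500, {
    i <- sample(length(ids), 2)
    lods$lod[i[1], i[2]]
  })
  mw <- stats::wilcox.test(true_lod, unrel, alternative = "greater")
  expect_lt(mw$p.value, 0.01)
})

test_that("assignment is deterministic and ties break lexicographically", {
  # two identical candidate parents -> tie broken to the smaller id
  x <- make_msat(list(P = list(
    list(c(1, 2), c(3, 3), c(1, 1)),   # offspring
    list(c(1, 1), c(3, 3), c(1, 1)),   # candidate 1
    list(c(1, 1), c(3, 3), c(1, 1)),   # identical candidate 2
    list(c(2, 2), c(4, 4), c(2, 2)),
    list(c(2, 2), c(4, 4), c(2, 2)))))
  thr <- structure(list(threshold = -10), class = "lod_threshold")
  expect_message(
    pairs <- assign_parentage(x, error = 1e-4, threshold = thr,
                              min_shared_loci = 1),
    "tie")
  row <- pairs[pairs$offspring == "P_i01", ]
  expect_equal(row$parent, "P_i02")

  sim <- simulate_metapopulation(sim_config(
    n_demes = 2, deme_size = 40, sample_per_deme = 15,
    parent_sampling_fraction = 0.5, n_time_slices = 1, seed = 29))
  sl <- time_slice(sim$data, 1)
  a <- assign_parentage(sl, error = 1e-3, seed = 7, n_sim = 2000)
  b <- assign_parentage(sl, error = 1e-3, seed = 7, n_sim = 2000)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("assignments are concordant across assumed error rates", {
  sim <- simulate_metapopulation(sim_config(
    n_demes = 2, deme_size = 80, sample_per_deme = 25,
    parent_sampling_fraction = 1, n_time_slices = 1,
    error_rate = 0, missing_rate = 0, seed = 37))
  sl <- time_slice(sim$data, 1)
  rep <- error_rate_robustness(sl, rates = c(1e-4, 1e-3, 1e-2, 5e-2),
                               seed = 3, n_sim = 2000)
  expect_true(all(rep$jaccard >= 0.8))
  expect_true(rep$informative)
  # per-population-pair counts are essentially unchanged across rates
  expect_true(all(rep$count_correlation >= 0.99, na.rm = TRUE))
  expect_error(error_rate_robustness(sl, rates = 0.01), "at least 2")
})
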
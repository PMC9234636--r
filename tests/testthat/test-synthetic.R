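small_cfg <- function(...) {
  do.call(sim_config, modifyList(
    list(n_pops_east = 3, n_pops_west = 3, n_individuals = 90,
         n_loci = 5, alleles_per_locus = 8, n_singletons = 3),
    list(...)))
}

test_that("equal seeds give bit-identical simulated data", {
  a <- simulate_metapopulation(small_cfg(), seed = 17)
  b <- simulate_metapopulation(small_cfg(), seed = 17)
  expect_identical(a$a1, b$a1)
  expect_identical(a$a2, b$a2)
  expect_identical(a$meta, b$meta)
  ex_a <- simulate_ex_situ(a, seed = 4)
  ex_b <- simulate_ex_situ(b, seed = 4)
  expect_identical(ex_a$a1, ex_b$a1)
  la <- simulate_landscape(a, ex_a, seed = 9)
  lb <- simulate_landscape(b, ex_b, seed = 9)
  expect_identical(la$occurrences, lb$occurrences)
  expect_identical(la$layer, lb$layer)
  # a different seed changes the draw
  c <- simulate_metapopulation(small_cfg(), seed = 18)
  expect_false(identical(a$a1, c$a1))
})

test_that("missing-data rate is recovered within binomial error", {
  cfg <- small_cfg(missing_rate = 0.026)
  rate <- 0.026
  n_calls <- cfg$n_individuals * cfg$n_loci
  se <- sqrt(rate * (1 - rate) / n_calls)
  rates <- vapply(1:6, function(s)
    missing_rate(simulate_metapopulation(cfg, seed = s)), numeric(1))
  expect_lt(abs(mean(rates) - rate), 3 * se / sqrt(6))
  cfg0 <- small_cfg(missing_rate = 0)
  expect_equal(missing_rate(simulate_metapopulation(cfg0, seed = 1)), 0)
})

test_that("zero divergence reproduces the base frequencies at large n", {
  cfg <- sim_config(n_pops_east = 1, n_pops_west = 1, n_individuals = 500,
                    n_loci = 4, alleles_per_locus = 6, divergence = 0,
                    pop_divergence = 0, missing_rate = 0, n_singletons = 0)
  gm <- simulate_metapopulation(cfg, seed = 31)
  freqs <- attr(gm, "pop_freqs")
  one_pop <- gm[gm$meta$population == "E01"]
  n_copies <- 2 * n_individuals(one_pop)
  for (l in seq_len(n_loci(gm))) {
    base <- freqs[[l]][, 1]   # with d = f = 0 every column equals the base
    expect_equal(freqs[[l]][, 1], freqs[[l]][, 2])
    codes <- 100L + 2L * seq_along(base)
    realized <- vapply(codes, function(v)
      (sum(one_pop$a1[, l] == v) + sum(one_pop$a2[, l] == v)) / n_copies,
      numeric(1))
    se <- sqrt(base * (1 - base) / n_copies)
    expect_true(all(abs(realized - base) <= 3 * se + 1e-12))
  }
})

test_that("singleton injection produces exact single copies", {
  cfg <- small_cfg(n_singletons = 5, missing_rate = 0)
  gm <- simulate_metapopulation(cfg, seed = 12)
  cat <- build_catalog(gm)
  injected <- cat[cat$allele > 100 + 2 * cfg$alleles_per_locus, ]
  expect_equal(nrow(injected), 5L)
  expect_true(all(injected$count == 1L))
})

test_that("ex situ seedlings obey half-sib Mendelian inheritance", {
  in_situ <- simulate_metapopulation(small_cfg(missing_rate = 0), seed = 3)
  ex <- simulate_ex_situ(in_situ, seed = 6, missing_rate = 0)
  mothers <- attr(ex, "mothers")
  for (i in seq_len(n_individuals(ex))) {
    fam <- ex$meta$maternal_line[i]
    mom <- in_situ[mothers[[fam]]]
    for (l in seq_len(n_loci(ex))) {
      if (is.na(ex$a1[i, l]) || is.na(mom$a1[1, l])) next
      shared <- length(intersect(c(ex$a1[i, l], ex$a2[i, l]),
                                 c(mom$a1[1, l], mom$a2[1, l])))
      expect_gte(shared, 1)
    }
  }
  # garden / source-population metadata round to the design
  expect_true(all(!is.na(ex$meta$garden)))
  expect_true(all(!is.na(ex$meta$source_population)))
  expect_true(all(ex$meta$cohort == "ex_situ"))
})

test_that("maternal alleles segregate 1:1 in large families", {
  # every wild plant heterozygous 1/2, so whichever mother is drawn the
  # maternal contribution is Bernoulli(1/2) and the pollen pool is 50:50:
  # copies of allele 1 per seed are Bern(.5) + Bern(.5) with mean 1
  a1 <- matrix(1L, 4, 1)
  a2 <- matrix(2L, 4, 1)
  rownames(a1) <- rownames(a2) <- paste0("m", 1:4)
  wild <- make_gm_from_matrices(a1, a2, population = "P1", region = "East")
  des <- data.frame(family = "F1", source_population = "P1", garden = "GA",
                    n_seeds = 1000L, stringsAsFactors = FALSE)
  attr(des, "germination_rate") <- 1.0
  class(des) <- c("ex_situ_design", "data.frame")
  ex <- simulate_ex_situ(wild, design = des, seed = 44, missing_rate = 0)
  expect_equal(n_individuals(ex), 1000L)
  copies1 <- (ex$a1[, 1] == 1L) + (ex$a2[, 1] == 1L)
  se <- sqrt(0.5 / 1000)   # var of Bern(.5) + Bern(.5) is 0.5
  expect_lt(abs(mean(copies1) - 1), 3 * se)
})

test_that("an empty design yields an empty ex situ cohort", {
  wild <- simulate_metapopulation(small_cfg(), seed = 2)
  des <- data.frame(family = "F1", source_population = "E01", garden = "GA",
                    n_seeds = 0L, stringsAsFactors = FALSE)
  class(des) <- c("ex_situ_design", "data.frame")
  ex <- simulate_ex_situ(wild, design = des, seed = 1)
  expect_equal(n_individuals(ex), 0L)
})

test_that("family requests beyond a population's mothers are rejected", {
  wild <- simulate_metapopulation(sim_config(
    n_pops_east = 1, n_pops_west = 1, n_individuals = 4, n_loci = 2,
    alleles_per_locus = 4, n_singletons = 0), seed = 5)
  des <- data.frame(family = sprintf("F%d", 1:5),
                    source_population = "E01", garden = "GA",
                    n_seeds = 1L, stringsAsFactors = FALSE)
  class(des) <- c("ex_situ_design", "data.frame")
  expect_error(simulate_ex_situ(wild, design = des, seed = 1),
               "families requested")
})

test_that("intense sampling of every population captures all common alleles", {
  # ex situ sampling every population at high intensity: very common
  # alleles are always fully captured
  for (s in 1:10) {
    wild <- simulate_metapopulation(sim_config(
      n_pops_east = 2, n_pops_west = 2, n_individuals = 80, n_loci = 4,
      alleles_per_locus = 6, n_singletons = 2), seed = s)
    des <- ex_situ_design(wild, n_gardens = 2,
                          source_pops = c(East = 2, West = 2),
                          families = c(East = 30, West = 30),
                          seeds = c(East = 120, West = 120), seed = s)
    ex <- simulate_ex_situ(wild, design = des, seed = s)
    gm <- combine_cohorts(wild, ex)
    rep <- overall_capture(gm, "full")
    vc <- rep[rep$class == "very_common", ]
    expect_equal(vc$percent, 100)
  }
})
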
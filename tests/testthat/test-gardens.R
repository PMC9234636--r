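test_that("garden summaries match hand-counted set intersections", {
  # 3 gardens with known allele holdings against a 4-allele reference
  gm <- make_gm(
    list(w1 = "1/2", w2 = "3/4",
         g1 = "1/1", g2 = "1/2", g3 = "3/3", g4 = "1/4"),
    population = c("P1", "P1", "GA", "GA", "GB", "GC"),
    region = "East",
    cohort = c("in_situ", "in_situ", rep("ex_situ", 4)),
    garden = c(NA, NA, "GA", "GA", "GB", "GC"),
    maternal_line = c(NA, NA, "F1", "F2", "F3", "F4"),
    source_population = c(NA, NA, "P1", "P1", "P1", "P1"))
  ref <- classify_alleles(build_catalog(gm, 1:2))
  summ <- garden_summaries(gm, ref)
  got <- setNames(summ$pct_all, summ$garden)
  # GA holds {1,2} of {1,2,3,4} = 50%; GB {3} = 25%; GC {1,4} = 50%
  expect_equal(got[["GA"]], 50)
  expect_equal(got[["GB"]], 25)
  expect_equal(got[["GC"]], 50)
  expect_equal(summ$n_plants, c(2L, 1L, 1L))
  expect_equal(summ$n_accessions, c(2L, 1L, 1L))

  # pooled ex situ capture dominates every single garden per class
  pooled <- capture_report(ref, gm, 3:6)
  for (g in summ$garden) {
    r <- attr(summ, "reports")[[g]]
    ok <- r$total > 0
    expect_true(all(pooled$percent[ok] >= r$percent[ok]))
  }

  # a garden holding the full reference set captures 100% everywhere
  gm2 <- make_gm(
    list(w1 = "1/2", g1 = "1/2"),
    population = c("P1", "GA"), region = "East",
    cohort = c("in_situ", "ex_situ"), garden = c(NA, "GA"),
    maternal_line = c(NA, "F1"), source_population = c(NA, "P1"))
  ref2 <- classify_alleles(build_catalog(gm2, 1))
  s2 <- garden_summaries(gm2, ref2)
  expect_equal(s2$pct_all, 100)
})

test_that("transform regressions match exact and hand-solved fits", {
  # data exactly linear in sqrt(x): sqrt transform attains adjusted R^2 = 1
  summ <- data.frame(garden = paste0("G", 1:5),
                     n_plants = c(4, 9, 16, 36, 64),
                     n_accessions = c(2, 3, 4, 6, 8),
                     n_populations = c(1, 2, 3, 4, 5))
  summ$pct_all <- 10 + 7 * sqrt(summ$n_plants)
  # lm warns about the deliberately perfect fit
  tr <- suppressWarnings(fit_transform_regressions(summ, "n_plants", "all"))
  sq <- tr[tr$transform == "sqrt", ]
  expect_equal(sq$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(sq$slope, 7, tolerance = 1e-9)
  expect_equal(attr(tr, "best"), "sqrt")

  # 4-point fixture: identity-transform coefficients from normal equations
  summ4 <- data.frame(garden = paste0("G", 1:4),
                      n_plants = c(5, 10, 20, 40),
                      n_accessions = 1:4, n_populations = 1:4,
                      pct_all = c(30, 52, 64, 81))
  x <- summ4$n_plants
  y <- summ4$pct_all
  slope <- (sum(x * y) - 4 * mean(x) * mean(y)) / (sum(x^2) - 4 * mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  adj <- 1 - (1 - r2) * (4 - 1) / (4 - 1 - 1)
  tr4 <- fit_transform_regressions(summ4, "n_plants", "all")
  id <- tr4[tr4$transform == "identity", ]
  expect_equal(id$slope, slope, tolerance = 1e-12)
  expect_equal(id$intercept, intercept, tolerance = 1e-12)
  expect_equal(id$adj_r_squared, adj, tolerance = 1e-12)

  summ4$n_populations[1] <- 0
  expect_error(fit_transform_regressions(summ4, "n_populations", "all"),
               "log transform")
  expect_error(fit_transform_regressions(summ4[1:2, ], "n_plants"),
               "at least 3")
})

test_that("pairwise theta hits the textbook anchors", {
  # two cohorts fixed for different alleles at every locus: theta = 1
  gm <- make_gm_from_matrices(
    a1 = matrix(rep(c(1L, 2L), c(5, 5)), 10, 3),
    a2 = matrix(rep(c(1L, 2L), c(5, 5)), 10, 3),
    population = rep(c("A", "B"), each = 5))
  expect_equal(as.numeric(pairwise_fst(gm, 1:5, 6:10)), 1)

  # identical cohorts of n >= 50: |theta| < 0.02
  set.seed(42)
  big <- make_gm_from_matrices(
    a1 = matrix(sample.int(5, 60 * 4, TRUE), 60, 4),
    a2 = matrix(sample.int(5, 60 * 4, TRUE), 60, 4),
    population = "A")
  expect_lt(abs(as.numeric(pairwise_fst(big, 1:60, 1:60))), 0.02)

  # symmetry and allele-relabeling invariance
  gm2 <- random_two_pop_gm(7)
  t_ab <- as.numeric(pairwise_fst(gm2, 1:8, 9:18))
  t_ba <- as.numeric(pairwise_fst(gm2, 9:18, 1:8))
  expect_identical(t_ab, t_ba)
  relab <- gm2
  relab$a1 <- relab$a1 * 10L
  relab$a2 <- relab$a2 * 10L
  expect_equal(as.numeric(pairwise_fst(relab, 1:8, 9:18)), t_ab,
               tolerance = 1e-12)
  # locus-order invariance
  perm <- gm2
  ord <- c(3, 1, 4, 2)
  perm$a1 <- perm$a1[, ord]
  perm$a2 <- perm$a2[, ord]
  expect_equal(as.numeric(pairwise_fst(perm, 1:8, 9:18)), t_ab,
               tolerance = 1e-12)

  mono <- make_gm_from_matrices(
    a1 = matrix(1L, 6, 2), a2 = matrix(1L, 6, 2),
    population = rep(c("A", "B"), each = 3))
  expect_error(pairwise_fst(mono, 1:3, 4:6), "polymorphic")
})

test_that("theta agrees with the independent ANOVA-form oracle to 1e-12", {
  for (s in 1:20) {
    gm <- random_two_pop_gm(s, n1 = 5 + s %% 4, n2 = 7 + s %% 3,
                            L = 3 + s %% 3, k = 3 + s %% 4)
    n1 <- sum(gm$meta$population == "A")
    idx1 <- seq_len(n1)
    idx2 <- seq(n1 + 1, n_individuals(gm))
    expect_equal(as.numeric(pairwise_fst(gm, idx1, idx2)),
                 wc84_oracle(gm, idx1, idx2), tolerance = 1e-12)
  }
})

test_that("fst_contrast pairs gardens with regions and degenerate t is handled", {
  sim <- simulate_dataset(seed = 5, config = sim_config(
    n_pops_east = 3, n_pops_west = 3, n_individuals = 120, n_loci = 5,
    alleles_per_locus = 8, n_singletons = 2),
    design = NULL)
  fc <- fst_contrast(sim$genotypes)
  expect_equal(nrow(fc$table), length(unique(
    sim$ex_situ$meta$garden)))
  # paired-t arithmetic recomputed from the table (textbook formula)
  d <- fc$table$fst_west - fc$table$fst_east
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  pval <- 2 * pt(-abs(tstat), df = length(d) - 1)
  expect_equal(fc$t_statistic, tstat, tolerance = 1e-12)
  expect_equal(fc$p_value, pval, tolerance = 1e-12)

  # identical East/West in situ pools give identical vectors: t = 0, p = 1
  base <- make_gm_from_matrices(
    a1 = matrix(sample.int(4, 40, TRUE), 10, 4),
    a2 = matrix(sample.int(4, 40, TRUE), 10, 4),
    population = "E1")
  twin <- base
  rownames(twin$a1) <- rownames(twin$a2) <- paste0("w", 1:10)
  twin$meta$id <- paste0("w", 1:10)
  twin$meta$population <- "W1"
  twin$meta$region <- "West"
  ga1 <- matrix(sample.int(4, 32, TRUE), 8, 4)
  ga2 <- matrix(sample.int(4, 32, TRUE), 8, 4)
  rownames(ga1) <- rownames(ga2) <- paste0("g", 1:8)
  gardens <- make_gm_from_matrices(
    a1 = ga1, a2 = ga2,
    population = rep(c("GA", "GB"), each = 4), cohort = "ex_situ")
  gardens$meta$garden <- gardens$meta$population
  gardens$meta$source_population <- "E1"
  allgm <- combine_cohorts(combine_cohorts(base, twin), gardens)
  fc2 <- fst_contrast(allgm)
  expect_identical(fc2$t_statistic, 0)
  expect_identical(fc2$p_value, 1)
})
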
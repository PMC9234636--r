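#' Simulation configuration for a two-region metapopulation
#'
#' Defaults emulate the structure of a range-wide microsatellite survey of a
#' disjunct shrub oak: roughly 667 wild individuals across 35 populations in
#' two diverged regions, 11 loci with a skewed allele-frequency spectrum,
#' about 2.6% missing calls, and a handful of injected singleton alleles so
#' the ultra-rare boundary of the reduced catalog is exercised.
#'
#' @param n_pops_east,n_pops_west populations per region
#' @param n_individuals total in situ individuals (spread evenly over
#'   populations)
#' @param n_loci number of microsatellite loci
#' @param alleles_per_locus candidate alleles per locus
#' @param allele_freq_alpha Dirichlet concentration for the base frequency
#'   spectrum (small values give many rare alleles)
#' @param divergence drift magnitude separating region-level frequencies
#'   from the species base (0 = panmictic regions)
#' @param pop_divergence drift magnitude separating populations within a
#'   region
#' @param missing_rate per-call missing probability
#' @param n_singletons ultra-rare alleles injected as exact single copies
#' @return a `sim_config` list
#' @export
sim_config <- function(n_pops_east = 18L, n_pops_west = 17L,
                       n_individuals = 667L, n_loci = 11L,
                       alleles_per_locus = 50L, allele_freq_alpha = 0.18,
                       divergence = 0.03, pop_divergence = 0.08,
                       missing_rate = 0.026, n_singletons = 20L) {
  cfg <- list(n_pops_east = as.integer(n_pops_east),
              n_pops_west = as.integer(n_pops_west),
              n_individuals = as.integer(n_individuals),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              allele_freq_alpha = allele_freq_alpha,
              divergence = divergence,
              pop_divergence = pop_divergence,
              missing_rate = missing_rate,
              n_singletons = as.integer(n_singletons))
  if (any(unlist(cfg[1:5]) <= 0L)) stop("all counts must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (cfg$divergence < 0 || cfg$pop_divergence < 0)
    stop("divergence parameters must be >= 0")
  if (cfg$alleles_per_locus < 2L && cfg$divergence > 0)
    stop("need at least 2 alleles per locus when divergence > 0")
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  g / sum(g)
}

# drift surrogate: Dirichlet draw centered on parent frequencies with
# concentration (1 - d) / d (Balding-Nichols parameterisation); d = 0 copies
# the parent exactly
drift_freqs <- function(parent, d) {
  if (d <= 0) return(parent)
  rdirichlet1(parent * (1 - d) / d)
}

distribute_evenly <- function(total, k) {
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0L) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

stage_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Simulate a two-region in situ metapopulation
#'
#' Hierarchical drift model: per locus a skewed base frequency spectrum is
#' drawn, perturbed once per region (drift magnitude `divergence`) and again
#' per population (`pop_divergence`); diploid genotypes are then sampled
#' under random mating within populations. Missing calls are injected at the
#' configured rate and `n_singletons` new alleles are injected as exact
#' single copies (each replaces one allele copy of a random individual). All
#' randomness flows from `seed` through named per-stage substreams, so equal
#' seeds give bit-identical cohorts.
#'
#' @param config a [sim_config()]
#' @param seed integer RNG seed
#' @return an in situ [genotype_matrix()] with populations `E01..`/`W01..`,
#'   regions set, and cohort `"in_situ"`; the per-population allele
#'   frequencies used are attached as attribute `pop_freqs`
#' @export
simulate_metapopulation <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  ss <- stage_seeds(seed, 4L)
  n_pops <- cfg$n_pops_east + cfg$n_pops_west
  pop_names <- c(sprintf("E%02d", seq_len(cfg$n_pops_east)),
                 sprintf("W%02d", seq_len(cfg$n_pops_west)))
  pop_region <- rep(c("East", "West"), c(cfg$n_pops_east, cfg$n_pops_west))
  pop_sizes <- distribute_evenly(cfg$n_individuals, n_pops)
  codes <- 100L + 2L * seq_len(cfg$alleles_per_locus)

  # stage 1: hierarchical allele frequencies
  set.seed(ss[1])
  pop_freqs <- vector("list", cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    base <- rdirichlet1(rep(cfg$allele_freq_alpha, cfg$alleles_per_locus))
    reg <- list(East = drift_freqs(base, cfg$divergence),
                West = drift_freqs(base, cfg$divergence))
    pop_freqs[[l]] <- vapply(seq_len(n_pops), function(p)
      drift_freqs(reg[[pop_region[p]]], cfg$pop_divergence),
      numeric(cfg$alleles_per_locus))
  }

  # stage 2: diploid genotypes under random mating within populations
  set.seed(ss[2])
  n <- cfg$n_individuals
  a1 <- matrix(NA_integer_, n, cfg$n_loci)
  a2 <- matrix(NA_integer_, n, cfg$n_loci)
  pop_of <- rep(seq_len(n_pops), pop_sizes)
  for (l in seq_len(cfg$n_loci)) {
    for (p in seq_len(n_pops)) {
      rows <- which(pop_of == p)
      draws <- sample(codes, 2L * length(rows), replace = TRUE,
                      prob = pop_freqs[[l]][, p])
      a1[rows, l] <- draws[seq_along(rows)]
      a2[rows, l] <- draws[length(rows) + seq_along(rows)]
    }
  }

  # stage 3: missing calls
  set.seed(ss[3])
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n * cfg$n_loci) < cfg$missing_rate, n)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }

  # stage 4: ultra-rare singleton injection (unique new code per injection,
  # so each injected allele occurs exactly once)
  set.seed(ss[4])
  if (cfg$n_singletons > 0L) {
    new_code <- max(codes) + 2L * seq_len(cfg$n_singletons)
    for (k in seq_len(cfg$n_singletons)) {
      repeat {
        i <- sample.int(n, 1L)
        l <- sample.int(cfg$n_loci, 1L)
        if (!is.na(a1[i, l])) break
      }
      a2[i, l] <- new_code[k]
    }
  }

  ids <- sprintf("I%04d", seq_len(n))
  dimnames(a1) <- dimnames(a2) <- list(ids, sprintf("loc%02d",
                                                    seq_len(cfg$n_loci)))
  meta <- data.frame(id = ids,
                     population = pop_names[pop_of],
                     region = pop_region[pop_of],
                     cohort = "in_situ",
                     garden = NA_character_,
                     maternal_line = NA_character_,
                     source_population = NA_character_,
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(a1, a2, meta)
  attr(gm, "pop_freqs") <- pop_freqs
  attr(gm, "seed") <- seed
  gm
}

#' Ex situ collection design
#'
#' Describes which wild populations were seed-sourced, how many maternal
#' families came from each, how many seedlings each family contributed, and
#' which garden holds each family. The defaults emulate a garden network of 8
#' institutions holding ~290 seedlings from 66 maternal families out of 26
#' source populations, with the western region under-collected (53 of 290
#' seedlings), and unequal garden sizes.
#'
#' @param in_situ the in situ [genotype_matrix()] seeds are sourced from
#' @param n_gardens number of gardens (labelled `GA`, `GB`, ...)
#' @param source_pops per-region count of seed-sourced populations,
#'   named `East`/`West`
#' @param families per-region count of maternal families
#' @param seeds per-region count of seedlings
#' @param garden_weights relative garden sizes (recycled/normalised)
#' @param germination_rate probability a requested seedling survives
#' @param seed RNG seed for the design draw
#' @return an `ex_situ_design`: data frame with one row per family
#'   (`family, source_population, garden, n_seeds`) plus attribute
#'   `germination_rate`
#' @export
ex_situ_design <- function(in_situ, n_gardens = 8L,
                           source_pops = c(East = 17L, West = 9L),
                           families = c(East = 50L, West = 16L),
                           seeds = c(East = 237L, West = 53L),
                           garden_weights = c(80, 62, 45, 35, 25, 22, 12, 9),
                           germination_rate = 1.0, seed = 1L) {
  set.seed(seed)
  meta <- in_situ$meta
  gardens <- paste0("G", LETTERS[seq_len(n_gardens)])
  gw <- rep_len(garden_weights, n_gardens)
  rows <- list()
  for (reg in names(source_pops)) {
    pops_avail <- unique(meta$population[meta$region %in% reg])
    k <- min(source_pops[[reg]], length(pops_avail))
    if (k < 1L) stop("region ", reg, " has no populations to source from")
    chosen <- sample(pops_avail, k)
    # capacity-aware allocation: a population cannot supply more maternal
    # families than it has individuals; small cohorts shrink the family
    # count instead of failing
    cap <- vapply(chosen, function(p) sum(meta$population == p), integer(1))
    n_fam <- min(families[[reg]], sum(cap))
    if (n_fam < k) {
      chosen <- chosen[seq_len(n_fam)]
      cap <- cap[seq_len(n_fam)]
      k <- n_fam
    }
    # every chosen population contributes >= 1 family, then fill remaining
    # capacity at random
    fam_pop <- chosen
    cap <- cap - 1L
    while (length(fam_pop) < n_fam) {
      open <- which(cap > 0L)
      p <- if (length(open) == 1L) open else
        sample(open, 1L, prob = cap[open])
      fam_pop <- c(fam_pop, chosen[p])
      cap[p] <- cap[p] - 1L
    }
    # every family contributes >= 1 seedling
    n_seed <- max(seeds[[reg]], n_fam)
    fam_seeds <- 1L + as.integer(rmultinom(1, n_seed - n_fam,
                                           rep(1, n_fam)))
    fam_garden <- sample(gardens, n_fam, replace = TRUE, prob = gw)
    rows[[reg]] <- data.frame(family = NA_character_,
                              source_population = fam_pop,
                              garden = fam_garden,
                              n_seeds = fam_seeds,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$family <- sprintf("F%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out, germination_rate = germination_rate,
            class = c("ex_situ_design", "data.frame"))
}

#' Simulate an ex situ seedling cohort of half-sib maternal families
#'
#' Each maternal family picks a distinct mother from its source population;
#' every seedling inherits one maternal allele (uniform over the mother's
#' two) and one paternal allele drawn from the source population's pooled
#' non-missing allele copies (open pollination), so seedlings within a
#' family are at least half-sibs. Seedlings are thinned by the design's
#' germination rate and missing calls injected at `missing_rate`.
#'
#' @param in_situ the in situ [genotype_matrix()]
#' @param design an [ex_situ_design()]; defaults to `ex_situ_design(in_situ,
#'   seed = seed)`
#' @param seed RNG seed
#' @param missing_rate per-call missing probability for the seedlings
#' @return an ex situ [genotype_matrix()] with garden, maternal line, source
#'   population, and region (of the source population) filled in
#' @export
simulate_ex_situ <- function(in_situ, design = NULL, seed = 1L,
                             missing_rate = 0.026) {
  ss <- stage_seeds(seed + 1L, 3L)
  design <- design %||% ex_situ_design(in_situ, seed = ss[1])
  meta <- in_situ$meta
  set.seed(ss[2])
  # distinct mothers per population across that population's families
  mothers <- character(nrow(design))
  for (p in unique(design$source_population)) {
    fam_rows <- which(design$source_population == p)
    avail <- which(meta$population == p)
    if (length(fam_rows) > length(avail))
      stop("population ", p, " has ", length(avail),
           " individuals but ", length(fam_rows), " families requested")
    mothers[fam_rows] <- individuals(in_situ)[sample(avail,
                                                     length(fam_rows))]
  }
  # pooled non-missing allele copies per population x locus (pollen pool)
  pool <- lapply(seq_len(n_loci(in_situ)), function(l) {
    lapply(split(seq_len(n_individuals(in_situ)), meta$population),
           function(rows) {
             v <- c(in_situ$a1[rows, l], in_situ$a2[rows, l])
             v[!is.na(v)]
           })
  })
  reg_of_pop <- source_region_map(in_situ)
  germ <- attr(design, "germination_rate") %||% 1.0
  blocks_a1 <- list()
  blocks_a2 <- list()
  blocks_meta <- list()
  for (f in seq_len(nrow(design))) {
    n_seeds <- if (germ >= 1.0) design$n_seeds[f] else
      sum(rbinom(design$n_seeds[f], 1L, germ))
    if (n_seeds == 0L) next
    mom <- in_situ[mothers[f]]
    p <- design$source_population[f]
    g1 <- matrix(NA_integer_, n_seeds, n_loci(in_situ))
    g2 <- matrix(NA_integer_, n_seeds, n_loci(in_situ))
    for (l in seq_len(n_loci(in_situ))) {
      pl <- pool[[l]][[p]]
      if (!length(pl)) stop("no allele copies at locus ", l,
                            " in population ", p)
      m1 <- mom$a1[1, l]
      m2 <- mom$a2[1, l]
      g1[, l] <- if (is.na(m1)) sample(pl, n_seeds, replace = TRUE)
      else sample(c(m1, m2), n_seeds, replace = TRUE)
      g2[, l] <- sample(pl, n_seeds, replace = TRUE)
    }
    blocks_a1[[length(blocks_a1) + 1L]] <- g1
    blocks_a2[[length(blocks_a2) + 1L]] <- g2
    blocks_meta[[length(blocks_meta) + 1L]] <- data.frame(
      population = rep(design$garden[f], n_seeds),
      region = unname(reg_of_pop[p]),
      cohort = "ex_situ",
      garden = design$garden[f],
      maternal_line = design$family[f],
      source_population = p,
      stringsAsFactors = FALSE)
  }
  if (!length(blocks_a1)) {
    empty <- matrix(NA_integer_, 0, n_loci(in_situ),
                    dimnames = list(NULL, loci(in_situ)))
    return(structure(list(a1 = empty, a2 = empty,
                          meta = complete_meta(NULL, character(0))),
                     class = "genotype_matrix"))
  }
  a1 <- do.call(rbind, blocks_a1)
  a2 <- do.call(rbind, blocks_a2)
  md <- do.call(rbind, blocks_meta)
  set.seed(ss[3])
  if (missing_rate > 0) {
    miss <- matrix(runif(length(a1)) < missing_rate, nrow(a1))
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  ids <- sprintf("X%04d", seq_len(nrow(a1)))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci(in_situ))
  md <- cbind(id = ids, md)
  out <- genotype_matrix(a1, a2, md)
  attr(out, "mothers") <- setNames(mothers, design$family)
  out
}

#' Simulate occurrence points and a grid ecoregion mosaic
#'
#' Places each wild population at a random point inside its region's
#' bounding box (two disjoint boxes emulate an East/West range disjunction),
#' scatters extra in situ occurrence records around the population centres,
#' flags the seed-sourced populations' points as ex situ source localities,
#' and lays a rectangular two-level ecoregion mosaic over the range: coarse
#' Level-III cells, each subdivided into Level-IV cells.
#'
#' @param in_situ the in situ [genotype_matrix()]
#' @param ex_situ optional ex situ cohort; its source populations become the
#'   ex situ source points (default: none, in situ points only)
#' @param seed RNG seed
#' @param n_extra_per_pop extra in situ records scattered near each
#'   population centre
#' @param l3_grid Level-III grid dimension `c(ncol, nrow)` over the range
#' @param l4_subdiv each Level-III cell is split into `l4_subdiv^2`
#'   Level-IV cells
#' @return list with `occurrences` (an [occurrence_set()]), `layer` (an
#'   [ecoregion_layer()]), and `pop_coords` (population centres)
#' @export
simulate_landscape <- function(in_situ, ex_situ = NULL, seed = 1L,
                               n_extra_per_pop = 6L, l3_grid = c(4L, 3L),
                               l4_subdiv = 2L) {
  set.seed(seed)
  meta <- in_situ$meta
  pops <- unique(meta[, c("population", "region")])
  boxes <- list(West = list(lon = c(-110.5, -106.5), lat = c(33.5, 37.5)),
                East = list(lon = c(-104.5, -100.0), lat = c(31.5, 35.5)))
  coords <- t(vapply(seq_len(nrow(pops)), function(i) {
    b <- boxes[[pops$region[i]]]
    c(runif(1, b$lon[1], b$lon[2]), runif(1, b$lat[1], b$lat[2]))
  }, numeric(2)))
  pop_coords <- data.frame(population = pops$population,
                           region = pops$region,
                           lon = coords[, 1], lat = coords[, 2],
                           stringsAsFactors = FALSE)
  occ <- data.frame(lon = pop_coords$lon, lat = pop_coords$lat,
                    role = "in_situ", region = pop_coords$region,
                    stringsAsFactors = FALSE)
  if (n_extra_per_pop > 0L) {
    extra <- do.call(rbind, lapply(seq_len(nrow(pop_coords)), function(i) {
      data.frame(lon = pop_coords$lon[i] + runif(n_extra_per_pop, -0.6, 0.6),
                 lat = pop_coords$lat[i] + runif(n_extra_per_pop, -0.6, 0.6),
                 role = "in_situ", region = pop_coords$region[i],
                 stringsAsFactors = FALSE)
    }))
    occ <- rbind(occ, extra)
  }
  if (!is.null(ex_situ)) {
    src <- unique(ex_situ$meta$source_population)
    src <- src[!is.na(src)]
    hit <- pop_coords$population %in% src
    if (any(hit)) {
      occ <- rbind(occ, data.frame(lon = pop_coords$lon[hit],
                                   lat = pop_coords$lat[hit],
                                   role = "ex_situ_source",
                                   region = pop_coords$region[hit],
                                   stringsAsFactors = FALSE))
    }
  }
  occ <- occurrence_set(occ)

  margin <- 0.3
  lon_rng <- range(occ$lon) + c(-margin, margin)
  lat_rng <- range(occ$lat) + c(-margin, margin)
  nx <- l3_grid[1]
  ny <- l3_grid[2]
  xs <- seq(lon_rng[1], lon_rng[2], length.out = nx + 1L)
  ys <- seq(lat_rng[1], lat_rng[2], length.out = ny + 1L)
  l3 <- character(0)
  l4 <- character(0)
  polys <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      id3 <- sprintf("L3-%d-%d", i, j)
      sx <- seq(xs[i], xs[i + 1L], length.out = l4_subdiv + 1L)
      sy <- seq(ys[j], ys[j + 1L], length.out = l4_subdiv + 1L)
      for (u in seq_len(l4_subdiv)) {
        for (v in seq_len(l4_subdiv)) {
          ring <- rbind(c(sx[u], sy[v]), c(sx[u + 1L], sy[v]),
                        c(sx[u + 1L], sy[v + 1L]), c(sx[u], sy[v + 1L]))
          l3 <- c(l3, id3)
          l4 <- c(l4, sprintf("%s-%d-%d", id3, u, v))
          polys[[length(polys) + 1L]] <- list(ring)
        }
      }
    }
  }
  list(occurrences = occ, layer = ecoregion_layer(l3, l4, polys),
       pop_coords = pop_coords)
}

#' Simulate a complete audit dataset
#'
#' One-call generator for the default study conditions: in situ
#' metapopulation, half-sib ex situ cohort, combined genotype matrix, and
#' the occurrence/ecoregion landscape.
#'
#' @param seed integer RNG seed
#' @param config a [sim_config()]
#' @param design optional [ex_situ_design()]
#' @return list with `genotypes` (combined [genotype_matrix()]), `in_situ`,
#'   `ex_situ`, `occurrences`, `layer`
#' @export
simulate_dataset <- function(seed = 1L, config = sim_config(),
                             design = NULL) {
  ss <- stage_seeds(seed + 7L, 3L)
  in_situ <- simulate_metapopulation(config, seed = ss[1])
  ex_situ <- simulate_ex_situ(in_situ, design = design, seed = ss[2],
                              missing_rate = config$missing_rate)
  land <- simulate_landscape(in_situ, ex_situ, seed = ss[3])
  list(genotypes = combine_cohorts(in_situ, ex_situ),
       in_situ = in_situ, ex_situ = ex_situ,
       occurrences = land$occurrences, layer = land$layer)
}
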
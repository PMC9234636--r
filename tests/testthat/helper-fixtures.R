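# Shared fixtures and independent oracles for the test suite.

# Build a small genotype_matrix from a list of per-individual genotype
# strings, one string per locus: "a/b" or "NA".
make_gm <- function(genotypes, population = NULL, region = NULL,
                    cohort = NULL, garden = NULL, maternal_line = NULL,
                    source_population = NULL) {
  n <- length(genotypes)
  L <- length(genotypes[[1]])
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (l in seq_len(L)) {
    g <- genotypes[[i]][l]
    if (!is.na(g) && g != "NA") {
      ab <- as.integer(strsplit(g, "/")[[1]])
      a1[i, l] <- ab[1]
      a2[i, l] <- ab[2]
    }
  }
  ids <- names(genotypes) %||% paste0("i", seq_len(n))
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- paste0("L", seq_len(L))
  meta <- data.frame(
    id = ids,
    population = population %||% rep("p1", n),
    region = region %||% rep("East", n),
    cohort = cohort %||% rep("in_situ", n),
    garden = garden %||% rep(NA_character_, n),
    maternal_line = maternal_line %||% rep(NA_character_, n),
    source_population = source_population %||% rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  genotype_matrix(a1, a2, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_genepop_text <- function(lines, path = tempfile(fileext = ".gen")) {
  writeLines(lines, path)
  path
}

# Independent Weir-Cockerham (1984) theta oracle via the nested ANOVA
# mean-squares formulation (gametes within individuals within populations):
#   c = MSG, b = (MSI - MSG) / 2, a = (MSP - MSI) / (2 n_c)
# summed over alleles and loci. Deliberately different algebra from the
# package's direct variance-component transcription.
wc84_oracle <- function(gm, idx1, idx2) {
  A <- gm[idx1]
  B <- gm[idx2]
  num <- 0
  den <- 0
  for (l in seq_len(n_loci(gm))) {
    x1a <- A$a1[, l]; x1b <- A$a2[, l]
    x2a <- B$a1[, l]; x2b <- B$a2[, l]
    k1 <- which(!is.na(x1a)); k2 <- which(!is.na(x2a))
    n1 <- length(k1); n2 <- length(k2)
    if (n1 < 1 || n2 < 1) next
    alleles <- unique(c(x1a[k1], x1b[k1], x2a[k2], x2b[k2]))
    if (length(alleles) < 2) next
    r <- 2
    nsum <- n1 + n2
    nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
    for (v in alleles) {
      # allele-copy counts per individual (0, 1, 2)
      cnt1 <- (x1a[k1] == v) + (x1b[k1] == v)
      cnt2 <- (x2a[k2] == v) + (x2b[k2] == v)
      p1 <- sum(cnt1) / (2 * n1)
      p2 <- sum(cnt2) / (2 * n2)
      pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * nsum)
      ssp <- 2 * n1 * (p1 - pbar)^2 + 2 * n2 * (p2 - pbar)^2
      ssi <- sum(2 * (cnt1 / 2 - p1)^2) + sum(2 * (cnt2 / 2 - p2)^2)
      ssg <- (sum(cnt1 == 1) + sum(cnt2 == 1)) / 2
      msp <- ssp / (r - 1)
      msi <- ssi / (nsum - r)
      msg <- ssg / nsum
      cc <- msg
      b <- (msi - msg) / 2
      a <- (msp - msi) / (2 * nc)
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# random two-population diploid fixture for FST checks
random_two_pop_gm <- function(seed, n1 = 8, n2 = 10, L = 4, k = 4,
                              miss = 0.05) {
  set.seed(seed)
  n <- n1 + n2
  a1 <- matrix(sample.int(k, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample.int(k, n * L, replace = TRUE), n, L)
  drop <- matrix(runif(n * L) < miss, n, L)
  a1[drop] <- NA_integer_
  a2[drop] <- NA_integer_
  rownames(a1) <- rownames(a2) <- paste0("r", seq_len(n))
  make_gm_from_matrices(a1, a2,
                        population = rep(c("A", "B"), c(n1, n2)),
                        region = rep(c("East", "West"), c(n1, n2)))
}

make_gm_from_matrices <- function(a1, a2, population, region = NULL,
                                  cohort = NULL) {
  n <- nrow(a1)
  ids <- rownames(a1) %||% paste0("i", seq_len(n))
  rownames(a1) <- rownames(a2) <- ids
  if (is.null(colnames(a1)))
    colnames(a1) <- colnames(a2) <- paste0("L", seq_len(ncol(a1)))
  meta <- data.frame(id = ids, population = population,
                     region = region %||% "East",
                     cohort = cohort %||% "in_situ",
                     garden = NA_character_, maternal_line = NA_character_,
                     source_population = NA_character_,
                     stringsAsFactors = FALSE)
  genotype_matrix(a1, a2, meta)
}

# Exhaustive-subset oracle: exact mean percent of catalog alleles captured
# over all size-n subsets of the cohort, by direct enumeration.
enumerate_capture <- function(carriers, N, n) {
  subsets <- utils::combn(N, n)
  pct <- apply(subsets, 2, function(s) {
    hit <- vapply(carriers, function(ix) any(ix %in% s), logical(1))
    100 * mean(hit)
  })
  mean(pct)
}

# a small annotated two-cohort dataset used across capture/garden tests
tiny_audit_gm <- function() {
  make_gm(
    list(
      w1 = c("1/1", "3/3"), w2 = c("1/2", "3/4"), w3 = c("2/2", "4/4"),
      w4 = c("1/1", "3/4"), w5 = c("5/5", "3/3"), w6 = c("1/5", "4/4"),
      x1 = c("1/1", "3/3"), x2 = c("1/2", "3/4"), x3 = c("2/5", "4/4")
    ),
    population = c("E1", "E1", "E2", "W1", "W1", "W2", "GA", "GA", "GB"),
    region = c("East", "East", "East", "West", "West", "West",
               "East", "West", "West"),
    cohort = c(rep("in_situ", 6), rep("ex_situ", 3)),
    garden = c(rep(NA, 6), "GA", "GA", "GB"),
    maternal_line = c(rep(NA, 6), "F1", "F1", "F2"),
    source_population = c(rep(NA, 6), "E1", "W1", "W2")
  )
}
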
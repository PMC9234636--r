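#' Per-garden capture summaries
#'
#' For each botanic garden holding ex situ individuals: the capture report of
#' that garden's plants against the supplied reference catalog, plus counts
#' of plants, maternal accessions, and distinct source populations (with an
#' East/West breakdown of source populations).
#'
#' @param gm an annotated [genotype_matrix()]
#' @param ref a classified `allele_catalog` built on the in situ cohort
#' @return a `garden_summaries` data frame, one row per garden, with columns
#'   `garden, n_plants, n_accessions, n_populations, n_populations_east,
#'   n_populations_west` and `pct_<class>` per report class; the full
#'   `capture_report`s are attached as attribute `reports`
#' @export
garden_summaries <- function(gm, ref) {
  ex <- which(gm$meta$cohort %in% "ex_situ" & !is.na(gm$meta$garden))
  if (!length(ex)) stop("no ex situ individuals with a garden")
  gardens <- unique(gm$meta$garden[ex])
  map <- source_region_map(gm)
  reports <- list()
  rows <- lapply(gardens, function(g) {
    idx <- ex[gm$meta$garden[ex] == g]
    meta <- gm$meta[idx, , drop = FALSE]
    rep <- capture_report(ref, gm, idx, scope = g)
    reports[[g]] <<- rep
    pops <- unique(meta$source_population[!is.na(meta$source_population)])
    pr <- unname(map[pops])
    pct <- setNames(rep$percent, paste0("pct_", rep$class))
    cbind(data.frame(garden = g,
                     n_plants = length(idx),
                     n_accessions = length(unique(
                       meta$maternal_line[!is.na(meta$maternal_line)])),
                     n_populations = length(pops),
                     n_populations_east = sum(pr %in% "East"),
                     n_populations_west = sum(pr %in% "West"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(pct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, reports = reports, view = catalog_view(ref),
            class = c("garden_summaries", "data.frame"))
}

#' Regressions of garden capture on collection size under three transforms
#'
#' Fits `percent ~ t(x)` by OLS for `t` in identity, square root, and natural
#' log, where `x` is a garden-level predictor (number of plants, maternal
#' accessions, or source populations) and the response is a class's capture
#' percentage across gardens. The transform with the highest adjusted R
#' squared is flagged.
#'
#' @param summaries a [garden_summaries()] data frame
#' @param predictor one of `"n_plants"`, `"n_accessions"`, `"n_populations"`
#' @param class report class for the response (default `"all"`)
#' @return a `transform_regressions` data frame with columns
#'   `transform, intercept, slope, r_squared, adj_r_squared` and attribute
#'   `best` (the winning transform)
#' @export
fit_transform_regressions <- function(summaries,
                                      predictor = c("n_plants",
                                                    "n_accessions",
                                                    "n_populations"),
                                      class = "all") {
  predictor <- match.arg(predictor)
  if (nrow(summaries) < 3L) stop("need at least 3 gardens")
  x <- summaries[[predictor]]
  y <- summaries[[paste0("pct_", class)]]
  if (is.null(y)) stop("unknown class: ", class)
  transforms <- list(identity = identity, sqrt = sqrt, log = log)
  rows <- lapply(names(transforms), function(tn) {
    if (tn == "log" && any(x <= 0))
      stop("log transform undefined: predictor has values <= 0")
    tx <- transforms[[tn]](x)
    fit <- lm(y ~ tx)
    sm <- summary(fit)
    data.frame(transform = tn,
               intercept = unname(coef(fit)[1]),
               slope = unname(coef(fit)[2]),
               r_squared = sm$r.squared,
               adj_r_squared = sm$adj.r.squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, predictor = predictor, response_class = class,
            best = out$transform[which.max(out$adj_r_squared)],
            class = c("transform_regressions", "data.frame"))
}

#' Weir-Cockerham (1984) multilocus theta between two cohorts
#'
#' Estimates F_ST between two sets of individuals as Weir & Cockerham's theta
#' with variance components `a` (among populations), `b` (among individuals
#' within populations) and `c` (within individuals) summed over every allele
#' at every locus (ratio of sums, not average of ratios). Missing calls are
#' excluded per locus; negative per-locus components are retained in the
#' sums. The `nei` method gives Nei's (1987) Gst-style estimator as a
#' cross-check variant.
#'
#' @param gm a [genotype_matrix()]
#' @param ind_a,ind_b individual selectors for the two cohorts
#'   (logical/integer/character), each with at least 2 individuals
#' @param method `"wc84"` (default) or `"nei"`
#' @return the F_ST estimate (scalar); per-locus components are attached as
#'   attribute `components` for `"wc84"`
#' @export
pairwise_fst <- function(gm, ind_a, ind_b, method = c("wc84", "nei")) {
  method <- match.arg(method)
  A <- gm[ind_a]
  B <- gm[ind_b]
  if (n_individuals(A) < 2L || n_individuals(B) < 2L)
    stop("each cohort needs at least 2 individuals")
  if (method == "nei") return(nei_fst(A, B))
  comp <- lapply(seq_len(n_loci(gm)), function(l)
    wc84_locus_components(A$a1[, l], A$a2[, l], B$a1[, l], B$a2[, l]))
  a <- sum(vapply(comp, `[[`, numeric(1), "a"))
  b <- sum(vapply(comp, `[[`, numeric(1), "b"))
  cc <- sum(vapply(comp, `[[`, numeric(1), "c"))
  if (a + b + cc == 0)
    stop("no polymorphic loci shared by the two cohorts")
  structure(a / (a + b + cc),
            components = data.frame(
              locus = loci(gm),
              a = vapply(comp, `[[`, numeric(1), "a"),
              b = vapply(comp, `[[`, numeric(1), "b"),
              c = vapply(comp, `[[`, numeric(1), "c")))
}

# Variance components for one locus, two populations (r = 2), all alleles.
# Notation follows the standard two-level hierarchy: n_i individuals typed in
# population i, p_i allele frequency, h_i observed frequency of heterozygotes
# carrying the allele.
wc84_locus_components <- function(a1A, a2A, a1B, a2B) {
  okA <- !is.na(a1A)
  okB <- !is.na(a1B)
  n1 <- sum(okA)
  n2 <- sum(okB)
  zero <- list(a = 0, b = 0, c = 0)
  if (n1 < 1L || n2 < 1L) return(zero)
  alleles <- sort(unique(c(a1A[okA], a2A[okA], a1B[okB], a2B[okB])))
  if (length(alleles) < 2L) return(zero)  # monomorphic locus contributes 0
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  p1 <- vapply(alleles, function(v)
    (sum(a1A[okA] == v) + sum(a2A[okA] == v)) / (2 * n1), numeric(1))
  p2 <- vapply(alleles, function(v)
    (sum(a1B[okB] == v) + sum(a2B[okB] == v)) / (2 * n2), numeric(1))
  h1 <- vapply(alleles, function(v)
    sum((a1A[okA] == v) != (a2A[okA] == v)) / n1, numeric(1))
  h2 <- vapply(alleles, function(v)
    sum((a1B[okB] == v) != (a2B[okB] == v)) / n2, numeric(1))
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = sum(a), b = sum(b), c = sum(cc))
}

# Nei (1987) Gst-style estimator: (Ht - Hs) / Ht pooled over loci.
nei_fst <- function(A, B) {
  ht_num <- 0
  hs_num <- 0
  for (l in seq_len(n_loci(A))) {
    cA <- c(A$a1[, l], A$a2[, l])
    cA <- cA[!is.na(cA)]
    cB <- c(B$a1[, l], B$a2[, l])
    cB <- cB[!is.na(cB)]
    if (!length(cA) || !length(cB)) next
    alleles <- unique(c(cA, cB))
    pA <- vapply(alleles, function(v) mean(cA == v), numeric(1))
    pB <- vapply(alleles, function(v) mean(cB == v), numeric(1))
    pbar <- (pA + pB) / 2
    ht <- 1 - sum(pbar^2)
    hs <- 1 - (sum(pA^2) + sum(pB^2)) / 2
    ht_num <- ht_num + ht
    hs_num <- hs_num + hs
  }
  if (ht_num == 0) stop("no polymorphic loci shared by the two cohorts")
  (ht_num - hs_num) / ht_num
}

#' Garden-versus-region F_ST contrast with paired t-test
#'
#' Computes Weir-Cockerham theta between each garden's plants and the pooled
#' in situ individuals of each region, then contrasts the two per-garden
#' F_ST vectors with a two-sided paired t-test.
#'
#' @param gm an annotated [genotype_matrix()] with both cohorts
#' @return an `fst_contrast`: list with `table` (garden, fst_east, fst_west),
#'   `mean_east`, `mean_west`, `t_statistic`, `p_value`
#' @export
fst_contrast <- function(gm) {
  ex <- which(gm$meta$cohort %in% "ex_situ" & !is.na(gm$meta$garden))
  gardens <- unique(gm$meta$garden[ex])
  sizes <- vapply(gardens, function(g) sum(gm$meta$garden[ex] == g),
                  integer(1))
  if (any(sizes < 2L)) {
    warning("excluding gardens with fewer than 2 plants (theta undefined): ",
            paste(gardens[sizes < 2L], collapse = ", "))
    gardens <- gardens[sizes >= 2L]
  }
  if (length(gardens) < 2L)
    stop("paired t-test requires at least 2 gardens with >= 2 plants")
  east <- cohort_index(gm, "in_situ", "East")
  west <- cohort_index(gm, "in_situ", "West")
  if (!length(east) || !length(west))
    stop("both in situ regions must be present")
  tab <- do.call(rbind, lapply(gardens, function(g) {
    idx <- ex[gm$meta$garden[ex] == g]
    data.frame(garden = g,
               fst_east = as.numeric(pairwise_fst(gm, idx, east)),
               fst_west = as.numeric(pairwise_fst(gm, idx, west)),
               stringsAsFactors = FALSE)
  }))
  d <- tab$fst_west - tab$fst_east
  if (var(d) == 0) {
    # degenerate pairing: identical vectors give t = 0, p = 1; a constant
    # nonzero difference is infinitely significant
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pval <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- t.test(tab$fst_west, tab$fst_east, paired = TRUE)
    tstat <- unname(ht$statistic)
    pval <- unname(ht$p.value)
  }
  structure(list(table = tab,
                 mean_east = mean(tab$fst_east),
                 mean_west = mean(tab$fst_west),
                 t_statistic = tstat,
                 p_value = pval),
            class = "fst_contrast")
}

#' @export
print.fst_contrast <- function(x, ...) {
  cat(sprintf(
    "fst_contrast over %d gardens: mean theta vs East = %.4f, vs West = %.4f\n",
    nrow(x$table), x$mean_east, x$mean_west))
  cat(sprintf("  paired t = %.3f, two-sided p = %.4g\n",
              x$t_statistic, x$p_value))
  invisible(x)
}
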
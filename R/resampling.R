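#' Carrier index lists for catalog alleles
#'
#' For each catalog entry, the (row) indices of the cohort individuals that
#' carry at least one copy of the allele. The cohort defaults to the
#' individuals the catalog was built from.
#'
#' @param ref an `allele_catalog`
#' @param gm the [genotype_matrix()] holding the cohort
#' @param individuals cohort selector; default: the catalog's reference
#'   individuals
#' @return list of integer vectors, one per catalog entry
#' @keywords internal
catalog_carriers <- function(ref, gm, individuals = NULL) {
  individuals <- individuals %||% attr(ref, "individuals")
  sub <- if (is.null(individuals)) gm else gm[individuals]
  out <- vector("list", nrow(ref))
  for (l in unique(ref$locus)) {
    rows <- which(ref$locus == l)
    x1 <- sub$a1[, l]
    x2 <- sub$a2[, l]
    for (r in rows) {
      v <- ref$allele[r]
      out[[r]] <- which((!is.na(x1) & x1 == v) | (!is.na(x2) & x2 == v))
    }
  }
  out
}

#' Exact expected capture percentage under random subsampling
#'
#' Closed form for the subsampling scheme used by [accumulation_curve()]:
#' sampling `n` of `N` individuals uniformly without replacement, an allele
#' carried by `m` individuals is captured with probability
#' `1 - choose(N - m, n) / choose(N, n)`. The expected percent captured is
#' 100 times the mean of that probability over alleles.
#'
#' @param carrier_counts integer vector, carriers per allele (all `>= 1`)
#' @param N cohort size
#' @param n subsample size(s), each in `[0, N]`
#' @return numeric vector of expected percentages, one per `n`
#' @export
expected_capture_closed_form <- function(carrier_counts, N, n) {
  if (any(carrier_counts < 1L)) stop("allele with zero carriers")
  if (any(carrier_counts > N)) stop("carrier count exceeds cohort size")
  if (any(n < 0L | n > N)) stop("subsample size outside [0, N]")
  vapply(n, function(k) {
    p_miss <- exp(lchoose(N - carrier_counts, k) - lchoose(N, k))
    100 * mean(1 - p_miss)
  }, numeric(1))
}

#' Allele accumulation curve by simulated subsampling
#'
#' Emulates an idealised range-wide seed collection: `reps` random subsamples
#' of each size `n = 1..N` are drawn uniformly without replacement from the
#' reference cohort, each sampled individual contributing both of its allele
#' copies (one seed or cutting per wild plant), and the percent of reference
#' alleles captured is averaged over replicates. One permutation per
#' replicate yields all sample sizes at once, so cost is linear in `reps`.
#' A missing call contributes no alleles but the individual still counts
#' toward `n`.
#'
#' @param ref a classified `allele_catalog` (full or reduced view)
#' @param gm the [genotype_matrix()] holding the reference cohort
#' @param reps number of Monte-Carlo replicates (the paper-scale default is
#'   75000; desk-scale runs use far fewer)
#' @param seed RNG seed, recorded on the result
#' @param individuals cohort selector; default: the catalog's reference
#'   individuals
#' @return an `accumulation_curve`: data frame with columns
#'   `n, class, mean_percent, se_percent`, attributes `reps`, `seed`, `view`,
#'   `n_ind` and `class_totals`
#' @export
accumulation_curve <- function(ref, gm, reps = 75000L, seed = 1L,
                               individuals = NULL) {
  if (anyNA(ref$class)) stop("reference catalog has unclassified entries")
  if (reps < 1L) stop("reps must be >= 1")
  carriers <- catalog_carriers(ref, gm, individuals)
  if (any(lengths(carriers) == 0L))
    stop("reference allele absent from the sampling cohort; the cohort must ",
         "contain every catalog allele")
  n_ind <- length(attr(ref, "individuals") %||%
                    individuals(if (is.null(individuals)) gm
                                else gm[individuals]))
  cls <- factor(ref$class, levels = ALLELE_CLASSES)
  totals <- table(cls)
  set.seed(seed)
  kern <- accum_kernel(carriers, as.integer(cls), length(ALLELE_CLASSES),
                       n_ind, as.integer(reps))
  rows <- lapply(seq_along(REPORT_CLASSES), function(ci) {
    cls_name <- REPORT_CLASSES[ci]
    total <- if (cls_name == "all") nrow(ref) else totals[[cls_name]]
    if (total == 0L) return(NULL)
    s <- kern$sum[ci, ]
    sq <- kern$sumsq[ci, ]
    mean_cnt <- s / reps
    var_cnt <- if (reps > 1L) pmax(0, (sq - s^2 / reps) / (reps - 1)) else
      rep(0, n_ind)
    data.frame(n = seq_len(n_ind), class = cls_name,
               mean_percent = 100 * mean_cnt / total,
               se_percent = 100 * sqrt(var_cnt / reps) / total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, reps = reps, seed = seed, view = catalog_view(ref),
            n_ind = n_ind, class_totals = c(all = nrow(ref), c(totals)),
            class = c("accumulation_curve", "data.frame"))
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf(
    "accumulation_curve: N = %d, %d replicates, view = %s, seed = %s\n",
    attr(x, "n_ind"), attr(x, "reps"), attr(x, "view"), attr(x, "seed")))
  print.data.frame(utils::head(x[x$class == "all", ]))
  invisible(x)
}

#' Minimum sample size to reach a capture threshold
#'
#' The smallest subsample size whose replicate-mean capture percentage meets
#' or exceeds the threshold (ties at exactly the threshold count as reaching
#' it).
#'
#' @param curve an [accumulation_curve()]
#' @param threshold target percentage, default 95
#' @param class allele class(es) to read off; default `"all"`
#' @return named integer vector of minimum sample sizes (`NA` with a warning
#'   if the curve never reaches the threshold)
#' @export
minimum_sample_size <- function(curve, threshold = 95, class = "all") {
  if (threshold > 100) stop("threshold above 100% is unreachable")
  vapply(class, function(cls) {
    sub <- curve[curve$class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) stop("class absent from curve: ", cls)
    hit <- which(sub$mean_percent >= threshold)
    if (!length(hit)) {
      warning("threshold ", threshold, "% never reached for class ", cls)
      return(NA_integer_)
    }
    sub$n[min(hit)]
  }, integer(1))
}

#' Logarithmic reference regression of capture on collection size
#'
#' Ordinary least-squares fit of `percent = a + b * ln(n)` over a set of
#' reference taxa (collection size, percent alleles conserved). A focal
#' species' residual against this reference relationship indicates whether it
#' conserves more (positive) or less (negative) diversity than expected for
#' its collection size.
#'
#' @param points data frame with columns `n` (collection sizes, all `>= 1`)
#'   and `percent`; at least 3 rows
#' @return a `log_reference`: list with `intercept`, `slope`, the `lm` fit,
#'   and the input points
#' @export
fit_log_reference <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("n", "percent") %in% names(points)))
    stop("points must have columns 'n' and 'percent'")
  if (nrow(points) < 3L) stop("need at least 3 reference points")
  if (any(points$n < 1)) stop("collection sizes must be >= 1")
  if (length(unique(points$n)) < 2L)
    stop("degenerate design: all collection sizes identical")
  fit <- lm(percent ~ log(n), data = points)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 model = fit, points = points),
            class = "log_reference")
}

#' @export
print.log_reference <- function(x, ...) {
  cat(sprintf("log_reference: percent = %.4g + %.4g * ln(n)  (%d taxa)\n",
              x$intercept, x$slope, nrow(x$points)))
  invisible(x)
}

#' @rdname fit_log_reference
#' @param object a `log_reference`
#' @param n collection size(s) at which to predict
#' @param ... unused
#' @export
predict.log_reference <- function(object, n, ...) {
  object$intercept + object$slope * log(n)
}

#' @rdname fit_log_reference
#' @param ref a `log_reference`
#' @param percent observed percent conserved for the focal species
#' @return `reference_residual()`: observed minus predicted percent
#'   (negative means below the reference relationship)
#' @export
reference_residual <- function(ref, n, percent) {
  percent - predict(ref, n)
}
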
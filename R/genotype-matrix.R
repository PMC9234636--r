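#' @useDynLib exsituaudit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats chisq.test coef lm predict pt qt rbinom rgamma rmultinom
#'   runif setNames t.test var
#' @importFrom utils read.csv write.csv
NULL

REGIONS <- c("East", "West")
COHORTS <- c("in_situ", "ex_situ")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diploid multilocus genotype matrix with individual metadata
#'
#' The central container of the package: an individuals-by-loci table of
#' unordered diploid allele calls plus a per-individual metadata record
#' (population, region, cohort, garden, maternal line, source population).
#' Allele pairs are unphased, so each call is stored as a sorted pair
#' (`a1 <= a2`); a missing call sets both slots to `NA`.
#'
#' @param a1,a2 integer matrices of identical dimension, individuals in rows
#'   (rownames are individual IDs) and loci in columns (colnames are locus
#'   names). Allele codes must be strictly positive integers (typically
#'   fragment lengths); `NA` in either slot marks the whole call missing.
#' @param meta optional data frame keyed by column `id` with columns
#'   `population`, `region`, `cohort`, `garden`, `maternal_line`,
#'   `source_population`. Missing columns are filled with `NA`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, meta = NULL) {
  if (!is.matrix(a1) || !is.matrix(a2) || !all(dim(a1) == dim(a2)))
    stop("a1 and a2 must be matrices of identical dimension")
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  miss <- is.na(a1) | is.na(a2)
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  lo[miss] <- NA_integer_
  hi[miss] <- NA_integer_
  if (any(lo <= 0L, na.rm = TRUE))
    stop("allele codes must be strictly positive integers")
  ids <- rownames(a1) %||% paste0("ind", seq_len(nrow(a1)))
  if (anyDuplicated(ids))
    stop("duplicate individual IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  loci <- colnames(a1) %||% paste0("loc", seq_len(ncol(a1)))
  dimnames(lo) <- dimnames(hi) <- list(ids, loci)
  meta <- complete_meta(meta, ids)
  structure(list(a1 = lo, a2 = hi, meta = meta), class = "genotype_matrix")
}

complete_meta <- function(meta, ids) {
  blank <- rep(NA_character_, length(ids))
  template <- data.frame(
    id = ids, population = blank, region = blank, cohort = blank,
    garden = blank, maternal_line = blank, source_population = blank,
    stringsAsFactors = FALSE
  )
  if (is.null(meta)) return(template)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta)) stop("metadata must have an 'id' column")
  idx <- match(ids, meta$id)
  if (anyNA(idx))
    stop("metadata missing for individuals: ",
         paste(ids[is.na(idx)], collapse = ", "))
  for (col in setdiff(names(template), "id")) {
    if (col %in% names(meta)) template[[col]] <- as.character(meta[[col]][idx])
  }
  check_meta_values(template)
  template
}

check_meta_values <- function(meta) {
  bad_region <- !is.na(meta$region) & !meta$region %in% REGIONS
  if (any(bad_region))
    stop("region must be one of ", paste(REGIONS, collapse = "/"),
         "; offending values: ",
         paste(unique(meta$region[bad_region]), collapse = ", "))
  bad_cohort <- !is.na(meta$cohort) & !meta$cohort %in% COHORTS
  if (any(bad_cohort))
    stop("cohort must be one of ", paste(COHORTS, collapse = "/"))
  invisible(meta)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n",
              n_individuals(x), n_loci(x)))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * missing_rate(x)))
  tab <- table(x$meta$cohort, useNA = "ifany")
  cat("  cohorts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
n_individuals <- function(gm) nrow(gm$a1)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$a1)

#' @rdname genotype_matrix
#' @export
individuals <- function(gm) rownames(gm$a1)

#' @rdname genotype_matrix
#' @export
loci <- function(gm) colnames(gm$a1)

#' Subset a genotype matrix by individuals
#'
#' @param x a `genotype_matrix`
#' @param i individual selector: logical, integer, or character IDs
#' @param ... unused
#' @return a `genotype_matrix` restricted to the selected individuals
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  if (is.character(i)) {
    pos <- match(i, individuals(x))
    if (anyNA(pos)) stop("unknown individual IDs: ",
                         paste(i[is.na(pos)], collapse = ", "))
    i <- pos
  }
  structure(list(a1 = x$a1[i, , drop = FALSE],
                 a2 = x$a2[i, , drop = FALSE],
                 meta = x$meta[i, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Stack two cohorts that share the same loci
#'
#' @param a,b `genotype_matrix` objects with identical locus sets
#' @return a combined `genotype_matrix`
#' @export
combine_cohorts <- function(a, b) {
  if (!identical(loci(a), loci(b)))
    stop("cohorts do not share the same loci")
  genotype_matrix(rbind(a$a1, b$a1), rbind(a$a2, b$a2),
                  meta = rbind(a$meta, b$meta))
}

#' Proportion of missing individual-by-locus calls
#'
#' A call is missing when both allele slots are unobserved; the rate is the
#' count of missing calls over individuals x loci.
#'
#' @param gm a `genotype_matrix`
#' @return a fraction in `[0, 1]`
#' @export
missing_rate <- function(gm) {
  if (n_individuals(gm) == 0L || n_loci(gm) == 0L)
    stop("empty genotype matrix")
  mean(is.na(gm$a1))
}

#' Attach or replace per-individual metadata
#'
#' Joins a metadata table onto the genotype matrix by individual ID. Every
#' genotyped individual must appear in the table; table rows that match no
#' genotyped individual are reported with a warning and ignored. Ex situ
#' individuals must carry a garden and a source population.
#'
#' @param gm a `genotype_matrix`
#' @param table data frame (or CSV path) with columns
#'   `id,population,region,cohort,garden,maternal_line,source_population`
#' @return the annotated `genotype_matrix`
#' @export
attach_metadata <- function(gm, table) {
  if (is.character(table) && length(table) == 1L) {
    table <- read.csv(table, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!"id" %in% names(table)) stop("metadata table must have an 'id' column")
  ids <- individuals(gm)
  absent <- setdiff(ids, table$id)
  if (length(absent))
    stop("metadata table missing genotyped individuals: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(table$id, ids)
  if (length(extra))
    warning(length(extra), " metadata rows match no genotyped individual: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ...")
  meta <- complete_meta(table, ids)
  if (anyNA(meta$region) || anyNA(meta$cohort))
    stop("region and cohort must be non-missing for every individual")
  ex <- meta$cohort == "ex_situ"
  if (any(ex & (is.na(meta$garden) | is.na(meta$source_population))))
    stop("ex situ individuals must have a garden and a source population")
  gm$meta <- meta
  gm
}

cohort_index <- function(gm, cohort = NULL, region = NULL) {
  keep <- rep(TRUE, n_individuals(gm))
  if (!is.null(cohort)) keep <- keep & gm$meta$cohort %in% cohort
  if (!is.null(region)) keep <- keep & gm$meta$region %in% region
  which(keep)
}
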
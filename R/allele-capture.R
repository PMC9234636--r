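ALLELE_CLASSES <- c("very_common", "common", "low_frequency", "rare")
REPORT_CLASSES <- c("all", ALLELE_CLASSES)

#' Build a pooled allele catalog for a reference cohort
#'
#' Counts, per locus, the copies of every allele over the non-missing calls of
#' the selected individuals (each individual contributes two gene copies per
#' non-missing call) and derives pooled frequencies. The catalog is the
#' reference against which capture percentages are computed; frequencies and
#' frequency classes always come from this reference cohort.
#'
#' @param gm a [genotype_matrix()]
#' @param individuals individual selector (logical/integer/character) naming
#'   the reference cohort; default: all individuals
#' @return an `allele_catalog`: data frame with columns
#'   `locus, allele, count, freq, class` (class is `NA` until
#'   [classify_alleles()]), with attributes `view` (`"full"`),
#'   `n_copies` (per-locus non-missing copy counts) and `individuals`
#' @export
build_catalog <- function(gm, individuals = NULL) {
  sub <- if (is.null(individuals)) gm else gm[individuals]
  if (n_individuals(sub) == 0L) stop("reference cohort is empty")
  entries <- vector("list", n_loci(sub))
  n_copies <- integer(n_loci(sub))
  for (l in seq_len(n_loci(sub))) {
    copies <- c(sub$a1[, l], sub$a2[, l])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0L)
      stop("locus with zero non-missing calls in cohort: ", loci(sub)[l])
    n_copies[l] <- length(copies)
    tab <- table(copies)
    entries[[l]] <- data.frame(
      locus = loci(sub)[l],
      allele = as.integer(names(tab)),
      count = as.integer(tab),
      freq = as.integer(tab) / length(copies),
      class = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  cat <- do.call(rbind, entries)
  rownames(cat) <- NULL
  structure(cat,
            view = "full",
            n_copies = setNames(n_copies, loci(sub)),
            individuals = individuals(sub),
            class = c("allele_catalog", "data.frame"))
}

catalog_view <- function(cat) attr(cat, "view") %||% "full"

#' Label catalog entries by pooled-frequency class
#'
#' Classes follow the conventional half-open-from-below reading of the
#' frequency bins: rare `[0, 0.01)`, low_frequency `[0.01, 0.05)`,
#' common `[0.05, 0.10)`, very_common `[0.10, 1]`.
#'
#' @param cat an `allele_catalog` from [build_catalog()]
#' @return the catalog with the `class` column filled
#' @export
classify_alleles <- function(cat) {
  cat$class <- as.character(cut(
    cat$freq,
    breaks = c(0, 0.01, 0.05, 0.10, 1 + 1e-9),
    labels = c("rare", "low_frequency", "common", "very_common"),
    right = FALSE, include.lowest = TRUE
  ))
  cat
}

#' Drop ultra-rare alleles (<= 2 copies) from a catalog
#'
#' Produces the "reduced" view: entries observed as singletons or doubletons
#' in the reference cohort are removed. Frequencies and class labels are kept
#' at their full-catalog values rather than re-normalised, so both views share
#' one class structure.
#'
#' @param cat a full-view `allele_catalog`
#' @param max_copies drop entries with `count <= max_copies` (default 2)
#' @return the reduced-view catalog
#' @export
reduce_catalog <- function(cat, max_copies = 2L) {
  if (catalog_view(cat) != "full")
    stop("reduce_catalog expects a full-view catalog")
  out <- cat[cat$count > max_copies, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "view") <- "reduced"
  attr(out, "n_copies") <- attr(cat, "n_copies")
  attr(out, "individuals") <- attr(cat, "individuals")
  class(out) <- class(cat)
  out
}

allele_keys <- function(locus, allele) paste(locus, allele, sep = "\r")

target_allele_keys <- function(gm, individuals = NULL) {
  sub <- if (is.null(individuals)) gm else gm[individuals]
  keys <- character(0)
  for (l in seq_len(n_loci(sub))) {
    copies <- unique(c(sub$a1[, l], sub$a2[, l]))
    copies <- copies[!is.na(copies)]
    keys <- c(keys, allele_keys(loci(sub)[l], copies))
  }
  keys
}

#' Percent of reference alleles present in a target cohort
#'
#' For each frequency class (and overall), counts the reference-catalog
#' entries whose (locus, allele) pair occurs at least once among the target
#' cohort's non-missing calls. Alleles present in the target but absent from
#' the reference are ignored: the denominator is fixed by the reference.
#'
#' @param ref a classified `allele_catalog` (see [classify_alleles()])
#' @param gm the [genotype_matrix()] holding the target individuals
#' @param individuals target-cohort selector; default: all of `gm`
#' @param scope label recorded on the report (e.g. `"overall"`, a region, a
#'   garden ID)
#' @return a `capture_report`: data frame with rows `all, very_common,
#'   common, low_frequency, rare` and columns `class, captured, total,
#'   percent` (`percent` is `NA` for empty classes), with attributes `scope`,
#'   `view` and `n_target`
#' @export
capture_report <- function(ref, gm, individuals = NULL, scope = "overall") {
  if (anyNA(ref$class)) stop("reference catalog has unclassified entries")
  sub <- if (is.null(individuals)) gm else gm[individuals]
  if (n_individuals(sub) == 0L) stop("target cohort is empty")
  present <- allele_keys(ref$locus, ref$allele) %in% target_allele_keys(sub)
  per_class <- function(cls) {
    keep <- if (cls == "all") rep(TRUE, nrow(ref)) else ref$class == cls
    total <- sum(keep)
    captured <- sum(present & keep)
    data.frame(class = cls, captured = captured, total = total,
               percent = if (total > 0) 100 * captured / total else NA_real_,
               stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, lapply(REPORT_CLASSES, per_class))
  rownames(rep) <- NULL
  structure(rep, scope = scope, view = catalog_view(ref),
            n_target = n_individuals(sub),
            class = c("capture_report", "data.frame"))
}

report_row <- function(report, cls) report[report$class == cls, , drop = FALSE]

#' Overall in-situ-versus-ex-situ capture report
#'
#' Convenience wrapper: reference catalog pooled over all in situ
#' individuals, target all ex situ individuals.
#'
#' @param gm a fully annotated [genotype_matrix()] with both cohorts
#' @param view `"full"` or `"reduced"` (drop alleles with <= 2 copies)
#' @return a `capture_report`
#' @export
overall_capture <- function(gm, view = c("reduced", "full")) {
  view <- match.arg(view)
  in_idx <- cohort_index(gm, "in_situ")
  ex_idx <- cohort_index(gm, "ex_situ")
  if (!length(in_idx)) stop("no in situ individuals")
  if (!length(ex_idx)) stop("no ex situ individuals")
  ref <- classify_alleles(build_catalog(gm, in_idx))
  if (view == "reduced") ref <- reduce_catalog(ref)
  capture_report(ref, gm, ex_idx, scope = "overall")
}

source_region_map <- function(gm) {
  ins <- gm$meta[gm$meta$cohort %in% "in_situ", , drop = FALSE]
  map <- unique(ins[!is.na(ins$population) & !is.na(ins$region),
                    c("population", "region")])
  setNames(map$region, map$population)
}

#' Regional allele capture (East or West)
#'
#' The reference set is the alleles present in the region's in situ
#' populations; the target is the ex situ individuals whose source population
#' lies in that region (individuals whose source population is unknown fall
#' back to their own region label).
#'
#' @param gm an annotated [genotype_matrix()]
#' @param region `"East"` or `"West"`
#' @param view `"reduced"` or `"full"`
#' @return a `capture_report` scoped to the region
#' @export
regional_capture <- function(gm, region = c("East", "West"),
                             view = c("reduced", "full")) {
  region <- match.arg(region)
  view <- match.arg(view)
  in_idx <- cohort_index(gm, "in_situ", region)
  if (!length(in_idx)) stop("no in situ individuals in region ", region)
  map <- source_region_map(gm)
  ex <- gm$meta$cohort %in% "ex_situ"
  src_region <- unname(map[gm$meta$source_population])
  src_region[is.na(src_region)] <- gm$meta$region[is.na(src_region)]
  ex_idx <- which(ex & src_region %in% region)
  if (!length(ex_idx))
    stop("no ex situ seedlings sourced from region ", region)
  ref <- classify_alleles(build_catalog(gm, in_idx))
  if (view == "reduced") ref <- reduce_catalog(ref)
  capture_report(ref, gm, ex_idx, scope = region)
}

#' Chi-square contrast of allele capture between two regions
#'
#' Builds the 2x2 table of reference alleles captured versus not captured in
#' each region (class `"all"`) and applies Pearson's chi-square test. Yates
#' continuity correction is on by default, matching the usual 2x2 default of
#' the test; set `correct = FALSE` for the raw Pearson statistic.
#'
#' @param east,west `capture_report`s computed on the same view
#' @param correct logical; apply Yates continuity correction
#' @return list with `statistic`, `p_value`, `table`, and `warning` (message
#'   if any expected cell is below 1, else `NULL`)
#' @export
capture_chi_square <- function(east, west, correct = TRUE) {
  if (!identical(attr(east, "view"), attr(west, "view")))
    stop("reports were computed on different catalog views")
  e <- report_row(east, "all")
  w <- report_row(west, "all")
  tab <- rbind(East = c(captured = e$captured, not = e$total - e$captured),
               West = c(captured = w$captured, not = w$total - w$captured))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  warn <- if (any(expected < 1))
    "expected cell count below 1; chi-square approximation unreliable"
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       table = tab, warning = warn)
}
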
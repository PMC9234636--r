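#' Run a full ex situ conservation audit
#'
#' Orchestrates the pipeline: load (or simulate) genotypes -> in situ allele
#' catalog -> capture reports (overall, per region, per garden) -> East/West
#' chi-square -> accumulation curves and minimum sample sizes -> garden
#' regressions -> garden-versus-region F_ST contrast -> ecogeographic
#' coverage. Writes a CSV/JSON report bundle plus a run log recording the
#' seed and row counts. The geography stage is optional: with no occurrence
#' data it is skipped with a logged warning.
#'
#' @param config a configuration list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genepop, metadata}{paths to the genotype and metadata inputs
#'       (alternative to `preset`)}
#'     \item{preset}{`"synthetic"` to simulate the default study conditions
#'       instead of reading files}
#'     \item{occurrences, ecoregions}{optional paths (occurrence CSV,
#'       ecoregion GeoJSON)}
#'     \item{missing_code}{GENEPOP missing token (default `"0000"`)}
#'     \item{views}{catalog views to report (default `c("reduced","full")`)}
#'     \item{reps}{resampling replicates (default 5000)}
#'     \item{threshold}{capture threshold percent (default 95)}
#'     \item{radii}{buffer radii km (default `c(10, 50, 100)`)}
#'     \item{levels}{ecoregion levels (default `c("III","IV")`)}
#'     \item{seed}{RNG seed (default 1)}
#'     \item{out_dir}{output directory (required)}
#'   }
#' @return (invisibly) the list of in-memory results backing the bundle
#' @export
run_audit <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config must give an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  views <- cfg$views %||% c("reduced", "full")
  reps <- as.integer(cfg$reps %||% 5000L)
  threshold <- cfg$threshold %||% 95
  radii <- cfg$radii %||% c(10, 50, 100)
  levels <- cfg$levels %||% c("III", "IV")
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  log("audit start, seed = ", seed)

  occ <- NULL
  layer <- NULL
  if (identical(cfg$preset, "synthetic")) {
    log("simulating default study conditions")
    sim <- simulate_dataset(seed = seed)
    gm <- sim$genotypes
    occ <- sim$occurrences
    layer <- sim$layer
  } else {
    if (is.null(cfg$genepop) || is.null(cfg$metadata))
      stop("config must give genepop + metadata paths, or preset: synthetic")
    gm <- read_genepop(cfg$genepop, missing_code = cfg$missing_code %||% "0000")
    gm <- attach_metadata(gm, cfg$metadata)
    if (!is.null(cfg$occurrences)) occ <- read_occurrences(cfg$occurrences)
    if (!is.null(cfg$ecoregions)) layer <- read_ecoregions_geojson(cfg$ecoregions)
  }
  clones <- identify_clones(gm)
  if (length(clones$dropped)) {
    log("dropping ", length(clones$dropped), " clonal duplicates")
    gm <- drop_clones(gm, clones)
  }
  log("genotypes: ", n_individuals(gm), " individuals x ", n_loci(gm),
      " loci, missing rate ", sprintf("%.4f", missing_rate(gm)))

  in_idx <- cohort_index(gm, "in_situ")
  ex_idx <- cohort_index(gm, "ex_situ")
  if (!length(in_idx)) stop("no in situ individuals after filtering")
  if (!length(ex_idx)) stop("no ex situ individuals after filtering")
  catalog_full <- classify_alleles(build_catalog(gm, in_idx))
  catalogs <- list(full = catalog_full,
                   reduced = reduce_catalog(catalog_full))
  ex_alleles <- length(target_allele_keys(gm, ex_idx))
  log("alleles: ", nrow(catalog_full), " in situ, ", ex_alleles, " ex situ")

  results <- list(seed = seed,
                  n_in_situ = length(in_idx), n_ex_situ = length(ex_idx),
                  missing_rate = missing_rate(gm),
                  n_alleles_in_situ = nrow(catalog_full),
                  n_alleles_ex_situ = ex_alleles,
                  clones_dropped = length(clones$dropped))

  # --- capture (Table-1-shaped) -----------------------------------------
  capture_rows <- list()
  for (view in views) {
    reports <- list(East = regional_capture(gm, "East", view),
                    West = regional_capture(gm, "West", view),
                    Overall = overall_capture(gm, view))
    chi <- capture_chi_square(reports$East, reports$West)
    results[[paste0("capture_", view)]] <- reports
    results[[paste0("chi_square_", view)]] <- chi
    log(sprintf("%s view: overall all-allele capture %.1f%%; E/W p = %.4g",
                view, report_row(reports$Overall, "all")$percent,
                chi$p_value))
    for (sc in names(reports)) {
      r <- reports[[sc]]
      capture_rows[[length(capture_rows) + 1L]] <- data.frame(
        view = view, scope = sc, n = attr(r, "n_target"),
        all = round(report_row(r, "all")$percent),
        very_common = round(report_row(r, "very_common")$percent),
        common = round(report_row(r, "common")$percent),
        low_frequency = round(report_row(r, "low_frequency")$percent),
        rare = round(report_row(r, "rare")$percent),
        stringsAsFactors = FALSE)
    }
  }
  capture_tab <- do.call(rbind, capture_rows)
  write.csv(capture_tab, file.path(cfg$out_dir, "capture_table.csv"),
            row.names = FALSE)

  # --- resampling -------------------------------------------------------
  min_rows <- list()
  curve_rows <- list()
  scopes <- list(overall = in_idx,
                 East = cohort_index(gm, "in_situ", "East"),
                 West = cohort_index(gm, "in_situ", "West"))
  for (view in views) {
    for (sc in names(scopes)) {
      ref <- classify_alleles(build_catalog(gm, scopes[[sc]]))
      if (view == "reduced") ref <- reduce_catalog(ref)
      curve <- accumulation_curve(ref, gm, reps = reps, seed = seed)
      nmin <- minimum_sample_size(curve, threshold = threshold)
      results[[paste0("n_min_", view, "_", sc)]] <- unname(nmin)
      min_rows[[length(min_rows) + 1L]] <- data.frame(
        view = view, scope = sc, threshold = threshold,
        n_min = unname(nmin), n_cohort = attr(curve, "n_ind"),
        stringsAsFactors = FALSE)
      all_curve <- curve[curve$class == "all", , drop = FALSE]
      curve_rows[[length(curve_rows) + 1L]] <-
        cbind(view = view, scope = sc, all_curve)
    }
  }
  min_tab <- do.call(rbind, min_rows)
  write.csv(min_tab, file.path(cfg$out_dir, "minimum_sample_size.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, curve_rows),
            file.path(cfg$out_dir, "accumulation_curves.csv"),
            row.names = FALSE)
  log("minimum sample sizes written (reps = ", reps, ")")

  # --- gardens ----------------------------------------------------------
  ref_gardens <- catalogs[[views[1]]]
  summ <- garden_summaries(gm, ref_gardens)
  write.csv(as.data.frame(summ),
            file.path(cfg$out_dir, "garden_summaries.csv"),
            row.names = FALSE)
  results$garden_summaries <- summ
  reg_rows <- list()
  if (nrow(summ) >= 3L) {
    for (pred in c("n_plants", "n_accessions", "n_populations")) {
      for (cls in REPORT_CLASSES) {
        if (anyNA(summ[[paste0("pct_", cls)]])) next  # class empty somewhere
        tr <- fit_transform_regressions(summ, pred, cls)
        reg_rows[[length(reg_rows) + 1L]] <-
          cbind(predictor = pred, class = cls, as.data.frame(tr),
                best = attr(tr, "best"))
      }
    }
    write.csv(do.call(rbind, reg_rows),
              file.path(cfg$out_dir, "garden_regressions.csv"),
              row.names = FALSE)
  } else log("warning: fewer than 3 gardens; regressions skipped")
  if (nrow(summ) >= 2L &&
        length(cohort_index(gm, "in_situ", "East")) &&
        length(cohort_index(gm, "in_situ", "West"))) {
    fstc <- fst_contrast(gm)
    results$fst_contrast <- fstc
    write.csv(fstc$table, file.path(cfg$out_dir, "fst_garden_region.csv"),
              row.names = FALSE)
    log(sprintf("F_ST contrast: mean vs East %.4f, vs West %.4f, p = %.4g",
                fstc$mean_east, fstc$mean_west, fstc$p_value))
  } else log("warning: F_ST contrast skipped (needs 2 gardens, 2 regions)")

  # --- ecogeography (optional, Table-2-shaped) --------------------------
  if (!is.null(occ)) {
    cov <- coverage_report(occ, layer, radii = radii, levels = levels)
    cov$cell <- sprintf("%.2f%% (%s/%s)", cov$percent,
                        format(round(cov$conserved), big.mark = ",",
                               trim = TRUE),
                        format(round(cov$total), big.mark = ",",
                               trim = TRUE))
    write.csv(cov, file.path(cfg$out_dir, "coverage_table.csv"),
              row.names = FALSE)
    results$coverage <- cov
    log("ecogeographic coverage written")
  } else {
    log("warning: no occurrence data supplied; ecogeo stage skipped")
  }

  # full-precision JSON twin of the bundle
  json <- list(seed = seed, reps = reps, threshold = threshold,
               n_in_situ = results$n_in_situ, n_ex_situ = results$n_ex_situ,
               missing_rate = results$missing_rate,
               n_alleles_in_situ = results$n_alleles_in_situ,
               n_alleles_ex_situ = results$n_alleles_ex_situ,
               capture = capture_tab, minimum_sample_size = min_tab)
  if (!is.null(results$fst_contrast))
    json$fst <- list(mean_east = results$fst_contrast$mean_east,
                     mean_west = results$fst_contrast$mean_west,
                     p_value = results$fst_contrast$p_value)
  if (!is.null(results$coverage))
    json$coverage <- results$coverage[, c("method", "level", "radius_km",
                                          "scope", "percent", "conserved",
                                          "total")]
  jsonlite::write_json(json, file.path(cfg$out_dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log("audit complete")
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(results)
}
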
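#' Read a GENEPOP genotype file
#'
#' Parses the GENEPOP dialect: a title line, locus names (one per line or
#' comma-separated), and `Pop`-delimited blocks of lines
#' `indID , a1a2 a1a2 ...` with fixed-width allele encoding. The per-allele
#' digit width (2 or 3) is auto-detected from token length; a file mixing
#' widths is rejected. Tokens equal to `missing_code`, or containing an
#' all-zero allele half, yield a missing call at both slots. Population
#' assignment follows the `Pop` blocks (`pop1`, `pop2`, ...) until
#' [attach_metadata()] supplies real labels.
#'
#' @param path path to the GENEPOP file
#' @param missing_code token treated as a missing call (default `"0000"`;
#'   all-zero tokens of either width are always treated as missing)
#' @return a [genotype_matrix()]
#' @export
read_genepop <- function(path, missing_code = "0000") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("not a GENEPOP file: fewer than 3 lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("zero loci declared")
  if (anyDuplicated(loci)) stop("duplicate locus names")

  ids <- character(0)
  pops <- character(0)
  geno_rows <- list()
  width <- NA_integer_  # characters per allele within a token
  pop_i <- 0L
  for (ln in seq(first_pop, length(lines))) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (grepl("^pop$", line, ignore.case = TRUE)) {
      pop_i <- pop_i + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("line %d: expected 'id , genotypes'", ln))
    id <- trimws(parts[1])
    tokens <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                       "[[:space:]]+")[[1]]
    if (length(tokens) != length(loci))
      stop(sprintf("line %d: %d genotype tokens for %d loci",
                   ln, length(tokens), length(loci)))
    nc <- unique(nchar(tokens))
    if (length(nc) != 1L || !nc %in% c(4L, 6L))
      stop(sprintf(
        "line %d: malformed token length (%s); expected 4 or 6 characters",
        ln, paste(nc, collapse = ",")))
    w <- nc %/% 2L
    if (is.na(width)) width <- w
    if (w != width)
      stop(sprintf("line %d: mixed 2- and 3-digit allele encodings", ln))
    if (any(!grepl("^[0-9]+$", tokens)))
      stop(sprintf("line %d: non-numeric genotype token", ln))
    a1 <- as.integer(substr(tokens, 1L, width))
    a2 <- as.integer(substr(tokens, width + 1L, 2L * width))
    miss <- tokens == missing_code | a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", max(pop_i, 1L)))
    geno_rows[[length(geno_rows) + 1L]] <- rbind(a1, a2)
  }
  if (length(ids) == 0L) stop("zero individuals in file")
  if (anyDuplicated(ids))
    stop("duplicate individual IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a1 <- do.call(rbind, lapply(geno_rows, function(g) g[1, ]))
  a2 <- do.call(rbind, lapply(geno_rows, function(g) g[2, ]))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  gm <- genotype_matrix(a1, a2)
  gm$meta$population <- pops
  attr(gm, "allele_digits") <- width
  gm
}

#' Write a genotype matrix as a GENEPOP file
#'
#' Individuals are grouped into `Pop` blocks by their population label (in
#' order of first appearance); missing calls are written as all-zero tokens.
#'
#' @param gm a [genotype_matrix()]
#' @param path output file path
#' @param digits per-allele digit width; default 3 if any allele code
#'   exceeds 99, else 2
#' @return `path`, invisibly
#' @export
write_genepop <- function(gm, path, digits = NULL) {
  digits <- digits %||% if (max(gm$a1, gm$a2, 0L, na.rm = TRUE) > 99L) 3L else 2L
  if (any(gm$a1 >= 10^digits, na.rm = TRUE))
    stop("allele codes do not fit in ", digits, " digits")
  fmt <- function(m) {
    s <- sprintf(paste0("%0", digits, "d"), ifelse(is.na(m), 0L, m))
    matrix(s, nrow = nrow(m))
  }
  s1 <- fmt(gm$a1)
  s2 <- fmt(gm$a2)
  pops <- gm$meta$population
  pops[is.na(pops)] <- "pop1"
  out <- c("exsituaudit GENEPOP export", loci(gm))
  for (p in unique(pops)) {
    out <- c(out, "Pop")
    for (i in which(pops == p)) {
      out <- c(out, paste0(individuals(gm)[i], " ,  ",
                           paste0(s1[i, ], s2[i, ], collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Identify clonal duplicates (identical multilocus genotypes)
#'
#' Groups individuals that share an identical multilocus genotype at every
#' locus (unordered within-locus comparison), within each population.
#' Matching is strict: a missing call at any locus disqualifies an individual
#' from matching anything, so ramets are only flagged on complete genotypes.
#' The first-encountered individual of each group is retained.
#'
#' @param gm a [genotype_matrix()]
#' @return a `clone_report`: list with `groups` (list of ID vectors sharing a
#'   genotype, size >= 2), `retained` (first ID per group), and `dropped`
#'   (all other IDs)
#' @seealso [drop_clones()]
#' @export
identify_clones <- function(gm) {
  if (n_individuals(gm) == 0L) stop("empty genotype matrix")
  ids <- individuals(gm)
  complete <- !apply(is.na(gm$a1), 1L, any)
  key <- rep(NA_character_, length(ids))
  key[complete] <- paste(
    gm$meta$population[complete],
    apply(cbind(gm$a1, gm$a2)[complete, , drop = FALSE], 1L, paste,
          collapse = "|"),
    sep = "//")
  key[!complete] <- paste0("unique//", ids[!complete])
  grp <- split(ids, factor(key, levels = unique(key)))
  groups <- unname(grp[lengths(grp) > 1L])
  retained <- vapply(groups, `[[`, character(1), 1L)
  dropped <- unlist(lapply(groups, `[`, -1L))
  structure(list(groups = groups, retained = retained,
                 dropped = as.character(dropped %||% character(0))),
            class = "clone_report")
}

#' @export
print.clone_report <- function(x, ...) {
  cat(sprintf("clone_report: %d clone groups, %d individuals dropped\n",
              length(x$groups), length(x$dropped)))
  invisible(x)
}

#' Remove clonal duplicates, keeping one representative per group
#'
#' @param gm a [genotype_matrix()]
#' @param report optional `clone_report`; computed from `gm` if omitted
#' @return the filtered `genotype_matrix`
#' @export
drop_clones <- function(gm, report = NULL) {
  report <- report %||% identify_clones(gm)
  if (length(report$dropped) == 0L) return(gm)
  gm[setdiff(individuals(gm), report$dropped)]
}
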
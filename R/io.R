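#' Read a GERMLINE match file
#'
#' Parses the common 15-column GERMLINE `.match` layout: family and individual
#' id of the first member, family and individual id of the second, chromosome,
#' bp start, bp end, first and last site labels, number of sites, segment
#' length, length unit (`cM` or `Mb`), mismatching sites, and two
#' homozygosity flags. Site indices are reconciled against the supplied site
#' map (closed bp endpoints, nearest contained site span) and the genetic
#' length is recomputed from the map. Rows whose length unit is `Mb` get
#' `length_recomputed = TRUE`.
#'
#' @param path Path to the `.match` file.
#' @param map The [site_map()] of the chromosome.
#' @return A segment table (see [ibd_segments()]) with a `length_recomputed`
#'   column.
#' @export
read_match <- function(path, map) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(cbind(empty_segments(),
                                   data.frame(length_recomputed = logical(0))))
  parts <- strsplit(trimws(lines), "[ \t]+")
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) != 15L) {
      stop(sprintf("line %d: expected 15 columns, got %d", k, length(p)))
    }
    unit <- p[12L]
    if (!unit %in% c("cM", "Mb")) {
      stop(sprintf("line %d: unknown length unit '%s' (expected cM or Mb)",
                   k, unit))
    }
    bp_s <- suppressWarnings(as.numeric(p[6L]))
    bp_e <- suppressWarnings(as.numeric(p[7L]))
    if (is.na(bp_s) || is.na(bp_e)) {
      stop(sprintf("line %d: malformed bp endpoints", k))
    }
    sites <- tryCatch(bp_to_sites(map, bp_s, bp_e), error = function(e) {
      stop(sprintf("line %d: %s", k, conditionMessage(e)), call. = FALSE)
    })
    out[[k]] <- data.frame(id_a = p[2L], id_b = p[4L],
                           site_start = sites[1L], site_end = sites[2L],
                           length_recomputed = unit == "Mb",
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  cbind(refresh_segments(out, map),
        data.frame(length_recomputed = out$length_recomputed))
}

#' Write segments as a GERMLINE match file
#'
#' @param segments Segment table.
#' @param path Output path.
#' @param map The [site_map()] (supplies chromosome label and site labels).
#' @param unit Length unit column to emit, `"cM"` (genetic length) or `"Mb"`.
#' @export
write_match <- function(segments, path, map, unit = c("cM", "Mb")) {
  unit <- match.arg(unit)
  len <- if (unit == "cM") {
    sprintf("%.6g", segments$genetic_length_cM)
  } else {
    sprintf("%.6g", (segments$bp_end - segments$bp_start) / 1e6)
  }
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%.0f\t%.0f\ts%d\ts%d\t%d\t%s\t%s\t0\t0\t0",
                   segments$id_a, segments$id_a, segments$id_b, segments$id_b,
                   map$chrom, segments$bp_start, segments$bp_end,
                   segments$site_start, segments$site_end, segments$n_sites,
                   len, unit)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a phased allele matrix
#'
#' A documented plain-text exchange format for phased diplotypes: a TSV with
#' header columns `chrom`, `bp`, `cM`, then two allele columns per individual
#' named `<id>_1` and `<id>_2`; alleles are 0/1 with `.` for missing. The
#' reader and the VCF reader produce identical [phased_cohort()] objects for
#' the same data.
#'
#' @param cohort A [phased_cohort()].
#' @param path File path.
#' @return `read_allele_matrix()` returns a [phased_cohort()].
#' @export
write_allele_matrix <- function(cohort, path) {
  enc <- function(h) ifelse(is.na(h), ".", as.character(h))
  n_ind <- length(cohort$ids)
  cols <- vector("list", 2L * n_ind)
  nm <- character(2L * n_ind)
  for (k in seq_len(n_ind)) {
    cols[[2L * k - 1L]] <- enc(cohort$hap1[, k])
    cols[[2L * k]] <- enc(cohort$hap2[, k])
    nm[2L * k - 1L] <- paste0(cohort$ids[k], "_1")
    nm[2L * k] <- paste0(cohort$ids[k], "_2")
  }
  tab <- data.frame(chrom = cohort$map$chrom, bp = cohort$map$bp,
                    cM = cohort$map$cM, stats::setNames(cols, nm),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_allele_matrix
#' @export
read_allele_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("chrom", "bp", "cM") %in% names(tab))) {
    stop("allele matrix must have chrom, bp and cM columns")
  }
  acols <- setdiff(names(tab), c("chrom", "bp", "cM"))
  if (length(acols) %% 2L != 0L) {
    stop("allele matrix must have two columns per individual")
  }
  ids1 <- sub("_1$", "", acols[seq(1L, length(acols), 2L)])
  ids2 <- sub("_2$", "", acols[seq(2L, length(acols), 2L)])
  if (!identical(ids1, ids2)) {
    stop("allele columns must come in <id>_1/<id>_2 pairs")
  }
  dec <- function(x) {
    v <- suppressWarnings(as.integer(x))
    v[x == "."] <- NA_integer_
    v
  }
  map <- site_map(tab$chrom[1L], as.numeric(tab$bp), as.numeric(tab$cM))
  h1 <- vapply(acols[seq(1L, length(acols), 2L)], function(cn) dec(tab[[cn]]),
               integer(nrow(tab)))
  h2 <- vapply(acols[seq(2L, length(acols), 2L)], function(cn) dec(tab[[cn]]),
               integer(nrow(tab)))
  phased_cohort(ids1, h1, h2, map)
}

#' Read phased genotypes from a VCF
#'
#' Reads a VCF with phased GT fields (pipe-separated) into a
#' [phased_cohort()]. Multiallelic records and unphased genotypes are
#' rejected; `.` alleles become missing. Genetic coordinates are obtained by
#' interpolating the supplied HapMap-format genetic map at the record
#' positions.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param genetic_map Genetic map `data.frame` (see [read_genetic_map()]).
#' @return A [phased_cohort()].
#' @export
read_phased_vcf <- function(path, genetic_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop dimensions
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multiallelic records are not supported; split or drop them first")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE)) {
    stop("unphased genotypes found (expected pipe-separated GT)")
  }
  gt[is.na(gt)] <- ".|."
  a1 <- sub("\\|.*$", "", gt)
  a2 <- sub("^.*\\|", "", gt)
  dec <- function(x) {
    v <- suppressWarnings(as.integer(x))
    bad <- !is.na(v) & !v %in% c(0L, 1L)
    if (any(bad)) stop("alleles other than 0/1 found; sites must be biallelic")
    matrix(v, nrow(gt), ncol(gt))
  }
  bp <- as.numeric(fix[, "POS"])
  map <- site_map(fix[1L, "CHROM"], bp, interpolate_cM(genetic_map, bp))
  phased_cohort(colnames(gt), dec(a1), dec(a2), map)
}

#' Write a phased cohort as a minimal VCF
#'
#' @param cohort A [phased_cohort()].
#' @param path Output path.
#' @export
write_phased_vcf <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", cohort$map$chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", cohort$ids), collapse = "\t")), con)
  enc <- function(h) ifelse(is.na(h), ".", as.character(h))
  for (s in seq_len(n_sites(cohort$map))) {
    gts <- paste(enc(cohort$hap1[s, ]), enc(cohort$hap2[s, ]), sep = "|")
    writeLines(paste(c(cohort$map$chrom,
                       format(cohort$map$bp[s], scientific = FALSE),
                       sprintf("s%d", s), "A", "G", ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a trio pedigree TSV
#'
#' Three-column TSV with header `father`, `mother`, `child`.
#'
#' @param path File path.
#' @param trios A [trio_set()].
#' @param cohort Optional cohort for id validation on read.
#' @return `read_pedigree()` returns a [trio_set()].
#' @export
read_pedigree <- function(path, cohort = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("father", "mother", "child") %in% names(tab))) {
    stop("pedigree must have father, mother and child columns")
  }
  trio_set(tab$father, tab$mother, tab$child, cohort)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(trios, path) {
  utils::write.table(as.data.frame(trios)[, c("father", "mother", "child")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a score threshold matrix as TSV
#'
#' Long-format TSV with columns `length_bin_low`, `length_bin_high`,
#' `overlap_level`, `max_haploscore` (empty for missing thresholds).
#'
#' @param matrix A [build_threshold_matrix()] result.
#' @param path File path.
#' @return `read_threshold_matrix()` returns a `score_threshold_matrix`.
#' @export
write_threshold_matrix <- function(matrix, path) {
  n_len <- length(matrix$length_edges) - 1L
  tab <- data.frame(
    length_bin_low = rep(matrix$length_edges[seq_len(n_len)],
                         times = length(matrix$overlap_levels)),
    length_bin_high = rep(matrix$length_edges[seq_len(n_len) + 1L],
                          times = length(matrix$overlap_levels)),
    overlap_level = rep(matrix$overlap_levels, each = n_len),
    max_haploscore = as.vector(matrix$thresholds))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_matrix
#' @export
read_threshold_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  lows <- sort(unique(tab$length_bin_low))
  highs <- sort(unique(tab$length_bin_high))
  length_edges <- c(lows, highs[length(highs)])
  overlap_levels <- sort(unique(tab$overlap_level))
  thr <- matrix(NA_real_, length(lows), length(overlap_levels))
  li <- match(tab$length_bin_low, lows)
  oi <- match(tab$overlap_level, overlap_levels)
  thr[cbind(li, oi)] <- tab$max_haploscore
  structure(list(length_edges = length_edges, overlap_levels = overlap_levels,
                 thresholds = thr,
                 counts = matrix(NA_integer_, length(lows),
                                 length(overlap_levels))),
            class = "score_threshold_matrix")
}

#' Write a scored segment table as TSV
#'
#' @param scored Segment table with score columns (see [haploscore_batch()]).
#' @param path Output path.
#' @param params Optional named list recorded as `#key=value` header comments
#'   so every output carries the parameter set used.
#' @export
write_scores <- function(scored, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("#%s=%s", names(params),
                       vapply(params, format, character(1))), con)
  }
  utils::write.table(scored, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored segment TSV written by [write_scores()]
#'
#' @param path File path.
#' @return A data frame (header comment lines are skipped).
#' @export
read_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
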
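#' Read a HapMap-format genetic map
#'
#' Parses the whitespace-delimited three-column genetic map format used by the
#' Phase II HapMap recombination maps: physical position (bp), local
#' recombination rate (cM/Mb) and cumulative map position (cM), with one header
#' line.
#'
#' @param path Path to the map file.
#' @return A `data.frame` with columns `bp` (integer), `rate_cM_Mb` and `cM`.
#' @seealso [interpolate_cM()], [site_map()]
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, colClasses = "numeric")
  if (ncol(tab) < 3L) {
    stop("genetic map must have >= 3 columns (position bp, rate cM/Mb, map cM); got ",
         ncol(tab))
  }
  out <- data.frame(bp = as.numeric(tab[[1L]]),
                    rate_cM_Mb = as.numeric(tab[[2L]]),
                    cM = as.numeric(tab[[3L]]))
  validate_genetic_map(out)
  out
}

validate_genetic_map <- function(map) {
  if (!all(c("bp", "cM") %in% names(map))) {
    stop("genetic map needs 'bp' and 'cM' columns")
  }
  if (nrow(map) < 1L) stop("genetic map is empty")
  d <- diff(map$bp)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L] + 1L
    stop(sprintf("genetic map rows must be sorted by bp with no duplicates; row %d (bp=%s) is not greater than its predecessor",
                 i, format(map$bp[i], scientific = FALSE)))
  }
  if (any(diff(map$cM) < 0)) {
    i <- which(diff(map$cM) < 0)[1L] + 1L
    stop(sprintf("genetic map cM column must be non-decreasing; violated at row %d", i))
  }
  invisible(map)
}

#' Interpolate genetic map positions at physical positions
#'
#' Piecewise-linear interpolation of the cumulative cM column of a genetic map
#' at arbitrary bp positions. Positions outside the map range are clamped to
#' the cM values at the map ends (no extrapolation).
#'
#' @param map A `data.frame` with `bp` and `cM` columns, e.g. from
#'   [read_genetic_map()]. Rows must be sorted by bp with no duplicates.
#' @param bp Numeric vector of physical positions to interpolate at.
#' @return Numeric vector of cM positions, same length as `bp`; non-decreasing
#'   whenever `bp` is non-decreasing.
#' @examples
#' map <- data.frame(bp = c(0, 1e6), cM = c(0, 1))
#' interpolate_cM(map, c(0, 5e5, 2e6))  # 0.0 0.5 1.0
#' @export
interpolate_cM <- function(map, bp) {
  validate_genetic_map(map)
  if (length(bp) == 0L) return(numeric(0))
  if (nrow(map) == 1L) return(rep(map$cM[1L], length(bp)))
  stats::approx(map$bp, map$cM, xout = bp, method = "linear", rule = 2,
                ties = "ordered")$y
}

#' Site map: the coordinate backbone for a chromosome
#'
#' An ordered list of genotyped sites on one chromosome with both physical (bp)
#' and genetic (cM) coordinates. All segment arithmetic (site counts, genetic
#' lengths, bp endpoints) is performed against a site map.
#'
#' @param chrom Chromosome label (scalar character).
#' @param bp Strictly increasing vector of physical positions.
#' @param cM Non-decreasing vector of genetic map positions, one per site.
#'   Typically produced with [interpolate_cM()] from a HapMap-format map.
#' @return An object of class `site_map` with fields `chrom`, `bp`, `cM`.
#' @export
site_map <- function(chrom, bp, cM) {
  bp <- as.numeric(bp)
  cM <- as.numeric(cM)
  if (length(bp) != length(cM)) {
    stop("bp and cM must have the same length (one entry per site)")
  }
  if (length(bp) == 0L) stop("a site map needs at least one site")
  if (any(diff(bp) <= 0)) stop("bp positions must be strictly increasing")
  if (any(diff(cM) < 0)) stop("cM positions must be non-decreasing")
  structure(list(chrom = as.character(chrom)[1L], bp = bp, cM = cM),
            class = "site_map")
}

#' Build a site map by interpolating a genetic map at site positions
#'
#' @inheritParams site_map
#' @param map Genetic map `data.frame` (see [read_genetic_map()]).
#' @return A [site_map()].
#' @export
site_map_from_genetic_map <- function(chrom, bp, map) {
  site_map(chrom, bp, interpolate_cM(map, bp))
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("<site_map> chrom %s: %d sites, %.0f-%.0f bp, %.3f-%.3f cM\n",
              x$chrom, length(x$bp), x$bp[1L], x$bp[length(x$bp)],
              x$cM[1L], x$cM[length(x$cM)]))
  invisible(x)
}

n_sites <- function(map) length(map$bp)

#' Map a closed bp interval to the site indices it contains
#'
#' Returns the 1-based indices of the first and last site of `map` whose bp
#' position lies inside `[bp_start, bp_end]`. GERMLINE match files report
#' closed bp endpoints at the first and last contained site, so this is the
#' inverse of that convention.
#'
#' @param map A [site_map()].
#' @param bp_start,bp_end Closed physical interval.
#' @return Integer vector `c(site_start, site_end)`, or an error when the
#'   interval contains no site.
#' @export
bp_to_sites <- function(map, bp_start, bp_end) {
  s <- findInterval(bp_start - 1, map$bp) + 1L  # first site with bp >= bp_start
  e <- findInterval(bp_end, map$bp)             # last site with bp <= bp_end
  if (s > e || s > n_sites(map) || e < 1L) {
    stop(sprintf("bp interval [%s, %s] contains no site of the map",
                 format(bp_start, scientific = FALSE),
                 format(bp_end, scientific = FALSE)))
  }
  c(as.integer(s), as.integer(e))
}
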
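#' Candidate IBD segments
#'
#' Builds the segment table used throughout the package: one row per candidate
#' IBD match between two individuals, as a closed 1-based site-index interval
#' into a [site_map()], together with derived bp endpoints (positions of the
#' first and last contained site, the GERMLINE match-file convention), the
#' number of genotyped sites and the genetic length in cM.
#'
#' @param id_a,id_b Individual identifiers (recycled to common length).
#' @param site_start,site_end 1-based site indices, `site_start <= site_end`.
#' @param map The [site_map()] the indices refer to.
#' @return A `data.frame` with columns `id_a`, `id_b`, `site_start`,
#'   `site_end`, `n_sites`, `bp_start`, `bp_end`, `genetic_length_cM`.
#' @export
ibd_segments <- function(id_a, id_b, site_start, site_end, map) {
  n <- max(length(id_a), length(id_b), length(site_start), length(site_end))
  if (n == 0L) return(empty_segments())
  id_a <- rep_len(as.character(id_a), n)
  id_b <- rep_len(as.character(id_b), n)
  site_start <- rep_len(as.integer(site_start), n)
  site_end <- rep_len(as.integer(site_end), n)
  if (any(site_start < 1L) || any(site_end > n_sites(map))) {
    stop("segment site indices out of map range")
  }
  if (any(site_start > site_end)) {
    stop("segments must satisfy site_start <= site_end")
  }
  data.frame(id_a = id_a, id_b = id_b,
             site_start = site_start, site_end = site_end,
             n_sites = site_end - site_start + 1L,
             bp_start = map$bp[site_start], bp_end = map$bp[site_end],
             genetic_length_cM = map$cM[site_end] - map$cM[site_start],
             stringsAsFactors = FALSE)
}

empty_segments <- function() {
  data.frame(id_a = character(0), id_b = character(0),
             site_start = integer(0), site_end = integer(0),
             n_sites = integer(0), bp_start = numeric(0), bp_end = numeric(0),
             genetic_length_cM = numeric(0), stringsAsFactors = FALSE)
}

validate_segments <- function(segments, map = NULL) {
  need <- c("id_a", "id_b", "site_start", "site_end")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(segments) && any(segments$site_start > segments$site_end)) {
    stop("segments must satisfy site_start <= site_end")
  }
  if (!is.null(map) && nrow(segments) &&
      (any(segments$site_start < 1L) || any(segments$site_end > n_sites(map)))) {
    stop("segment site indices out of map range")
  }
  invisible(segments)
}

# Recompute derived columns (n_sites, bp, genetic length) from the site
# interval; used after readers or manual edits.
refresh_segments <- function(segments, map) {
  validate_segments(segments, map)
  ibd_segments(segments$id_a, segments$id_b,
               segments$site_start, segments$site_end, map)
}

# Unordered pair key for joining candidate and truth tables.
pair_key <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "\r")
}

# Total number of sites of [site_start, site_end] covered by the union of
# intervals in `starts`/`ends` (all 1-based closed). Used for segment overlap
# and truth labelling.
covered_sites <- function(site_start, site_end, starts, ends) {
  if (length(starts) == 0L) return(0L)
  s <- pmax(as.integer(starts), site_start)
  e <- pmin(as.integer(ends), site_end)
  keep <- s <= e
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0L
  cur_s <- s[1L]; cur_e <- e[1L]
  for (k in seq_along(s)[-1L]) {
    if (s[k] <= cur_e + 1L) {
      cur_e <- max(cur_e, e[k])
    } else {
      tot <- tot + (cur_e - cur_s + 1L)
      cur_s <- s[k]; cur_e <- e[k]
    }
  }
  tot + (cur_e - cur_s + 1L)
}
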
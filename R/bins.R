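#' Build a bin table
#'
#' A bin is the atomic unit repositioned by the sampler: a run of consecutive
#' restriction fragments on a source sequence. A bin can only be oriented if
#' it contains at least two restriction fragments, because orientation is
#' read off the internal arrangement of its fragments.
#'
#' @param length_bp integer vector of bin lengths in bp (> 0).
#' @param n_rf integer vector of restriction-fragment counts per bin (>= 1).
#' @param source_name character vector naming the originating contig or
#'   chromosome of each bin.
#' @param source_start,source_end 0-based half-open interval of each bin on
#'   its source sequence. Defaults to consecutive tiling per source.
#' @return A `data.frame` with one row per bin: `bin_id`, `length_bp`,
#'   `n_rf`, `source_name`, `source_start`, `source_end`, `orientable`.
#' @export
bin_table <- function(length_bp, n_rf, source_name,
                      source_start = NULL, source_end = NULL) {
  n <- length(length_bp)
  length_bp <- as.numeric(length_bp)
  n_rf <- as.integer(rep_len(n_rf, n))
  source_name <- as.character(rep_len(source_name, n))
  stopifnot(all(length_bp > 0), all(n_rf >= 1))
  if (is.null(source_start)) {
    # consecutive tiling within each source, in input order
    source_start <- numeric(n)
    source_end <- numeric(n)
    for (s in unique(source_name)) {
      idx <- which(source_name == s)
      e <- cumsum(length_bp[idx])
      source_start[idx] <- e - length_bp[idx]
      source_end[idx] <- e
    }
  }
  stopifnot(all(source_end - source_start == length_bp))
  data.frame(
    bin_id = seq_len(n),
    length_bp = length_bp,
    n_rf = n_rf,
    source_name = source_name,
    source_start = as.numeric(source_start),
    source_end = as.numeric(source_end),
    orientable = n_rf >= 2L,
    stringsAsFactors = FALSE
  )
}

#' Half-bin units of a bin table
#'
#' Contact counts are stored at sub-bin resolution: each orientable bin
#' (>= 2 restriction fragments) contributes two "units" (its two halves along
#' the source sequence), a non-orientable bin contributes one. Units are what
#' make bin orientation identifiable from contact data: flipping a bin swaps
#' the scaffold positions of its two halves, while a strictly bin-level
#' matrix is blind to orientation.
#'
#' @param bins a bin table from [bin_table()].
#' @return A `data.frame` with one row per unit: `unit`, `bin_id`, `half`
#'   (0 for whole-bin units, 1/2 for first/second half in source order) and
#'   `length_bp`.
#' @export
make_units <- function(bins) {
  nu <- ifelse(bins$orientable, 2L, 1L)
  bin_id <- rep.int(bins$bin_id, nu)
  half <- unlist(lapply(seq_len(nrow(bins)), function(i) {
    if (bins$orientable[i]) c(1L, 2L) else 0L
  }), use.names = FALSE)
  len <- ifelse(half == 0L, bins$length_bp[bin_id], bins$length_bp[bin_id] / 2)
  data.frame(unit = seq_along(bin_id), bin_id = bin_id, half = half,
             length_bp = len, stringsAsFactors = FALSE)
}

# Per-bin unit lookup vectors used by the flattener: first/second unit id
# (second is NA for single-unit bins).
unit_index <- function(bins, units) {
  u1 <- integer(nrow(bins))
  u2 <- rep(NA_integer_, nrow(bins))
  first <- !duplicated(units$bin_id)
  u1[units$bin_id[first]] <- units$unit[first]
  second <- duplicated(units$bin_id)
  u2[units$bin_id[second]] <- units$unit[second]
  list(u1 = u1, u2 = u2)
}
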
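#' Create a genome structure
#'
#' A genome structure is a partition of the bin universe into ordered,
#' oriented scaffolds plus a pool of unplaced (deleted) bins. Bins may be
#' placed more than once (duplications); every placement carries a
#' `copy_index` so that `(bin_id, copy_index)` identifies it uniquely.
#'
#' @param bins a bin table from [bin_table()].
#' @param scaffolds a list of placement matrices, one per scaffold, each with
#'   columns `bin`, `orient` (+1/-1) and `copy` (copy index, 0 for the first
#'   placement of a bin). `NULL` builds one scaffold per `source_name`, bins
#'   in source order, all forward.
#' @param unplaced integer vector of bin ids held out of all scaffolds.
#' @return An object of class `genome_structure`.
#' @seealso [initial_structure()], [apply_mutation()], [validate_structure()]
#' @export
genome_structure <- function(bins, scaffolds = NULL, unplaced = integer(0)) {
  units <- make_units(bins)
  if (is.null(scaffolds)) {
    src <- unique(bins$source_name)
    scaffolds <- lapply(src, function(s) {
      ids <- bins$bin_id[bins$source_name == s]
      ids <- setdiff(ids, unplaced)
      cbind(bin = ids, orient = rep(1L, length(ids)), copy = rep(0L, length(ids)))
    })
    scaffolds <- scaffolds[vapply(scaffolds, nrow, 1L) > 0L]
  }
  scaffolds <- lapply(scaffolds, function(m) {
    m <- matrix(as.integer(m), ncol = 3L,
                dimnames = list(NULL, c("bin", "orient", "copy")))
    m
  })
  gs <- structure(list(
    scaffolds = scaffolds,
    unplaced = as.integer(unplaced),
    bins = bins,
    units = units,
    uidx = unit_index(bins, units),
    next_copy = vapply(seq_len(nrow(bins)), function(b) {
      cp <- unlist(lapply(scaffolds, function(m) m[m[, 1L] == b, 3L]))
      if (length(cp)) max(cp) + 1L else 0L
    }, 1L),
    next_scaf = length(scaffolds) + 1L
  ), class = "genome_structure")
  names(gs$scaffolds) <- sprintf("scf%04d", seq_along(scaffolds))
  gs
}

#' Convenience initial structures
#'
#' @param bins a bin table.
#' @param mode `"by_source"` keeps each source sequence as one scaffold
#'   (curation/finishing start point); `"singletons"` puts every bin in its
#'   own scaffold (de novo start point, as when the sampler is initialised
#'   with a bag of unordered bins).
#' @return A `genome_structure`.
#' @export
initial_structure <- function(bins, mode = c("by_source", "singletons")) {
  mode <- match.arg(mode)
  if (mode == "by_source") return(genome_structure(bins))
  scafs <- lapply(bins$bin_id, function(b) cbind(bin = b, orient = 1L, copy = 0L))
  genome_structure(bins, scafs)
}

#' Number of contigs (scaffolds) of a structure
#'
#' The unplaced pool is not counted.
#' @param structure a `genome_structure`.
#' @return Integer scaffold count.
#' @export
n_contigs <- function(structure) length(structure$scaffolds)

#' Copy count of every bin
#'
#' @param structure a `genome_structure`.
#' @return Integer vector indexed by `bin_id`: number of placements of each
#'   bin (0 for unplaced bins).
#' @export
multiplicity <- function(structure) {
  n <- nrow(structure$bins)
  M <- do.call(rbind, structure$scaffolds)
  if (is.null(M)) return(integer(n))
  tabulate(M[, 1L], nbins = n)
}

#' All placements of a structure as a data frame
#'
#' @param structure a `genome_structure`.
#' @return `data.frame` with `scaffold`, `rank` (1-based within scaffold),
#'   `bin_id`, `orient`, `copy`.
#' @export
placements <- function(structure) {
  sc <- structure$scaffolds
  if (!length(sc)) {
    return(data.frame(scaffold = character(0), rank = integer(0),
                      bin_id = integer(0), orient = integer(0),
                      copy = integer(0)))
  }
  sizes <- lengths(sc) %/% 3L
  M <- do.call(rbind, sc)
  data.frame(
    scaffold = rep.int(names(sc), sizes),
    rank = unlist(lapply(sizes, seq_len), use.names = FALSE),
    bin_id = M[, 1L], orient = M[, 2L], copy = M[, 3L],
    stringsAsFactors = FALSE
  )
}

# copy indices of one placed bin
copies_of <- function(gs, bin) {
  M <- do.call(rbind, gs$scaffolds)
  if (is.null(M)) return(integer(0))
  unname(M[M[, 1L] == bin, 3L])
}

# Locate a placement (bin, copy). Returns c(scaffold index, row) or NULL.
find_placement <- function(structure, bin, copy = 0L) {
  for (s in seq_along(structure$scaffolds)) {
    m <- structure$scaffolds[[s]]
    r <- which(m[, 1L] == bin & m[, 3L] == copy)
    if (length(r)) return(c(s, r[1L]))
  }
  NULL
}

#' Genomic geometry of a placement pair
#'
#' Distance is measured midpoint to midpoint in bp using cumulative bin
#' lengths along the scaffold. Placements on different scaffolds are trans
#' and carry no distance.
#'
#' @param structure a `genome_structure`.
#' @param a,b placements, each `c(bin_id, copy_index)` (copy defaults to 0
#'   when a single id is given).
#' @return A list with `s` (bp, `NA` for trans) and `is_trans`.
#' @export
genomic_distance <- function(structure, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) == 1L) a <- c(a, 0L)
  if (length(b) == 1L) b <- c(b, 0L)
  pa <- find_placement(structure, a[1L], a[2L])
  pb <- find_placement(structure, b[1L], b[2L])
  if (is.null(pa) || is.null(pb)) stop("placement not found")
  if (pa[1L] != pb[1L]) return(list(s = NA_real_, is_trans = TRUE))
  m <- structure$scaffolds[[pa[1L]]]
  len <- structure$bins$length_bp[m[, 1L]]
  mid <- cumsum(len) - len / 2
  list(s = abs(mid[pa[2L]] - mid[pb[2L]]), is_trans = FALSE)
}

#' Check structure invariants
#'
#' Verifies that every bin of the universe is accounted for (placed with
#' matching multiplicity or unplaced), that `(bin, copy)` pairs are unique,
#' that no scaffold is empty, and that orientations are +1/-1.
#'
#' @param structure a `genome_structure`.
#' @return A list with `ok` (logical) and `violations` (character vector).
#' @export
validate_structure <- function(structure) {
  v <- character(0)
  n <- nrow(structure$bins)
  for (i in seq_along(structure$scaffolds)) {
    m <- structure$scaffolds[[i]]
    if (!is.matrix(m) || ncol(m) != 3L) { v <- c(v, sprintf("scaffold %d malformed", i)); next }
    if (nrow(m) == 0L) v <- c(v, sprintf("scaffold %d is empty", i))
    if (any(m[, 1L] < 1L | m[, 1L] > n)) v <- c(v, sprintf("scaffold %d references unknown bin", i))
    if (any(!m[, 2L] %in% c(-1L, 1L))) v <- c(v, sprintf("scaffold %d has invalid orientation", i))
  }
  pl <- placements(structure)
  key <- paste(pl$bin_id, pl$copy)
  if (anyDuplicated(key)) v <- c(v, "duplicated (bin, copy) placement")
  mult <- multiplicity(structure)
  placed <- which(mult > 0L)
  if (length(intersect(placed, structure$unplaced)))
    v <- c(v, "bin both placed and unplaced")
  missing <- setdiff(seq_len(n), union(placed, structure$unplaced))
  if (length(missing))
    v <- c(v, sprintf("bins neither placed nor unplaced: %s",
                      paste(missing, collapse = ",")))
  if (any(mult[structure$unplaced] > 0L))
    v <- c(v, "unplaced bin has placements")
  list(ok = length(v) == 0L, violations = v)
}

#' Reverse one scaffold in place
#'
#' Reverses the order of placements and flips every orientation. A structure
#' and its scaffold-reversed image are equivalent (strand symmetry).
#'
#' @param structure a `genome_structure`.
#' @param which scaffold index or name.
#' @return The modified `genome_structure`.
#' @export
reverse_scaffold <- function(structure, which) {
  m <- structure$scaffolds[[which]]
  structure$scaffolds[[which]] <- rev_segment(m)
  structure
}

# reverse a placement-matrix segment: flip order and orientations
rev_segment <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[, 2L] <- -m[, 2L]
  m
}

#' @export
print.genome_structure <- function(x, ...) {
  mult <- multiplicity(x)
  cat(sprintf("genome structure: %d scaffolds, %d bins (%d placed, %d unplaced, %d duplicated)\n",
              n_contigs(x), nrow(x$bins), sum(mult > 0L),
              length(x$unplaced), sum(mult > 1L)))
  sizes <- vapply(x$scaffolds, nrow, 1L)
  if (length(sizes))
    cat(sprintf("scaffold sizes (bins): %s\n",
                paste(utils::head(sort(sizes, decreasing = TRUE), 20L), collapse = " ")))
  invisible(x)
}

# ---- flattening to placed half-bin units (likelihood input) ----

# Returns parallel vectors over placed units: scaf (1-based scaffold group),
# pos (unit midpoint bp within scaffold), len (unit length), unit (data unit
# id). Orientation enters here: reversing a bin swaps the scaffold positions
# of its two halves.
flatten_structure <- function(gs) {
  sc <- gs$scaffolds
  nsc <- length(sc)
  if (!nsc) return(list(scaf = integer(0), pos = numeric(0),
                        len = numeric(0), unit = integer(0)))
  sizes <- lengths(sc) %/% 3L
  M <- do.call(rbind, sc)
  bin <- M[, 1L]; orient <- M[, 2L]
  scaf_id <- rep.int(seq_len(nsc), sizes)
  len <- gs$bins$length_bp[bin]
  cum <- cumsum(len)
  ends <- cumsum(sizes)
  before <- c(0, cum[ends])[scaf_id]
  start <- cum - len - before
  u1 <- gs$uidx$u1[bin]; u2 <- gs$uidx$u2[bin]
  two <- !is.na(u2)
  if (!any(two))
    return(list(scaf = scaf_id, pos = start + len / 2, len = len, unit = u1))
  t2 <- which(two)
  q <- len[t2] / 4
  rev2 <- 2 * q * (orient[t2] != 1L) # reversed bins swap their halves
  pos1 <- start + len / 2
  len1 <- len
  pos1[t2] <- start[t2] + q + rev2
  len1[t2] <- 2 * q
  list(scaf = c(scaf_id, scaf_id[t2]),
       pos = c(pos1, start[t2] + 3 * q - rev2),
       len = c(len1, 2 * q),
       unit = c(u1, u2[t2]))
}

# ---- layout serialisation ----

#' Write / read a structure layout file
#'
#' Tab-separated, one row per placement: `scaffold`, `rank`, `bin_id`,
#' `orientation` (+/-), `copy_index`. Round-trips losslessly against the
#' same bin table.
#'
#' @param structure a `genome_structure`.
#' @param path file path.
#' @export
write_layout <- function(structure, path) {
  pl <- placements(structure)
  pl$orientation <- ifelse(pl$orient == 1L, "+", "-")
  out <- pl[, c("scaffold", "rank", "bin_id", "orientation", "copy")]
  names(out)[5L] <- "copy_index"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param bins the bin table the layout refers to.
#' @rdname write_layout
#' @export
read_layout <- function(path, bins) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("scaffold", "rank", "bin_id", "orientation", "copy_index")
                %in% names(d)))
  d <- d[order(match(d$scaffold, unique(d$scaffold)), d$rank), ]
  scafs <- lapply(split(d, factor(d$scaffold, levels = unique(d$scaffold))),
                  function(g) cbind(bin = g$bin_id,
                                    orient = ifelse(g$orientation == "+", 1L, -1L),
                                    copy = g$copy_index))
  unplaced <- setdiff(bins$bin_id, d$bin_id)
  gs <- genome_structure(bins, unname(scafs), unplaced = unplaced)
  names(gs$scaffolds) <- unique(d$scaffold)
  gs
}
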
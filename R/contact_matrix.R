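#' Create a contact matrix
#'
#' Observed ligation counts between pairs of half-bin units (see
#' [make_units()]): orientable bins contribute two units, so that bin
#' orientation is identifiable; a bin-level view is available through
#' [bin_counts()]. Counts are symmetric; the diagonal (within-unit contacts)
#' is permitted.
#'
#' @param bins a bin table from [bin_table()].
#' @param counts either a `data.frame` with columns `i`, `j`, `k` of
#'   unit-level counts (either triangle accepted), or a dense symmetric
#'   matrix over units.
#' @return An object of class `contact_matrix` with fields `bins`, `units`,
#'   `trip` (upper-triangle triplets, `i <= j`), `n_bins`, `n_units`,
#'   `total_contacts`.
#' @export
contact_matrix <- function(bins, counts) {
  units <- make_units(bins)
  nu <- nrow(units)
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == nu, ncol(counts) == nu)
    idx <- which(upper.tri(counts, diag = TRUE) & counts != 0, arr.ind = TRUE)
    low <- which(lower.tri(counts) & counts != 0)
    if (length(low) && !isTRUE(all.equal(counts, t(counts))))
      stop("dense counts must be symmetric")
    trip <- data.frame(i = idx[, 1L], j = idx[, 2L], k = counts[idx])
  } else {
    trip <- data.frame(i = as.integer(counts$i), j = as.integer(counts$j),
                       k = as.numeric(counts$k))
    stopifnot(all(trip$i >= 1L & trip$i <= nu),
              all(trip$j >= 1L & trip$j <= nu))
    swap <- trip$i > trip$j
    tmp <- trip$i[swap]; trip$i[swap] <- trip$j[swap]; trip$j[swap] <- tmp
    if (anyDuplicated(paste(trip$i, trip$j))) {
      agg <- stats::aggregate(k ~ i + j, data = trip, FUN = sum)
      trip <- agg
    }
    trip <- trip[trip$k != 0, , drop = FALSE]
  }
  if (any(trip$k < 0)) stop("contact counts must be non-negative")
  trip <- trip[order(trip$i, trip$j), , drop = FALSE]
  rownames(trip) <- NULL
  structure(list(
    bins = bins, units = units, trip = trip,
    n_bins = nrow(bins), n_units = nu,
    total_contacts = sum(trip$k),
    lgamma_const = sum(lgamma(trip$k + 1))
  ), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact matrix: %d bins (%d units), %s contacts on %d non-zero pairs\n",
              x$n_bins, x$n_units, format(x$total_contacts, big.mark = ","),
              nrow(x$trip)))
  invisible(x)
}

#' Bin-level count matrix
#'
#' Aggregates unit-level counts to a dense symmetric bin-by-bin matrix.
#'
#' @param data a `contact_matrix`.
#' @return Dense symmetric numeric matrix, `n_bins` x `n_bins`.
#' @export
bin_counts <- function(data) {
  b <- data$units$bin_id
  n <- data$n_bins
  K <- unit_counts(data)
  Tm <- matrix(0, data$n_units, n)
  Tm[cbind(seq_len(data$n_units), b)] <- 1
  crossprod(Tm, K %*% Tm)
}

#' Dense unit-level count matrix
#' @param data a `contact_matrix`.
#' @return Dense symmetric numeric matrix over units.
#' @export
unit_counts <- function(data) {
  n <- data$n_units
  M <- matrix(0, n, n)
  M[cbind(data$trip$i, data$trip$j)] <- data$trip$k
  M[cbind(data$trip$j, data$trip$i)] <- data$trip$k
  M
}

#' Write / read a contact matrix as plain text
#'
#' Writes three tab-separated files: `<prefix>.mat.tsv` (upper-triangle
#' unit-level triplets `unit_i`, `unit_j`, `count`), `<prefix>.bins.tsv`
#' (`bin_id`, `source_name`, `start`, `end`, `n_rf`, `length_bp`) and
#' `<prefix>.units.tsv` (`unit`, `bin_id`, `half`, `length_bp`). The reader
#' also accepts a matrix file whose `unit` columns index bins directly (no
#' units file): such bin-level counts are spread evenly over the half-bin
#' unit pairs, which preserves totals but carries no orientation
#' information.
#'
#' @param data a `contact_matrix`.
#' @param prefix path prefix for the three files.
#' @return `read_contacts` returns a `contact_matrix`.
#' @export
write_contacts <- function(data, prefix) {
  write.table(setNames(data$trip, c("unit_i", "unit_j", "count")),
              paste0(prefix, ".mat.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  b <- data$bins
  write.table(data.frame(bin_id = b$bin_id, source_name = b$source_name,
                         start = b$source_start, end = b$source_end,
                         n_rf = b$n_rf, length_bp = b$length_bp),
              paste0(prefix, ".bins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data$units, paste0(prefix, ".units.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(prefix) {
  bt <- read.delim(paste0(prefix, ".bins.tsv"), stringsAsFactors = FALSE)
  bins <- bin_table(bt$length_bp, bt$n_rf, bt$source_name, bt$start, bt$end)
  mat <- read.delim(paste0(prefix, ".mat.tsv"), stringsAsFactors = FALSE)
  trip <- data.frame(i = mat[[1L]], j = mat[[2L]], k = mat[[3L]])
  ufile <- paste0(prefix, ".units.tsv")
  if (file.exists(ufile)) return(contact_matrix(bins, trip))
  # bin-level triplets: spread each count evenly over the unit pairs
  units <- make_units(bins)
  ulist <- split(units$unit, units$bin_id)
  out <- list()
  for (r in seq_len(nrow(trip))) {
    ui <- ulist[[as.character(trip$i[r])]]
    uj <- ulist[[as.character(trip$j[r])]]
    grid <- expand.grid(i = ui, j = uj)
    if (trip$i[r] == trip$j[r]) grid <- grid[grid$i <= grid$j, , drop = FALSE]
    grid$k <- trip$k[r] / nrow(grid)
    out[[r]] <- grid
  }
  contact_matrix(bins, do.call(rbind, out))
}
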
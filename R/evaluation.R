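# Canonical oriented adjacency keys of a structure. An adjacency
# (a, oa) -> (b, ob) and its reverse complement (b, -ob) -> (a, -oa)
# describe the same junction, so each pair is stored under the
# lexicographically smaller of the two encodings.
adjacency_keys <- function(structure) {
  out <- character(0)
  for (m in structure$scaffolds) {
    n <- nrow(m)
    if (n < 2L) next
    a <- m[-n, , drop = FALSE]; b <- m[-1L, , drop = FALSE]
    k1 <- paste(a[, 1L], a[, 2L], b[, 1L], b[, 2L], sep = ":")
    k2 <- paste(b[, 1L], -b[, 2L], a[, 1L], -a[, 2L], sep = ":")
    out <- c(out, pmin(k1, k2))
  }
  out
}

#' Order-and-orientation reconstruction error
#'
#' Fraction of the reference's oriented bin adjacencies missing from the
#' assembly. An adjacency matches when present directly or as its reverse
#' complement, so whole-scaffold reversals do not count as errors.
#' Duplicated bins are compared as multisets of adjacencies.
#'
#' @param assembly,reference `genome_structure`s over the same bin
#'   universe.
#' @return Error fraction in `[0, 1]` (0 iff every reference adjacency is
#'   recovered).
#' @export
reconstruction_error <- function(assembly, reference) {
  if (!setequal(assembly$bins$bin_id, reference$bins$bin_id))
    stop("assembly and reference have different bin universes")
  ref <- adjacency_keys(reference)
  if (!length(ref)) return(0)
  asm <- adjacency_keys(assembly)
  tr <- table(ref); ta <- table(asm)
  common <- intersect(names(tr), names(ta))
  matched <- sum(pmin(tr[common], ta[common]))
  1 - matched / length(ref)
}

#' Chromosome assignment accuracy
#'
#' Each assembly scaffold is mapped to the reference chromosome
#' contributing most of its length (majority rule); a bin placement is
#' correctly assigned when its scaffold maps to the bin's true chromosome.
#'
#' @inheritParams reconstruction_error
#' @return Percentage in `[0, 100]`.
#' @export
chromosome_assignment_accuracy <- function(assembly, reference) {
  truth_chrom <- bin_chromosome(reference)
  len <- reference$bins$length_bp
  good <- 0L; total <- 0L
  for (m in assembly$scaffolds) {
    ch <- truth_chrom[m[, 1L]]
    w <- tapply(len[m[, 1L]], ch, sum)
    major <- names(w)[which.max(w)]
    good <- good + sum(ch == major)
    total <- total + nrow(m)
  }
  if (!total) return(0)
  100 * good / total
}

# reference scaffold (chromosome) id of every bin; unplaced bins get NA
bin_chromosome <- function(reference) {
  out <- rep(NA_character_, nrow(reference$bins))
  for (i in seq_along(reference$scaffolds)) {
    m <- reference$scaffolds[[i]]
    out[m[, 1L]] <- names(reference$scaffolds)[i] %||% as.character(i)
  }
  out
}

#' Ordering accuracy and rank errors
#'
#' `ordered_pct` is the percentage of bins whose set of immediate
#' neighbours (bin ids, orientation ignored) matches the reference.
#' Rank errors compare each bin's position index within its assembly
#' scaffold with its position within its reference chromosome, after
#' choosing the direction of each assembly scaffold that minimises its
#' total rank error (so reversed scaffolds score zero).
#'
#' @inheritParams reconstruction_error
#' @return A list with `ordered_pct`, `rank_error_mean`,
#'   `rank_error_median`.
#' @export
ordering_and_rank <- function(assembly, reference) {
  nb <- nrow(reference$bins)
  nbrs <- function(structure) {
    out <- vector("list", nb)
    for (m in structure$scaffolds) {
      ids <- m[, 1L]; n <- length(ids)
      for (r in seq_len(n)) {
        nb_ids <- ids[c(r - 1L, r + 1L)[c(r > 1L, r < n)]]
        out[[ids[r]]] <- sort(unique(c(out[[ids[r]]], nb_ids)))
      }
    }
    out
  }
  na <- nbrs(assembly); nr <- nbrs(reference)
  placed <- which(multiplicity(reference) > 0L & multiplicity(assembly) > 0L)
  ordered <- vapply(placed, function(b) identical(na[[b]], nr[[b]]), TRUE)

  ref_rank <- rep(NA_real_, nb)
  for (m in reference$scaffolds) ref_rank[m[, 1L]] <- seq_len(nrow(m))
  errs <- numeric(0)
  for (m in assembly$scaffolds) {
    ids <- m[, 1L]
    rr <- ref_rank[ids]
    fwd <- abs(seq_along(ids) - rr)
    bwd <- abs(rev(seq_along(ids)) - rr)
    e <- if (sum(fwd, na.rm = TRUE) <= sum(bwd, na.rm = TRUE)) fwd else bwd
    errs <- c(errs, e[!is.na(e)])
  }
  list(ordered_pct = 100 * mean(ordered),
       rank_error_mean = if (length(errs)) mean(errs) else NA_real_,
       rank_error_median = if (length(errs)) median(errs) else NA_real_)
}

#' Full assembly-quality report
#'
#' @param assembly a `genome_structure` (or a `proxiscaf` fit, whose best
#'   structure is used).
#' @param reference the reference `genome_structure`.
#' @param trace optional fit or trace for the contig-count dispersion.
#' @return An object of class `assembly_report`: `error`, `n_contigs`,
#'   `iqr_contigs`, `chrom_assignment_pct`, `ordered_pct`,
#'   `rank_error_mean`, `rank_error_median`.
#' @export
assembly_report <- function(assembly, reference, trace = NULL) {
  if (inherits(assembly, "proxiscaf")) {
    trace <- trace %||% assembly
    assembly <- assembly$best
  }
  oar <- ordering_and_rank(assembly, reference)
  rep <- list(
    error = reconstruction_error(assembly, reference),
    n_contigs = n_contigs(assembly),
    iqr_contigs = if (!is.null(trace)) dispersion(trace) else NA_real_,
    chrom_assignment_pct = chromosome_assignment_accuracy(assembly, reference),
    ordered_pct = oar$ordered_pct,
    rank_error_mean = oar$rank_error_mean,
    rank_error_median = oar$rank_error_median
  )
  class(rep) <- "assembly_report"
  rep
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("reconstruction error: %.4f\n", x$error))
  cat(sprintf("contigs: %d (iqr %s)\n", x$n_contigs,
              ifelse(is.na(x$iqr_contigs), "NA",
                     sprintf("%.2f", x$iqr_contigs))))
  cat(sprintf("chromosome assignment: %.1f%%\n", x$chrom_assignment_pct))
  cat(sprintf("accurately ordered bins: %.1f%%\n", x$ordered_pct))
  cat(sprintf("rank error: mean %.2f, median %.1f\n",
              x$rank_error_mean, x$rank_error_median))
  invisible(x)
}

#' Write a report as key-value text and JSON
#'
#' @param report an [assembly_report()].
#' @param prefix path prefix; writes `<prefix>.txt` and `<prefix>.json`.
#' @export
write_report <- function(report, prefix) {
  vals <- unclass(report)
  txt <- paste(names(vals), vapply(vals, format, ""), sep = "\t")
  writeLines(txt, paste0(prefix, ".txt"))
  jsonlite::write_json(vals, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
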
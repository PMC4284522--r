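# Are two consecutive placements seamless in the source assembly (same
# source sequence, abutting spans, consistent orientations)? If so no gap
# is written between them.
seamless <- function(bins, a, b) {
  ba <- bins[a[1L], ]; bb <- bins[b[1L], ]
  if (ba$source_name != bb$source_name) return(FALSE)
  if (a[2L] != b[2L]) return(FALSE)
  if (a[2L] == 1L) ba$source_end == bb$source_start
  else bb$source_end == ba$source_start
}

#' Write a structure as AGP v2.1
#'
#' One component line (`W`) per placed bin, pointing at the bin's span on
#' its source sequence; a 100-N gap line of type `scaffold` (evidence
#' `proximity_ligation`) is placed between bins that were not adjacent in
#' the input assembly.
#'
#' @param structure a `genome_structure`.
#' @param path output file.
#' @param gap_len gap length in N (default 100).
#' @return The path, invisibly.
#' @export
write_agp <- function(structure, path, gap_len = 100L) {
  bins <- structure$bins
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (si in seq_along(structure$scaffolds)) {
    m <- structure$scaffolds[[si]]
    obj <- names(structure$scaffolds)[si] %||% sprintf("scf%04d", si)
    pos <- 0L; part <- 0L
    for (r in seq_len(nrow(m))) {
      if (r > 1L && !seamless(bins, m[r - 1L, ], m[r, ])) {
        part <- part + 1L
        writeLines(sprintf("%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\tproximity_ligation",
                           obj, pos + 1L, pos + gap_len, part, gap_len), con)
        pos <- pos + gap_len
      }
      b <- bins[m[r, 1L], ]
      L <- as.integer(b$length_bp)
      part <- part + 1L
      writeLines(sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s",
                         obj, pos + 1L, pos + L, part,
                         b$source_name, as.integer(b$source_start) + 1L,
                         as.integer(b$source_end),
                         if (m[r, 2L] == 1L) "+" else "-"), con)
      pos <- pos + L
    }
  }
  invisible(path)
}

#' Read an AGP file back into a genome structure
#'
#' Components are matched to bins by (source name, span); copy indices are
#' assigned in order of appearance per bin. Together with [write_agp()]
#' this round-trips a layout losslessly.
#'
#' @param path AGP file.
#' @param bins the bin table the AGP components refer to.
#' @return A `genome_structure`.
#' @export
read_agp <- function(path, bins) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 1L) >= 9L]
  comp <- Filter(function(x) x[[5L]] == "W", f)
  key <- paste(bins$source_name, bins$source_start + 1L, bins$source_end)
  seen <- integer(nrow(bins))
  obj <- vapply(comp, `[[`, "", 1L)
  rows <- lapply(comp, function(x) {
    b <- match(paste(x[[6L]], x[[7L]], x[[8L]]), key)
    if (is.na(b)) stop("AGP component does not match any bin: ", x[[6L]])
    b
  })
  scafs <- list()
  for (o in unique(obj)) {
    sel <- which(obj == o)
    mb <- integer(0); mo <- integer(0); mc <- integer(0)
    for (i in sel) {
      b <- rows[[i]]
      mb <- c(mb, b)
      mo <- c(mo, if (comp[[i]][[9L]] == "+") 1L else -1L)
      mc <- c(mc, seen[b])
      seen[b] <- seen[b] + 1L
    }
    scafs[[o]] <- cbind(bin = mb, orient = mo, copy = mc)
  }
  unplaced <- setdiff(bins$bin_id, unlist(lapply(scafs, function(m) m[, 1L])))
  gs <- genome_structure(bins, unname(scafs), unplaced = unplaced)
  names(gs$scaffolds) <- names(scafs)
  gs
}

#' Write scaffold sequences as FASTA
#'
#' Extracts each placed bin's span from the source sequences (reverse
#' complemented for `-` placements) and concatenates them per scaffold,
#' with `gap_len` Ns between bins that were not adjacent in the input.
#'
#' @param structure a `genome_structure`.
#' @param sequences source FASTA path or `DNAStringSet` (names must match
#'   the bin table's source names).
#' @param path output FASTA path.
#' @param gap_len gap length in N.
#' @return The path, invisibly.
#' @export
write_scaffold_fasta <- function(structure, sequences, path, gap_len = 100L) {
  if (is.character(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  bins <- structure$bins
  gap <- strrep("N", gap_len)
  out <- character(length(structure$scaffolds))
  for (si in seq_along(structure$scaffolds)) {
    m <- structure$scaffolds[[si]]
    parts <- character(nrow(m))
    for (r in seq_len(nrow(m))) {
      b <- bins[m[r, 1L], ]
      s <- Biostrings::subseq(sequences[[b$source_name]],
                              start = b$source_start + 1L, end = b$source_end)
      if (m[r, 2L] == -1L) s <- Biostrings::reverseComplement(s)
      pre <- if (r > 1L && !seamless(bins, m[r - 1L, ], m[r, ])) gap else ""
      parts[r] <- paste0(pre, as.character(s))
    }
    out[si] <- paste0(parts, collapse = "")
  }
  dss <- Biostrings::DNAStringSet(out)
  names(dss) <- names(structure$scaffolds)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
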
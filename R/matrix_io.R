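#' Digest sequences at a restriction site
#'
#' Cuts every sequence immediately before each occurrence of the
#' recognition motif on the forward strand (e.g. `GATC` for DpnII), so the
#' restriction fragments tile each sequence exactly.
#'
#' @param sequences a FASTA file path, a `Biostrings::DNAStringSet`, or a
#'   named character vector of sequences.
#' @param site recognition motif, ACGT letters only (ambiguity codes are
#'   not supported).
#' @return A restriction map: `data.frame` with `seq_name`, `frag`
#'   (1-based index within the sequence), `start`, `end` (0-based
#'   half-open).
#' @export
digest <- function(sequences, site) {
  if (!nzchar(site) || grepl("[^ACGTacgt]", site))
    stop("restriction site must be non-empty and contain only A, C, G, T")
  site <- toupper(site)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  } else if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  hits <- Biostrings::vmatchPattern(site, sequences, fixed = TRUE)
  out <- lapply(seq_along(sequences), function(i) {
    L <- Biostrings::width(sequences)[i]
    cuts <- Biostrings::start(hits[[i]]) - 1L # 0-based cut before the motif
    cuts <- cuts[cuts > 0L & cuts < L]
    b <- c(0L, sort(unique(cuts)), L)
    data.frame(seq_name = names(sequences)[i],
               frag = seq_len(length(b) - 1L),
               start = b[-length(b)], end = b[-1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group restriction fragments into bins
#'
#' Greedy left-to-right grouping per sequence: a bin is closed as soon as
#' it holds at least `min_rf` fragments and (when `target_bp` is given) at
#' least `target_bp` bp. A trailing bin below `min_rf` fragments is merged
#' into its left neighbour; bins never span sequences. A sequence with
#' fewer than `min_rf` fragments in total yields a single non-orientable
#' bin.
#'
#' @param rmap a restriction map from [digest()].
#' @param min_rf minimum restriction fragments per bin (2 keeps every bin
#'   orientable; use 3 for noisy de novo contigs).
#' @param target_bp optional minimum bin length in bp.
#' @return A [bin_table()].
#' @export
make_bins <- function(rmap, min_rf = 2L, target_bp = NULL) {
  stopifnot(min_rf >= 1L)
  res <- list()
  for (s in unique(rmap$seq_name)) {
    fr <- rmap[rmap$seq_name == s, , drop = FALSE]
    groups <- integer(nrow(fr))
    g <- 1L; cnt <- 0L; len <- 0
    for (i in seq_len(nrow(fr))) {
      groups[i] <- g
      cnt <- cnt + 1L
      len <- len + (fr$end[i] - fr$start[i])
      if (cnt >= min_rf && (is.null(target_bp) || len >= target_bp) &&
          i < nrow(fr)) {
        g <- g + 1L; cnt <- 0L; len <- 0
      }
    }
    # merge an undersized trailing bin leftwards
    last <- groups == max(groups)
    if (sum(last) < min_rf && max(groups) > 1L)
      groups[last] <- max(groups) - 1L
    st <- tapply(fr$start, groups, min)
    en <- tapply(fr$end, groups, max)
    nrf <- tapply(groups, groups, length)
    res[[s]] <- data.frame(source_name = s, start = as.numeric(st),
                           end = as.numeric(en), n_rf = as.integer(nrf),
                           stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, res)
  bin_table(length_bp = d$end - d$start, n_rf = d$n_rf,
            source_name = d$source_name,
            source_start = d$start, source_end = d$end)
}

#' Read fragment-level contact pairs
#'
#' Tab-separated, one pair per line, eight columns: `seq1`, `pos1`,
#' `strand1` (+/-), `mapq1`, `seq2`, `pos2`, `strand2`, `mapq2`. Mapping of
#' raw reads is out of scope: these are pre-mapped records (a SAM/BAM file
#' can be converted with e.g. `samtools view` + awk into these columns).
#'
#' @param path file path (header optional; detected on the first line).
#' @return A `data.frame` with the eight columns above.
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("seq1", first, fixed = TRUE)
  d <- read.delim(path, header = header, stringsAsFactors = FALSE)
  names(d) <- c("seq1", "pos1", "strand1", "mapq1",
                "seq2", "pos2", "strand2", "mapq2")
  d
}

#' Build a contact matrix from fragment-level pairs
#'
#' Applies the standard filters in order: pairs with either mate's mapping
#' quality at or below `mapq_min` are dropped (strictly greater than 30 is
#' retained by default); mates are assigned to restriction fragments and
#' same-fragment pairs are dropped; exact duplicate pairs (same coordinates
#' and strands, unordered) are collapsed to one. Remaining pairs increment
#' the count of their (unit, unit) pair, assigning each mate to the half of
#' its bin that contains its fragment position.
#'
#' @param pairs a `data.frame` from [read_pairs()].
#' @param rmap restriction map from [digest()].
#' @param bins bin table from [make_bins()] (derived from `rmap`).
#' @param mapq_min mapping-quality threshold (exclusive).
#' @return A `contact_matrix`; `attr(, "filter_stats")` reports input,
#'   retained and per-filter dropped counts (which always sum to the
#'   input).
#' @export
build_matrix <- function(pairs, rmap, bins, mapq_min = 30L) {
  n_in <- nrow(pairs)
  stats <- c(input = n_in, mapq = 0L, unknown_seq = 0L, same_fragment = 0L,
             duplicate = 0L, retained = 0L)

  keep <- pairs$mapq1 > mapq_min & pairs$mapq2 > mapq_min
  stats["mapq"] <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]

  known <- pairs$seq1 %in% rmap$seq_name & pairs$seq2 %in% rmap$seq_name
  stats["unknown_seq"] <- sum(!known)
  pairs <- pairs[known, , drop = FALSE]

  # fragment assignment (global fragment index over the restriction map)
  frag_of <- function(seqs, pos) {
    out <- integer(length(seqs))
    for (s in unique(seqs)) {
      fr <- which(rmap$seq_name == s)
      sel <- seqs == s
      out[sel] <- fr[findInterval(pos[sel], rmap$start[fr])]
    }
    out
  }
  f1 <- frag_of(pairs$seq1, pairs$pos1)
  f2 <- frag_of(pairs$seq2, pairs$pos2)

  same <- f1 == f2
  stats["same_fragment"] <- sum(same)
  pairs <- pairs[!same, , drop = FALSE]
  f1 <- f1[!same]; f2 <- f2[!same]

  a <- paste(pairs$seq1, pairs$pos1, pairs$strand1)
  bkey <- paste(pairs$seq2, pairs$pos2, pairs$strand2)
  key <- ifelse(a < bkey, paste(a, bkey, sep = "|"), paste(bkey, a, sep = "|"))
  dup <- duplicated(key)
  stats["duplicate"] <- sum(dup)
  pairs <- pairs[!dup, , drop = FALSE]
  f1 <- f1[!dup]; f2 <- f2[!dup]
  stats["retained"] <- nrow(pairs)

  # map each mate to a half-bin unit
  units <- make_units(bins)
  uix <- unit_index(bins, units)
  unit_of <- function(seqs, pos) {
    out <- integer(length(seqs))
    for (s in unique(seqs)) {
      sel <- seqs == s
      bsel <- which(bins$source_name == s)
      bi <- bsel[findInterval(pos[sel], bins$source_start[bsel])]
      off <- pos[sel] - bins$source_start[bi]
      second <- bins$orientable[bi] & off >= bins$length_bp[bi] / 2
      out[sel] <- ifelse(second, uix$u2[bi], uix$u1[bi])
    }
    out
  }
  u1 <- unit_of(pairs$seq1, pairs$pos1)
  u2 <- unit_of(pairs$seq2, pairs$pos2)

  trip <- if (length(u1)) data.frame(i = u1, j = u2, k = 1)
          else data.frame(i = integer(0), j = integer(0), k = numeric(0))
  cm <- contact_matrix(bins, trip)
  attr(cm, "filter_stats") <- stats
  cm
}
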
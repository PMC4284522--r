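#' Chromosome length presets
#'
#' `yeast_chrom_lengths` holds the 16 S. cerevisiae chromosome lengths (bp,
#' sacCer3); `human_subset_lengths` the hg19 lengths of chromosomes 7, 17,
#' 19 and 22. Simulated genomes reuse their length *ratios* at reduced
#' scale.
#' @export
yeast_chrom_lengths <- c(
  chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
  chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
  chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
  chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066
)

#' @rdname yeast_chrom_lengths
#' @export
human_subset_lengths <- c(
  chr7 = 159138663, chr17 = 81195210, chr19 = 59128983, chr22 = 51304566
)

#' Sequencing depth matching a per-bin contact budget
#'
#' Total contact count giving each bin the same expected number of incident
#' contacts regardless of genome size. The default budget (about 19,300
#' incident contacts per bin) corresponds to a deeply sequenced
#' chromosome-contact library on a yeast-scale genome and is the package's
#' full-depth study condition.
#'
#' @param n_bins number of bins.
#' @param per_bin incident contacts per bin.
#' @return Integer total contact count.
#' @export
depth_for_bins <- function(n_bins, per_bin = 19333) {
  as.integer(round(per_bin * n_bins / 2))
}

#' Build a synthetic multi-chromosome genome
#'
#' Bins of fixed size are distributed over chromosomes proportionally to
#' the given lengths (each chromosome gets at least two bins). All bins are
#' orientable (`n_rf` restriction fragments each). The returned truth
#' structure has one forward scaffold per chromosome.
#'
#' @param n_bins total number of bins.
#' @param chrom_lengths chromosome lengths (only their ratios are used);
#'   named vector names become source names.
#' @param bin_bp bin size in bp.
#' @param n_rf restriction fragments per bin (>= 2 keeps bins orientable).
#' @return A list with `bins` (a [bin_table()]) and `structure` (the truth
#'   `genome_structure`).
#' @export
sim_genome <- function(n_bins, chrom_lengths = yeast_chrom_lengths,
                       bin_bp = 11000, n_rf = 4L) {
  k <- length(chrom_lengths)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%02d", seq_len(k))
  alloc <- pmax(2L, round(n_bins * chrom_lengths / sum(chrom_lengths)))
  # adjust the largest chromosomes so the total is exact
  while (sum(alloc) != n_bins) {
    d <- n_bins - sum(alloc)
    i <- if (d > 0) which.max(chrom_lengths / alloc) else which.max(alloc)
    alloc[i] <- max(2L, alloc[i] + sign(d))
    if (all(alloc == 2L) && d < 0) break
  }
  bins <- bin_table(length_bp = rep(bin_bp, sum(alloc)),
                    n_rf = rep(as.integer(n_rf), sum(alloc)),
                    source_name = rep(names(chrom_lengths), alloc))
  list(bins = bins, structure = genome_structure(bins))
}

#' Simulate a contact matrix from a genome structure
#'
#' Computes the expected unit-level contact matrix under the power-law /
#' plateau model, rescales it so the expected total equals `n_contacts`,
#' and draws independent Poisson counts. Because every intensity is
#' proportional to `Pt`, the rescaling amounts to an effective plateau
#' intensity `Pt * scale`, reported in the `sim_params` attribute as the
#' ground truth for parameter-recovery experiments.
#'
#' @param truth a `genome_structure`.
#' @param params a [nuisance_params()] (shape; `Pt` is rescaled to depth).
#' @param n_contacts target expected total contact count.
#' @param seed integer seed.
#' @return A `contact_matrix` with attributes `sim_params` (the effective
#'   [nuisance_params()]) and `sim_seed`.
#' @export
simulate_contacts <- function(truth, params, n_contacts, seed = 1L) {
  stopifnot(n_contacts > 0)
  lam <- expected_matrix(truth, params, exposure = 1)
  up <- upper.tri(lam, diag = TRUE)
  scale <- n_contacts / sum(lam[up])
  set.seed(as.integer(seed))
  idx <- which(up, arr.ind = TRUE)
  k <- rpois(nrow(idx), lam[up] * scale)
  keep <- k > 0
  cm <- contact_matrix(truth$bins,
                       data.frame(i = idx[keep, 1L], j = idx[keep, 2L],
                                  k = k[keep]))
  attr(cm, "sim_params") <- nuisance_params(params$b, params$s0,
                                            params$Pt * scale)
  attr(cm, "sim_seed") <- seed
  cm
}

#' Binomially downsample a contact matrix
#'
#' Each contact is retained independently with probability `fraction`,
#' emulating a shallower sequencing run.
#'
#' @param data a `contact_matrix`.
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed.
#' @return A `contact_matrix`.
#' @export
downsample_contacts <- function(data, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(as.integer(seed))
  k <- rbinom(nrow(data$trip), size = as.integer(round(data$trip$k)),
              prob = fraction)
  keep <- k > 0
  contact_matrix(data$bins, data.frame(i = data$trip$i[keep],
                                       j = data$trip$j[keep], k = k[keep]))
}

#' Randomly scramble a genome structure
#'
#' Permutes all placements into `n_scaffolds` scaffolds with independent
#' random orientations; the multiset of bins is conserved. The default
#' (one scaffold per placement) reproduces a de novo initialisation from a
#' bag of unordered bins.
#'
#' @param truth a `genome_structure`.
#' @param seed integer seed.
#' @param n_scaffolds number of scaffolds to scatter the placements into.
#' @return A scrambled `genome_structure`.
#' @export
scramble <- function(truth, seed = 1L, n_scaffolds = NULL) {
  set.seed(as.integer(seed))
  pl <- placements(truth)
  n <- nrow(pl)
  n_scaffolds <- n_scaffolds %||% n
  stopifnot(n_scaffolds >= 1L, n_scaffolds <= n)
  ord <- sample.int(n)
  orient <- sample(c(-1L, 1L), n, replace = TRUE)
  grp <- sort(rep_len(seq_len(n_scaffolds), n))
  scafs <- lapply(split(seq_len(n), grp), function(ix) {
    cbind(bin = pl$bin_id[ord[ix]], orient = orient[ix],
          copy = pl$copy[ord[ix]])
  })
  genome_structure(truth$bins, unname(scafs), unplaced = truth$unplaced)
}

#' Inject a structural rearrangement into a truth structure
#'
#' Produces the misassembly scenarios used to exercise detection:
#' * `translocation`: reciprocal arm exchange between two scaffolds at the
#'   given span boundary;
#' * `inversion`: reverse the order and orientations of the span in place;
#' * `segmental_duplication`: place a copy of the span at a random position
#'   on another scaffold (multiplicity + 1);
#' * `collapsed_duplication`: same duplication in `$structure` (the truth
#'   reads are simulated from), while `$reference` keeps the single-copy
#'   arrangement that a collapsed assembly would report; the collapsed
#'   bins then show about twice the marginal contact count.
#'
#' @param truth a `genome_structure`.
#' @param kind one of `"translocation"`, `"inversion"`,
#'   `"segmental_duplication"`, `"collapsed_duplication"`.
#' @param span integer vector: `c(scaffold index, first rank, last rank)`.
#' @param seed integer seed (for random placement of duplicates and
#'   translocation partners).
#' @return A list with `structure` (rearranged truth), `reference` (the
#'   structure an unaware assembly would report) and `breakpoints`
#'   (description of what was done where).
#' @export
inject_rearrangement <- function(truth,
                                 kind = c("translocation", "inversion",
                                          "segmental_duplication",
                                          "collapsed_duplication"),
                                 span, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  s <- span[1L]; a <- span[2L]; b <- span[3L]
  m <- truth$scaffolds[[s]]
  if (a < 1L || b > nrow(m) || a > b) stop("span outside scaffold")
  gs <- truth

  if (kind == "inversion") {
    gs$scaffolds[[s]] <- rbind(m[seq_len(a - 1L), , drop = FALSE],
                               rev_segment(m[a:b, , drop = FALSE]),
                               if (b < nrow(m)) m[(b + 1L):nrow(m), , drop = FALSE])
    return(list(structure = gs, reference = truth,
                breakpoints = list(kind = kind, scaffold = s, span = c(a, b))))
  }

  if (kind == "translocation") {
    others <- setdiff(seq_along(truth$scaffolds), s)
    if (!length(others)) stop("translocation needs a second scaffold")
    t <- others[sample.int(length(others), 1L)]
    mt <- truth$scaffolds[[t]]
    cut2 <- sample.int(nrow(mt) - 1L, 1L)
    # exchange the arm starting at `a` with the arm of scaffold t after cut2
    gs$scaffolds[[s]] <- rbind(m[seq_len(a - 1L), , drop = FALSE],
                               mt[(cut2 + 1L):nrow(mt), , drop = FALSE])
    gs$scaffolds[[t]] <- rbind(mt[seq_len(cut2), , drop = FALSE],
                               m[a:nrow(m), , drop = FALSE])
    gs$scaffolds <- Filter(function(x) nrow(x) > 0L, gs$scaffolds)
    return(list(structure = gs, reference = truth,
                breakpoints = list(kind = kind, scaffolds = c(s, t),
                                   cuts = c(a, cut2))))
  }

  # duplications: copy the span somewhere else
  dup <- m[a:b, , drop = FALSE]
  dup[, 3L] <- gs$next_copy[dup[, 1L]]
  gs$next_copy[dup[, 1L]] <- gs$next_copy[dup[, 1L]] + 1L
  others <- setdiff(seq_along(truth$scaffolds), s)
  t <- if (length(others)) others[sample.int(length(others), 1L)] else s
  mt <- gs$scaffolds[[t]]
  at <- sample.int(nrow(mt), 1L)
  gs$scaffolds[[t]] <- rbind(mt[seq_len(at), , drop = FALSE], dup,
                             if (at < nrow(mt)) mt[(at + 1L):nrow(mt), , drop = FALSE])
  bp <- list(kind = kind, from = c(s, a, b), to = c(t, at),
             bins = dup[, 1L])
  if (kind == "segmental_duplication")
    return(list(structure = gs, reference = gs, breakpoints = bp))
  # collapsed: reads come from the duplicated truth, the reference assembly
  # keeps a single copy
  list(structure = gs, reference = truth, breakpoints = bp)
}
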
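#' The 14-move rearrangement catalogue
#'
#' At each sampler iteration a selected bin placement A and a partner
#' placement B define 14 candidate rearrangements spanning the classic
#' structural-variation families:
#'
#' * M1-M4 `transpose`: remove A and reinsert it before/after B, keeping or
#'   flipping its orientation (in-place inversion arises when B is A's
#'   neighbour and the orientation is flipped);
#' * M5-M8 `translocate`: cut A's scaffold and B's scaffold (both before or
#'   both after the respective bin) and rejoin the four arms, either
#'   directly (reciprocal exchange) or with the inverted pairing; when A and
#'   B share a scaffold these degenerate to scaffold splits (direct) or a
#'   segmental inversion (inverted);
#' * M9 `delete`: move A to the unplaced pool;
#' * M10-M13 `duplicate`: insert a new copy of A before/after B, keeping or
#'   flipping orientation, leaving the original in place;
#' * M14 `eject`: split A out into a new single-bin scaffold.
#'
#' Orientation parameters are relative: `forward` keeps the current
#' orientation of A, `reverse` flips it, so the catalogue commutes with
#' whole-scaffold reversal.
#'
#' @return A `data.frame` with columns `kind`, `side`, `orientation`
#'   (14 rows).
#' @export
move_catalogue <- function() {
  data.frame(
    kind = c(rep("transpose", 4L), rep("translocate", 4L), "delete",
             rep("duplicate", 4L), "eject"),
    side = c("before", "before", "after", "after",
             "before", "before", "after", "after", NA,
             "before", "before", "after", "after", NA),
    orientation = c("forward", "reverse", "forward", "reverse",
                    "forward", "reverse", "forward", "reverse", NA,
                    "forward", "reverse", "forward", "reverse", NA),
    stringsAsFactors = FALSE
  )
}

#' Construct a rearrangement move
#'
#' @param kind one of `"transpose"`, `"translocate"`, `"delete"`,
#'   `"duplicate"`, `"eject"`, `"reinsert"` (the latter re-places an
#'   unplaced bin and is used by the sampler when it visits a deleted bin;
#'   it is not part of the 14-move catalogue).
#' @param bin placement `c(bin_id, copy_index)` the move acts on (for
#'   `reinsert`, just the bin id).
#' @param partner partner placement `c(bin_id, copy_index)`; required for
#'   pair moves, must differ from `bin`.
#' @param side `"before"` or `"after"` where applicable.
#' @param orientation `"forward"` or `"reverse"` where applicable.
#' @return An object of class `mutation`.
#' @export
mutation <- function(kind, bin, partner = NULL, side = NA, orientation = NA) {
  kind <- match.arg(kind, c("transpose", "translocate", "delete",
                            "duplicate", "eject", "reinsert"))
  bin <- as.integer(bin)
  if (length(bin) == 1L) bin <- c(bin, 0L)
  if (!is.null(partner)) {
    partner <- as.integer(partner)
    if (length(partner) == 1L) partner <- c(partner, 0L)
  }
  pairmove <- kind %in% c("transpose", "translocate", "duplicate", "reinsert")
  if (pairmove) {
    if (is.null(partner)) stop("move '", kind, "' requires a partner")
    if (all(bin == partner)) stop("bin and partner must differ")
  }
  structure(list(kind = kind, bin = bin, partner = partner,
                 side = side, orientation = orientation),
            class = "mutation")
}

#' @export
print.mutation <- function(x, ...) {
  cat(sprintf("mutation: %s bin (%d,%d)%s%s\n", x$kind, x$bin[1L], x$bin[2L],
              if (!is.null(x$partner))
                sprintf(" partner (%d,%d)", x$partner[1L], x$partner[2L]) else "",
              if (!is.na(x$side)) sprintf(" [%s, %s]", x$side, x$orientation) else ""))
  invisible(x)
}

# splice a row into a placement matrix before/after row i
splice_row <- function(m, row, i, side) {
  at <- if (side == "before") i else i + 1L
  n <- nrow(m)
  rbind(m[seq_len(at - 1L), , drop = FALSE],
        row,
        if (at <= n) m[at:n, , drop = FALSE])
}

# remove row r from scaffold s; drop the scaffold if emptied
drop_row <- function(gs, s, r) {
  m <- gs$scaffolds[[s]]
  if (nrow(m) == 1L) gs$scaffolds[[s]] <- NULL
  else gs$scaffolds[[s]] <- m[-r, , drop = FALSE]
  gs
}

new_scaffold_name <- function(gs) sprintf("scf%04d", gs$next_scaf)

# index of all (bin, copy) -> (scaffold, row) locations of a structure;
# lets a batch of moves against one base structure skip repeated scans
placement_index <- function(gs) {
  sc <- gs$scaffolds
  if (!length(sc)) return(list(keys = character(0)))
  sizes <- lengths(sc) %/% 3L
  M <- do.call(rbind, sc)
  list(keys = paste0(M[, 1L], ":", M[, 3L]),
       scaf = rep.int(seq_along(sc), sizes),
       row = sequence(sizes))
}

locate_placement <- function(gs, pl, pidx = NULL) {
  if (is.null(pidx)) return(find_placement(gs, pl[1L], pl[2L]))
  i <- match(paste0(pl[1L], ":", pl[2L]), pidx$keys)
  if (is.na(i)) NULL else c(pidx$scaf[i], pidx$row[i])
}

#' Apply a rearrangement move to a genome structure
#'
#' Returns a new structure; the input is unchanged. The multiplicity map is
#' conserved by all moves except `delete` (-1) and `duplicate` (+1); empty
#' scaffolds are never retained. Deleting the last copy of a bin is legal
#' (the bin moves to the unplaced pool, where its observed contacts are
#' explained at a floor intensity by the contact model).
#'
#' @param structure a `genome_structure`.
#' @param move a [mutation()].
#' @param .pidx optional `placement_index()` of `structure`, used by the
#'   sampler to amortise placement lookups over a candidate batch.
#' @return The rearranged `genome_structure`.
#' @export
apply_mutation <- function(structure, move, .pidx = NULL) {
  gs <- structure
  stopifnot(inherits(move, "mutation"))
  kind <- move$kind

  if (kind == "reinsert") {
    b <- move$bin[1L]
    if (!b %in% gs$unplaced) stop("reinsert: bin is not unplaced")
    pb <- locate_placement(gs, move$partner, .pidx)
    if (is.null(pb)) stop("unknown partner placement")
    o <- if (identical(move$orientation, "reverse")) -1L else 1L
    row <- c(b, o, gs$next_copy[b])
    gs$next_copy[b] <- gs$next_copy[b] + 1L
    gs$scaffolds[[pb[1L]]] <- splice_row(gs$scaffolds[[pb[1L]]], row,
                                         pb[2L], move$side)
    gs$unplaced <- setdiff(gs$unplaced, b)
    return(gs)
  }

  pa <- locate_placement(gs, move$bin, .pidx)
  if (is.null(pa)) stop("unknown placement for move")
  arow <- gs$scaffolds[[pa[1L]]][pa[2L], ]

  if (kind == "delete") {
    gs <- drop_row(gs, pa[1L], pa[2L])
    if (multiplicity(gs)[arow[1L]] == 0L)
      gs$unplaced <- c(gs$unplaced, arow[1L])
    return(gs)
  }

  if (kind == "eject") {
    gs <- drop_row(gs, pa[1L], pa[2L])
    nm <- new_scaffold_name(gs)
    gs$scaffolds[[nm]] <- matrix(arow, ncol = 3L,
                                 dimnames = list(NULL, c("bin", "orient", "copy")))
    gs$next_scaf <- gs$next_scaf + 1L
    return(gs)
  }

  if (kind == "transpose") {
    pb <- locate_placement(gs, move$partner, .pidx)
    if (is.null(pb)) stop("unknown partner placement")
    dropped <- nrow(gs$scaffolds[[pa[1L]]]) == 1L
    gs <- drop_row(gs, pa[1L], pa[2L])
    sb <- pb[1L]; rb <- pb[2L]
    if (dropped && sb > pa[1L]) sb <- sb - 1L
    if (!dropped && sb == pa[1L] && rb > pa[2L]) rb <- rb - 1L
    o <- arow[2L] * (if (identical(move$orientation, "reverse")) -1L else 1L)
    row <- c(arow[1L], o, arow[3L])
    gs$scaffolds[[sb]] <- splice_row(gs$scaffolds[[sb]], row, rb, move$side)
    return(gs)
  }

  if (kind == "duplicate") {
    pb <- locate_placement(gs, move$partner, .pidx)
    if (is.null(pb)) stop("unknown partner placement")
    b <- arow[1L]
    o <- arow[2L] * (if (identical(move$orientation, "reverse")) -1L else 1L)
    row <- c(b, o, gs$next_copy[b])
    gs$next_copy[b] <- gs$next_copy[b] + 1L
    gs$scaffolds[[pb[1L]]] <- splice_row(gs$scaffolds[[pb[1L]]], row,
                                         pb[2L], move$side)
    return(gs)
  }

  # translocate
  pb <- locate_placement(gs, move$partner, .pidx)
  if (is.null(pb)) stop("unknown partner placement")
  inverted <- identical(move$orientation, "reverse")
  cut_at <- function(r) if (identical(move$side, "after")) r + 1L else r

  if (pa[1L] != pb[1L]) {
    ma <- gs$scaffolds[[pa[1L]]]; mb <- gs$scaffolds[[pb[1L]]]
    ca <- cut_at(pa[2L]); cb <- cut_at(pb[2L])
    a1 <- ma[seq_len(ca - 1L), , drop = FALSE]
    a2 <- ma[seq_len(nrow(ma)) >= ca, , drop = FALSE]
    b1 <- mb[seq_len(cb - 1L), , drop = FALSE]
    b2 <- mb[seq_len(nrow(mb)) >= cb, , drop = FALSE]
    if (!inverted) {
      n1 <- rbind(a1, b2); n2 <- rbind(b1, a2)
    } else {
      n1 <- rbind(a1, rev_segment(b1)); n2 <- rbind(rev_segment(a2), b2)
    }
    keep <- c(pa[1L], pb[1L])
    for (k in seq_along(keep)) {
      nn <- if (k == 1L) n1 else n2
      gs$scaffolds[[keep[k]]] <- nn
    }
    empty <- which(vapply(gs$scaffolds, nrow, 1L) == 0L)
    if (length(empty)) gs$scaffolds[empty] <- NULL
    return(gs)
  }

  # same scaffold: splits (direct) or segmental inversion (inverted)
  m <- gs$scaffolds[[pa[1L]]]
  c1 <- cut_at(pa[2L]); c2 <- cut_at(pb[2L])
  if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp }
  x <- m[seq_len(c1 - 1L), , drop = FALSE]
  y <- m[seq_len(nrow(m)) >= c1 & seq_len(nrow(m)) < c2, , drop = FALSE]
  z <- m[seq_len(nrow(m)) >= c2, , drop = FALSE]
  if (inverted) {
    gs$scaffolds[[pa[1L]]] <- rbind(x, rev_segment(y), z)
    return(gs)
  }
  segs <- Filter(function(s) nrow(s) > 0L, list(x, y, z))
  gs$scaffolds[[pa[1L]]] <- segs[[1L]]
  if (length(segs) > 1L) {
    for (k in 2L:length(segs)) {
      gs$scaffolds[[new_scaffold_name(gs)]] <- segs[[k]]
      gs$next_scaf <- gs$next_scaf + 1L
    }
  }
  gs
}

#' Enumerate the 14 x m candidate structures around a bin
#'
#' For each of the `m` partner placements, instantiates all 14 catalogue
#' moves on (`bin`, partner) and applies them. Candidates that are
#' structurally identical to the input (which happens at scaffold ends) are
#' still emitted, so the count is always exactly `14 * m`.
#'
#' @param structure a `genome_structure`.
#' @param bin placement `c(bin_id, copy_index)` to rearrange.
#' @param partners list of partner placements (or a vector of bin ids, copy
#'   0 assumed).
#' @param .pidx optional precomputed `placement_index()`.
#' @return A list of `length(partners) * 14` elements, each
#'   `list(move = <mutation>, structure = <genome_structure>)`.
#' @export
enumerate_candidates <- function(structure, bin, partners, .pidx = NULL) {
  if (is.atomic(partners)) partners <- lapply(partners, function(b) c(b, 0L))
  if (!length(partners)) stop("empty partner list")
  if (is.null(.pidx)) .pidx <- placement_index(structure)
  cat14 <- move_catalogue()
  bin <- as.integer(bin)
  if (length(bin) == 1L) bin <- c(bin, 0L)
  out <- vector("list", 14L * length(partners))
  k <- 0L
  for (p in partners) {
    p <- as.integer(p)
    if (length(p) == 1L) p <- c(p, 0L)
    if (all(p == bin)) stop("partners must be distinct from bin")
    for (i in seq_len(14L)) {
      mv <- structure(list(kind = cat14$kind[i], bin = bin, partner = p,
                           side = cat14$side[i],
                           orientation = cat14$orientation[i]),
                      class = "mutation")
      k <- k + 1L
      out[[k]] <- list(move = mv,
                       structure = apply_mutation(structure, mv, .pidx = .pidx))
    }
  }
  out
}
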
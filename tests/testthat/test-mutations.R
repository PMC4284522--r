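label_chain <- function(gs) {
  # human-readable scaffold encodings like "A+ B+ | C- D+"
  lapply(gs$scaffolds, function(m)
    paste0(LETTERS[m[, 1L]], ifelse(m[, 2L] == 1L, "+", "-"), collapse = " "))
}

test_that("transposition is pure permutation bookkeeping", {
  bins <- toy_bins(3)
  gs <- genome_structure(bins) # [A+ B+ C+]
  out <- apply_mutation(gs, mutation("transpose", c(3, 0), c(1, 0),
                                     side = "before", orientation = "forward"))
  expect_equal(unname(unlist(label_chain(out))), "C+ A+ B+")
  expect_equal(multiplicity(out), multiplicity(gs))
  # relative orientation: reverse flips the moved bin only
  out2 <- apply_mutation(gs, mutation("transpose", c(3, 0), c(1, 0),
                                      side = "before", orientation = "reverse"))
  expect_equal(unname(unlist(label_chain(out2))), "C- A+ B+")
})

test_that("duplication conserves the original and increments multiplicity", {
  bins <- toy_bins(3)
  gs <- genome_structure(bins)
  out <- apply_mutation(gs, mutation("duplicate", c(2, 0), c(3, 0),
                                     side = "after", orientation = "forward"))
  expect_equal(unname(unlist(label_chain(out))), "A+ B+ C+ B+")
  expect_equal(multiplicity(out)[2], 2L)
  m <- out$scaffolds[[1]]
  expect_equal(m[4, 3], 1L) # fresh copy index
  expect_true(validate_structure(out)$ok)
})

test_that("reciprocal translocation realises all four arm pairings", {
  bins <- toy_bins(4, sources = c("s1", "s1", "s2", "s2"))
  gs <- genome_structure(bins) # [A B | C D]
  # the spec's worked pairing: cut before B and before D, direct rejoin
  out <- apply_mutation(gs, mutation("translocate", c(2, 0), c(4, 0),
                                     side = "before", orientation = "forward"))
  expect_setequal(unname(unlist(label_chain(out))), c("A+ D+", "C+ B+"))

  # brute force: all 4 (side x rejoin) variants on (B, D) are distinct legal
  # structures, and together with other (bin, partner) choices every
  # unordered arm pairing {A.|C.} x {B,D arms} is reachable
  variants <- list()
  for (side in c("before", "after")) for (ori in c("forward", "reverse")) {
    v <- apply_mutation(gs, mutation("translocate", c(2, 0), c(4, 0),
                                     side = side, orientation = ori))
    expect_true(validate_structure(v)$ok)
    variants[[paste(side, ori)]] <- structure_signature(v)
  }
  expect_equal(length(unique(unlist(variants))), 4L)

  reachable <- character(0)
  for (bp in list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))) {
    for (side in c("before", "after")) for (ori in c("forward", "reverse")) {
      v <- apply_mutation(gs, mutation("translocate", c(bp[1], 0), c(bp[2], 0),
                                       side = side, orientation = ori))
      reachable <- c(reachable, structure_signature(v))
    }
  }
  # arm exchanges pairing A with D, A with C-arm content, etc.
  expect_true(structure_signature(genome_structure(bins, list(
    cbind(bin = c(1, 4), orient = 1L, copy = 0L),
    cbind(bin = c(3, 2), orient = 1L, copy = 0L)))) %in% reachable)
  expect_true(structure_signature(genome_structure(bins, list(
    cbind(bin = c(1, 3), orient = c(1L, -1L), copy = 0L),
    cbind(bin = c(2, 4), orient = c(-1L, 1L), copy = 0L)))) %in% reachable)
})

test_that("same-scaffold translocations split, inverted ones invert", {
  bins <- toy_bins(5)
  gs <- genome_structure(bins) # [A B C D E]
  sp <- apply_mutation(gs, mutation("translocate", c(2, 0), c(4, 0),
                                    side = "before", orientation = "forward"))
  expect_equal(n_contigs(sp), 3L)
  expect_setequal(unname(unlist(label_chain(sp))),
                  c("A+", "B+ C+", "D+ E+"))
  inv <- apply_mutation(gs, mutation("translocate", c(2, 0), c(4, 0),
                                     side = "before", orientation = "reverse"))
  expect_equal(unname(unlist(label_chain(inv))), "A+ C- B- D+ E+")
})

test_that("delete and eject handle boundary cases", {
  bins <- toy_bins(3)
  gs <- genome_structure(bins)
  # deleting the last copy is legal: bin moves to the unplaced pool
  d <- apply_mutation(gs, mutation("delete", c(2, 0)))
  expect_equal(multiplicity(d)[2], 0L)
  expect_true(2L %in% d$unplaced)
  # eject into a new singleton scaffold
  e <- apply_mutation(gs, mutation("eject", c(2, 0)))
  expect_equal(n_contigs(e), 2L)
  expect_equal(sort(unname(vapply(e$scaffolds, nrow, 1L)),
                    decreasing = TRUE), c(2L, 1L))
  # unknown placements are rejected with an explicit error
  expect_error(apply_mutation(gs, mutation("delete", c(2, 7))), "unknown")
  expect_error(apply_mutation(gs, mutation("transpose", c(1, 0), c(9, 0),
                                           side = "before",
                                           orientation = "forward")),
               "unknown")
})

test_that("candidate sets have exactly 14 x m members, all valid", {
  bins <- toy_bins(6, sources = c(rep("a", 3), rep("b", 3)))
  gs <- genome_structure(bins)
  c1 <- enumerate_candidates(gs, c(1, 0), list(c(4, 0)))
  expect_length(c1, 14L)
  c3 <- enumerate_candidates(gs, c(1, 0), list(c(4, 0), c(5, 0), c(2, 0)))
  expect_length(c3, 42L)
  for (cand in c3) {
    v <- validate_structure(cand$structure)
    expect_true(v$ok)
    expect_true(inherits(cand$move, "mutation"))
  }
  expect_error(enumerate_candidates(gs, c(1, 0), list()), "empty")
})

test_that("conservation: non-delete/duplicate moves preserve the placement multiset", {
  bins <- toy_bins(8, sources = c(rep("a", 4), rep("b", 4)))
  gs <- genome_structure(bins)
  set.seed(11)
  for (rep in 1:100) {
    mv <- random_move(gs)
    out <- apply_mutation(gs, mv)
    m0 <- multiplicity(gs); m1 <- multiplicity(out)
    if (mv$kind == "delete") {
      expect_equal(sum(m1), sum(m0) - 1L)
    } else if (mv$kind == "duplicate") {
      expect_equal(sum(m1), sum(m0) + 1L)
    } else {
      expect_identical(m1, m0)
    }
  }
})

test_that("non-delete moves are reversible on small toys", {
  bins <- toy_bins(5, sources = c("a", "a", "a", "b", "b"))
  gs <- genome_structure(bins)
  sig0 <- structure_signature(gs)
  cat14 <- move_catalogue()
  pairmoves <- cat14[!cat14$kind %in% c("delete", "duplicate", "eject"), ]

  all_followups <- function(state) {
    pl <- placements(state)
    out <- list()
    for (a in seq_len(nrow(pl))) for (b in seq_len(nrow(pl))) {
      if (a == b) next
      for (k in seq_len(nrow(pairmoves))) {
        out[[length(out) + 1L]] <-
          mutation(pairmoves$kind[k], c(pl$bin_id[a], pl$copy[a]),
                   c(pl$bin_id[b], pl$copy[b]),
                   pairmoves$side[k], pairmoves$orientation[k])
      }
    }
    out
  }
  reversible <- function(out, depth = 2L) {
    if (structure_signature(out) == sig0) return(TRUE)
    if (depth == 0L) return(FALSE)
    for (mv2 in all_followups(out)) {
      nxt <- apply_mutation(out, mv2)
      if (structure_signature(nxt) == sig0) return(TRUE)
      if (depth > 1L && reversible(nxt, 1L)) return(TRUE)
    }
    FALSE
  }

  set.seed(21)
  for (rep in 1:15) {
    i <- sample.int(nrow(cat14), 1L)
    if (cat14$kind[i] %in% c("delete", "duplicate")) next
    pl <- placements(gs)
    ab <- pl[sample.int(nrow(pl), 2L), ]
    mv <- mutation(cat14$kind[i], c(ab$bin_id[1], ab$copy[1]),
                   c(ab$bin_id[2], ab$copy[2]),
                   cat14$side[i], cat14$orientation[i])
    expect_true(reversible(apply_mutation(gs, mv)),
                info = paste("irreversible:", cat14$kind[i], cat14$side[i],
                             cat14$orientation[i]))
  }
  # duplicate is undone by deleting the fresh copy
  dup <- apply_mutation(gs, mutation("duplicate", c(2, 0), c(4, 0),
                                     side = "after", orientation = "forward"))
  undone <- apply_mutation(dup, mutation("delete", c(2, 1)))
  expect_identical(structure_signature(undone), sig0)
})

test_that("structures survive 1000 random legal moves", {
  bins <- toy_bins(10, sources = c(rep("a", 5), rep("b", 5)))
  gs <- genome_structure(bins)
  set.seed(99)
  for (i in 1:1000) {
    gs <- apply_mutation(gs, random_move(gs))
    # occasionally reinsert an unplaced bin so deletes do not accumulate
    if (length(gs$unplaced) && runif(1) < 0.5) {
      pl <- placements(gs)
      anchor <- pl[sample.int(nrow(pl), 1L), ]
      gs <- apply_mutation(gs, mutation("reinsert", gs$unplaced[1],
                                        c(anchor$bin_id, anchor$copy),
                                        side = "after",
                                        orientation = "forward"))
    }
  }
  expect_true(validate_structure(gs)$ok)
})

test_that("indexed move application matches the scanning path", {
  bins <- toy_bins(9, sources = c(rep("a", 4), rep("b", 5)))
  gs <- scramble(genome_structure(bins), seed = 3, n_scaffolds = 4)
  set.seed(31)
  for (i in 1:80) {
    mv <- random_move(gs)
    pidx <- proxiscaf:::placement_index(gs)
    expect_identical(structure_signature(apply_mutation(gs, mv, .pidx = pidx)),
                     structure_signature(apply_mutation(gs, mv)))
    gs <- apply_mutation(gs, mv)
    if (length(gs$unplaced) > 2L) {
      pl <- placements(gs)
      anchor <- pl[1L, ]
      gs <- apply_mutation(gs, mutation("reinsert", gs$unplaced[1],
                                        c(anchor$bin_id, anchor$copy),
                                        side = "before",
                                        orientation = "reverse"))
    }
  }
})
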
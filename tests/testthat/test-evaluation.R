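# independent brute-force adjacency error: enumerate reference junctions and
# look each up in the assembly in both reading directions
oracle_error <- function(assembly, reference) {
  junctions <- function(gs) {
    out <- list()
    for (m in gs$scaffolds) {
      if (nrow(m) < 2L) next
      for (r in seq_len(nrow(m) - 1L))
        out[[length(out) + 1L]] <- c(m[r, 1L], m[r, 2L], m[r + 1L, 1L],
                                     m[r + 1L, 2L])
    }
    out
  }
  ref <- junctions(reference)
  if (!length(ref)) return(0)
  asm <- junctions(assembly)
  used <- rep(FALSE, length(asm))
  matched <- 0L
  for (j in ref) {
    for (i in seq_along(asm)) {
      if (used[i]) next
      a <- asm[[i]]
      direct <- all(a == j)
      flipped <- all(c(a[3], -a[4], a[1], -a[2]) == j)
      if (direct || flipped) {
        used[i] <- TRUE
        matched <- matched + 1L
        break
      }
    }
  }
  1 - matched / length(ref)
}

test_that("reconstruction error is zero exactly for equivalent structures", {
  g <- sim_genome(40, chrom_lengths = c(a = 2, b = 1, c = 1), bin_bp = 10000)
  ref <- g$structure
  expect_equal(reconstruction_error(ref, ref), 0)
  # whole-scaffold reversals and scaffold renaming are equivalences
  rev1 <- reverse_scaffold(ref, 1)
  names(rev1$scaffolds) <- paste0("x", seq_along(rev1$scaffolds))
  expect_equal(reconstruction_error(rev1, ref), 0)
  # any real perturbation is seen
  tweak <- apply_mutation(ref, mutation("transpose", c(3, 0), c(10, 0),
                                        side = "after",
                                        orientation = "forward"))
  expect_gt(reconstruction_error(tweak, ref), 0)
  flip <- ref
  flip$scaffolds[[1]][2, 2] <- -1L # flip one bin's orientation only
  expect_gt(reconstruction_error(flip, ref), 0)
  expect_error(reconstruction_error(ref, genome_structure(toy_bins(5))),
               "universes")
})

test_that("reconstruction error agrees with the brute-force oracle", {
  g <- sim_genome(100, chrom_lengths = yeast_chrom_lengths, bin_bp = 11000)
  ref <- g$structure
  set.seed(9)
  for (seed in 1:5) {
    sc <- scramble(ref, seed = seed, n_scaffolds = sample(c(1, 5, 100), 1))
    expect_equal(reconstruction_error(sc, ref), oracle_error(sc, ref))
  }
  # partially repaired structures too
  gs <- scramble(ref, seed = 77)
  for (i in 1:20) {
    gs <- apply_mutation(gs, random_move(gs))
    expect_equal(reconstruction_error(gs, ref), oracle_error(gs, ref))
  }
})

test_that("error decreases monotonically as correct junctions are restored", {
  bins <- toy_bins(12, sources = "chr1")
  ref <- genome_structure(bins)
  # start from singletons and glue bins back left to right
  gs <- initial_structure(bins, "singletons")
  errs <- reconstruction_error(gs, ref)
  for (b in 2:12) {
    gs <- apply_mutation(gs, mutation("transpose", c(b, 0), c(b - 1, 0),
                                      side = "after", orientation = "forward"))
    errs <- c(errs, reconstruction_error(gs, ref))
  }
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[1], 1)
  expect_equal(errs[length(errs)], 0)
})

test_that("chromosome assignment uses majority rule", {
  g <- sim_genome(10, chrom_lengths = c(a = 6, b = 4), bin_bp = 10000)
  ref <- g$structure # bins 1..6 on a, 7..10 on b
  expect_equal(chromosome_assignment_accuracy(ref, ref), 100)
  # fusing both chromosomes: the minority chromosome's bins all count wrong
  fused <- genome_structure(g$bins, list(
    cbind(bin = 1:10, orient = 1L, copy = 0L)))
  expect_equal(chromosome_assignment_accuracy(fused, ref), 60)
  # random scatter over 4 equal chromosomes: about 25% correct
  g4 <- sim_genome(120, chrom_lengths = c(a = 1, b = 1, c = 1, d = 1),
                   bin_bp = 10000)
  accs <- vapply(1:10, function(s)
    chromosome_assignment_accuracy(scramble(g4$structure, seed = s,
                                            n_scaffolds = 4),
                                   g4$structure), 0)
  expect_gt(mean(accs), 15)
  expect_lt(mean(accs), 45)
})

test_that("ordering and rank metrics handle reversal and transposition", {
  g <- sim_genome(50, chrom_lengths = c(chr = 1), bin_bp = 10000)
  ref <- g$structure
  perfect <- ordering_and_rank(ref, ref)
  expect_equal(perfect$ordered_pct, 100)
  expect_equal(perfect$rank_error_mean, 0)
  # a reversed scaffold scores perfectly after direction alignment
  rev1 <- reverse_scaffold(ref, 1)
  oar <- ordering_and_rank(rev1, ref)
  expect_equal(oar$ordered_pct, 100)
  expect_equal(oar$rank_error_mean, 0)
  expect_equal(reconstruction_error(rev1, ref), 0)
  # one bin transposed far away: the three broken junctions are the only
  # missing reference adjacencies, and the bins around them lose their
  # neighbour sets
  mid <- apply_mutation(ref, mutation("transpose", c(10, 0), c(30, 0),
                                      side = "after", orientation = "forward"))
  expect_equal(reconstruction_error(mid, ref), 3 / 49)
  oar2 <- ordering_and_rank(mid, ref)
  expect_equal(round(50 * (100 - oar2$ordered_pct) / 100), 5)
})

test_that("metrics are invariant under renaming and reversal", {
  g <- sim_genome(36, chrom_lengths = c(a = 1, b = 1, c = 1), bin_bp = 10000)
  ref <- g$structure
  asm <- scramble(ref, seed = 5, n_scaffolds = 3)
  m1 <- assembly_report(asm, ref)
  asm2 <- reverse_scaffold(asm, 2)
  names(asm2$scaffolds) <- c("foo", "bar", "baz")
  m2 <- assembly_report(asm2, ref)
  expect_equal(m1$error, m2$error)
  expect_equal(m1$chrom_assignment_pct, m2$chrom_assignment_pct)
  expect_equal(m1$ordered_pct, m2$ordered_pct)
})

test_that("reports serialise to text and JSON", {
  g <- sim_genome(12, chrom_lengths = c(a = 1, b = 1), bin_bp = 10000)
  rep <- assembly_report(g$structure, g$structure)
  prefix <- tempfile()
  write_report(rep, prefix)
  j <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(j$error, 0)
  expect_equal(j$chrom_assignment_pct, 100)
  expect_true(file.exists(paste0(prefix, ".txt")))
})
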
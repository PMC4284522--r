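test_that("contact probability follows the power law with plateau", {
  p <- toy_params(b = -1, s0 = 1e5, Pt = 2e-9)
  # continuity at the plateau onset
  expect_equal(contact_probability(1e5, p), 2e-9)
  expect_equal(contact_probability(5e6, p), 2e-9)
  # hand evaluation of the power law: b = -1, s = s0/2 -> 2 Pt
  expect_equal(contact_probability(5e4, p), 4e-9)
  # trans pairs take the plateau intensity regardless of b
  for (b in c(-0.5, -1.5, -3)) {
    pb <- toy_params(b = b)
    expect_equal(contact_probability(123, pb, is_trans = TRUE), pb$Pt)
  }
  # monotone non-increasing decay for b < 0
  s <- sort(runif(200, 1, 1e6))
  v <- contact_probability(s, toy_params(b = -1.5), floor_bp = 1)
  expect_true(all(diff(v) <= 1e-20))
  # invalid parameters are rejected
  expect_error(nuisance_params(-1, -5, 1e-9), "s0")
  expect_error(nuisance_params(-1, 1e5, 0), "Pt")
})

test_that("expected counts scale with lengths, copies and exposure", {
  bins <- bin_table(length_bp = c(10000, 10000, 8000), n_rf = 4L,
                    source_name = c("a", "b", "c"))
  gs <- genome_structure(bins) # three scaffolds: all pairs trans
  p <- toy_params()
  expect_equal(expected_count(gs, 1, 2, p, exposure = 1),
               p$Pt * 1e4 * 1e4)
  expect_equal(expected_count(gs, 1, 3, p, exposure = 2),
               2 * p$Pt * 1e4 * 8e3)
  # symmetry
  expect_equal(expected_count(gs, 1, 3, p), expected_count(gs, 3, 1, p))
  # a duplicated bin doubles its trans expectation with the rest
  dup <- apply_mutation(gs, mutation("duplicate", c(1, 0), c(2, 0),
                                     side = "after", orientation = "forward"))
  expect_equal(expected_count(dup, 1, 3, p), 2 * expected_count(gs, 1, 3, p))
  # collapsing a 2-copy bin into 1 halves its expected contacts with the
  # rest of the genome (bin 3 is trans to both copies)
  expect_equal(expected_count(gs, 1, 3, p) / expected_count(dup, 1, 3, p),
               0.5)
})

test_that("our Poisson term assembly is a normalised pmf", {
  # k ln(lambda) - lambda - ln k!, summed over k, must integrate to 1
  for (lam in c(0.3, 5, 50)) {
    k <- 0:200
    expect_equal(sum(exp(k * log(lam) - lam - lgamma(k + 1))), 1,
                 tolerance = 1e-10)
  }
})

test_that("compiled likelihood matches the scalar oracle exactly", {
  set.seed(5)
  g <- sim_genome(12, chrom_lengths = c(a = 2, b = 1), bin_bp = 10000)
  p <- toy_params()
  cm <- simulate_contacts(g$structure, p, n_contacts = 5e4, seed = 2)
  pe <- attr(cm, "sim_params")
  expect_equal(log_likelihood(cm, g$structure, pe),
               oracle_loglik(cm, g$structure, pe),
               tolerance = 1e-10)
  # the expected-matrix path agrees with the oracle lambda too
  expect_equal(expected_matrix(g$structure, pe),
               oracle_lambda(g$structure, pe), tolerance = 1e-12)
  # empty data, empty model: a zero-count matrix against lambda ~ 0
  # degenerates to -sum(lambda), finite
  cm0 <- contact_matrix(g$bins, data.frame(i = 1L, j = 2L, k = 0))
  expect_true(is.finite(log_likelihood(cm0, g$structure, pe)))
})

test_that("likelihood stays exact across random rearrangements", {
  set.seed(77)
  g <- sim_genome(15, chrom_lengths = c(a = 2, b = 2, c = 1), bin_bp = 9000)
  p <- toy_params()
  cm <- simulate_contacts(g$structure, p, n_contacts = 1e5, seed = 3)
  pe <- attr(cm, "sim_params")
  gs <- g$structure
  for (i in 1:25) {
    gs <- apply_mutation(gs, random_move(gs))
    expect_equal(log_likelihood(cm, gs, pe), oracle_loglik(cm, gs, pe),
                 tolerance = 1e-8)
  }
})

test_that("scrambling a structure with strong diagonal data lowers the likelihood", {
  g <- sim_genome(20, chrom_lengths = c(a = 1, b = 1), bin_bp = 10000)
  p <- toy_params()
  cm <- simulate_contacts(g$structure, p, n_contacts = 5e5, seed = 4)
  pe <- attr(cm, "sim_params")
  ll0 <- log_likelihood(cm, g$structure, pe)
  for (seed in 1:50) {
    expect_lt(log_likelihood(cm, scramble(g$structure, seed = seed), pe), ll0)
  }
})

test_that("delta likelihood agrees with full recomputation", {
  set.seed(13)
  g <- sim_genome(30, chrom_lengths = c(a = 3, b = 2, c = 1), bin_bp = 10000)
  p <- toy_params()
  cm <- simulate_contacts(g$structure, p, n_contacts = 3e5, seed = 5)
  pe <- attr(cm, "sim_params")
  gs <- g$structure
  for (i in 1:200) {
    mv <- random_move(gs)
    st <- likelihood_state(cm, gs, pe)
    after <- apply_mutation(gs, mv)
    expect_equal(delta_log_likelihood(st, cm, gs, mv),
                 log_likelihood(cm, after, pe) - log_likelihood(cm, gs, pe),
                 tolerance = 1e-6)
    gs <- after
  }
  # identity-like move: reinsert a bin at its own position
  pl <- placements(g$structure)
  mv0 <- mutation("transpose", c(pl$bin_id[2], pl$copy[2]),
                  c(pl$bin_id[1], pl$copy[1]),
                  side = "after", orientation = "forward")
  st <- likelihood_state(cm, g$structure, pe)
  expect_equal(delta_log_likelihood(st, cm, g$structure, mv0), 0,
               tolerance = 1e-9)
  # delete then reinsert at the same spot: deltas cancel
  del <- mutation("delete", c(pl$bin_id[2], pl$copy[2]))
  d1 <- delta_log_likelihood(st, cm, g$structure, del)
  gdel <- apply_mutation(g$structure, del)
  back <- mutation("reinsert", pl$bin_id[2], c(pl$bin_id[1], pl$copy[1]),
                   side = "after", orientation = "forward")
  d2 <- delta_log_likelihood(likelihood_state(cm, gdel, pe), cm, gdel, back)
  expect_equal(d1 + d2, 0, tolerance = 1e-6)
  # stale state is refused
  st2 <- likelihood_state(cm, g$structure, pe)
  expect_error(delta_log_likelihood(st2, cm, gdel, del), "stale")
})

test_that("exposure fitting matches depth and is linear in counts", {
  g <- sim_genome(16, chrom_lengths = c(a = 1, b = 1), bin_bp = 10000)
  p <- toy_params()
  cm <- simulate_contacts(g$structure, p, n_contacts = 2e5, seed = 6)
  pe <- attr(cm, "sim_params")
  e1 <- fit_exposure(cm, g$structure, pe)
  expect_gt(e1, 0)
  expect_equal(e1, 1, tolerance = 0.01) # simulation is depth-matched
  cm2 <- contact_matrix(cm$bins, transform(cm$trip, k = 2 * k))
  expect_equal(fit_exposure(cm2, g$structure, pe), 2 * e1, tolerance = 1e-10)
  cm0 <- contact_matrix(cm$bins, data.frame(i = 1L, j = 2L, k = 0))
  expect_error(fit_exposure(cm0, g$structure, pe), "zero")
})

test_that("the simulated truth beats all its single-move neighbours at depth", {
  g <- sim_genome(20, chrom_lengths = c(a = 1, b = 1), bin_bp = 10000)
  p <- toy_params()
  cm <- simulate_contacts(g$structure, p, n_contacts = 1e6, seed = 8)
  pe <- attr(cm, "sim_params")
  ll0 <- log_likelihood(cm, g$structure, pe)
  set.seed(14)
  for (bin in sample(1:20, 5)) {
    partners <- setdiff(sample(1:20, 4), bin)[1:3]
    cands <- enumerate_candidates(g$structure, c(bin, 0),
                                  lapply(partners, function(b) c(b, 0L)))
    for (cand in cands) {
      llc <- log_likelihood(cm, cand$structure, pe)
      expect_lte(llc, ll0 + 1e-6)
    }
  }
})
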
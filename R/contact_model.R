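#' Nuisance parameters of the contact model
#'
#' The contact model has three nuisance parameters, estimated jointly with
#' the genome structure: the power-law exponent `b` (< 0) of the cis
#' contact-intensity decay, the genomic distance `s0` (bp) at which the
#' decay reaches its plateau, and the plateau/trans intensity `Pt`
#' (contacts per bp^2, at unit exposure). Continuity at `s0` fixes the
#' power-law prefactor: `P_c(s) = Pt * (s / s0)^b` for `s <= s0`.
#'
#' @param b power-law exponent, dimensionless, `b < 0`.
#' @param s0 plateau onset distance in bp, `> 0`.
#' @param Pt trans/plateau contact intensity per bp^2, `> 0`.
#' @return An object of class `nuisance_params`.
#' @export
nuisance_params <- function(b, s0, Pt) {
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  if (!is.finite(Pt) || Pt <= 0) stop("Pt must be positive")
  if (!is.finite(b)) stop("b must be finite")
  structure(list(b = b, s0 = s0, Pt = Pt), class = "nuisance_params")
}

#' @export
print.nuisance_params <- function(x, ...) {
  cat(sprintf("contact-model parameters: b = %.3f, s0 = %.3g bp, Pt = %.3g per bp^2\n",
              x$b, x$s0, x$Pt))
  invisible(x)
}

#' Contact intensity of a pair geometry
#'
#' Cis pairs at distance `s` have intensity `Pt * (s / s0)^b` up to the
#' plateau onset `s0` and `Pt` beyond it; trans pairs have the uniform
#' intensity `Pt` per bp^2 regardless of the other parameters. `s` is
#' floored at `max(1, floor_bp)` so that coinciding midpoints keep a finite
#' intensity (bins self-contact at finite rates).
#'
#' @param s genomic distance in bp (vectorised); ignored where `is_trans`.
#' @param params a [nuisance_params()].
#' @param is_trans logical (vectorised) trans flag.
#' @param floor_bp lower bound applied to `s` (bp); typically half the
#'   smaller bin length of the pair.
#' @return Intensity per bp^2 (vector).
#' @export
contact_probability <- function(s, params, is_trans = FALSE, floor_bp = 1) {
  stopifnot(inherits(params, "nuisance_params"))
  n <- max(length(s), length(is_trans))
  s <- rep_len(as.numeric(s), n)
  is_trans <- rep_len(is_trans, n)
  fl <- pmax(1, rep_len(floor_bp, n))
  s <- pmax(s, fl)
  out <- ifelse(s >= params$s0, params$Pt,
                params$Pt * exp(params$b * log(s / params$s0)))
  out[is_trans] <- params$Pt
  out
}

# geometry of all placed units of a structure, as dense matrices; used by
# expected_matrix() and by the simulator (independent of the C++ likelihood)
unit_rate_matrix <- function(flat, params) {
  P <- length(flat$pos)
  same <- outer(flat$scaf, flat$scaf, "==")
  d <- abs(outer(flat$pos, flat$pos, "-"))
  fl <- pmax(1, outer(flat$len, flat$len, pmin) / 2)
  d <- pmax(d, fl)
  R <- matrix(params$Pt, P, P)
  cis <- same & d < params$s0
  R[cis] <- params$Pt * exp(params$b * log(d[cis] / params$s0))
  R
}

#' Expected contact matrix of a structure
#'
#' Dense matrix of Poisson means over all unit pairs: for placed units the
#' intensity is summed over all placement (copy) pairs and multiplied by the
#' unit length product and the exposure; pairs involving unplaced bins get
#' the floor intensity `1e-3 * Pt`. Entry `(u, v)` is the mean of the
#' observed count `k_uv` (upper triangle including the diagonal).
#'
#' @param structure a `genome_structure`.
#' @param params a [nuisance_params()].
#' @param exposure depth-matching scale factor (default 1).
#' @return Dense symmetric matrix over units.
#' @export
expected_matrix <- function(structure, params, exposure = 1) {
  units <- structure$units
  U <- nrow(units)
  flat <- flatten_structure(structure)
  lam <- matrix(0, U, U)
  if (length(flat$pos)) {
    R <- unit_rate_matrix(flat, params)
    P <- length(flat$pos)
    Tm <- matrix(0, P, U)
    Tm[cbind(seq_len(P), flat$unit)] <- 1
    S <- crossprod(Tm, R %*% Tm)
    diag(S) <- diag(S) / 2  # placement pairs p<q counted once, self halved
    lam <- S * outer(units$length_bp, units$length_bp)
  }
  placed_units <- sort(unique(flat$unit))
  unpl <- setdiff(seq_len(U), placed_units)
  if (length(unpl)) {
    copies <- tabulate(flat$unit, nbins = U)
    w <- pmax(copies, 1L) * units$length_bp
    eps_rate <- EPS_UNPLACED * params$Pt
    for (u in unpl) {
      lam[u, ] <- eps_rate * units$length_bp[u] * w
      lam[, u] <- lam[u, ]
      lam[u, u] <- eps_rate * units$length_bp[u]^2 / 2
    }
  }
  lam * exposure
}

#' Expected bin-pair contact count
#'
#' The Poisson mean for the bin pair `(i, j)`: the sum of the expected
#' unit-level counts over all unit pairs and all placement (copy) pairs of
#' the two bins. A bin placed twice therefore doubles its expected contacts
#' with the rest of the genome, which is the collapsed-duplication
#' signature.
#'
#' @param structure a `genome_structure`.
#' @param i,j bin ids.
#' @param params a [nuisance_params()].
#' @param exposure depth-matching scale factor.
#' @return Scalar expected count.
#' @export
expected_count <- function(structure, i, j, params, exposure = 1) {
  lam <- expected_matrix(structure, params, exposure)
  ui <- structure$units$unit[structure$units$bin_id == i]
  uj <- structure$units$unit[structure$units$bin_id == j]
  sub <- lam[ui, uj, drop = FALSE]
  if (i == j) {
    keep <- outer(ui, uj, "<=")
    sum(sub[keep])
  } else {
    sum(sub)
  }
}

# shared precomputation for fast likelihood evaluation
ll_env <- function(data) {
  ul <- as.numeric(data$units$length_bp)
  U <- data$n_units
  ti <- data$trip$i; tj <- data$trip$j; tk <- data$trip$k
  tw <- log(ul[ti] * ul[tj])
  # symmetric CSR over units (diagonal stored once)
  off <- ti != tj
  row <- c(ti, tj[off])
  col <- c(tj, ti[off])
  kk <- c(tk, tk[off])
  ww <- c(tw, tw[off])
  o <- order(row, col)
  row <- row[o]
  csr_ptr <- c(0L, cumsum(tabulate(row, nbins = U)))
  list(K = unit_counts(data),
       csr_ptr = as.integer(csr_ptr), csr_col = as.integer(col[o]),
       csr_k = as.numeric(kk[o]), csr_w = as.numeric(ww[o]),
       k_tot = sum(tk), kw_tot = sum(tk * tw),
       u_len = ul,
       lgamma_const = data$lgamma_const)
}

ll_flat <- function(flat, env, params, exposure) {
  cpp_loglik(as.integer(flat$scaf), flat$pos, flat$len, as.integer(flat$unit),
             env$u_len, env$K, env$csr_ptr, env$csr_col, env$csr_k, env$csr_w,
             env$k_tot, env$kw_tot,
             params$b, params$s0, params$Pt, EPS_UNPLACED,
             exposure, env$lgamma_const)
}

#' Poisson log-likelihood of a structure given contact data
#'
#' `sum over unit pairs (i <= j) of k_ij * log(lambda_ij) - lambda_ij -
#' log(k_ij!)`, with the expected counts `lambda` given by the power-law /
#' plateau contact model evaluated on the structure. The evaluation cost is
#' `O(non-zero pairs + intra-scaffold pairs)`: the trans and unplaced mass
#' is accumulated in closed form from scaffold length totals.
#'
#' @param data a `contact_matrix`.
#' @param structure a `genome_structure` over the same bin universe.
#' @param params a [nuisance_params()].
#' @param exposure depth-matching scale factor (default 1).
#' @return Scalar log-likelihood (finite for all legal inputs).
#' @export
log_likelihood <- function(data, structure, params, exposure = 1) {
  if (data$n_units != nrow(structure$units) ||
      data$n_bins != nrow(structure$bins))
    stop("contact matrix and structure dimensions differ")
  ll_flat(flatten_structure(structure), ll_env(data), params, exposure)
}

#' Cached likelihood state
#'
#' Bundles the log-likelihood of a structure with the inputs it was
#' computed from, for use with [delta_log_likelihood()]. The state carries a
#' fingerprint of the structure layout and errors out if used against a
#' structure it does not describe.
#'
#' @inheritParams log_likelihood
#' @return An object of class `likelihood_state`.
#' @export
likelihood_state <- function(data, structure, params, exposure = 1) {
  structure(list(
    loglik = log_likelihood(data, structure, params, exposure),
    params = params, exposure = exposure,
    fingerprint = structure_fingerprint(structure)
  ), class = "likelihood_state")
}

structure_fingerprint <- function(structure) {
  pl <- placements(structure)
  paste(c(pl$scaffold, pl$bin_id, pl$orient, pl$copy,
          sort(structure$unplaced)), collapse = "|")
}

#' Log-likelihood change under a move
#'
#' Applies `move` to `structure` and returns the log-likelihood difference
#' (after minus before). Agrees with a full recomputation to numerical
#' precision; both evaluations share the sparse-support fast path.
#'
#' @param state a [likelihood_state()] for `structure`.
#' @param data the `contact_matrix` the state was computed on.
#' @param structure the current `genome_structure`.
#' @param move a [mutation()].
#' @param params a [nuisance_params()]; must match the state.
#' @return Scalar log-likelihood difference.
#' @export
delta_log_likelihood <- function(state, data, structure, move, params = state$params) {
  stopifnot(inherits(state, "likelihood_state"))
  if (!identical(state$fingerprint, structure_fingerprint(structure)))
    stop("stale likelihood state: structure has changed")
  after <- apply_mutation(structure, move)
  log_likelihood(data, after, params, state$exposure) - state$loglik
}

#' Depth-matching exposure
#'
#' The exposure scale that makes the total expected contact count equal the
#' total observed count for a given structure and parameters. Exposure is a
#' deterministic depth constant, not a sampled parameter (it is confounded
#' with `Pt`).
#'
#' @inheritParams log_likelihood
#' @return Positive scalar.
#' @export
fit_exposure <- function(data, structure, params) {
  if (data$total_contacts <= 0) stop("all-zero contact matrix")
  lam <- expected_matrix(structure, params, exposure = 1)
  model_sum <- sum(lam[upper.tri(lam, diag = TRUE)])
  data$total_contacts / model_sum
}

#' Initial estimate of the nuisance parameters
#'
#' Least-squares initialisation: cis unit pairs of the structure are binned
#' by genomic distance on a log grid; the log mean intensity is regressed on
#' log distance to give `b`, the trans mean intensity gives `Pt`, and `s0`
#' is where the fitted power law crosses the trans level. Falls back to
#' mild defaults (`b = -1`, `s0` = 20 median bin lengths) when the
#' structure has too few cis pairs to fit, e.g. at a singleton
#' initialisation.
#'
#' @param data a `contact_matrix`.
#' @param structure a `genome_structure`.
#' @param bounds optional box constraints as from [default_xi_bounds()].
#' @return A [nuisance_params()].
#' @export
estimate_xi <- function(data, structure, bounds = default_xi_bounds()) {
  flat <- flatten_structure(structure)
  K <- unit_counts(data)
  P <- length(flat$pos)
  lenprod <- outer(flat$len, flat$len)
  Kp <- K[flat$unit, flat$unit, drop = FALSE]
  same <- outer(flat$scaf, flat$scaf, "==")
  d <- abs(outer(flat$pos, flat$pos, "-"))
  up <- upper.tri(d)
  intens <- Kp[up] / lenprod[up]
  cis <- same[up]; dd <- d[up]
  med_len <- median(structure$bins$length_bp)
  pt0 <- if (any(!cis)) mean(intens[!cis]) else mean(intens) / 2
  if (!is.finite(pt0) || pt0 <= 0) pt0 <- max(mean(intens), 1e-12)
  b0 <- -1; s00 <- 20 * med_len
  if (sum(cis) >= 20) {
    dc <- dd[cis]; ic <- intens[cis]
    brks <- exp(seq(log(max(min(dc), 1)), log(max(dc) + 1), length.out = 16))
    g <- cut(dc, breaks = unique(brks), include.lowest = TRUE)
    mi <- tapply(ic, g, mean)
    ms <- tapply(dc, g, mean)
    keep <- is.finite(mi) & mi > 1.5 * pt0 & is.finite(ms)
    if (sum(keep) >= 3) {
      fit <- lm(log(mi[keep]) ~ log(ms[keep]))
      b0 <- unname(coef(fit)[2L])
      # crossing point of the fitted line with the trans level
      s00 <- exp((log(pt0) - unname(coef(fit)[1L])) / b0)
    }
  }
  clamp <- function(x, r) min(max(x, r[1L]), r[2L])
  nuisance_params(clamp(b0, bounds$b), clamp(s00, bounds$s0),
                  clamp(pt0, bounds$Pt))
}

#' Default box constraints for the nuisance parameters
#'
#' @return A list with elements `b`, `s0`, `Pt`, each `c(lower, upper)`.
#' @export
default_xi_bounds <- function() {
  list(b = c(-4, -0.05), s0 = c(1e3, 1e8), Pt = c(1e-14, 1e-2))
}
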
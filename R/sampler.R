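#' Sampler configuration
#'
#' Bundles the tunable parameters of the structure sampler. Defaults are
#' the package-wide study conditions; see the methods vignette for the
#' rationale behind each.
#'
#' @param m number of partner bins drawn per iteration (>= 1).
#' @param n_cycles number of sweeps over all bins.
#' @param burn_in burn-in, in cycles, discarded from posterior summaries.
#' @param temperature softmax temperature on the log-likelihood scale used
#'   to select among the `14 * m + 1` candidates; `temperature -> 0` gives
#'   greedy selection of a highest-likelihood structure.
#' @param alpha pseudocount added to contact frequencies when drawing
#'   partners, so zero-contact partners remain reachable.
#' @param xi_bounds box constraints for the nuisance parameters, as from
#'   [default_xi_bounds()].
#' @param proposal_scales starting random-walk step sizes for the
#'   Metropolis updates of the nuisance parameters: linear in `b`,
#'   log-scale for `s0` and `Pt`.
#' @param adapt adapt the proposal scales during burn-in towards an
#'   acceptance rate of about 0.3 (diminishing adaptation; scales are
#'   frozen after burn-in so the post-burn-in chain is Markovian).
#' @param exposure fixed depth-matching scale (see [fit_exposure()]).
#' @param thin keep every `thin`-th post-burn-in structure in the trace
#'   (default: a tenth of the bin count).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(m = 3L, n_cycles = 10L, burn_in = 2L,
                           temperature = 1, alpha = 0.01,
                           xi_bounds = default_xi_bounds(),
                           proposal_scales = c(b = 0.08, log_s0 = 0.15,
                                               log_Pt = 0.08),
                           adapt = TRUE, exposure = 1, thin = NULL) {
  stopifnot(m >= 1L, n_cycles >= 1L, burn_in >= 0L, temperature >= 0)
  structure(list(m = as.integer(m), n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in), temperature = temperature,
                 alpha = alpha, xi_bounds = xi_bounds,
                 proposal_scales = proposal_scales, adapt = isTRUE(adapt),
                 exposure = exposure,
                 thin = thin), class = "sampler_config")
}

#' Draw partner placements for a bin
#'
#' Partners are drawn without replacement with probability proportional to
#' the observed bin-level contact count plus a pseudocount `alpha`. When a
#' partner bin has several placed copies one is chosen uniformly. If `m`
#' meets or exceeds the number of available partners, all partners are
#' returned.
#'
#' @param data a `contact_matrix`.
#' @param bin the focal bin id.
#' @param m number of partners to draw.
#' @param structure optional `genome_structure` used to resolve copies and
#'   to exclude unplaced bins from partnering.
#' @param alpha pseudocount.
#' @param counts optional precomputed [bin_counts()] matrix.
#' @param exclude_copy copy index of the focal placement; when the focal
#'   bin is placed more than once its *other* copies are legal partners
#'   (this is how a spurious duplicate can be reabsorbed), but the focal
#'   placement itself never is.
#' @return A list of placements `c(bin_id, copy_index)`.
#' @export
choose_partners <- function(data, bin, m, structure = NULL, alpha = 0.01,
                            counts = NULL, exclude_copy = NULL) {
  stopifnot(m >= 1L)
  if (is.null(counts)) counts <- bin_counts(data)
  w <- counts[bin, ] + alpha
  mult <- NULL
  self_ok <- FALSE
  if (!is.null(structure)) {
    mult <- multiplicity(structure)
    w[mult == 0L] <- 0 # unplaced bins cannot anchor an insertion
    self_ok <- !is.null(exclude_copy) && mult[bin] > 1L
  }
  if (!self_ok) w[bin] <- 0
  avail <- which(w > 0)
  ids <- if (m >= length(avail)) avail
         else avail[sample.int(length(avail), m, prob = w[avail])]
  lapply(ids, function(b) {
    cp <- 0L
    if (!is.null(structure)) {
      copies <- copies_of(structure, b)
      if (b == bin && !is.null(exclude_copy))
        copies <- setdiff(copies, exclude_copy)
      cp <- if (length(copies) == 1L) copies
            else copies[sample.int(length(copies), 1L)]
    }
    c(b, cp)
  })
}

softmax_select <- function(ll, temperature) {
  if (temperature <= 0) {
    top <- which(ll == max(ll))
    return(if (length(top) == 1L) top else top[sample.int(length(top), 1L)])
  }
  w <- (ll - max(ll)) / temperature
  p <- exp(w)
  sample.int(length(ll), 1L, prob = p / sum(p))
}

#' One multiple-try structure update
#'
#' Builds the `14 * m` candidate structures around `bin` (plus the current
#' structure as a null candidate), scores each with the Poisson
#' log-likelihood, and selects one with probability proportional to
#' `exp(loglik / temperature)`. The selection is returned unconditionally
#' (systematic acceptance). When the visited bin is unplaced, the candidate
#' set consists of the `4 * m` reinsertion moves plus the null candidate.
#'
#' @param structure current `genome_structure`.
#' @param data a `contact_matrix`.
#' @param params current [nuisance_params()].
#' @param bin the bin id visited this iteration.
#' @param config a [sampler_config()].
#' @param counts optional precomputed [bin_counts()].
#' @param env,flat,ll_current internal caches (precomputed likelihood
#'   environment, flattened structure, current log-likelihood).
#' @return A list with `structure`, `move` (the chosen [mutation()], or
#'   `NULL` for the null candidate), `loglik` of the selection, `delta`
#'   relative to the input structure, and the updated internal caches.
#' @export
structure_step <- function(structure, data, params, bin, config,
                           counts = NULL, env = NULL, flat = NULL,
                           ll_current = NULL) {
  if (is.null(env)) env <- ll_env(data)
  if (is.null(flat)) flat <- flatten_structure(structure)
  if (is.null(ll_current))
    ll_current <- ll_flat(flat, env, params, config$exposure)

  mult <- multiplicity(structure)
  pidx <- placement_index(structure)
  cp <- NULL
  if (mult[bin] > 0L) {
    copies <- copies_of(structure, bin)
    cp <- if (length(copies) == 1L) copies
          else copies[sample.int(length(copies), 1L)]
  }
  partners <- choose_partners(data, bin, config$m, structure,
                              alpha = config$alpha, counts = counts,
                              exclude_copy = cp)
  if (!length(partners)) {
    return(list(structure = structure, move = NULL, loglik = ll_current,
                delta = 0, flat = flat))
  }

  if (is.null(cp)) {
    cands <- list()
    for (p in partners) {
      for (side in c("before", "after")) for (ori in c("forward", "reverse")) {
        mv <- mutation("reinsert", bin, partner = p, side = side,
                       orientation = ori)
        cands[[length(cands) + 1L]] <-
          list(move = mv, structure = apply_mutation(structure, mv, .pidx = pidx))
      }
    }
  } else {
    cands <- enumerate_candidates(structure, c(bin, cp), partners,
                                  .pidx = pidx)
  }

  nc <- length(cands)
  ll <- numeric(nc + 1L)
  flats <- vector("list", nc)
  for (i in seq_len(nc)) {
    flats[[i]] <- flatten_structure(cands[[i]]$structure)
    ll[i] <- ll_flat(flats[[i]], env, params, config$exposure)
  }
  ll[nc + 1L] <- ll_current

  sel <- softmax_select(ll, config$temperature)
  if (sel == nc + 1L) {
    list(structure = structure, move = NULL, loglik = ll_current, delta = 0,
         flat = flat)
  } else {
    list(structure = cands[[sel]]$structure, move = cands[[sel]]$move,
         loglik = ll[sel], delta = ll[sel] - ll_current, flat = flats[[sel]])
  }
}

#' One Metropolis sweep over the nuisance parameters
#'
#' Updates `b` (linear random walk), then `s0` and `Pt` (log-scale random
#' walks), each with a Metropolis accept/reject against the Poisson
#' likelihood under a flat prior inside the box constraints; proposals
#' falling outside the box are rejected.
#'
#' @inheritParams structure_step
#' @param params current [nuisance_params()].
#' @return A list with `params`, the updated `loglik`, and `accepted`
#'   (logical 3-vector for `b`, `s0`, `Pt`).
#' @export
nuisance_step <- function(params, structure, data, config,
                          env = NULL, flat = NULL, ll_current = NULL) {
  if (is.null(env)) env <- ll_env(data)
  if (is.null(flat)) flat <- flatten_structure(structure)
  if (is.null(ll_current))
    ll_current <- ll_flat(flat, env, params, config$exposure)
  sc <- config$proposal_scales
  bounds <- config$xi_bounds
  accepted <- c(b = FALSE, s0 = FALSE, Pt = FALSE)

  prop <- list(
    b = function(p) { p$b <- p$b + stats::rnorm(1, 0, sc[["b"]]); p },
    s0 = function(p) { p$s0 <- p$s0 * exp(stats::rnorm(1, 0, sc[["log_s0"]])); p },
    Pt = function(p) { p$Pt <- p$Pt * exp(stats::rnorm(1, 0, sc[["log_Pt"]])); p }
  )
  inside <- function(p)
    p$b >= bounds$b[1L] && p$b <= bounds$b[2L] &&
    p$s0 >= bounds$s0[1L] && p$s0 <= bounds$s0[2L] &&
    p$Pt >= bounds$Pt[1L] && p$Pt <= bounds$Pt[2L]

  for (nm in names(prop)) {
    cand <- prop[[nm]](params)
    if (!inside(cand)) next
    ll_new <- ll_flat(flat, env, cand, config$exposure)
    if (log(runif(1)) < ll_new - ll_current) {
      params <- cand
      ll_current <- ll_new
      accepted[nm] <- TRUE
    }
  }
  list(params = params, loglik = ll_current, accepted = accepted)
}

# diminishing-adaptation update of the proposal scales towards ~0.3
# acceptance (applied during burn-in only)
adapt_scales <- function(sc, rates, batch) {
  step <- min(1, 2 / sqrt(batch))
  pmin(pmax(sc * exp(step * (unname(rates) - 0.3)), 1e-4), 2)
}

#' Sample the nuisance parameters at a fixed structure
#'
#' Runs the Metropolis chain over `(b, s0, Pt)` holding the genome
#' structure fixed; used for parameter-recovery experiments and for
#' profiling the contact model on a trusted assembly. Proposal scales are
#' adapted during burn-in towards ~0.3 acceptance and then frozen.
#'
#' @param data a `contact_matrix`.
#' @param structure the `genome_structure` to condition on.
#' @param n_sweeps total Metropolis sweeps (each updates all three
#'   parameters once).
#' @param burn_in sweeps discarded from the posterior summary.
#' @param config a [sampler_config()] (bounds and starting scales).
#' @param xi0 optional starting [nuisance_params()].
#' @param seed integer seed.
#' @return A list with `chain` (`n_sweeps` x 3 matrix), `params`
#'   (posterior medians as [nuisance_params()]), `acceptance`
#'   (post-burn-in acceptance rate) and `scales` (adapted step sizes).
#' @export
fit_nuisance <- function(data, structure, n_sweeps = 1000,
                         burn_in = max(100L, n_sweeps %/% 3L),
                         config = sampler_config(), xi0 = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  params <- xi0 %||% estimate_xi(data, structure, config$xi_bounds)
  env <- ll_env(data)
  flat <- flatten_structure(structure)
  ll <- ll_flat(flat, env, params, config$exposure)
  sc <- config$proposal_scales
  chain <- matrix(NA_real_, n_sweeps, 3L,
                  dimnames = list(NULL, c("b", "s0", "Pt")))
  accw <- c(0, 0, 0); win <- 0L; nbatch <- 0L
  acc_post <- 0; n_post <- 0L
  cfg <- config
  for (i in seq_len(n_sweeps)) {
    cfg$proposal_scales <- sc
    st <- nuisance_step(params, structure, data, cfg, env = env, flat = flat,
                        ll_current = ll)
    params <- st$params; ll <- st$loglik
    if (i <= burn_in) {
      accw <- accw + st$accepted; win <- win + 1L
      if (config$adapt && win == 25L) {
        nbatch <- nbatch + 1L
        sc <- adapt_scales(sc, accw / 25, nbatch)
        accw[] <- 0; win <- 0L
      }
    } else {
      acc_post <- acc_post + mean(st$accepted); n_post <- n_post + 1L
    }
    chain[i, ] <- c(params$b, params$s0, params$Pt)
  }
  post <- chain[(burn_in + 1L):n_sweeps, , drop = FALSE]
  list(chain = chain,
       params = nuisance_params(median(post[, 1L]), median(post[, 2L]),
                                median(post[, 3L])),
       acceptance = if (n_post) acc_post / n_post else NA_real_,
       scales = sc)
}

#' Dispersion of the number of contigs along a trace
#'
#' Interquartile range (Q3 - Q1, linear interpolation) of the scaffold
#' count over iterations from `from_iteration` on. Zero indicates that the
#' chain has collapsed onto a single structure mode.
#'
#' @param trace a fit object from [proxiscaf()] or its `trace` data frame.
#' @param from_iteration first iteration to include (default: after
#'   burn-in when a fit is given, else 1).
#' @return Scalar IQR.
#' @export
dispersion <- function(trace, from_iteration = NULL) {
  if (inherits(trace, "proxiscaf")) {
    from_iteration <- from_iteration %||% (trace$config$burn_in *
                                             nrow(trace$bins) + 1L)
    trace <- trace$trace
  }
  from_iteration <- from_iteration %||% 1L
  if (from_iteration > nrow(trace)) stop("from_iteration beyond trace length")
  x <- trace$n_contigs[trace$iteration >= from_iteration]
  unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7))
}
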
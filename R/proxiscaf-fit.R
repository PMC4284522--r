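#' Fit a genome structure to contact data
#'
#' Runs the multiple-try rearrangement sampler: each cycle visits every bin
#' once in random order (without replacement); at each visit, `m` partner
#' bins are drawn from the observed contact frequencies, the `14 * m`
#' candidate rearrangements (plus the current structure) are scored under
#' the Poisson contact likelihood, one is selected with probability
#' proportional to `exp(loglik / temperature)` and systematically accepted,
#' and the nuisance parameters `(b, s0, Pt)` are then updated by a
#' Metropolis sweep. Each new cycle restarts from the highest-likelihood
#' structure seen during the previous cycle. Runs are deterministic given
#' `seed`: all stochastic choices (bin order, partner draws, candidate
#' selection, parameter proposals) come from one seeded generator in that
#' order.
#'
#' @param data a [contact_matrix()].
#' @param init initial structure: a `genome_structure`, or `"singletons"`
#'   (every bin its own contig; de novo assembly) or `"by_source"` (one
#'   scaffold per input sequence; curation of an existing assembly).
#' @param config a [sampler_config()]; individual fields can also be passed
#'   through `...` for convenience.
#' @param xi0 optional starting [nuisance_params()]; default is the
#'   least-squares initialisation of [estimate_xi()].
#' @param seed integer seed.
#' @param verbose print one progress line per cycle.
#' @param ... fields forwarded to [sampler_config()] when `config` is NULL.
#' @return An object of class `proxiscaf` with components `best` (the
#'   highest-likelihood post-burn-in structure), `final`, `trace`
#'   (per-iteration data frame: `iteration`, `cycle`, `loglik`,
#'   `n_contigs`, `b`, `s0`, `Pt`, `move`), `structures` (thinned
#'   post-burn-in structures), `xi` (posterior medians), `bins`, `config`,
#'   `seed` and `call`.
#' @examples
#' sim <- sim_genome(n_bins = 24, chrom_lengths = c(3, 2, 1), bin_bp = 10000)
#' cm <- simulate_contacts(sim$structure, nuisance_params(-1.5, 1e5, 1e-9),
#'                         n_contacts = 2e5, seed = 1)
#' fit <- proxiscaf(cm, init = "singletons", n_cycles = 4, seed = 1)
#' summary(fit)
#' @export
proxiscaf <- function(data, init = "singletons", config = NULL, xi0 = NULL,
                      seed = 1L, verbose = FALSE, ...) {
  stopifnot(inherits(data, "contact_matrix"))
  if (data$total_contacts <= 0) stop("empty contact matrix")
  if (is.null(config)) config <- sampler_config(...)
  cl <- match.call()

  gs <- if (inherits(init, "genome_structure")) init
        else initial_structure(data$bins, match.arg(init, c("singletons", "by_source")))
  if (nrow(gs$units) != data$n_units)
    stop("structure and contact matrix dimensions differ")

  set.seed(as.integer(seed))
  params <- xi0 %||% estimate_xi(data, gs, config$xi_bounds)
  env <- ll_env(data)
  counts <- bin_counts(data)
  n_bins <- data$n_bins
  thin <- config$thin %||% max(1L, n_bins %/% 10L)
  burn_iter <- config$burn_in * n_bins

  flat <- flatten_structure(gs)
  ll <- ll_flat(flat, env, params, config$exposure)

  n_total <- config$n_cycles * n_bins
  tr_ll <- tr_nc <- tr_b <- tr_s0 <- tr_pt <- numeric(n_total)
  tr_cycle <- integer(n_total)
  tr_move <- character(n_total)
  kept <- list()
  best <- list(ll = -Inf, gs = gs)          # post-burn-in global best
  overall_best <- list(ll = ll, gs = gs)    # fallback when burn-in too long

  it <- 0L
  sc <- config$proposal_scales
  accw <- c(0, 0, 0); win <- 0L; nbatch <- 0L
  for (cycle in seq_len(config$n_cycles)) {
    cyc_best <- list(ll = -Inf, gs = NULL, flat = NULL)
    for (bin in sample.int(n_bins)) {
      it <- it + 1L
      st <- structure_step(gs, data, params, bin, config,
                           counts = counts, env = env, flat = flat,
                           ll_current = ll)
      gs <- st$structure; flat <- st$flat; ll <- st$loglik
      config$proposal_scales <- sc
      nu <- nuisance_step(params, gs, data, config, env = env, flat = flat,
                          ll_current = ll)
      params <- nu$params; ll <- nu$loglik
      if (config$adapt && it <= burn_iter) {
        accw <- accw + nu$accepted; win <- win + 1L
        if (win == 25L) {
          nbatch <- nbatch + 1L
          sc <- adapt_scales(sc, accw / 25, nbatch)
          accw[] <- 0; win <- 0L
        }
      }

      tr_cycle[it] <- cycle
      tr_ll[it] <- ll
      tr_nc[it] <- n_contigs(gs)
      tr_b[it] <- params$b; tr_s0[it] <- params$s0; tr_pt[it] <- params$Pt
      tr_move[it] <- if (is.null(st$move)) "null" else st$move$kind

      if (ll > cyc_best$ll) cyc_best <- list(ll = ll, gs = gs, flat = flat)
      if (ll > overall_best$ll) overall_best <- list(ll = ll, gs = gs)
      if (it > burn_iter) {
        if (ll > best$ll) best <- list(ll = ll, gs = gs)
        if ((it - burn_iter) %% thin == 0L)
          kept[[length(kept) + 1L]] <- list(iteration = it, structure = gs)
      }
    }
    # restart rule: new cycle resumes from the best structure of this cycle
    if (!is.null(cyc_best$gs)) {
      gs <- cyc_best$gs; flat <- cyc_best$flat
      ll <- ll_flat(flat, env, params, config$exposure)
    }
    if (verbose)
      message(sprintf("cycle %d/%d: loglik %.1f, %d contigs, b=%.2f s0=%.3g Pt=%.3g",
                      cycle, config$n_cycles, ll, n_contigs(gs),
                      params$b, params$s0, params$Pt))
  }

  if (!is.finite(best$ll)) best <- overall_best
  trace <- data.frame(iteration = seq_len(n_total), cycle = tr_cycle,
                      loglik = tr_ll, n_contigs = tr_nc,
                      b = tr_b, s0 = tr_s0, Pt = tr_pt, move = tr_move,
                      stringsAsFactors = FALSE)
  post <- trace[trace$iteration > burn_iter, , drop = FALSE]
  if (!nrow(post)) post <- trace
  xi <- nuisance_params(median(post$b), median(post$s0), median(post$Pt))

  structure(list(
    best = best$gs, best_loglik = best$ll, final = gs, trace = trace,
    structures = kept, xi = xi, bins = data$bins, config = config,
    seed = seed, data_summary = list(n_bins = n_bins,
                                     total_contacts = data$total_contacts),
    call = cl
  ), class = "proxiscaf")
}

#' Write the per-iteration trace of a fit
#'
#' One tab-separated line per iteration: iteration, loglik, n_contigs, b,
#' s0, Pt, move kind. If `structures_dir` is given, the thinned
#' post-burn-in structures are additionally written there as layout files
#' (`structure_<iteration>.tsv`).
#' @param fit a `proxiscaf` fit.
#' @param path file path.
#' @param structures_dir optional directory for thinned structure layouts.
#' @export
write_trace <- function(fit, path, structures_dir = NULL) {
  write.table(fit$trace[, c("iteration", "loglik", "n_contigs",
                            "b", "s0", "Pt", "move")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(structures_dir)) {
    dir.create(structures_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in fit$structures)
      write_layout(s$structure,
                   file.path(structures_dir,
                             sprintf("structure_%06d.tsv", s$iteration)))
  }
  invisible(path)
}

#' @export
print.proxiscaf <- function(x, ...) {
  cat("Genome structure fit from contact data\n")
  cat(sprintf("  %d bins, %s contacts, %d iterations (%d cycles)\n",
              x$data_summary$n_bins,
              format(x$data_summary$total_contacts, big.mark = ","),
              nrow(x$trace), x$config$n_cycles))
  cat(sprintf("  best log-likelihood: %.2f; scaffolds in best structure: %d\n",
              x$best_loglik, n_contigs(x$best)))
  print(x$xi)
  invisible(x)
}

#' @export
summary.proxiscaf <- function(object, ...) {
  burn_iter <- object$config$burn_in * object$data_summary$n_bins
  post <- object$trace[object$trace$iteration > burn_iter, , drop = FALSE]
  if (!nrow(post)) post <- object$trace
  out <- list(
    n_iterations = nrow(object$trace),
    burn_in_iterations = burn_iter,
    best_loglik = object$best_loglik,
    n_contigs_best = n_contigs(object$best),
    n_contigs_median = median(post$n_contigs),
    n_contigs_iqr = unname(quantile(post$n_contigs, 0.75) -
                             quantile(post$n_contigs, 0.25)),
    xi = object$xi,
    move_acceptance = prop.table(table(post$move))
  )
  class(out) <- "summary.proxiscaf"
  out
}

#' @export
print.summary.proxiscaf <- function(x, ...) {
  cat(sprintf("iterations: %d (burn-in %d)\n", x$n_iterations,
              x$burn_in_iterations))
  cat(sprintf("best log-likelihood: %.2f\n", x$best_loglik))
  cat(sprintf("contigs: best %d, post-burn-in median %.1f, iqr %.2f\n",
              x$n_contigs_best, x$n_contigs_median, x$n_contigs_iqr))
  print(x$xi)
  cat("selected move mix:\n")
  print(round(x$move_acceptance, 3))
  invisible(x)
}

#' @export
coef.proxiscaf <- function(object, ...) {
  c(b = object$xi$b, s0 = object$xi$s0, Pt = object$xi$Pt)
}

#' @export
logLik.proxiscaf <- function(object, ...) {
  val <- object$best_loglik
  attr(val, "df") <- 3L # the nuisance parameters; structure is nonparametric
  class(val) <- "logLik"
  val
}

#' Trace plots of a structure fit
#'
#' Three base-graphics panels: log-likelihood, number of contigs, and the
#' nuisance-parameter traces.
#' @param x a `proxiscaf` fit.
#' @param ... ignored.
#' @export
plot.proxiscaf <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(tr$iteration, tr$loglik, type = "l", xlab = "iteration",
       ylab = "log-likelihood")
  plot(tr$iteration, tr$n_contigs, type = "s", xlab = "iteration",
       ylab = "contigs")
  plot(tr$iteration, tr$b, type = "l", xlab = "iteration", ylab = "b")
  invisible(x)
}

#' Simulate contact matrices from a fit
#'
#' Draws Poisson contact matrices from the fitted structure and posterior
#' median parameters at the observed sequencing depth.
#' @param object a `proxiscaf` fit.
#' @param nsim number of matrices.
#' @param seed integer seed.
#' @param ... ignored.
#' @return A list of `contact_matrix` objects.
#' @export
simulate.proxiscaf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_contacts(object$best, object$xi,
                      n_contacts = object$data_summary$total_contacts,
                      seed = sample.int(.Machine$integer.max, 1L))
  })
}
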
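# Shared fixtures and independent oracles. Everything here is deliberately
# written as plain scalar loops, independent of the package's vectorised /
# compiled code paths it is used to check.

toy_bins <- function(n, sources = "chrA", len = 10000, n_rf = 4L) {
  bin_table(length_bp = rep_len(len, n), n_rf = rep_len(n_rf, n),
            source_name = rep_len(sources, n))
}

toy_params <- function(b = -1.5, s0 = 1e5, Pt = 1e-9) nuisance_params(b, s0, Pt)

# one placed-unit row per placement, computed by naive scaffold walking
oracle_unit_positions <- function(gs) {
  rows <- list()
  for (si in seq_along(gs$scaffolds)) {
    m <- gs$scaffolds[[si]]
    at <- 0
    for (r in seq_len(nrow(m))) {
      b <- m[r, 1L]
      L <- gs$bins$length_bp[b]
      us <- gs$units[gs$units$bin_id == b, ]
      if (nrow(us) == 1L) {
        rows[[length(rows) + 1L]] <-
          data.frame(unit = us$unit, scaf = si, pos = at + L / 2, len = L)
      } else {
        o <- m[r, 2L]
        p1 <- if (o == 1L) at + L / 4 else at + 3 * L / 4
        p2 <- if (o == 1L) at + 3 * L / 4 else at + L / 4
        rows[[length(rows) + 1L]] <-
          data.frame(unit = us$unit[1L], scaf = si, pos = p1, len = L / 2)
        rows[[length(rows) + 1L]] <-
          data.frame(unit = us$unit[2L], scaf = si, pos = p2, len = L / 2)
      }
      at <- at + L
    }
  }
  do.call(rbind, rows)
}

# dense expected-count matrix by scalar loops
oracle_lambda <- function(gs, params, exposure = 1) {
  U <- nrow(gs$units)
  lam <- matrix(0, U, U)
  pu <- oracle_unit_positions(gs)
  rate1 <- function(d, fl) {
    d <- max(d, fl)
    if (d >= params$s0) params$Pt else params$Pt * (d / params$s0)^params$b
  }
  for (u in seq_len(U)) for (v in u:U) {
    P <- pu[pu$unit == u, , drop = FALSE]
    Q <- pu[pu$unit == v, , drop = FALSE]
    lu <- gs$units$length_bp[u]; lv <- gs$units$length_bp[v]
    if (nrow(P) == 0L || nrow(Q) == 0L) {
      s <- 1e-3 * params$Pt *
        (if (u == v) 0.5 else max(1L, nrow(P), nrow(Q)))
      lam[u, v] <- exposure * s * lu * lv
    } else {
      S <- 0
      for (i in seq_len(nrow(P))) {
        jj <- if (u == v) i:nrow(Q) else seq_len(nrow(Q))
        for (j in jj) {
          S <- S +
            if (u == v && i == j) 0.5 * rate1(0, max(1, P$len[i] / 2))
            else if (P$scaf[i] == Q$scaf[j])
              rate1(abs(P$pos[i] - Q$pos[j]),
                    max(1, min(P$len[i], Q$len[j]) / 2))
            else params$Pt
        }
      }
      lam[u, v] <- exposure * S * lu * lv
    }
    lam[v, u] <- lam[u, v]
  }
  lam
}

# scalar-loop Poisson log-likelihood
oracle_loglik <- function(cm, gs, params, exposure = 1) {
  lam <- oracle_lambda(gs, params, exposure)
  K <- unit_counts(cm)
  s <- 0
  for (u in seq_len(nrow(lam))) for (v in u:nrow(lam))
    s <- s + K[u, v] * log(lam[u, v]) - lam[u, v] - lgamma(K[u, v] + 1)
  s
}

# a random legal move on the current structure
random_move <- function(gs) {
  pl <- placements(gs)
  cat14 <- move_catalogue()
  repeat {
    i <- sample.int(14L, 1L)
    a <- pl[sample.int(nrow(pl), 1L), ]
    if (cat14$kind[i] %in% c("delete", "eject")) {
      if (cat14$kind[i] == "delete" && nrow(pl) < 4L) next
      return(mutation(cat14$kind[i], c(a$bin_id, a$copy)))
    }
    b <- pl[sample.int(nrow(pl), 1L), ]
    if (a$bin_id == b$bin_id && a$copy == b$copy) next
    return(mutation(cat14$kind[i], c(a$bin_id, a$copy),
                    c(b$bin_id, b$copy), cat14$side[i], cat14$orientation[i]))
  }
}

# signature of a structure ignoring scaffold names: sorted canonical strings
structure_signature <- function(gs) {
  enc <- vapply(gs$scaffolds, function(m) {
    fwd <- paste(m[, 1L] * m[, 2L], collapse = ",")
    rv <- paste(rev(-m[, 1L] * m[, 2L]), collapse = ",")
    min(fwd, rv)
  }, "")
  paste(c(sort(enc), sort(gs$unplaced)), collapse = "|")
}
`%||%` <- function(a, b) if (is.null(a)) b else a
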
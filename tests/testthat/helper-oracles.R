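# Independent oracles used across the suite. These deliberately re-derive
# each quantity by a different route than the package (stepwise vergence
# propagation + numeric root finding for the optics; permutation /
# enumeration / textbook sums for the statistics) so agreement is evidence,
# not tautology.

# --- stepwise thin-lens vergence oracle -----------------------------------
# Required IOL power at ELP for a trial spectacle refraction, propagating
# vergence surface by surface; refraction for a given power is recovered by
# bracketed root finding.
oracle_required_power <- function(corneal_power, n, elp_mm, axial_mm, ref,
                                  vertex_mm = 12) {
  v_cornea <- if (abs(ref) < 1e-14) 0 else 1000 / (1000 / ref - vertex_mm)
  v_after_cornea <- v_cornea + corneal_power
  v_at_iol <- 1000 * n / (1000 * n / v_after_cornea - elp_mm)
  1000 * n / (axial_mm - elp_mm) - v_at_iol
}

oracle_refraction <- function(corneal_power, n, elp_mm, axial_mm, power,
                              vertex_mm = 12) {
  stats::uniroot(function(r) {
    oracle_required_power(corneal_power, n, elp_mm, axial_mm, r, vertex_mm) -
      power
  }, c(-45, 45), tol = 1e-12)$root
}

# SRK/T oracle: recompute the published intermediates step by step (scalar
# arithmetic, no shared code path), then invert the vergence chain.
oracle_srkt_refraction <- function(al, k_flat, k_steep, a_constant, power) {
  k <- (k_flat + k_steep) / 2
  r <- 337.5 / k
  lcor <- if (al <= 24.2) al else -3.446 + 1.716 * al - 0.0237 * al * al
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k
  arg <- r * r - cw * cw / 4
  h <- r - sqrt(max(arg, 0))
  elp <- h + (0.62467 * a_constant - 68.747) - 3.336
  lopt <- al + 0.65696 - 0.02029 * al
  dc <- (1.333 - 1) * 1000 / r
  oracle_refraction(dc, 1.336, elp, lopt, power)
}

oracle_haigis_refraction <- function(al, acd, k_flat, k_steep, a0, a1, a2,
                                     power) {
  k <- (k_flat + k_steep) / 2
  rc <- 337.5 / k
  dc <- (1.3315 - 1) * 1000 / rc
  elp <- a0 + a1 * acd + a2 * al
  oracle_refraction(dc, 1.336, elp, al, power)
}

# Emmetropia power by bracketed root finding on the package's own forward
# function (checks the closed-form inversion against a numeric solver).
oracle_emmetropia_power <- function(forward, lo = -10, hi = 40) {
  stats::uniroot(forward, c(lo, hi), tol = 1e-10)$root
}

# --- Friedman permutation oracle ------------------------------------------
# Monte Carlo null of the Friedman chi-square under independent within-block
# permutations of the columns.
oracle_friedman_perm_p <- function(abs_err, n_perm = 4000, seed = 123) {
  stat_of <- function(m) {
    r <- t(apply(m, 1, rank))
    n <- nrow(m); k <- ncol(m)
    cs <- colSums(r)
    # tie-corrected Friedman statistic (matches the standard definition)
    ties <- apply(m, 1, function(row) {
      tab <- table(row); sum(tab^3 - tab)
    })
    num <- 12 * sum((cs - n * (k + 1) / 2)^2)
    den <- n * k * (k + 1) - sum(ties) / (k - 1)
    num / den
  }
  obs <- stat_of(abs_err)
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    perm <- t(apply(abs_err, 1, sample))
    if (stat_of(perm) >= obs - 1e-12) ge <- ge + 1L
  }
  list(stat = obs, p = ge / n_perm)
}

# --- Cochran's Q exact enumeration oracle ---------------------------------
# Under the null, each block's indicator multiset is exchangeable across the
# k formulas. Q depends only on the column totals, whose exact distribution
# follows by dynamic programming over blocks (full enumeration of the
# k!^n permutation space, collapsed by sufficiency).
oracle_cochran_exact <- function(ind) {
  n <- nrow(ind); k <- ncol(ind)
  q_of <- function(col_tot, row_tot) {
    den <- k * sum(row_tot) - sum(row_tot^2)
    if (den == 0) return(0)
    (k - 1) * (k * sum(col_tot^2) - sum(col_tot)^2) / den
  }
  row_tot <- rowSums(ind)
  obs <- q_of(colSums(ind), row_tot)
  perms <- .permutations_of(seq_len(k))
  # exact distribution over column-total vectors by DP over blocks
  dist <- list()
  dist[[paste(rep(0, k), collapse = ",")]] <- 1
  w <- 1 / nrow(perms)
  for (i in seq_len(n)) {
    counts <- table(apply(t(apply(perms, 1, function(p) ind[i, p])), 1,
                          paste, collapse = ","))
    nd <- list()
    for (key in names(dist)) {
      base <- as.integer(strsplit(key, ",")[[1]])
      for (ck in names(counts)) {
        add <- as.integer(strsplit(ck, ",")[[1]])
        nk <- paste(base + add, collapse = ",")
        nd[[nk]] <- (if (is.null(nd[[nk]])) 0 else nd[[nk]]) +
          dist[[key]] * counts[[ck]] * w
      }
    }
    dist <- nd
  }
  p_gt <- 0; p_eq <- 0
  for (key in names(dist)) {
    ct <- as.integer(strsplit(key, ",")[[1]])
    q <- q_of(ct, row_tot)
    if (q > obs + 1e-12) p_gt <- p_gt + dist[[key]]
    else if (abs(q - obs) <= 1e-12) p_eq <- p_eq + dist[[key]]
  }
  # p: conservative exact tail; midp: half-mass correction for the discrete
  # atom at the observed statistic (the right comparator for a continuous
  # chi-square approximation)
  list(q = obs, p = p_gt + p_eq, midp = p_gt + p_eq / 2)
}

.permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# --- textbook log-rank oracle ---------------------------------------------
# Standard two-group log-rank sums over distinct event times (no censoring).
oracle_logrank_chisq <- function(t_a, t_b) {
  times <- sort(unique(c(t_a, t_b)))
  o_a <- 0; e_a <- 0; v <- 0
  for (t in times) {
    n_a <- sum(t_a >= t); n_b <- sum(t_b >= t)
    d_a <- sum(t_a == t); d_b <- sum(t_b == t)
    n <- n_a + n_b; d <- d_a + d_b
    if (n < 2) next
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    v <- v + d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
  }
  (o_a - e_a)^2 / v
}
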
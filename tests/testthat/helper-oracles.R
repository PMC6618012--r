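# Independent oracles used to cross-check the finite-volume solver.

# Closed-form steady profile of a single-layer slab with first-order sink:
# C(y) = C0 cosh(sqrt(k/D)(L - y)) / cosh(sqrt(k/D) L), Dirichlet C0 at
# y = 0, no-flux at y = L.
slab_cosh_profile <- function(y, L, d, k, c0) {
  lam <- sqrt(k / d)
  c0 * cosh(lam * (L - y)) / cosh(lam * L)
}

# Monte-Carlo random-walk estimate of the reassimilated fraction on the
# frozen-coefficient lattice of a converged solve. Walkers start in the
# source region (area-weighted); at each cell they either escape across the
# airspace boundary, are absorbed by the first-order sink, or hop to a
# neighbour with probability proportional to the face conductance. The
# absorbed fraction estimates freass; this is the same discrete harmonic
# problem the tracer solves, sampled by particles instead of linear algebra.
rw_freass <- function(result, n_walkers = 1e5, seed = 7L, max_steps = 1e6) {
  int <- result$internals
  ctx <- int$ctx
  n <- length(ctx$area)
  A <- as(ctx$A0, "TsparseMatrix")
  off <- which(A@i != A@j)
  from <- A@j[off] + 1L
  to <- A@i[off] + 1L
  g <- -A@x[off]
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; g <- g[ord]
  max_nb <- max(table(from))
  nb_idx <- matrix(0L, n, max_nb)
  nb_g <- matrix(0, n, max_nb)
  slot <- integer(n)
  for (m in seq_along(from)) {
    f <- from[m]
    slot[f] <- slot[f] + 1L
    nb_idx[f, slot[f]] <- to[m]
    nb_g[f, slot[f]] <- g[m]
  }
  absorb <- int$k * ctx$area
  escape <- numeric(n)
  escape[ctx$top_idx] <- ctx$gtop
  total <- escape + absorb + rowSums(nb_g)
  # cumulative outcome probabilities: escape | absorb | neighbours...
  cum <- cbind(escape, absorb, nb_g) / total
  cum <- t(apply(cum, 1, cumsum))

  set.seed(seed)
  start_p <- ctx$area[int$src_idx] / sum(ctx$area[int$src_idx])
  state <- sample(int$src_idx, n_walkers, replace = TRUE, prob = start_p)
  absorbed <- 0L
  escaped <- 0L
  for (step in seq_len(max_steps)) {
    m <- length(state)
    if (m == 0L) break
    u <- stats::runif(m)
    cu <- cum[state, , drop = FALSE]
    pick <- rowSums(u > cu) + 1L  # 1 escape, 2 absorb, >2 neighbour
    escaped <- escaped + sum(pick == 1L)
    absorbed <- absorbed + sum(pick == 2L)
    move <- pick > 2L
    state <- nb_idx[cbind(state[move], pick[move] - 2L)]
  }
  if (length(state) > 0L) {
    stop("random-walk oracle did not terminate within max_steps")
  }
  absorbed / n_walkers
}
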
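# Shared fixtures: all synthetic, built in code.

# noise-free camera for exact-value assertions
quietParams <- function(shape = c(64L, 64L), ...) {
  VirtualSampleParams(imageShape = shape, backgroundLevel = 50,
                      readNoiseSd = 0, shotNoise = FALSE, ...)
}

# population with fully specified geometry (circular cells of radius r)
cellsAt <- function(centers, r = 6, protein = 0, dye = 0) {
  n <- nrow(centers)
  data.frame(id = seq_len(n), parent_id = NA_integer_,
             cx = centers[, 1], cy = centers[, 2],
             a = rep(r, n), b = rep(r, n), theta = 0,
             protein = rep_len(protein, n), dye = rep_len(dye, n),
             recombined = FALSE, rec_time = NA_real_,
             growth_rate = 0)
}

# minimal experiment scaffold (no fluorescence channels, no analysis)
blankExperiment <- function(nCellsPerPos = 0L, positions = "pos1",
                            shape = c(64L, 64L)) {
  pops <- lapply(stats::setNames(positions, positions),
                 function(p) initPopulation(nCellsPerPos, shape))
  scope <- VirtualMicroscope(quietParams(shape), pops)
  state <- ExperimentState(positions = positions, channels = character(),
                           logger = scope@env$logger)
  list(state = state, scope = scope)
}

# clean-room brute-force assignment by permutation enumeration (n <= 7)
bruteForceAssignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bestCost) { bestCost <- cc; best <- p }
  }
  list(assignment = best, cost = bestCost)
}

# clean-room transition matrix of the truncated birth-death chain by
# uniformization (independent of the package's expm-based kernel)
uniformizationKernel <- function(N, birth, gamma, dt) {
  n <- N + 2L
  A <- matrix(0, n, n)
  for (s in 0:N) {
    i <- s + 1L
    if (s < N) A[i + 1L, i] <- birth else A[n, i] <- birth
    if (s > 0) A[i - 1L, i] <- gamma * s
  }
  diag(A) <- -colSums(A)
  lam <- max(-diag(A)) * 1.0001 + 1e-12
  M <- diag(n) + A / lam
  P <- diag(n)
  term <- diag(n)
  w <- exp(-lam * dt)
  out <- w * P
  for (j in 1:400) {
    term <- M %*% term
    w <- w * lam * dt / j
    out <- out + w * term
    if (w < 1e-18 && j > lam * dt) break
  }
  out
}
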
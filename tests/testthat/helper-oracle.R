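# Brute-force CJS likelihood by enumeration over latent alive/left paths.
# Conditional on being alive at `first`, a latent path is determined by the
# last occasion `a` at which the individual is still alive and present
# (a = first..n_occ); the bird leaves/dies during interval a -> a+1. This is
# deliberately a different algorithm from the chi recursion in the package.
enum_cjs_lik <- function(history, first, phi, p) {
  n_occ <- length(history)
  if (first >= n_occ) return(1)
  last <- max(which(history == 1))
  total <- 0
  for (a in first:n_occ) {
    if (a < last) next # inconsistent: detected after departure
    pr <- 1
    if (a > first) {
      for (t in (first + 1):a) {
        pr <- pr * phi[t] * (if (history[t] == 1) p[t] else 1 - p[t])
      }
    }
    if (a < n_occ) pr <- pr * (1 - phi[a + 1])
    total <- total + pr
  }
  total
}

# all detection patterns after first capture, as rows of a matrix
all_histories_after <- function(n_occ, first) {
  k <- n_occ - first
  if (k == 0) {
    h <- matrix(0L, 1, n_occ)
    h[1, first] <- 1L
    return(h)
  }
  pats <- as.matrix(expand.grid(rep(list(0:1), k)))
  out <- matrix(0L, nrow(pats), n_occ)
  out[, first] <- 1L
  out[, (first + 1):n_occ] <- as.integer(pats)
  out
}

rand_unit <- function(n) runif(n, 0.05, 0.95)
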
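# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: likelihoods by exhaustive enumeration,
# matrix exponentials by Taylor series, HDIs and signed-rank p-values by
# brute force.

dep_names <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")

random_dep_rates <- function() setNames(rexp(8) + 0.1, dep_names)

# exhaustive sum over all internal-state assignments (uniform root)
enum_loglik <- function(tree, tips, Q, root_prior = rep(0.25, 4)) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1):(n_tip + tree$Nnode)
  root <- tree$edge[nrow(tree$edge), 1]
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  tipmat <- tips[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  colnames(grid) <- as.character(internals)
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(n_tip + tree$Nnode)
    st[internals] <- grid[g, ]
    p <- root_prior[st[root]]
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      p <- p * if (ch <= n_tip) {
        sum(Pm[[e]][st[pa], ] * tipmat[ch, ])
      } else {
        Pm[[e]][st[pa], st[ch]]
      }
    }
    tot <- tot + p
  }
  log(tot)
}

# truncated Taylor series with scaling and squaring
taylor_expm <- function(Q, t, n_terms = 30, n_square = 10) {
  A <- Q * t / 2^n_square
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in seq_len(n_terms)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (s in seq_len(n_square)) P <- P %*% P
  P
}

# brute-force shortest window HDI
brute_hdi <- function(x, prob = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(s[1], s[m])
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1] - 1e-15) {
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
enum_signed_rank_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  Vs <- vapply(seq_len(2^n) - 1, function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, 0)
  p_le <- mean(Vs <= V_obs + 1e-12)
  p_ge <- mean(Vs >= V_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# per-pair shared path length by walking root-to-tip paths
path_walk_covariance <- function(tree, taxa) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1]
  anc <- integer(n_tip + tree$Nnode)
  elen <- numeric(n_tip + tree$Nnode)
  anc[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    out <- integer(0)
    while (node != root) {
      out <- c(out, node)
      node <- anc[node]
    }
    out
  }
  idx <- match(taxa, tree$tip.label)
  C <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  paths <- lapply(idx, path_to_root)
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(elen[shared])
    }
  }
  C
}

make_ctmc_dataset <- function(tree, Q, root_state = 1L, seed = 1) {
  st <- simulate_evolution(tree, Q, root_state, seed = seed)
  xy <- decode_four_state(st)
  list(taxa = tree$tip.label,
       x = setNames(xy[, "x"], tree$tip.label),
       y = setNames(xy[, "y"], tree$tip.label),
       root_state = attr(st, "root_state"), states = st)
}
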
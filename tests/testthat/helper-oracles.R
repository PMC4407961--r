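# Independent oracles and fixture builders. The oracles deliberately use a
# different code path than the implementation: root-to-tip edge walks instead
# of depth/MRCA matrices, and dense solve()/determinant() instead of Cholesky
# factorizations.

# edges (child-node ids) on the path from a tip up to the root
path_edges <- function(tree, tip) {
  n <- length(tree$tip.label)
  node <- tip
  out <- integer(0)
  repeat {
    row <- which(tree$edge[, 2] == node)
    if (length(row) == 0) break
    out <- c(out, node)
    node <- tree$edge[row, 1]
  }
  out
}

edge_len <- function(tree, child) {
  tree$edge.length[match(child, tree$edge[, 2])]
}

# shared root-to-MRCA path length of two tips, by edge-set intersection
bf_shared_length <- function(tree, i, j) {
  shared <- intersect(path_edges(tree, i), path_edges(tree, j))
  if (length(shared) == 0) 0 else sum(edge_len(tree, shared))
}

bf_depth <- function(tree, node) {
  p <- path_edges(tree, node)
  if (length(p) == 0) 0 else sum(edge_len(tree, p))
}

bf_bm_cov <- function(tree, sigma2 = 1) {
  n <- length(tree$tip.label)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- if (i == j) sigma2 * bf_depth(tree, i)
               else sigma2 * bf_shared_length(tree, i, j)
  }
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

bf_ou_cov <- function(tree, alpha, sigma2 = 1) {
  n <- length(tree$tip.label)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ti <- bf_depth(tree, i); tj <- bf_depth(tree, j)
    s <- if (i == j) ti else bf_shared_length(tree, i, j)
    V[i, j] <- sigma2 / (2 * alpha) * exp(-alpha * (ti + tj - 2 * s)) *
      (1 - exp(-2 * alpha * s))
  }
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

# multivariate normal log-density via dense solve/determinant
mvn_logl <- function(x, mu, S) {
  n <- length(x)
  r <- x - mu
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + as.numeric(t(r) %*% solve(S, r)))
}

# brute-force conditioning of one coordinate of a joint normal on the rest
bf_condition <- function(mu_joint, S_joint, idx, x_obs) {
  obs <- setdiff(seq_along(mu_joint), idx)
  Soo <- S_joint[obs, obs, drop = FALSE]
  Sno <- S_joint[idx, obs, drop = FALSE]
  w <- solve(Soo, t(Sno))
  m <- mu_joint[idx] + as.numeric(Sno %*% solve(Soo, x_obs - mu_joint[obs]))
  v <- S_joint[idx, idx] - as.numeric(Sno %*% w)
  list(mean = m, var = max(0, v))
}

# joint (node + tips) covariance under the root-conditioned model, built
# pair-by-pair from the closed-form entries
bf_joint_cov <- function(tree, node, model, alpha, sigma2) {
  n <- length(tree$tip.label)
  mrf <- ape::mrca(tree, full = TRUE)
  dep <- vapply(seq_len(n + tree$Nnode), function(k) bf_depth(tree, k),
                numeric(1))
  units <- c(node, seq_len(n))
  m <- length(units)
  S <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    ia <- units[a]; ib <- units[b]
    ta <- dep[ia]; tb <- dep[ib]
    s <- if (ia == ib) ta else dep[mrf[ia, ib]]
    S[a, b] <- if (model == "BM") sigma2 * s
               else sigma2 / (2 * alpha) * exp(-alpha * (ta + tb - 2 * s)) *
                 (1 - exp(-2 * alpha * s))
  }
  S
}

# random rooted tree with branch lengths (non-ultrametric stress case)
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.05  # keep paths clearly positive
    tr
  })
}

# small synthetic raw trait table: allometric line plus planted residuals
# orthogonalized against body length (so standardization is exactly known)
make_raw_table <- function(n = 8, seed = 1, slope = 0.15, intercept = 0.4,
                           resid_scale = 0.1) {
  withr::with_seed(seed, {
    bl <- sort(runif(n, 5, 20))
    tab <- data.frame(species = sprintf("sp%02d", seq_len(n)),
                      body_length = bl, stringsAsFactors = FALSE)
    for (tr in c("coxa2", "coxa3", "basis5", "basis7")) {
      z <- rnorm(n)
      z <- residuals(lm(z ~ bl))
      tab[[tr]] <- intercept + slope * bl + resid_scale * z
    }
    tab
  })
}

channel_traits <- c("coxa2", "coxa3", "basis5", "basis7")
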
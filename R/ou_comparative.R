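#' Read and validate a rooted phylogeny
#'
#' Parses a newick tree (file path or newick string) via \pkg{ape} and checks
#' the contract the comparative analyses rely on: a rooted topology, unique
#' tip labels, and non-negative branch lengths with every root-to-tip path of
#' positive total length. Branch lengths are taken as given, in arbitrary
#' time-proportional units.
#'
#' @param newick path to a newick file, or a newick string.
#' @return an \pkg{ape} `"phylo"` object.
#' @export
read_tree <- function(newick) {
  tree <- if (length(newick) == 1 && !grepl("\\(", newick) && file.exists(newick)) {
    ape::read.tree(newick)
  } else {
    ape::read.tree(text = paste(newick, collapse = "\n"))
  }
  if (is.null(tree)) stop("could not parse newick input", call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("branch lengths required on every edge", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  d <- node_depths(tree)
  if (any(d[seq_along(tree$tip.label)] <= 0)) {
    stop("every root-to-tip path must have positive total length",
         call. = FALSE)
  }
  tree
}

#' Drop tips without trait data
#'
#' @param tree a `"phylo"`. @param species ids to keep.
#' @return pruned tree; dropped tips are reported in a warning.
#' @export
prune_to_traits <- function(tree, species) {
  drop <- setdiff(tree$tip.label, species)
  if (length(drop) > 0) {
    warning("pruning ", length(drop), " tip(s) without trait data: ",
            paste(drop, collapse = ", "), call. = FALSE)
    tree <- ape::drop.tip(tree, drop)
  }
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    stop("species missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tree
}

# Depth (total branch length from the root) of every tip and internal node.
node_depths <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  d <- numeric(length(tree$tip.label) + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    d[tree$edge[e, 2]] <- d[tree$edge[e, 1]] + tree$edge.length[e]
  }
  d
}

# Shared-depth matrix among tips: entry (i, j) is the depth of MRCA(i, j).
shared_depths <- function(tree) {
  d <- node_depths(tree)
  mr <- ape::mrca(tree)
  s <- matrix(d[mr], nrow = nrow(mr), dimnames = dimnames(mr))
  s
}

#' Brownian-motion covariance among the tips of a tree
#'
#' Under Brownian motion with rate `sigma2` started at the root, the trait
#' covariance of two tips equals `sigma2` times the length of their shared
#' root-to-MRCA path; a tip's variance is `sigma2` times its depth.
#'
#' @param tree a rooted `"phylo"` with branch lengths.
#' @param sigma2 evolutionary rate (trait units squared per unit branch
#'   length).
#' @return a symmetric matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree, sigma2 = 1) {
  validate_tree(tree)
  sigma2 * shared_depths(tree)
}

#' Ornstein-Uhlenbeck covariance among the tips of a tree
#'
#' Root-conditioned OU process (the root fixed at the optimum): for tips
#' `i, j` with depths `t_i, t_j` and shared depth `s`,
#' `cov = sigma2/(2 alpha) * exp(-alpha (t_i + t_j - 2 s)) * (1 - exp(-2 alpha s))`.
#' Brownian motion is the exact `alpha -> 0` limit, so BM and OU fits are
#' nested and AIC-comparable.
#'
#' @param tree a rooted `"phylo"` with branch lengths.
#' @param alpha restraining force (> 0; per unit branch length).
#' @param sigma2 evolutionary rate.
#' @return a symmetric matrix with tip labels as dimnames.
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1) {
  validate_tree(tree)
  if (!(alpha > 0)) stop("alpha must be > 0; use bm_covariance for alpha = 0",
                         call. = FALSE)
  s <- shared_depths(tree)
  t_tip <- diag(s)
  tsum <- outer(t_tip, t_tip, `+`)
  sigma2 / (2 * alpha) * exp(-alpha * (tsum - 2 * s)) * (1 - exp(-2 * alpha * s))
}

# Gaussian profile likelihood given a unit-rate covariance structure V0:
# root state by GLS, sigma2 in closed form, log-likelihood of the tip data.
profile_loglik <- function(V0, x) {
  n <- length(x)
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) {
    s <- V0
    pat <- outer(diag(s), diag(s), pmin) - s  # zero where tips coincide
    bad <- which(pat < 1e-12 & upper.tri(pat), arr.ind = TRUE)
    labs <- if (nrow(bad) > 0 && !is.null(rownames(s))) {
      paste(rownames(s)[bad[, 1]], rownames(s)[bad[, 2]], sep = "/",
            collapse = ", ")
    } else "unknown"
    stop("singular covariance (tips at zero patristic distance: ", labs, ")",
         call. = FALSE)
  }
  logdet <- 2 * sum(log(diag(R)))
  # solve V0^{-1} applied to x and to the ones vector via triangular solves
  zx <- backsolve(R, x, transpose = TRUE)
  z1 <- backsolve(R, rep(1, n), transpose = TRUE)
  a <- sum(z1 * z1)
  b <- sum(z1 * zx)
  mu <- b / a
  zr <- zx - mu * z1
  q <- sum(zr * zr)
  sigma2 <- q / n
  ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(logL = ll, root_state = mu, sigma2 = sigma2)
}

#' Fit a Brownian-motion or Ornstein-Uhlenbeck model to tip traits
#'
#' Maximum-likelihood fit of a single trait on a rooted phylogeny. Under BM,
#' the root state is the generalized-least-squares mean and `sigma2` has a
#' closed form (2 free parameters). Under OU, the likelihood is profiled over
#' `alpha` on a log-spaced grid spanning `[1e-6, 1e2]` followed by bounded
#' golden-section refinement; `root_state` and `sigma2` are profiled
#' analytically at each `alpha` (3 free parameters). The deterministic grid
#' guards against the characteristically flat profile likelihood in `alpha`.
#'
#' @param tree a rooted `"phylo"`.
#' @param traits numeric vector named by tip label (every tip must be
#'   present).
#' @param model `"BM"` or `"OU"`.
#' @param alpha_bounds search range for the OU restraining force.
#' @return object of class `"trait_model_fit"`: list with `model`, `sigma2`,
#'   `alpha` (0 for BM), `root_state`, `logL`, `k`, `aic`, `n`.
#' @export
fit_model <- function(tree, traits, model = c("BM", "OU"),
                      alpha_bounds = c(1e-6, 1e2)) {
  model <- match.arg(model)
  validate_tree(tree)
  if (is.null(names(traits))) stop("traits must be named by tip label",
                                   call. = FALSE)
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing) > 0) {
    stop("no trait value for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.numeric(traits[tree$tip.label])
  # shared-depth geometry computed once; the alpha profile search only
  # re-evaluates the closed-form covariance entries
  s <- shared_depths(tree)
  t_tip <- diag(s)
  tsum <- outer(t_tip, t_tip, `+`)
  ou_v0 <- function(a) {
    1 / (2 * a) * exp(-a * (tsum - 2 * s)) * (1 - exp(-2 * a * s))
  }
  if (model == "BM") {
    pf <- profile_loglik(s, x)
    k <- 2L
    out <- list(model = "BM", sigma2 = pf$sigma2, alpha = 0,
                root_state = pf$root_state, logL = pf$logL, k = k,
                aic = -2 * pf$logL + 2 * k, n = length(x))
  } else {
    nll <- function(log_alpha) {
      -profile_loglik(ou_v0(exp(log_alpha)), x)$logL
    }
    grid <- seq(log(alpha_bounds[1]), log(alpha_bounds[2]), length.out = 41)
    vals <- vapply(grid, nll, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(nll, interval = c(lo, hi), tol = 1e-10)
    best_la <- if (opt$objective <= vals[i]) opt$minimum else grid[i]
    alpha_hat <- exp(best_la)
    pf <- profile_loglik(ou_v0(alpha_hat), x)
    k <- 3L
    out <- list(model = "OU", sigma2 = pf$sigma2, alpha = alpha_hat,
                root_state = pf$root_state, logL = pf$logL,
                k = k, aic = -2 * pf$logL + 2 * k, n = length(x))
  }
  structure(out, class = "trait_model_fit")
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: sigma2 = %.4g, alpha = %.4g, root = %.4g, logL = %.3f, AIC = %.3f (n = %d tips)\n",
              x$model, x$sigma2, x$alpha, x$root_state, x$logL, x$aic, x$n))
  invisible(x)
}

#' Select among fitted trait-evolution models by AIC
#'
#' Returns the minimum-AIC fit; exact ties are broken toward the model with
#' fewer parameters (so BM wins a BM/OU tie).
#'
#' @param fits list of `"trait_model_fit"` objects for the same data.
#' @return the selected `"trait_model_fit"`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  best <- which(aics == min(aics))
  if (length(best) > 1) best <- best[which.min(ks[best])]
  fits[[best]]
}

#' Reconstruct the ancestral trait value at the MRCA of a species pair
#'
#' Estimates the trait at the most recent common ancestor of two tips as the
#' conditional expectation of that node's state given all tip values under
#' the fitted model: the node is treated as an additional point at its depth
#' in the joint multivariate normal implied by the BM or OU covariance rules,
#' and conditioned on the tips. The standard error is the square root of the
#' conditional variance; `lower`/`upper` are `mean -/+ se`, the three
#' reconstruction variants carried through the downstream pair tests.
#'
#' @param tree a rooted `"phylo"`. @param traits named tip values.
#' @param fit a `"trait_model_fit"` for these traits.
#' @param pair character vector of two tip labels.
#' @return object of class `"ancestral_estimate"`: list with `node`, `pair`,
#'   `mean`, `se`, `lower`, `upper`, `model`.
#' @export
reconstruct_ancestor <- function(tree, traits, fit, pair) {
  validate_tree(tree)
  stopifnot(inherits(fit, "trait_model_fit"), length(pair) == 2)
  if (!all(pair %in% tree$tip.label)) {
    stop("pair members must be tips of the tree: ",
         paste(setdiff(pair, tree$tip.label), collapse = ", "), call. = FALSE)
  }
  x <- as.numeric(traits[tree$tip.label])
  if (anyNA(x)) stop("every tip needs a trait value", call. = FALSE)
  n <- length(tree$tip.label)
  node <- ape::getMRCA(tree, pair)
  root <- n + 1L
  if (node == root) {
    warning("MRCA of the pair is the root; reconstruction accuracy decreases ",
            "toward the base of the tree", call. = FALSE)
  }
  d <- node_depths(tree)
  mr_full <- ape::mrca(tree, full = TRUE)
  t_node <- d[node]
  t_tip <- d[seq_len(n)]
  s_nt <- d[mr_full[node, seq_len(n)]]  # shared depth of the node with each tip
  if (fit$model == "BM") {
    V <- bm_covariance(tree, fit$sigma2)
    c_nt <- fit$sigma2 * s_nt
    v_node <- fit$sigma2 * t_node
  } else {
    V <- ou_covariance(tree, fit$alpha, fit$sigma2)
    a <- fit$alpha
    c_nt <- fit$sigma2 / (2 * a) * exp(-a * (t_node + t_tip - 2 * s_nt)) *
      (1 - exp(-2 * a * s_nt))
    v_node <- fit$sigma2 / (2 * a) * (1 - exp(-2 * a * t_node))
  }
  mu <- fit$root_state
  if (t_node == 0) {
    # MRCA at the root: its state is the (fixed) root state with no variance
    w <- rep(0, n)
    cond_mean <- mu
    cond_var <- 0
  } else {
    R <- chol(V)
    zc <- backsolve(R, c_nt, transpose = TRUE)
    zx <- backsolve(R, x - mu, transpose = TRUE)
    cond_mean <- mu + sum(zc * zx)
    cond_var <- max(0, v_node - sum(zc * zc))
  }
  se <- sqrt(cond_var)
  structure(list(node = node, pair = pair, mean = cond_mean, se = se,
                 lower = cond_mean - se, upper = cond_mean + se,
                 model = fit$model),
            class = "ancestral_estimate")
}

#' @export
print.ancestral_estimate <- function(x, ...) {
  cat(sprintf("Ancestral state at node %d (MRCA of %s, %s; %s model): %.4g +/- %.4g [%.4g, %.4g]\n",
              x$node, x$pair[1], x$pair[2], x$model, x$mean, x$se,
              x$lower, x$upper))
  invisible(x)
}

# Variant-v trait vector of a species from its per-coordinate ancestral
# estimates: v in {"lower", "mean", "upper"}, applied coordinate-wise.
ancestral_vector <- function(estimates, variant) {
  vapply(estimates, `[[`, numeric(1), variant)
}

#' Extant-vs-ancestral divergence factors for a species pair
#'
#' Compares the extant Euclidean distance of a coexisting pair with the
#' distance between their reconstructed ancestors, for each of the three
#' reconstruction variants (lower, mean, upper, applied coordinate-wise and
#' species-wise). The divergence factor is extant distance / ancestral
#' distance; a factor > 1 means the pair diverged since the ancestors.
#'
#' @param extant_distance observed extant Euclidean distance.
#' @param ancestral either a named numeric vector of ancestral distances
#'   `c(lower = , mean = , upper = )` (e.g. transcribed from a published
#'   table), or a list with elements `a` and `b`, each a list of
#'   `"ancestral_estimate"` objects (one per trait coordinate) for the two
#'   species.
#' @param trait_set `"body_size"` or `"channel"` (used when computing
#'   ancestral distances from estimates).
#' @return data.frame with rows `lower`, `mean`, `upper`: columns `variant`,
#'   `ancestral_distance`, `factor` (NA where the ancestral distance is 0).
#' @export
divergence_report <- function(extant_distance, ancestral,
                              trait_set = c("channel", "body_size")) {
  trait_set <- match.arg(trait_set)
  stopifnot(extant_distance >= 0)
  variants <- c("lower", "mean", "upper")
  if (is.numeric(ancestral)) {
    if (!all(variants %in% names(ancestral))) {
      stop("ancestral distances must be named lower/mean/upper", call. = FALSE)
    }
    anc_d <- ancestral[variants]
  } else {
    stopifnot(is.list(ancestral), all(c("a", "b") %in% names(ancestral)))
    anc_d <- vapply(variants, function(v) {
      euclidean_distance(ancestral_vector(ancestral$a, v),
                         ancestral_vector(ancestral$b, v), trait_set)
    }, numeric(1))
  }
  if (any(anc_d < 0)) stop("ancestral distances must be >= 0", call. = FALSE)
  fac <- ifelse(anc_d > 0, extant_distance / anc_d, NA_real_)
  data.frame(variant = variants,
             ancestral_distance = as.numeric(anc_d),
             factor = as.numeric(fac),
             row.names = NULL, stringsAsFactors = FALSE)
}
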
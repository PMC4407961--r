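test_that("read_tree parses, validates, and round-trips", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  dep <- diag(bm_covariance(tr, 1))
  expect_equal(unname(dep[c("A", "B", "C")]), c(2, 2, 2))
  expect_error(read_tree("((A,B),C);"), "branch lengths")
  expect_error(read_tree("((A:1,A:1):1,C:2);"), "duplicate")
  # 44-tip synthetic tree round-trips through write/read
  big <- simulate_tree(44, birth_rate = 1, seed = 17)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(big, path)
  back <- read_tree(path)
  expect_equal(sort(back$tip.label), sort(big$tip.label))
  expect_equal(sum(back$edge.length), sum(big$edge.length), tolerance = 1e-8)
})

test_that("BM covariance equals brute-force shared path lengths", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  V <- bm_covariance(tr, sigma2 = 1)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["A", "A"], 2)
  # star tree: no shared history off the diagonal
  star <- read_tree("(A:1,B:1,C:1,D:1);")
  Vs <- bm_covariance(star, 2)
  expect_true(all(Vs[upper.tri(Vs)] == 0))
  expect_equal(unname(diag(Vs)), rep(2, 4))
  # random trees against the edge-walk oracle and ape's own BM vcv
  for (seed in 1:6) {
    tr <- random_tree(withr::with_seed(seed, sample(4:10, 1)), seed)
    s2 <- withr::with_seed(seed + 100, runif(1, 0.2, 3))
    expect_equal(bm_covariance(tr, s2), bf_bm_cov(tr, s2), tolerance = 1e-10)
    V_ape <- s2 * ape::vcv.phylo(tr)
    expect_equal(bm_covariance(tr, s2)[rownames(V_ape), colnames(V_ape)],
                 V_ape, tolerance = 1e-10)
  }
})

test_that("OU covariance matches the closed form and nests BM", {
  # single-branch variance: sigma2/(2 alpha) (1 - exp(-2 alpha t))
  two <- read_tree("(A:1.5,B:1.5);")
  V <- ou_covariance(two, alpha = 0.7, sigma2 = 2)
  expect_equal(V["A", "A"], 2 / (2 * 0.7) * (1 - exp(-2 * 0.7 * 1.5)),
               tolerance = 1e-12)
  expect_equal(V["A", "B"], 0)  # lineages split at the root
  expect_error(ou_covariance(two, alpha = 0), "alpha")
  for (seed in 1:6) {
    tr <- random_tree(withr::with_seed(seed + 7, sample(4:10, 1)), seed + 7)
    a <- withr::with_seed(seed + 200, runif(1, 0.05, 2))
    s2 <- withr::with_seed(seed + 300, runif(1, 0.2, 3))
    expect_equal(ou_covariance(tr, a, s2), bf_ou_cov(tr, a, s2),
                 tolerance = 1e-10)
    # entrywise convergence to BM as alpha -> 0
    expect_equal(ou_covariance(tr, 1e-8, s2), bm_covariance(tr, s2),
                 tolerance = 1e-5)
  }
})

test_that("fit_model maximizes a likelihood that matches the density oracle", {
  # symmetric two-tip tree: BM root state is the tip average
  two <- read_tree("(A:1,B:1);")
  fit2 <- fit_model(two, c(A = 0, B = 2), "BM")
  expect_equal(fit2$root_state, 1, tolerance = 1e-10)
  expect_equal(fit2$aic, -2 * fit2$logL + 4)

  for (seed in 1:4) {
    tr <- random_tree(8, seed + 40)
    x <- simulate_traits(tr, "BM", list(sigma2 = 1.3, root_state = 2),
                         seed = seed + 50)
    bm <- fit_model(tr, x, "BM")
    ou <- fit_model(tr, x, "OU")
    # logL equals the direct multivariate normal density at the fitted
    # parameters (dense solve/determinant oracle)
    expect_equal(bm$logL,
                 mvn_logl(x[tr$tip.label], bm$root_state,
                          bm_covariance(tr, bm$sigma2)), tolerance = 1e-8)
    expect_equal(ou$logL,
                 mvn_logl(x[tr$tip.label], ou$root_state,
                          ou_covariance(tr, ou$alpha, ou$sigma2)),
                 tolerance = 1e-8)
    expect_equal(ou$aic, -2 * ou$logL + 6)
    # OU nests BM; at the bounded alpha search floor the OU likelihood can
    # trail the BM one by O(alpha_min * depth)
    expect_gte(ou$logL, bm$logL - 1e-4)
  }
})

test_that("duplicate zero-length tips are reported as singular", {
  tr <- read_tree("((A:0,B:0):1,C:2);")
  expect_error(fit_model(tr, c(A = 1, B = 2, C = 3), "BM"),
               "singular covariance.*A/B")
})

test_that("select_model picks minimum AIC with ties to fewer parameters", {
  f1 <- structure(list(model = "OU", aic = 10, k = 3), class = "trait_model_fit")
  f2 <- structure(list(model = "BM", aic = 12, k = 2), class = "trait_model_fit")
  expect_equal(select_model(list(f1, f2))$model, "OU")
  f3 <- structure(list(model = "BM", aic = 10, k = 2), class = "trait_model_fit")
  expect_equal(select_model(list(f1, f3))$model, "BM")
})

test_that("ancestral reconstruction equals brute-force joint conditioning", {
  # symmetric cherry under BM: the MRCA estimate is the tip average
  two <- read_tree("((A:1,B:1):0.5,C:1.5);")
  fit <- fit_model(two, c(A = 0, B = 2, C = 1), "BM")
  est <- reconstruct_ancestor(two, c(A = 0, B = 2, C = 1), fit, c("A", "B"))
  joint <- bf_joint_cov(two, est$node, "BM", 0, fit$sigma2)
  cond <- bf_condition(rep(fit$root_state, 4), joint, 1, c(0, 2, 1))
  expect_equal(est$mean, cond$mean, tolerance = 1e-10)
  expect_equal(est$se, sqrt(cond$var), tolerance = 1e-10)
  expect_equal(est$lower, est$mean - est$se)
  expect_equal(est$upper, est$mean + est$se)

  for (seed in 1:4) {
    tr <- random_tree(10, seed + 60)
    x <- simulate_traits(tr, "OU", list(sigma2 = 1, alpha = 0.8,
                                        root_state = 0), seed = seed + 70)
    for (model in c("BM", "OU")) {
      fit <- fit_model(tr, x, model)
      pair <- withr::with_seed(seed, sample(tr$tip.label, 2))
      est <- suppressWarnings(reconstruct_ancestor(tr, x, fit, pair))
      if (est$node == length(tr$tip.label) + 1) next  # root handled below
      joint <- bf_joint_cov(tr, est$node, model, fit$alpha, fit$sigma2)
      cond <- bf_condition(rep(fit$root_state, 11), joint, 1,
                           unname(x[tr$tip.label]))
      expect_equal(est$mean, cond$mean, tolerance = 1e-8)
      expect_equal(est$se, sqrt(cond$var), tolerance = 1e-8)
    }
  }
})

test_that("degenerate and boundary reconstructions behave sensibly", {
  # a tip attached to the MRCA by a zero-length branch pins the estimate
  tr <- read_tree("((A:0.0,B:1):1,C:2);")
  x <- c(A = 0.7, B = 2, C = 1)
  fit <- fit_model(tr, x, "BM")
  est <- reconstruct_ancestor(tr, x, fit, c("A", "B"))
  expect_equal(est$mean, 0.7, tolerance = 1e-9)
  expect_equal(est$se, 0, tolerance = 1e-9)
  # MRCA at the root: warns, and the state is the (conditioned) root state
  expect_warning(
    root_est <- reconstruct_ancestor(tr, x, fit, c("A", "C")),
    "root")
  expect_equal(root_est$mean, fit$root_state)
  expect_equal(root_est$se, 0)
})

test_that("BM reconstruction weights are affine in the tip data", {
  # conditional mean under BM is a weighted tip average with weights summing
  # to 1: shifting every tip by a constant shifts the estimate by the same
  tr <- random_tree(9, 91)
  x <- simulate_traits(tr, "BM", list(sigma2 = 1, root_state = 0), seed = 92)
  fit <- fit_model(tr, x, "BM")
  pair <- c(tr$tip.label[1], tr$tip.label[4])
  est <- reconstruct_ancestor(tr, x, fit, pair)
  shift <- 3.7
  fit_s <- fit
  fit_s$root_state <- fit$root_state + shift  # GLS mean is equivariant
  est_s <- reconstruct_ancestor(tr, x + shift, fit_s, pair)
  expect_equal(est_s$mean, est$mean + shift, tolerance = 1e-8)
  expect_equal(est_s$se, est$se, tolerance = 1e-10)
})

test_that("conditional uncertainty is bounded by the prior and by the data", {
  # the conditional SE at a node never exceeds the node's prior SD under the
  # fitted model, vanishes where the node is pinned by a zero-length tip,
  # and is zero at the conditioned root
  tr <- simulate_tree(12, 1, seed = 123)
  x <- simulate_traits(tr, "BM", list(sigma2 = 1, root_state = 0), seed = 124)
  fit <- fit_model(tr, x, "BM")
  dep_all <- ape::node.depth.edgelength(tr)
  for (i in c(1, 4, 8)) {
    tip <- tr$tip.label[i]
    pair <- c(tip, setdiff(tr$tip.label, tip)[1])
    est <- suppressWarnings(reconstruct_ancestor(tr, x, fit, pair))
    prior_sd <- sqrt(fit$sigma2 * dep_all[est$node])
    expect_lte(est$se, prior_sd + 1e-10)
  }
})

test_that("pruning uninformative tips preserves the remaining covariance", {
  tr <- random_tree(10, 140)
  # keep tips on both sides of the root so pruning cannot relocate it (a
  # relocated root legitimately drops the stem segment shared by all
  # remaining tips)
  root_kids <- tr$edge[tr$edge[, 1] == length(tr$tip.label) + 1, 2]
  clade_tips <- lapply(root_kids, function(k) {
    if (k <= length(tr$tip.label)) tr$tip.label[k]
    else ape::extract.clade(tr, k)$tip.label
  })
  keep <- unlist(lapply(clade_tips, function(tl) tl[seq_len(min(3, length(tl)))]))
  pruned <- suppressWarnings(prune_to_traits(tr, keep))
  V_full <- bm_covariance(tr, 1.7)
  V_sub <- bm_covariance(pruned, 1.7)
  expect_equal(V_sub[keep, keep], V_full[keep, keep], tolerance = 1e-10)
  # hence the marginal likelihood of the kept tips is unchanged at fixed
  # parameters
  x <- simulate_traits(tr, "BM", list(sigma2 = 1.7, root_state = 0), seed = 9)
  expect_equal(mvn_logl(x[keep], 0, V_sub[keep, keep]),
               mvn_logl(x[keep], 0, V_full[keep, keep]), tolerance = 1e-10)
})

test_that("divergence factors are extant over ancestral, per variant", {
  rep1 <- divergence_report(3.0, c(lower = 3.0, mean = 1.5, upper = 0.5))
  expect_equal(rep1$factor, c(1.0, 2.0, 6.0))
  # zero ancestral distance: the factor is undefined, not infinite
  rep0 <- divergence_report(2.0, c(lower = 0, mean = 1, upper = 2))
  expect_true(is.na(rep0$factor[1]))
  expect_equal(rep0$factor[2:3], c(2, 1))
  # estimate-based route agrees with the distance-based route
  mk <- function(m, s) structure(list(mean = m, se = s, lower = m - s,
                                      upper = m + s), class = "ancestral_estimate")
  a <- list(mk(1, 0.1), mk(0, 0.2), mk(2, 0.1), mk(1, 0.3))
  b <- list(mk(0, 0.2), mk(1, 0.1), mk(1, 0.2), mk(0, 0.1))
  repE <- divergence_report(4, list(a = a, b = b), trait_set = "channel")
  for (i in seq_along(repE$variant)) {
    v <- repE$variant[i]
    va <- vapply(a, `[[`, numeric(1), v)
    vb <- vapply(b, `[[`, numeric(1), v)
    expect_equal(repE$ancestral_distance[i], sqrt(sum((va - vb)^2)),
                 tolerance = 1e-12)
    expect_equal(repE$factor[i], 4 / repE$ancestral_distance[i],
                 tolerance = 1e-12)
  }
})
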
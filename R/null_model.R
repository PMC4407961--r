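#' Read a regional-pool membership file
#'
#' One species id per line; blank lines and `#` comments ignored. Every id
#' must be present in the trait table, and focal species must not be pool
#' members (the pool defines the null expectation the focal pair is tested
#' against).
#'
#' @param path pool file path.
#' @param trait_table trait table the ids must belong to (optional check).
#' @param focal character vector of focal species ids that must be absent.
#' @return character vector of pool member ids.
#' @export
read_pool_file <- function(path, trait_table = NULL, focal = character()) {
  if (!file.exists(path)) stop("pool file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- trimws(lines)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    stop("duplicate species in pool file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(trait_table)) {
    unknown <- setdiff(ids, trait_table$species)
    if (length(unknown) > 0) {
      stop("pool species absent from trait table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  bad <- intersect(ids, focal)
  if (length(bad) > 0) {
    stop("focal species may not be members of the regional pool: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ids
}

#' Per-trait ranges of a regional pool
#'
#' Coordinate-wise minimum and maximum over the pool members, for body size
#' (mm) and each of the four standardized ventral-channel coordinates. These
#' ranges bound the virtual species simulated by the null model.
#'
#' @param pool_members profiles data.frame (or `"std_profiles"`) restricted to
#'   the pool.
#' @return 2 x 5 matrix with rows `min`, `max` and columns
#'   `body_size, coxa2, coxa3, basis5, basis7`.
#' @export
trait_ranges <- function(pool_members) {
  if (inherits(pool_members, "std_profiles")) pool_members <- pool_members$profiles
  if (is.null(nrow(pool_members)) || nrow(pool_members) < 2) {
    stop("pool must contain >= 2 members", call. = FALSE)
  }
  m <- as.matrix(pool_members[, ALL_TRAITS, drop = FALSE])
  rbind(min = apply(m, 2, min), max = apply(m, 2, max))
}

#' Simulate a virtual regional pool
#'
#' Draws `n` virtual species, each defined by the five traits, every
#' coordinate independently uniform between the pool's observed minimum and
#' maximum for that trait. A trait whose range has zero width yields a
#' constant coordinate (with a warning).
#'
#' @param ranges 2 x k matrix from [trait_ranges()].
#' @param n number of virtual species (default 100).
#' @param seed integer seed; the draw is reproducible and does not disturb the
#'   global RNG state.
#' @return object of class `"virtual_pool"`: an `n x k` matrix with trait
#'   columns, attributes `seed` and `ranges`.
#' @export
simulate_virtual_pool <- function(ranges, n = 100, seed) {
  stopifnot(is.matrix(ranges), nrow(ranges) == 2)
  if (any(ranges["max", ] < ranges["min", ])) {
    stop("invalid ranges: max < min", call. = FALSE)
  }
  if (n < 2) stop("virtual pool needs n >= 2", call. = FALSE)
  if (any(ranges["max", ] == ranges["min", ])) {
    warning("zero-width range for trait(s) ",
            paste(colnames(ranges)[ranges["max", ] == ranges["min", ]],
                  collapse = ", "),
            "; virtual species are constant in those traits", call. = FALSE)
  }
  k <- ncol(ranges)
  sp <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(n * k), nrow = n, ncol = k)
  })
  sp <- sweep(sp, 2, ranges["max", ] - ranges["min", ], `*`)
  sp <- sweep(sp, 2, ranges["min", ], `+`)
  colnames(sp) <- colnames(ranges)
  structure(sp, class = c("virtual_pool", "matrix"),
            seed = as.integer(seed), ranges = ranges)
}

#' Null distribution of pairwise distances among virtual species
#'
#' Draws `n_pairs` unordered pairs of distinct virtual species (a species may
#' recur across pairs) and records their Euclidean distances for the chosen
#' trait set. The resulting distribution is the null model against which an
#' observed focal-pair distance is tested.
#'
#' @param pool a `"virtual_pool"`.
#' @param trait_set `"body_size"` or `"channel"`.
#' @param n_pairs number of pairs (default 1000).
#' @param seed integer seed.
#' @return object of class `"null_distribution"`: numeric distance vector with
#'   attributes `trait_set`, `n_pairs`, `seed`.
#' @export
sample_null_distances <- function(pool, trait_set = c("body_size", "channel"),
                                  n_pairs = 1000, seed) {
  trait_set <- match.arg(trait_set)
  n <- nrow(pool)
  if (n < 2) stop("virtual pool must contain >= 2 species", call. = FALSE)
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  idx <- withr::with_seed(as.integer(seed), {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # j uniform on the n-1 others
    cbind(i, j)
  })
  cols <- if (trait_set == "body_size") "body_size" else CHANNEL_TRAITS
  diffs <- pool[idx[, 1], cols, drop = FALSE] - pool[idx[, 2], cols, drop = FALSE]
  d <- sqrt(rowSums(diffs^2))
  structure(as.numeric(d), class = "null_distribution",
            trait_set = trait_set, n_pairs = n_pairs, seed = as.integer(seed))
}

#' Empirical p-value of an observed distance against a null distribution
#'
#' One-sided empirical probabilities with the add-one correction
#' `(r + 1) / (n + 1)`, so p is never exactly zero: `side = "similarity"`
#' counts null distances less than or equal to the observed one (are the two
#' species unusually similar?), `side = "difference"` counts those greater or
#' equal (unusually different?). Ties contribute to both sides, so
#' `p_similarity + p_difference >= 1`.
#'
#' @param observed observed distance (scalar, >= 0).
#' @param null a `"null_distribution"` or numeric vector of null distances.
#' @param side `"similarity"` or `"difference"`.
#' @return scalar probability in (0, 1]; attribute `at_bound` is TRUE when no
#'   null distance was as extreme as the observation (the "p < 1/n" case).
#' @export
empirical_p <- function(observed, null, side = c("similarity", "difference")) {
  side <- match.arg(side)
  null <- as.numeric(null)
  if (length(null) == 0) stop("empty null distribution", call. = FALSE)
  stopifnot(length(observed) == 1, observed >= 0)
  r <- if (side == "similarity") sum(null <= observed) else sum(null >= observed)
  p <- (r + 1) / (length(null) + 1)
  attr(p, "at_bound") <- r == 0
  p
}

#' Classify the eco-evolutionary process for a species pair
#'
#' Decision rule on the two one-sided empirical p-values: a significantly
#' larger-than-null distance indicates competition-driven divergence, a
#' significantly smaller one environmental filtering, otherwise the pair is
#' indistinguishable from a random draw.
#'
#' @param p_similarity,p_difference one-sided p-values from [empirical_p()].
#' @param alpha significance level (default 0.05).
#' @return character scalar `"competition"`, `"filtering"` or `"random"`,
#'   with attribute `p` = min(p_similarity, p_difference).
#' @export
classify_pair <- function(p_similarity, p_difference, alpha = 0.05) {
  stopifnot(p_similarity > 0, p_similarity <= 1,
            p_difference > 0, p_difference <= 1,
            alpha > 0, alpha < 1)
  if (alpha < 0.5 && p_similarity <= alpha && p_difference <= alpha) {
    stop("both one-sided p-values <= alpha: impossible under the ",
         "tie-sharing construction; null distribution is corrupt",
         call. = FALSE)
  }
  process <- if (p_difference <= alpha) "competition"
             else if (p_similarity <= alpha) "filtering"
             else "random"
  structure(process, p = min(p_similarity, p_difference))
}

#' Test one focal species pair against a null distribution
#'
#' Convenience wrapper: computes the observed distance, both one-sided
#' empirical p-values, and the process classification.
#'
#' @param a,b trait vectors or single profile rows (see
#'   [euclidean_distance()]).
#' @param null a `"null_distribution"` for the same trait set.
#' @param trait_set `"body_size"` or `"channel"`.
#' @param alpha significance level.
#' @return one-row data.frame: `trait_set`, `observed`, `p_similarity`,
#'   `p_difference`, `p` (the reported side), `p_label` (presentation form,
#'   e.g. `"p < 0.001"` when the observation beats every null draw),
#'   `process`.
#' @export
test_pair <- function(a, b, null, trait_set = c("body_size", "channel"),
                      alpha = 0.05) {
  trait_set <- match.arg(trait_set)
  obs <- euclidean_distance(a, b, trait_set)
  ps <- empirical_p(obs, null, "similarity")
  pd <- empirical_p(obs, null, "difference")
  proc <- classify_pair(as.numeric(ps), as.numeric(pd), alpha)
  winner <- if (as.numeric(pd) <= as.numeric(ps)) pd else ps
  data.frame(trait_set = trait_set, observed = obs,
             p_similarity = as.numeric(ps), p_difference = as.numeric(pd),
             p = as.numeric(winner),
             p_label = format_p(winner, length(as.numeric(null))),
             process = as.character(proc), stringsAsFactors = FALSE)
}

#' Presentation form of an empirical p-value
#'
#' When the observed value lies beyond every null draw, the add-one p-value
#' `1/(n+1)` is a bound rather than an estimate and is printed as
#' `"p < 1/n"` (e.g. `"p < 0.001"` for 1000 null pairs); otherwise the
#' numeric value is printed.
#'
#' @param p p-value carrying the `at_bound` attribute from [empirical_p()].
#' @param n_null size of the null distribution.
#' @return character scalar.
#' @export
format_p <- function(p, n_null) {
  if (isTRUE(attr(p, "at_bound"))) {
    sprintf("p < %s", format(1 / n_null, digits = 3))
  } else {
    sprintf("p = %s", format(as.numeric(p), digits = 3))
  }
}
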
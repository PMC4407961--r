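#' Build and validate an analysis configuration
#'
#' @param traits path to the trait CSV (see [read_trait_table()]).
#' @param tree path to the newick tree.
#' @param pools named list or vector mapping `region_id` to a pool membership
#'   file.
#' @param pairs path to the focal-pair CSV
#'   (`pair_id,species_a,species_b,region_id`, optional `sister_a,sister_b`).
#' @param n_virtual virtual species per simulated regional pool (default
#'   100). @param n_pairs null pairs per distribution (default 1000).
#' @param alpha_level significance level (default 0.05).
#' @param model `"BM"`, `"OU"` or `"auto"` (AIC selection per trait).
#' @param seed integer master seed; every stochastic stage derives its own
#'   sub-seed from it, so the virtual pool is unchanged when, say, `n_pairs`
#'   changes.
#' @param standardization_scope `"per_region"` (allometric regression fitted
#'   on each region's pool plus its focal species) or `"global"` (one
#'   regression across the whole trait table).
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(traits, tree, pools, pairs,
                            n_virtual = 100, n_pairs = 1000,
                            alpha_level = 0.05,
                            model = c("auto", "BM", "OU"), seed = 1,
                            standardization_scope = c("per_region", "global")) {
  model <- match.arg(model)
  standardization_scope <- match.arg(standardization_scope)
  stopifnot(n_virtual >= 2, n_pairs >= 1,
            alpha_level > 0, alpha_level < 1)
  pools <- as.list(pools)
  if (is.null(names(pools)) || any(!nzchar(names(pools)))) {
    stop("pools must be named by region_id", call. = FALSE)
  }
  for (p in c(traits, tree, unlist(pools), pairs)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  structure(list(traits = traits, tree = tree, pools = pools, pairs = pairs,
                 n_virtual = as.integer(n_virtual),
                 n_pairs = as.integer(n_pairs),
                 alpha_level = alpha_level, model = model,
                 seed = as.integer(seed),
                 standardization_scope = standardization_scope),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with the [analysis_config()] fields; relative input
#'   paths are resolved against the YAML file's directory.
#' @return an `"analysis_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  y$traits <- resolve(y$traits)
  y$tree <- resolve(y$tree)
  y$pools <- lapply(y$pools, resolve)
  y$pairs <- resolve(y$pairs)
  do.call(analysis_config, y)
}

# First-level sister tip of a given tip: an arbitrary tip from the sibling
# clade, so that MRCA(tip, sister) is the tip's parent node.
sister_tip <- function(tree, tip) {
  it <- match(tip, tree$tip.label)
  if (is.na(it)) stop("tip not in tree: ", tip, call. = FALSE)
  parent <- tree$edge[tree$edge[, 2] == it, 1]
  kids <- tree$edge[tree$edge[, 1] == parent, 2]
  other <- kids[kids != it][1]
  if (other <= length(tree$tip.label)) {
    tree$tip.label[other]
  } else {
    ape::extract.clade(tree, other)$tip.label[1]
  }
}

#' Run the full eco-evolutionary pair analysis
#'
#' Stage order: load and validate inputs; standardize traits; build the
#' virtual-species null distributions per region and trait set; test the
#' extant focal pairs; fit BM/OU per trait coordinate (AIC selection when
#' `model = "auto"`); reconstruct ancestral states at the first-level MRCA of
#' each focal species and its sister lineage; test the ancestral pairs
#' (lower/mean/upper reconstruction variants) against the same nulls; compute
#' divergence factors and normalized distances.
#'
#' @param config an `"analysis_config"` (or YAML path).
#' @return object of class `"nichepair_report"`: list with `table` (one row
#'   per region x trait set x {extant, ancestral-lower, ancestral-mean,
#'   ancestral-upper}), `model_fits` (per region x trait coordinate), and
#'   `provenance` (config echo, sub-seeds, package version).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))
  traits <- read_trait_table(config$traits)
  tree <- read_tree(config$tree)
  tree <- prune_to_traits(tree, intersect(tree$tip.label, traits$species))
  pairs <- utils::read.csv(config$pairs, stringsAsFactors = FALSE)
  need <- c("pair_id", "species_a", "species_b", "region_id")
  if (!all(need %in% names(pairs))) {
    stop("pair file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  missing_regions <- setdiff(pairs$region_id, names(config$pools))
  if (length(missing_regions) > 0) {
    stop("no pool file configured for region(s): ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }
  focal_all <- unique(c(pairs$species_a, pairs$species_b))
  not_in_tree <- setdiff(focal_all, tree$tip.label)
  if (length(not_in_tree) > 0) {
    stop("focal species missing from tree: ",
         paste(not_in_tree, collapse = ", "), call. = FALSE)
  }

  global_std <- standardize(traits)
  rows <- list()
  fit_rows <- list()
  seeds_used <- list()

  for (r in seq_len(nrow(pairs))) {
    pr <- pairs[r, ]
    region <- pr$region_id
    focal <- c(pr$species_a, pr$species_b)
    pool_ids <- read_pool_file(config$pools[[region]], traits, focal = focal)

    std <- if (config$standardization_scope == "global") {
      global_std
    } else {
      standardize(traits[traits$species %in% c(pool_ids, focal), , drop = FALSE])
    }
    # one standardized space for every tree tip (linear map of the fitted
    # regression applied to all species)
    prof_all <- apply_standardization(std, traits)
    pool_prof <- prof_all[match(pool_ids, prof_all$species), , drop = FALSE]

    ranges <- trait_ranges(pool_prof)
    pool_seed <- derive_seed(config$seed, paste0(region, "/virtual_pool"))
    vpool <- simulate_virtual_pool(ranges, config$n_virtual, seed = pool_seed)
    seeds_used[[paste0(region, "/virtual_pool")]] <- pool_seed

    # per-trait model fits on the full tree, in this region's trait space
    fits <- list()
    for (coord in ALL_TRAITS) {
      xv <- stats::setNames(prof_all[[coord]], prof_all$species)[tree$tip.label]
      fits[[coord]] <- switch(config$model,
        BM = fit_model(tree, xv, "BM"),
        OU = fit_model(tree, xv, "OU"),
        auto = select_model(list(fit_model(tree, xv, "BM"),
                                 fit_model(tree, xv, "OU"))))
      f <- fits[[coord]]
      fit_rows[[paste(pr$pair_id, coord)]] <- data.frame(
        pair_id = pr$pair_id, region = region, trait = coord,
        model = f$model, sigma2 = f$sigma2, alpha = f$alpha,
        root_state = f$root_state, logL = f$logL, aic = f$aic,
        stringsAsFactors = FALSE)
    }

    # ancestral estimates at the first-level MRCA of each focal species
    sisters <- c(
      if (!is.null(pr$sister_a) && !is.na(pr$sister_a) && nzchar(pr$sister_a))
        pr$sister_a else sister_tip(tree, focal[1]),
      if (!is.null(pr$sister_b) && !is.na(pr$sister_b) && nzchar(pr$sister_b))
        pr$sister_b else sister_tip(tree, focal[2]))
    anc <- lapply(1:2, function(i) {
      lapply(stats::setNames(ALL_TRAITS, ALL_TRAITS), function(coord) {
        xv <- stats::setNames(prof_all[[coord]], prof_all$species)[tree$tip.label]
        reconstruct_ancestor(tree, xv, fits[[coord]], c(focal[i], sisters[i]))
      })
    })

    for (ts in c("body_size", "channel")) {
      coords <- if (ts == "body_size") "body_size" else CHANNEL_TRAITS
      null_seed <- derive_seed(config$seed, paste0(region, "/null/", ts))
      null <- sample_null_distances(vpool, ts, config$n_pairs, seed = null_seed)
      seeds_used[[paste0(region, "/null/", ts)]] <- null_seed
      ext <- theoretical_extremes(pool_prof, ts)

      a_vec <- profile_vector(prof_all, focal[1], ts)
      b_vec <- profile_vector(prof_all, focal[2], ts)
      extant <- test_pair(a_vec, b_vec, null, ts, config$alpha_level)
      extant_norm <- as.numeric(normalize_distance(extant$observed,
                                                   ext["dmin"], ext["dmax"]))
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = pr$pair_id, region = region, trait_set = ts, row = "extant",
        distance = extant$observed, p_similarity = extant$p_similarity,
        p_difference = extant$p_difference, p = extant$p,
        p_label = extant$p_label, process = extant$process,
        normalized = extant_norm, factor = NA_real_,
        stringsAsFactors = FALSE)

      anc_a <- anc[[1]][coords]
      anc_b <- anc[[2]][coords]
      div <- divergence_report(extant$observed,
                               list(a = anc_a, b = anc_b), trait_set = ts)
      for (v in c("lower", "mean", "upper")) {
        va <- ancestral_vector(anc_a, v)
        vb <- ancestral_vector(anc_b, v)
        tst <- test_pair(va, vb, null, ts, config$alpha_level)
        rows[[length(rows) + 1]] <- data.frame(
          pair_id = pr$pair_id, region = region, trait_set = ts,
          row = paste0("ancestral-", v),
          distance = tst$observed, p_similarity = tst$p_similarity,
          p_difference = tst$p_difference, p = tst$p, p_label = tst$p_label,
          process = tst$process,
          normalized = as.numeric(normalize_distance(tst$observed,
                                                     ext["dmin"], ext["dmax"])),
          factor = div$factor[div$variant == v],
          stringsAsFactors = FALSE)
      }
    }
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(
    table = table,
    model_fits = do.call(rbind, c(fit_rows, list(make.row.names = FALSE))),
    provenance = list(
      package = as.character(utils::packageVersion("nichepair")),
      config = unclass(config),
      seeds = seeds_used)),
    class = "nichepair_report")
}

#' @export
print.nichepair_report <- function(x, ...) {
  cat("Eco-evolutionary pair analysis report\n")
  cat("(distances: mm for body_size, standardized units for channel)\n\n")
  print(x$table[, c("pair_id", "region", "trait_set", "row", "distance",
                    "p_label", "process", "normalized", "factor")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a report to disk
#'
#' @param report a `"nichepair_report"`. @param dir output directory.
#' @param format `"tsv"`, `"json"` or both.
#' @return paths written, invisibly.
#' @export
write_report <- function(report, dir, format = c("tsv", "json")) {
  stopifnot(inherits(report, "nichepair_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("tsv" %in% format) {
    p <- file.path(dir, "report.tsv")
    utils::write.table(report$table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pf <- file.path(dir, "model_fits.tsv")
    utils::write.table(report$model_fits, pf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p, pf)
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(list(table = report$table,
                              model_fits = report$model_fits,
                              provenance = report$provenance),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
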
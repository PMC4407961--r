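#' Published pairwise distance summaries for the two sulfidic cave systems
#'
#' Transcription of the published Euclidean distances, p-value labels and
#' process classifications for the coexisting *Niphargus* pairs of Movile
#' Cave (Romania) and the Frasassi cave system (Italy): one row per region x
#' trait set x {extant, ancestral-lower, ancestral-mean, ancestral-upper}.
#' Body-size distances are in mm, ventral-channel distances in standardized
#' residual units. These printed summary values are an *input* for the
#' divergence-factor arithmetic ([divergence_report()]); the underlying
#' specimen morphometrics are not part of this package.
#'
#' @return data.frame with columns `region`, `trait_set`, `row`, `distance`,
#'   `p_label`, `process`.
#' @export
published_pair_distances <- function() {
  path <- system.file("extdata", "cave_pair_distances.tsv",
                      package = "nichepair", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Divergence factors recomputed from the published distance summaries
#'
#' For each region and trait set, divides the published extant distance by
#' each published ancestral distance (lower/mean/upper reconstruction
#' variants) via [divergence_report()].
#'
#' @return data.frame `region`, `trait_set`, `variant`,
#'   `ancestral_distance`, `factor`.
#' @export
published_divergence_factors <- function() {
  tab <- published_pair_distances()
  out <- list()
  for (region in unique(tab$region)) {
    for (ts in unique(tab$trait_set)) {
      sub <- tab[tab$region == region & tab$trait_set == ts, ]
      extant <- sub$distance[sub$row == "extant"]
      anc <- stats::setNames(sub$distance[match(
        paste0("ancestral-", c("lower", "mean", "upper")), sub$row)],
        c("lower", "mean", "upper"))
      rep <- divergence_report(extant, anc, trait_set = ts)
      rep$region <- region
      rep$trait_set <- ts
      out[[paste(region, ts)]] <- rep
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("region", "trait_set", "variant", "ancestral_distance", "factor")]
}
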
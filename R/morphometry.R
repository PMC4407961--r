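# Trait layout shared across the package: body size is analyzed in raw mm,
# the four ventral-channel measurements as allometrically standardized
# residuals (dimensionless).
CHANNEL_TRAITS <- c("coxa2", "coxa3", "basis5", "basis7")
ALL_TRAITS <- c("body_size", CHANNEL_TRAITS)

#' Read a species-by-measurement trait table
#'
#' Reads a CSV of species mean morphometric measurements: adult body length
#' and the four ventral-channel measurements (ventro-distal lengths of coxal
#' plates II and III, widths of the bases of pereopods V and VII), all in mm.
#' One row per species is expected; a per-specimen dialect (repeated species)
#' is accepted and averaged, with a message reporting the specimen counts.
#'
#' @param path path to a CSV file with header
#'   `species,body_length_mm,coxa2_mm,coxa3_mm,basis5_mm,basis7_mm` and an
#'   optional `n_specimens` column.
#' @return a data.frame with columns `species`, `body_length`, `coxa2`,
#'   `coxa3`, `basis5`, `basis7` (all mm), one row per species.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    stop("trait table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "body_length_mm", paste0(CHANNEL_TRAITS, "_mm"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("trait table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(required, "species")
  for (cl in num_cols) {
    if (anyNA(raw[[cl]]) || !is.numeric(raw[[cl]])) {
      stop("missing or non-numeric measurement in column '", cl,
           "'; damaged measurements must be excluded upstream, not imputed",
           call. = FALSE)
    }
  }
  if (anyDuplicated(raw$species)) {
    counts <- table(raw$species)
    message("per-specimen table detected; averaging ",
            sum(counts > 1), " species over specimens (max n = ",
            max(counts), ")")
    agg <- stats::aggregate(raw[num_cols], by = list(species = raw$species),
                            FUN = mean)
    raw <- agg[match(unique(raw$species), agg$species), , drop = FALSE]
  }
  out <- data.frame(
    species = raw$species,
    body_length = raw$body_length_mm,
    coxa2 = raw$coxa2_mm,
    coxa3 = raw$coxa3_mm,
    basis5 = raw$basis5_mm,
    basis7 = raw$basis7_mm,
    stringsAsFactors = FALSE
  )
  validate_trait_table(out)
  rownames(out) <- NULL
  out
}

validate_trait_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("species", "body_length", CHANNEL_TRAITS)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$species)) {
    stop("duplicate species_id in trait table: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(tab[, c("body_length", CHANNEL_TRAITS)])
  if (anyNA(vals)) stop("missing measurement in trait table", call. = FALSE)
  if (any(vals <= 0)) {
    bad <- tab$species[apply(vals <= 0, 1, any)]
    stop("non-positive measurement for species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Allometric regression of one measurement on body length
#'
#' Ordinary least-squares fit of a ventral-channel measurement on species mean
#' body length, across species. The residual standard deviation is the usual
#' regression sigma-hat (residual sum of squares over n - 2 degrees of
#' freedom), later used to express residuals in standard-deviation units.
#'
#' @param records trait table as returned by [read_trait_table()].
#' @param trait_name one of `"coxa2"`, `"coxa3"`, `"basis5"`, `"basis7"`.
#' @return a list of class `"allometry_fit"` with elements `trait_name`,
#'   `slope`, `intercept`, `residual_sd`, `n`, `residuals` (named by species).
#' @export
fit_allometry <- function(records, trait_name) {
  validate_trait_table(records)
  trait_name <- match.arg(trait_name, CHANNEL_TRAITS)
  n <- nrow(records)
  if (n < 3) stop("insufficient data: need >= 3 species, got ", n,
                  call. = FALSE)
  x <- records$body_length
  if (stats::var(x) == 0) stop("degenerate regression: zero variance in body length",
                               call. = FALSE)
  y <- records[[trait_name]]
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  rsd <- sqrt(sum(res^2) / (n - 2))
  # collinearity detected relative to the measurement scale, so exact-line
  # fixtures do not trip on floating-point residue
  degenerate <- rsd <= 1e-10 * max(abs(y))
  if (degenerate) {
    warning("degenerate fit for ", trait_name,
            ": measurements perfectly collinear with body length",
            call. = FALSE)
  }
  names(res) <- records$species
  structure(
    list(trait_name = trait_name,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residual_sd = rsd,
         n = n,
         degenerate = degenerate,
         residuals = res),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("Allometric fit: %s = %.4f + %.4f * body_length (n = %d, residual SD = %.4g mm)\n",
              x$trait_name, x$intercept, x$slope, x$n, x$residual_sd))
  invisible(x)
}

#' Standardize a trait table into analysis-ready profiles
#'
#' Converts raw measurements into the two trait sets the analysis uses:
#' body size (species mean body length, kept in raw mm) and the
#' four-dimensional ventral-channel shape, each channel measurement expressed
#' as its allometric regression residual divided by the residual SD of that
#' regression (a standardized residual, dimensionless).
#'
#' @param records trait table (see [read_trait_table()]).
#' @return object of class `"std_profiles"`: a list with `profiles` (a
#'   data.frame `species`, `body_size`, `coxa2`, `coxa3`, `basis5`, `basis7`)
#'   and `fits` (a data.frame of the per-trait regression parameters).
#' @export
standardize <- function(records) {
  validate_trait_table(records)
  fits <- lapply(CHANNEL_TRAITS, function(tr) fit_allometry(records, tr))
  names(fits) <- CHANNEL_TRAITS
  prof <- data.frame(species = records$species,
                     body_size = records$body_length,
                     stringsAsFactors = FALSE)
  for (tr in CHANNEL_TRAITS) {
    f <- fits[[tr]]
    prof[[tr]] <- if (f$degenerate) rep(0, nrow(records))
                  else unname(f$residuals) / f$residual_sd
  }
  fit_tab <- data.frame(
    trait_name = CHANNEL_TRAITS,
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    residual_sd = vapply(fits, `[[`, numeric(1), "residual_sd"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(profiles = prof, fits = fit_tab), class = "std_profiles")
}

#' @export
print.std_profiles <- function(x, ...) {
  cat("Standardized trait profiles for", nrow(x$profiles), "species\n")
  print(x$profiles, digits = 4)
  invisible(x)
}

#' Apply an existing standardization to further species
#'
#' Re-uses the regression parameters of a fitted standardization (the linear
#' allometric map per channel trait) on species that were not part of the
#' regression, e.g. the full phylogeny's tips when the regression was fitted
#' within one regional pool.
#'
#' @param std a `"std_profiles"` object.
#' @param records trait table rows to project.
#' @return a profiles data.frame in the same standardized space as `std`.
#' @export
apply_standardization <- function(std, records) {
  stopifnot(inherits(std, "std_profiles"))
  validate_trait_table(records)
  prof <- data.frame(species = records$species,
                     body_size = records$body_length,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(std$fits))) {
    f <- std$fits[i, ]
    res <- records[[f$trait_name]] - (f$intercept + f$slope * records$body_length)
    prof[[f$trait_name]] <- if (f$residual_sd > 0) res / f$residual_sd else res
  }
  prof
}

#' Extract one species' numeric trait vector
#'
#' @param profiles profiles data.frame or `"std_profiles"`.
#' @param species a species id. @param trait_set `"body_size"` or
#'   `"channel"`.
#' @return numeric vector (length 1 for body size, 4 for the channel).
#' @export
profile_vector <- function(profiles, species, trait_set) {
  if (inherits(profiles, "std_profiles")) profiles <- profiles$profiles
  i <- match(species, profiles$species)
  if (is.na(i)) stop("species not in profiles: ", species, call. = FALSE)
  if (trait_set == "body_size") {
    profiles$body_size[i]
  } else {
    as.numeric(profiles[i, CHANNEL_TRAITS])
  }
}

#' Euclidean distance between two species' trait profiles
#'
#' For `trait_set = "body_size"` this is the absolute body-length difference
#' in mm; for `"channel"` the 4-D Euclidean norm of the standardized-residual
#' differences (dimensionless).
#'
#' @param a,b either numeric trait vectors (length 1 for body size, 4 for the
#'   channel) or single species rows selected from a profiles data.frame.
#' @param trait_set `"body_size"` or `"channel"`.
#' @return non-negative scalar distance.
#' @export
euclidean_distance <- function(a, b, trait_set = c("body_size", "channel")) {
  trait_set <- match.arg(trait_set)
  a <- as_trait_vector(a, trait_set)
  b <- as_trait_vector(b, trait_set)
  sqrt(sum((a - b)^2))
}

as_trait_vector <- function(v, trait_set) {
  if (is.data.frame(v)) {
    stopifnot(nrow(v) == 1)
    v <- if (trait_set == "body_size") v$body_size
         else as.numeric(v[1, CHANNEL_TRAITS])
  }
  v <- as.numeric(v)
  want <- if (trait_set == "body_size") 1L else 4L
  if (length(v) != want) {
    stop("trait vector for '", trait_set, "' must have length ", want,
         ", got ", length(v), call. = FALSE)
  }
  if (anyNA(v)) stop("NA in trait vector", call. = FALSE)
  v
}

#' Normalize a distance onto the theoretical [0, 1] range of a species pool
#'
#' Maps an observed Euclidean distance onto
#' `(d - dmin) / (dmax - dmin)` where `dmin` and `dmax` are the theoretical
#' minimal and maximal distances attainable within the regional pool (see
#' [theoretical_extremes()]). Values outside `[0, 1]` are allowed — ancestral
#' pairs can exceed the theoretical extremes — and are flagged via the
#' `"out_of_range"` attribute rather than clamped.
#'
#' @param d observed distance. @param dmin,dmax theoretical extremes,
#'   `dmax > dmin >= 0`.
#' @return scalar fraction, with attribute `out_of_range` (logical).
#' @export
normalize_distance <- function(d, dmin, dmax) {
  if (!(dmax > dmin) || dmin < 0) {
    stop("degenerate range: need dmax > dmin >= 0 (got dmin = ", dmin,
         ", dmax = ", dmax, ")", call. = FALSE)
  }
  v <- (d - dmin) / (dmax - dmin)
  attr(v, "out_of_range") <- v < 0 | v > 1
  v
}

#' Theoretical minimal and maximal distances within a regional pool
#'
#' The theoretical minimum is 0 (two species may coincide anywhere inside the
#' pool's trait ranges); the theoretical maximum is the diagonal of the pool's
#' per-trait bounding box — the largest Euclidean distance achievable between
#' two points whose coordinates all lie within the observed pool ranges.
#'
#' @param pool_profiles profiles data.frame (or `"std_profiles"`) of the pool
#'   members. @param trait_set `"body_size"` or `"channel"`.
#' @return named numeric `c(dmin = 0, dmax = ...)`.
#' @export
theoretical_extremes <- function(pool_profiles, trait_set = c("body_size", "channel")) {
  trait_set <- match.arg(trait_set)
  if (inherits(pool_profiles, "std_profiles")) pool_profiles <- pool_profiles$profiles
  if (is.null(nrow(pool_profiles)) || nrow(pool_profiles) < 2) {
    stop("pool must contain >= 2 species", call. = FALSE)
  }
  cols <- if (trait_set == "body_size") "body_size" else CHANNEL_TRAITS
  m <- as.matrix(pool_profiles[, cols, drop = FALSE])
  spans <- apply(m, 2, function(col) diff(range(col)))
  c(dmin = 0, dmax = sqrt(sum(spans^2)))
}

#' Pairwise distance summaries for a set of species
#'
#' @param profiles profiles data.frame or `"std_profiles"`.
#' @param pairs two-column character matrix/data.frame of species id pairs.
#' @param trait_set `"body_size"` or `"channel"`.
#' @param extremes optional result of [theoretical_extremes()] used to add a
#'   normalized column.
#' @return data.frame `species_a`, `species_b`, `trait_set`, `distance`, and
#'   `normalized` when `extremes` is supplied.
#' @export
distance_summary <- function(profiles, pairs, trait_set, extremes = NULL) {
  if (inherits(profiles, "std_profiles")) profiles <- profiles$profiles
  pairs <- as.matrix(pairs)
  d <- apply(pairs, 1, function(p) {
    euclidean_distance(profile_vector(profiles, p[1], trait_set),
                       profile_vector(profiles, p[2], trait_set),
                       trait_set)
  })
  out <- data.frame(species_a = pairs[, 1], species_b = pairs[, 2],
                    trait_set = trait_set, distance = d,
                    stringsAsFactors = FALSE)
  if (!is.null(extremes)) {
    out$normalized <- vapply(d, function(di)
      as.numeric(normalize_distance(di, extremes["dmin"], extremes["dmax"])),
      numeric(1))
  }
  rownames(out) <- NULL
  out
}
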
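#' Population coordinate tables
#'
#' @param id population identifiers (unique).
#' @param lat,lon decimal degrees, lat in \[-90, 90\], lon in \[-180, 180\].
#' @param label free-text labels.
#' @return data.frame of class `population_sites`.
#' @export
population_sites <- function(id, lat, lon, label = id) {
  id <- as.character(id); lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (anyDuplicated(id)) stop("duplicate population id")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  structure(data.frame(id = id, lat = lat, lon = lon, label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("population_sites", "data.frame"))
}

#' @rdname population_sites
#' @param path TSV with columns population_id, lat, lon, label.
#' @export
read_population_sites <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  population_sites(df[[1]], df[[2]], df[[3]],
                   if (ncol(df) >= 4) df[[4]] else df[[1]])
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0088)
}

#' Interpopulation distances of lineages in a class
#'
#' For each lineage of the requested class, every unordered pair of
#' distinct carrier populations contributes one great-circle distance; the
#' distances are pooled across the class's lineages. Lineages carried by a
#' single population contribute nothing (a message reports how many).
#'
#' @param occurrences data.frame with columns `lineage_key`, `class`,
#'   `population_id` (one row per lineage-population occurrence).
#' @param sites a [population_sites()] table covering every referenced
#'   population.
#' @param class_label which class to pool.
#' @return list with `distances` (km), `mean_km`, `frac_below_1000km`,
#'   `n_lineages_used`, `n_lineages_skipped`.
#' @export
lineage_distances <- function(occurrences, sites, class_label) {
  occ <- occurrences[occurrences$class == class_label, , drop = FALSE]
  miss <- setdiff(unique(occ$population_id), sites$id)
  if (length(miss))
    stop("populations without coordinates: ", paste(miss, collapse = ", "))
  d <- numeric(0); used <- 0L; skipped <- 0L
  for (lk in unique(occ$lineage_key)) {
    pops <- unique(occ$population_id[occ$lineage_key == lk])
    if (length(pops) < 2L) { skipped <- skipped + 1L; next }
    used <- used + 1L
    idx <- match(pops, sites$id)
    pr <- utils::combn(idx, 2)
    d <- c(d, haversine_km(sites$lat[pr[1, ]], sites$lon[pr[1, ]],
                           sites$lat[pr[2, ]], sites$lon[pr[2, ]]))
  }
  if (skipped) message(skipped, " lineage(s) with a single carrier population skipped")
  list(distances = d,
       mean_km = if (length(d)) mean(d) else NA_real_,
       frac_below_1000km = if (length(d)) mean(d < 1000) else NA_real_,
       n_lineages_used = used, n_lineages_skipped = skipped)
}

## exact two-sided p for U1 by complete enumeration over the pooled sample
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  obs_u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(N, n1)
  u1s <- apply(idx, 2, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  p <- 2 * min(mean(u1s <= obs_u1 + eps), mean(u1s >= obs_u1 - eps))
  min(p, 1)
}

#' Mann-Whitney U comparison of two distance samples
#'
#' Computes both U statistics from midrank sums. Small samples
#' (`n1 + n2 <= exact_limit`) are tested by complete enumeration of the
#' `choose(n1 + n2, n1)` group assignments of the pooled observed values
#' (valid with ties); larger samples use the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction. The two-sided
#' probability is reported in both modes.
#'
#' @param x,y numeric samples (e.g. pooled interpopulation distances of two
#'   lineage classes).
#' @param exact_limit switch to exact enumeration when `n1 + n2` is at or
#'   below this (default 12).
#' @param force one of `"auto"`, `"exact"`, `"approx"`.
#' @return object of class `geo_test` with fields `U` (the smaller of the
#'   two U statistics), `U1`, `U2`, `Z`, `p`, `n1`, `n2`, `mean1_km`,
#'   `mean2_km`, `frac_below_1000km_1`, `frac_below_1000km_2`, `method`.
#' @export
mann_whitney <- function(x, y, exact_limit = 12L,
                         force = c("auto", "exact", "approx")) {
  force <- match.arg(force)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  N <- n1 + n2
  rk <- rank(c(x, y))
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  s2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (s2 <= 0) { # fully tied samples
    Z <- 0; p_approx <- 1
  } else {
    z_mag <- max(abs(U1 - mu) - 0.5, 0) / sqrt(s2)
    Z <- sign(U1 - mu) * z_mag
    p_approx <- 2 * stats::pnorm(-z_mag)
  }
  use_exact <- force == "exact" || (force == "auto" && N <= exact_limit)
  p <- if (use_exact) mw_exact_p(x, y) else min(p_approx, 1)
  structure(list(U = min(U1, U2), U1 = U1, U2 = U2, Z = Z, p = p,
                 n1 = n1, n2 = n2,
                 mean1_km = mean(x), mean2_km = mean(y),
                 frac_below_1000km_1 = mean(x < 1000),
                 frac_below_1000km_2 = mean(y < 1000),
                 method = if (use_exact) "exact enumeration"
                          else "normal approximation (tie-corrected, continuity-corrected)"),
            class = "geo_test")
}

#' @export
print.geo_test <- function(x, ...) {
  cat("Mann-Whitney U comparison of interpopulation distances\n")
  cat(sprintf("  n1 = %d (mean %.0f km, %.0f%% < 1000 km), n2 = %d (mean %.0f km, %.0f%% < 1000 km)\n",
              x$n1, x$mean1_km, 100 * x$frac_below_1000km_1,
              x$n2, x$mean2_km, 100 * x$frac_below_1000km_2))
  cat(sprintf("  U = %g (U1 = %g, U2 = %g), Z = %.2f, p = %.4g  [%s]\n",
              x$U, x$U1, x$U2, x$Z, x$p, x$method))
  invisible(x)
}

#' Compare the dispersion of two lineage classes
#'
#' Pools interpopulation distances per class via [lineage_distances()] and
#' tests them with [mann_whitney()].
#'
#' @inheritParams lineage_distances
#' @param class1,class2 class labels (e.g. `"ancestral"`, `"derived"`).
#' @param ... passed to [mann_whitney()].
#' @return a `geo_test` (or `NULL` with a warning if either class yields
#'   fewer than one distance).
#' @export
compare_dispersion <- function(occurrences, sites, class1, class2, ...) {
  d1 <- lineage_distances(occurrences, sites, class1)
  d2 <- lineage_distances(occurrences, sites, class2)
  if (!length(d1$distances) || !length(d2$distances)) {
    warning("not enough interpopulation distances to test (",
            class1, ": ", length(d1$distances), ", ",
            class2, ": ", length(d2$distances), ")")
    return(NULL)
  }
  mann_whitney(d1$distances, d2$distances, ...)
}

#' Classify panel haplotypes into lineage occurrence records
#'
#' A haplotype whose derived states equal the root motif exactly is
#' `ancestral`; anything else is `derived`. Alternatively, classes can be
#' defined by the allele carried at a single position (`by_state_at`),
#' e.g. the 194C vs 194T split. The lineage key is the haplotype's variant
#' fingerprint.
#'
#' @param panel a [hap_panel()] (haplotypes must carry population ids).
#' @param root_motif motif tokens or variant data.frame.
#' @param by_state_at optional np: classes become the derived/reference
#'   states observed at that position (haplotypes without coverage there
#'   are dropped).
#' @return occurrence data.frame (`lineage_key`, `class`, `population_id`).
#' @export
classify_lineages <- function(panel, root_motif, by_state_at = NULL) {
  motif_sig <- hap_signature(haplotype("motif",
    if (is.data.frame(root_motif)) root_motif else parse_motif(root_motif)))
  rows <- lapply(panel$haplotypes, function(h) {
    if (is.na(h$population)) return(NULL)
    sig <- hap_signature(h)
    cls <- if (!is.null(by_state_at)) {
      if (!pos_in_intervals(by_state_at, h$covered)) return(NULL)
      s <- state_map(h); k <- paste0(by_state_at, "s")
      paste0(by_state_at, if (k %in% names(s)) s[[k]] else "ref")
    } else if (sig == motif_sig) "ancestral" else "derived"
    data.frame(lineage_key = if (nzchar(sig)) sig else "(root motif)",
               class = cls, population_id = h$population,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
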
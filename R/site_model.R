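#' Per-site relative mutation rates
#'
#' Relative rates are dimensionless, with 1.0 meaning the average rate of
#' the site's region. Sites absent from the table default to 1.0.
#'
#' @param pos integer rCRS positions.
#' @param rate positive relative rates.
#' @return data.frame of class `site_rates` with columns `pos`, `rate`.
#' @export
site_rates <- function(pos = integer(0), rate = numeric(0)) {
  pos <- as.integer(pos); rate <- as.numeric(rate)
  if (length(pos) != length(rate)) stop("pos and rate must have equal length")
  if (any(rate <= 0)) stop("relative rates must be positive")
  if (any(pos < 1L | pos > RCRS_LENGTH)) stop("invalid rCRS position in rate table")
  if (anyDuplicated(pos)) stop("duplicate position in rate table")
  structure(data.frame(pos = pos, rate = rate), class = c("site_rates", "data.frame"))
}

#' Read/write a two-column rate table (np, relative_rate; TSV)
#' @param path file path.
#' @return a [site_rates()] table.
#' @export
read_site_rates <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  site_rates(df[[1]], df[[2]])
}

#' @rdname read_site_rates
#' @param rates a [site_rates()] table.
#' @export
write_site_rates <- function(rates, path) {
  utils::write.table(data.frame(np = rates$pos, relative_rate = rates$rate),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Integer site weight from a relative mutation rate
#'
#' Weights decrease as the relative rate increases, anchored at a weight of
#' 8 for an average-rate site and 6 for a site at twice the average. Those
#' two anchors define a linear rule, `w = round(10 - 2 r)`, clipped to
#' `[1, 10]`; this is the default. Although the convention is often phrased
#' as "inverse proportional", a strictly inverse rule (`w = round(8 / r)`,
#' floored at 1) would give weight 4 at rate 2 and break the second anchor;
#' it is available via `method = "inverse"` for sensitivity analysis.
#'
#' @param relative_rate positive relative rate(s).
#' @param method `"linear"` (default) or `"inverse"`.
#' @return integer weight(s).
#' @examples
#' weight_for_rate(1.0)  # 8
#' weight_for_rate(2.0)  # 6
#' @export
weight_for_rate <- function(relative_rate, method = c("linear", "inverse")) {
  method <- match.arg(method)
  if (any(!is.finite(relative_rate)) || any(relative_rate <= 0))
    stop("relative rate must be positive")
  w <- if (method == "linear") round_half_up(10 - 2 * relative_rate)
       else round_half_up(8 / relative_rate)
  if (method == "linear") w <- pmin(w, 10L)
  as.integer(pmax(w, 1L))
}

round_half_up <- function(x) floor(x + 0.5)

#' Build a site-weight scheme from a rate table
#'
#' @param rates a [site_rates()] table or `NULL` (all sites average).
#' @param default_weight weight for sites absent from the table (8, the
#'   average-rate weight).
#' @param method weighting rule, see [weight_for_rate()].
#' @return object of class `weight_scheme`.
#' @export
weight_scheme <- function(rates = NULL, default_weight = 8L,
                          method = c("linear", "inverse")) {
  method <- match.arg(method)
  w <- if (is.null(rates) || !nrow(rates)) stats::setNames(integer(0), character(0))
       else stats::setNames(weight_for_rate(rates$rate, method), as.character(rates$pos))
  structure(list(weights = w, default_weight = as.integer(default_weight),
                 method = method),
            class = "weight_scheme")
}

#' Look up site weights
#' @param scheme a [weight_scheme()] or `NULL` (uniform weight 1, for plain
#'   mutation counting).
#' @param pos integer positions.
#' @return integer weights.
#' @export
site_weight <- function(scheme, pos) {
  if (is.null(scheme)) return(rep(1L, length(pos)))
  w <- scheme$weights[as.character(pos)]
  w[is.na(w)] <- scheme$default_weight
  as.integer(w)
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("<weight_scheme> %s rule; %d site-specific weight(s), default %d\n",
              x$method, length(x$weights), x$default_weight))
  invisible(x)
}

## poly-nucleotide stretches of the control region in which indels are
## considered length variants of the run rather than independent events
POLY_STRETCHES <- rbind(c(302L, 316L), c(16180L, 16193L))

#' Site exclusion sets
#'
#' Construct an exclusion set: positions whose mutations are ignored, plus
#' an indel policy (`"none"`: keep all indels; `"poly"`: ignore indels
#' anchored in poly-nucleotide stretches, np 302-316 and 16180-16193;
#' `"all"`: ignore every indel).
#'
#' @param positions integer rCRS positions to exclude.
#' @param indels indel policy.
#' @param label text label.
#' @return object of class `exclusion_set`.
#' @export
exclusion_set <- function(positions = integer(0),
                          indels = c("none", "poly", "all"), label = "custom") {
  indels <- match.arg(indels)
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && any(positions < 1L | positions > RCRS_LENGTH))
    stop("excluded position outside rCRS")
  structure(list(label = label, positions = positions, indels = indels),
            class = "exclusion_set")
}

#' Built-in exclusion sets for control-region hotspots
#'
#' Three published site lists are available:
#' \describe{
#'   \item{`network_hvr1`}{the five HVR-I hypervariable sites ignored when
#'     building networks: 16093, 16129, 16189, 16311, 16362.}
#'   \item{`network_hvr2_extra`}{the additional HVR-II sites ignored in the
#'     joint HVR-I+II network (146, 150, 152, 195), together with indels in
#'     poly-nucleotide stretches.}
#'   \item{`rho_fast_sites`}{the 41 sites with mutation rates three times or
#'     more above their regional average, excluded (together with all
#'     indels) when computing rho under the phylogenetic rate convention:
#'     20 HVR-I sites and 21 HVR-II sites.}
#' }
#'
#' @param label one of the three names above.
#' @return an [exclusion_set()].
#' @export
builtin_exclusions <- function(label = c("network_hvr1", "network_hvr2_extra",
                                         "rho_fast_sites")) {
  label <- match.arg(label)
  switch(label,
    network_hvr1 = exclusion_set(c(16093L, 16129L, 16189L, 16311L, 16362L),
                                 "none", label),
    network_hvr2_extra = exclusion_set(c(146L, 150L, 152L, 195L), "poly", label),
    rho_fast_sites = exclusion_set(
      c(16093L, 16126L, 16129L, 16148L, 16163L, 16172L, 16183L, 16187L,
        16189L, 16192L, 16223L, 16230L, 16270L, 16278L, 16293L, 16294L,
        16309L, 16311L, 16319L, 16362L,
        64L, 73L, 93L, 146L, 150L, 151L, 152L, 153L, 182L, 185L, 186L,
        189L, 195L, 198L, 199L, 200L, 207L, 236L, 247L, 263L, 316L),
      "all", label))
}

#' Combine exclusion sets
#' @param ... [exclusion_set()] objects (or `NULL`s, dropped).
#' @return an [exclusion_set()] with the union of positions and the most
#'   restrictive indel policy.
#' @export
combine_exclusions <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  if (!length(sets)) return(NULL)
  lev <- c(none = 0L, poly = 1L, all = 2L)
  ind <- names(lev)[max(lev[vapply(sets, `[[`, character(1), "indels")]) + 1L]
  exclusion_set(unlist(lapply(sets, `[[`, "positions")), ind,
                paste(vapply(sets, `[[`, character(1), "label"), collapse = "+"))
}

#' Check exclusion positions against analysis regions
#'
#' Excluded positions falling outside the configured regions are dropped
#' with a warning (they cannot affect the analysis).
#' @param excl an [exclusion_set()] or `NULL`.
#' @param regions list of [region()]s.
#' @return filtered [exclusion_set()].
#' @export
restrict_exclusions <- function(excl, regions) {
  if (is.null(excl)) return(NULL)
  inside <- pos_in_intervals(excl$positions, region_mat(regions))
  if (any(!inside))
    warning("excluded position(s) outside the configured regions: ",
            paste(excl$positions[!inside], collapse = ", "))
  exclusion_set(excl$positions[inside], excl$indels, excl$label)
}

## is a variant key excluded?
key_excluded <- function(keys, excl) {
  if (is.null(excl)) return(rep(FALSE, length(keys)))
  if (is.numeric(excl)) excl <- exclusion_set(excl)
  pos <- key_pos(keys); kind <- key_kind(keys)
  out <- pos %in% excl$positions
  if (excl$indels == "all") out <- out | kind != "sub"
  if (excl$indels == "poly")
    out <- out | (kind != "sub" & pos_in_intervals(pos, POLY_STRETCHES))
  out
}

#' @export
print.exclusion_set <- function(x, ...) {
  cat(sprintf("<exclusion_set> %s: %d position(s), indel policy '%s'\n",
              x$label, length(x$positions), x$indels))
  invisible(x)
}

#' A synthetic relative-rate table for the control region
#'
#' The published hotspot lists are placed several-fold above average (the
#' five HVR-I network-excluded sites at 4x, the four HVR-II sites at 6x,
#' the remaining rho-excluded fast sites at 3x) and the remaining sites of
#' each region share one sub-average value chosen so that the region's mean
#' relative rate is exactly 1.0 (the defining property of a relative-rate
#' table). This emulates the shape of an empirical control-region rate
#' table - a minority of hotspot sites several-fold above average - without
#' asserting any site's true rate; it is synthetic and used for simulation,
#' weighting demos and tests.
#'
#' @param regions region list; default the joint HVR-I+II window. Each
#'   region is normalised separately ("1.0 = average of the site's own
#'   region").
#' @return a [site_rates()] table.
#' @export
synthetic_site_rates <- function(regions = region_preset("hvr1_hvr2")) {
  hot4 <- builtin_exclusions("network_hvr1")$positions
  hot6 <- builtin_exclusions("network_hvr2_extra")$positions
  hot3 <- setdiff(builtin_exclusions("rho_fast_sites")$positions, c(hot4, hot6))
  m <- region_mat(as_region_list(regions))
  pos <- integer(0); rate <- numeric(0)
  for (i in seq_len(nrow(m))) {
    p <- m[i, 1]:m[i, 2]
    r <- rep(NA_real_, length(p))
    r[p %in% hot3] <- 3.0
    r[p %in% hot4] <- 4.0
    r[p %in% hot6] <- 6.0
    base <- is.na(r)
    ## mean over the region is exactly 1
    r[base] <- if (any(!base)) (length(p) - sum(r[!base])) / sum(base) else 1.0
    pos <- c(pos, p); rate <- c(rate, r)
  }
  site_rates(pos, rate)
}
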
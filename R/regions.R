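#' Control-region coordinate intervals
#'
#' A region is a closed 1-based interval of rCRS nucleotide positions (np).
#' Circularity of the mitochondrial genome is not modelled: no region may
#' wrap the origin, so `start <= end` always.
#'
#' @param start,end 1-based rCRS positions, inclusive; `start <= end`.
#' @param label short text label.
#' @return An object of class `hap_region`: a list with `start`, `end`,
#'   `label`.
#' @examples
#' region(16051, 16365, "HVR-I (315 bp)")
#' @export
region <- function(start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("region start/end must be single integers")
  if (start > end) stop("region start must be <= end (no origin-wrapping)")
  if (start < 1L || end > RCRS_LENGTH)
    stop("region must lie within 1..", RCRS_LENGTH, " (rCRS)")
  structure(list(start = start, end = end, label = as.character(label)),
            class = "hap_region")
}

#' rCRS length in base pairs
#' @keywords internal
RCRS_LENGTH <- 16569L

#' Named region presets
#'
#' The presets mirror the two analysis windows used for control-region C1d
#' work: the 315-bp HVR-I truncation (np 16051-16365) used for the HVR-I-only
#' network, and the joint HVR-I (np 16024-16383) + HVR-II (np 57-372) window
#' used when both hypervariable regions are available.
#'
#' @param name one of `"hvr1_315"`, `"hvr1_hvr2"`, `"full"`.
#' @return A list of `hap_region` objects.
#' @export
region_preset <- function(name = c("hvr1_315", "hvr1_hvr2", "full")) {
  name <- match.arg(name)
  switch(name,
    hvr1_315  = list(region(16051, 16365, "HVR-I (315 bp)")),
    hvr1_hvr2 = list(region(57, 372, "HVR-II"),
                     region(16024, 16383, "HVR-I")),
    full      = list(region(1, RCRS_LENGTH, "rCRS"))
  )
}

#' Total length in bp of a list of regions
#' @param regions list of `hap_region`.
#' @return integer number of bases covered (regions assumed disjoint).
#' @export
region_length <- function(regions) {
  regions <- as_region_list(regions)
  sum(vapply(regions, function(r) r$end - r$start + 1L, integer(1)))
}

as_region_list <- function(regions) {
  if (inherits(regions, "hap_region")) return(list(regions))
  if (!is.list(regions) || !all(vapply(regions, inherits, logical(1), "hap_region")))
    stop("expected a hap_region or a list of hap_region objects")
  regions
}

## regions as a two-column integer matrix for set arithmetic
region_mat <- function(regions) {
  regions <- as_region_list(regions)
  if (!length(regions)) return(matrix(integer(0), ncol = 2))
  cbind(vapply(regions, `[[`, integer(1), "start"),
        vapply(regions, `[[`, integer(1), "end"))
}

## normalise an interval matrix: sort, merge overlapping/adjacent
normalise_intervals <- function(m) {
  if (!nrow(m)) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2] + 1L) out[k, 2] <- max(out[k, 2], m[i, 2])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

intersect_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[0, , drop = FALSE])
  res <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a[i, 1], b[j, 1]); e <- min(a[i, 2], b[j, 2])
    if (s <= e) res <- rbind(res, c(s, e))
  }
  if (is.null(res)) a[0, , drop = FALSE] else normalise_intervals(res)
}

subtract_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  cur <- a
  for (j in seq_len(nrow(b))) {
    nxt <- NULL
    for (i in seq_len(nrow(cur))) {
      s <- cur[i, 1]; e <- cur[i, 2]
      bs <- b[j, 1]; be <- b[j, 2]
      if (be < s || bs > e) { nxt <- rbind(nxt, c(s, e)); next }
      if (bs > s) nxt <- rbind(nxt, c(s, bs - 1L))
      if (be < e) nxt <- rbind(nxt, c(be + 1L, e))
    }
    cur <- if (is.null(nxt)) a[0, , drop = FALSE] else nxt
    if (!nrow(cur)) break
  }
  normalise_intervals(cur)
}

pos_in_intervals <- function(pos, m) {
  if (!nrow(m)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= m[, 1] & p <= m[, 2]), logical(1))
}

#' @export
print.hap_region <- function(x, ...) {
  cat(sprintf("<region> np %d-%d (%d bp)%s\n", x$start, x$end,
              x$end - x$start + 1L,
              if (nzchar(x$label)) paste0("  ", x$label) else ""))
  invisible(x)
}
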
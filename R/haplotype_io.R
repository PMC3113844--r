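#' Parse a variant table in the printed-table dialect
#'
#' Reads tab-separated haplotype tables of the form used in control-region
#' population reports: one column per variable rCRS position (integer
#' headers; `"310i"` or `"310.2i"` for insertion columns), a reference row
#' labelled `rCRS` giving the reference allele of every column (`-` for
#' insertion columns), and one row per sample. Body cells are `.` (identity
#' with the reference), a base (substitution, or inserted base in an
#' insertion column), `d` (deletion), or blank (no data). Maximal runs of
#' contiguous blank columns in a row become a single missing interval
#' spanning from the first to the last position of the run.
#'
#' Leading non-positional columns (sample id, then any metadata columns such
#' as a birthplace/population column) are detected from the header; the
#' first metadata column, if present, is used as the population id.
#'
#' @param table_text the table as a single string, a character vector of
#'   lines, or a path to a file.
#' @param base_coverage region(s) assumed covered where the table is not
#'   blank; defaults to the full rCRS.
#' @return a [hap_panel()].
#' @export
parse_variant_table <- function(table_text, base_coverage = region_preset("full")) {
  lines <- as_lines(table_text)
  lines <- lines[nzchar(trimws(lines, whitespace = "[\r\n]"))]
  cells <- strsplit(sub("\r$", "", lines), "\t", fixed = TRUE)
  header <- trimws(cells[[1]])

  is_pos <- grepl("^[0-9]+(\\.[0-9]+)?i?$", header)
  n_meta <- match(TRUE, is_pos) - 1L
  if (is.na(n_meta) || n_meta < 1L)
    stop("header must start with a sample-id column followed by np columns")
  if (!all(is_pos[(n_meta + 1L):length(header)]))
    stop("non-positional column amid np columns: ",
         paste(header[-(1:n_meta)][!is_pos[-(1:n_meta)]], collapse = ", "))

  ph <- header[is_pos]
  col_pos <- as.integer(sub("^([0-9]+).*$", "\\1", ph))
  col_ins <- grepl("i$", ph)
  col_idx <- ifelse(grepl("^[0-9]+\\.[0-9]+i$", ph),
                    as.integer(sub("^[0-9]+\\.([0-9]+)i$", "\\1", ph)), 1L)
  colkey <- paste0(col_pos, ifelse(col_ins, paste0(".", col_idx, "i"), ""))
  if (anyDuplicated(colkey))
    stop("duplicate position column: ", paste(colkey[duplicated(colkey)], collapse = ", "))

  pad <- function(x, n) { length(x) <- n; x[is.na(x)] <- ""; trimws(x) }
  body <- lapply(cells[-1], pad, n = length(header))
  labels <- vapply(body, `[`, character(1), 1L)
  iref <- which(labels == "rCRS")
  if (length(iref) != 1L) stop("exactly one reference row labelled 'rCRS' is required")
  ref_cells <- body[[iref]][-(1:n_meta)]
  ## "N" marks a column whose reference allele is unstated (e.g. invariant
  ## boundary columns used to delimit sequenced regions)
  bad_ref <- !(ref_cells %in% c("A", "C", "G", "T", "N") |
               (col_ins & ref_cells %in% c("-", "")))
  if (any(bad_ref))
    stop("invalid reference allele in column ", paste(ph[bad_ref], collapse = ", "))

  base_m <- normalise_intervals(region_mat(base_coverage))
  haps <- list()
  for (i in seq_along(body)[-iref]) {
    row <- body[[i]]
    id <- row[1L]
    if (!nzchar(id)) stop("row ", i + 1L, ": empty sample id")
    popn <- if (n_meta >= 2L && nzchar(row[2L])) row[2L] else NA_character_
    cc <- row[-(1:n_meta)]

    blank <- !nzchar(cc)
    v <- list(pos = integer(0), kind = character(0), ref = character(0),
              alt = character(0), idx = integer(0))
    for (j in which(!blank)) {
      cell <- cc[j]
      if (cell == ".") next
      if (col_ins[j]) {
        if (cell %in% c("-")) next
        if (!cell %in% c("A", "C", "G", "T"))
          stop("row '", id, "', column ", ph[j], ": unknown cell symbol '", cell, "'")
        v <- add_var(v, col_pos[j], "ins", "", cell, col_idx[j])
      } else if (cell == "d") {
        v <- add_var(v, col_pos[j], "del", ref_cells[j], "", 1L)
      } else if (cell %in% c("A", "C", "G", "T")) {
        if (ref_cells[j] == "N")
          stop("row '", id, "', column ", ph[j],
               ": variant cell under a column with no stated reference allele")
        if (cell == ref_cells[j]) {
          warning("row '", id, "', column ", ph[j],
                  ": cell equals reference allele; no variant recorded")
        } else v <- add_var(v, col_pos[j], "sub", ref_cells[j], cell, 1L)
      } else stop("row '", id, "', column ", ph[j], ": unknown cell symbol '", cell, "'")
    }

    cov <- base_m
    if (any(blank)) {
      r <- rle(blank)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      miss <- cbind(col_pos[starts[r$values]], col_pos[ends[r$values]])
      cov <- subtract_intervals(cov, normalise_intervals(miss))
    }
    haps[[length(haps) + 1L]] <- haplotype(
      id, variants(v$pos, v$kind, v$ref, v$alt, v$idx),
      covered = interval_regions(cov), population = popn)
  }
  hap_panel(haps)
}

add_var <- function(v, pos, kind, ref, alt, idx) {
  v$pos <- c(v$pos, pos); v$kind <- c(v$kind, kind); v$ref <- c(v$ref, ref)
  v$alt <- c(v$alt, alt); v$idx <- c(v$idx, idx)
  v
}

as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x)
  else if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]]
  else x
}

interval_regions <- function(m) {
  lapply(seq_len(nrow(m)), function(i) region(m[i, 1], m[i, 2]))
}

#' Serialize a panel back to the variant-table dialect
#'
#' Inverse of [parse_variant_table()] up to column choice: columns are the
#' union of variant keys in the panel (plus any requested extra positions),
#' in genomic order. Positions a haplotype does not cover are emitted blank.
#'
#' @param panel a [hap_panel()].
#' @param extra_positions additional np columns to include even if invariant.
#' @return character vector of tab-separated lines.
#' @export
write_variant_table <- function(panel, extra_positions = integer(0)) {
  vs <- lapply(panel$haplotypes, `[[`, "variants")
  all_v <- do.call(rbind, c(vs, list(variants())))
  cols <- unique(data.frame(pos = c(all_v$pos, as.integer(extra_positions)),
                            kind = c(ifelse(all_v$kind == "ins", "ins", "sub"),
                                     rep("sub", length(extra_positions))),
                            idx = c(all_v$ins_index, rep(1L, length(extra_positions)))))
  cols <- cols[order(cols$pos, cols$kind == "ins", cols$idx), , drop = FALSE]
  is_ins <- cols$kind == "ins"
  head_lab <- paste0(cols$pos, ifelse(is_ins,
                     ifelse(cols$idx == 1L, "i", paste0(".", cols$idx, "i")), ""))

  ## reference alleles: take from any variant record at that column
  ref_allele <- rep("-", nrow(cols))
  for (j in seq_len(nrow(cols))) {
    if (is_ins[j]) next
    hit <- all_v[all_v$pos == cols$pos[j] & all_v$kind != "ins", , drop = FALSE]
    ref_allele[j] <- if (nrow(hit)) hit$ref[1] else "N"
  }

  colkey <- paste0(cols$pos, ifelse(is_ins, paste0(".", cols$idx, "i"), "s"))
  lines <- c(paste(c("Sample ID", "Population", head_lab), collapse = "\t"),
             paste(c(panel$reference_label, "", ref_allele), collapse = "\t"))
  for (h in panel$haplotypes) {
    st <- state_map(h)
    del_keys <- sub("d$", "s", names(st)[key_kind(names(st)) == "del"])
    cell <- character(nrow(cols))
    for (j in seq_len(nrow(cols))) {
      if (!pos_in_intervals(cols$pos[j], h$covered)) { cell[j] <- ""; next }
      k <- colkey[j]
      cell[j] <- if (k %in% names(st)) st[[k]]
        else if (k %in% del_keys) "d"
        else "."
    }
    ## deletions live under substitution-style columns: patch symbol
    for (j in which(!is_ins)) {
      dk <- paste0(cols$pos[j], "d")
      if (dk %in% names(st)) cell[j] <- "d"
    }
    lines <- c(lines, paste(c(h$id, if (is.na(h$population)) "" else h$population,
                              cell), collapse = "\t"))
  }
  lines
}

#' Restrict a panel to a set of regions
#'
#' Variants outside the regions are dropped and per-haplotype coverage is
#' intersected with the regions (insertions follow their anchor np).
#' Haplotypes left with zero coverage are retained and flagged.
#'
#' @param panel a [hap_panel()].
#' @param regions non-empty list of [region()]s.
#' @return trimmed [hap_panel()]; zero-coverage haplotype ids are stored in
#'   `attr(, "flagged")`.
#' @export
trim_to_regions <- function(panel, regions) {
  regions <- as_region_list(regions)
  if (!length(regions)) stop("empty region list")
  rm_ <- normalise_intervals(region_mat(regions))
  haps <- lapply(panel$haplotypes, function(h) {
    cov <- intersect_intervals(h$covered, rm_)
    keep <- pos_in_intervals(h$variants$pos, cov)
    haplotype(h$id, h$variants[keep, , drop = FALSE],
              covered = if (nrow(cov)) interval_regions(cov) else list(),
              population = h$population)
  })
  out <- hap_panel(haps, panel$reference_label)
  attr(out, "flagged") <- names(out$haplotypes)[vapply(out$haplotypes,
                                                       hap_is_empty_coverage, logical(1))]
  out
}

#' Lossless panel serialization to JSON
#' @param panel a [hap_panel()].
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
panel_to_json <- function(panel, path = NULL) {
  obj <- list(reference_label = panel$reference_label,
              haplotypes = lapply(unname(panel$haplotypes), function(h)
                list(id = h$id, population = h$population,
                     variants = h$variants,
                     covered = as.data.frame(h$covered))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname panel_to_json
#' @param json JSON string or path produced by [panel_to_json()].
#' @export
panel_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  haps <- lapply(seq_len(length(obj$haplotypes$id)), function(i) {
    v <- obj$haplotypes$variants[[i]]
    cov <- obj$haplotypes$covered[[i]]
    haplotype(obj$haplotypes$id[i],
              if (length(v) && nrow(v)) variants(v$pos, v$kind, v$ref, v$alt, v$ins_index)
              else variants(),
              covered = if (length(cov) && nrow(cov))
                interval_regions(cbind(as.integer(cov[[1]]), as.integer(cov[[2]])))
                else list(),
              population = if (is.null(obj$haplotypes$population[i]) ||
                               is.na(obj$haplotypes$population[i])) NA_character_
                           else obj$haplotypes$population[i])
  })
  hap_panel(haps, obj$reference_label)
}

#' Reconstruct literal sequences and emit FASTA
#'
#' Applies each haplotype's variants to a supplied reference segment:
#' substitutions replace the base, deletions remove it, insertions are
#' inserted after their anchor np (ordered by insert index), and positions
#' outside the haplotype's coverage are emitted as `N`.
#'
#' @param panel a [hap_panel()].
#' @param reference_segment reference sequence of the region, as a single
#'   string of A/C/G/T with `nchar == region_length(region)`.
#' @param region a [region()] giving the rCRS span of `reference_segment`.
#' @return character vector of FASTA lines (two per haplotype).
#' @export
export_fasta <- function(panel, reference_segment, region) {
  region <- as_region_list(region)[[1]]
  refb <- strsplit(toupper(reference_segment), "")[[1]]
  if (length(refb) != region$end - region$start + 1L)
    stop("reference segment length must equal region length")
  out <- character(0)
  for (h in panel$haplotypes) {
    v <- h$variants
    if (nrow(v) && any(v$pos < region$start | v$pos > region$end))
      stop("haplotype ", h$id, ": variant outside the export region")
    pos_np <- region$start:region$end
    base <- refb
    base[!pos_in_intervals(pos_np, h$covered)] <- "N"
    keep <- rep(TRUE, length(base))
    ins_after <- vector("list", length(base))
    if (nrow(v)) for (r in seq_len(nrow(v))) {
      i <- v$pos[r] - region$start + 1L
      if (v$kind[r] == "sub") base[i] <- v$alt[r]
      else if (v$kind[r] == "del") keep[i] <- FALSE
      else ins_after[[i]] <- c(ins_after[[i]],
                               stats::setNames(v$alt[r], v$ins_index[r]))
    }
    seqc <- unlist(lapply(seq_along(base), function(i) {
      ins <- ins_after[[i]]
      c(if (keep[i]) base[i],
        if (!is.null(ins)) unname(ins[order(as.integer(names(ins)))]))
    }))
    out <- c(out, paste0(">", h$id), paste(seqc, collapse = ""))
  }
  out
}

#' Diff a literal sequence against a reference segment
#'
#' Base-by-base comparison for equal-length (substitution-only) sequences;
#' `N` positions are treated as missing and produce no variant.
#'
#' @param seq,ref equal-length sequence strings.
#' @param region the [region()] the segment spans.
#' @return variant data.frame of substitutions.
#' @export
diff_against_reference <- function(seq, ref, region) {
  region <- as_region_list(region)[[1]]
  s <- strsplit(toupper(seq), "")[[1]]; r <- strsplit(toupper(ref), "")[[1]]
  if (length(s) != length(r)) stop("sequences of unequal length (indels not supported here)")
  d <- which(s != r & s != "N")
  variants(region$start + d - 1L, rep("sub", length(d)), r[d], s[d])
}
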
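#' Build a variant table
#'
#' Variants are named relative to the rCRS. A variant is identified by the
#' key (position, kind, insert index); its state is the derived allele
#' (a base for substitutions and insertions, the symbol `d` for deletions).
#' Insertions are anchored: `310iC` means "insert C after np 310"; multiple
#' inserts after the same np are ordered by `ins_index`.
#'
#' @param pos integer vector of rCRS positions.
#' @param kind character vector, each `"sub"`, `"ins"` or `"del"`.
#' @param ref reference allele (one of ACGT for `sub`/`del`, `""` for `ins`).
#' @param alt derived allele (one of ACGT for `sub`/`ins`, `""` for `del`).
#' @param ins_index order among multiple inserts after the same np (1-based;
#'   ignored for non-insertions).
#' @return data.frame with columns `pos`, `kind`, `ins_index`, `ref`, `alt`.
#' @export
variants <- function(pos = integer(0), kind = character(0),
                     ref = character(0), alt = character(0),
                     ins_index = rep(1L, length(pos))) {
  df <- data.frame(pos = as.integer(pos), kind = as.character(kind),
                   ins_index = as.integer(ins_index),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  validate_variants(df)
  df
}

validate_variants <- function(df) {
  if (!nrow(df)) return(invisible(df))
  ok_kind <- df$kind %in% c("sub", "ins", "del")
  if (!all(ok_kind)) stop("variant kind must be sub/ins/del")
  if (any(df$pos < 1L | df$pos > RCRS_LENGTH)) stop("variant position outside rCRS")
  bases <- c("A", "C", "G", "T")
  sub <- df$kind == "sub"
  if (any(sub & (!df$ref %in% bases | !df$alt %in% bases)))
    stop("substitution alleles must be A/C/G/T")
  if (any(sub & df$ref == df$alt))
    stop("substitution with derived allele equal to reference")
  if (any(df$kind == "del" & df$alt != ""))
    stop("deletion must have empty derived allele")
  if (any(df$kind == "ins" & (df$ref != "" | !df$alt %in% bases)))
    stop("insertion must have empty ref and an A/C/G/T derived allele")
  df$ins_index[df$kind != "ins"] <- 1L
  key <- variant_keys(df)
  if (anyDuplicated(key)) stop("duplicate variant key: ",
                               paste(key[duplicated(key)], collapse = ", "))
  invisible(df)
}

#' Canonical key strings for a variant table
#'
#' `"195s"` (substitution at np 195), `"290d"` (deletion of np 290),
#' `"310.1i"` (first insertion after np 310).
#' @param v variant data.frame (see [variants()]).
#' @return character vector of keys.
#' @export
variant_keys <- function(v) {
  ifelse(v$kind == "sub", paste0(v$pos, "s"),
  ifelse(v$kind == "del", paste0(v$pos, "d"),
         paste0(v$pos, ".", v$ins_index, "i")))
}

## key -> derived state ("d" for deletions)
state_map <- function(h) {
  v <- h$variants
  if (!nrow(v)) return(stats::setNames(character(0), character(0)))
  stats::setNames(ifelse(v$kind == "del", "d", v$alt), variant_keys(v))
}

key_pos <- function(keys) as.integer(sub("[sd]$|\\.[0-9]+i$", "", keys))
key_kind <- function(keys) {
  ifelse(grepl("s$", keys), "sub", ifelse(grepl("d$", keys), "del", "ins"))
}

#' Construct a single haplotype
#'
#' @param id sample identifier (unique within a panel).
#' @param variants variant data.frame (see [variants()]).
#' @param covered list of [region()]s with data; positions outside are
#'   treated as missing. Defaults to the full rCRS.
#' @param population population identifier or `NA`.
#' @return object of class `haplotype`.
#' @export
haplotype <- function(id, variants = rhonet::variants(),
                      covered = region_preset("full"), population = NA_character_) {
  cov <- normalise_intervals(region_mat(covered))
  h <- structure(list(id = as.character(id),
                      population = as.character(population),
                      variants = variants,
                      covered = cov),
                 class = "haplotype")
  validate_haplotype(h)
  h
}

validate_haplotype <- function(h) {
  validate_variants(h$variants)
  if (nrow(h$variants)) {
    inside <- pos_in_intervals(h$variants$pos, h$covered)
    if (!all(inside))
      stop("haplotype ", h$id, ": variant at np ",
           paste(h$variants$pos[!inside], collapse = ","),
           " outside covered regions")
  }
  invisible(h)
}

hap_is_empty_coverage <- function(h) nrow(h$covered) == 0L

#' Assemble a haplotype panel
#'
#' @param haplotypes list of [haplotype()] objects with unique ids.
#' @param reference_label label of the reference row (fixed `"rCRS"`).
#' @return object of class `hap_panel`.
#' @export
hap_panel <- function(haplotypes, reference_label = "rCRS") {
  ids <- vapply(haplotypes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate haplotype ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(haplotypes) <- ids
  for (h in haplotypes) validate_haplotype(h)
  structure(list(haplotypes = haplotypes, reference_label = reference_label),
            class = "hap_panel")
}

#' @export
length.hap_panel <- function(x) length(x$haplotypes)

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype> %s%s: %d variant(s)", x$id,
              if (!is.na(x$population)) paste0(" [", x$population, "]") else "",
              nrow(x$variants)))
  if (nrow(x$variants)) {
    st <- state_map(x)
    cat(": ", paste0(sub("[s]$", "", names(st)),
                     ifelse(key_kind(names(st)) == "del", "d", st)), "\n")
  } else cat("\n")
  if (nrow(x$covered) == 0L) cat("  (no covered data)\n")
  invisible(x)
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotype(s) vs %s\n", length(x), x$reference_label))
  nv <- vapply(x$haplotypes, function(h) nrow(h$variants), integer(1))
  cat(sprintf("  variants per haplotype: median %s, range %s-%s\n",
              stats::median(nv), min(nv), max(nv)))
  flagged <- vapply(x$haplotypes, hap_is_empty_coverage, logical(1))
  if (any(flagged))
    cat("  flagged (zero coverage):", paste(names(flagged)[flagged], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hap_panel <- function(object, ...) {
  sm <- lapply(object$haplotypes, state_map)
  sig <- vapply(sm, function(s) paste(sort(paste0(names(s), "=", s)), collapse = ";"),
                character(1))
  pops <- vapply(object$haplotypes, `[[`, character(1), "population")
  out <- list(n = length(object), n_distinct = length(unique(sig)),
              n_populations = length(unique(pops[!is.na(pops)])),
              segregating_keys = sort(unique(unlist(lapply(sm, names)))))
  class(out) <- "summary.hap_panel"
  out
}

#' @export
print.summary.hap_panel <- function(x, ...) {
  cat(sprintf("haplotype panel: %d sequences, %d distinct, %d population(s)\n",
              x$n, x$n_distinct, x$n_populations))
  cat(sprintf("  %d segregating variant key(s)\n", length(x$segregating_keys)))
  invisible(x)
}

#' Parse a root-motif specification
#'
#' Accepts tokens in the conventional shorthand: `"16051G"` (substitution to
#' G at np 16051), `"249d"` (deletion), `"310.1iC"` or `"310iC"` (insertion
#' of C after np 310).
#'
#' @param tokens character vector of motif tokens.
#' @param ref named character vector of reference alleles per position
#'   (required only for substitution tokens whose ref allele matters for
#'   FASTA export; defaults to `"N"` placeholders).
#' @return variant data.frame as from [variants()].
#' @export
parse_motif <- function(tokens, ref = NULL) {
  if (!length(tokens)) return(variants())
  m_del <- grepl("^[0-9]+d$", tokens)
  m_ins <- grepl("^[0-9]+(\\.[0-9]+)?i[ACGT]$", tokens)
  m_sub <- grepl("^[0-9]+[ACGT]$", tokens)
  if (!all(m_del | m_ins | m_sub))
    stop("cannot parse motif token(s): ",
         paste(tokens[!(m_del | m_ins | m_sub)], collapse = ", "))
  pos <- as.integer(sub("^([0-9]+).*$", "\\1", tokens))
  kind <- ifelse(m_del, "del", ifelse(m_ins, "ins", "sub"))
  alt <- ifelse(m_del, "", sub("^.*([ACGT])$", "\\1", tokens))
  idx <- ifelse(grepl("\\.[0-9]+i", tokens),
                as.integer(sub("^[0-9]+\\.([0-9]+)i.*$", "\\1", tokens)), 1L)
  rf <- ifelse(kind == "ins", "",
               if (is.null(ref)) synthetic_ref_base(pos) else unname(ref[as.character(pos)]))
  ## a stated ref equal to the derived allele would be invalid; fall back
  bad <- kind == "sub" & rf == alt
  rf[bad] <- vapply(alt[bad], function(a) setdiff(c("A", "C", "G", "T"), a)[1], character(1))
  variants(pos, kind, rf, alt, idx)
}
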
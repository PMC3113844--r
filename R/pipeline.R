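#' Read a run configuration (JSON or YAML)
#'
#' A run configuration is a plain list of the arguments understood by the
#' `run_*` functions (input paths, region and exclusion preset names, rate
#' settings, root motif, seed, output directory). JSON is read with
#' jsonlite; `.yml`/`.yaml` files require the yaml package.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

resolve_exclusions <- function(preset, regions) {
  excl <- switch(preset,
    none = NULL,
    network = if (identical(region_mat(regions), region_mat(region_preset("hvr1_315"))))
        builtin_exclusions("network_hvr1")
      else combine_exclusions(builtin_exclusions("network_hvr1"),
                              builtin_exclusions("network_hvr2_extra")),
    rho = builtin_exclusions("rho_fast_sites"),
    stop("unknown exclusion preset '", preset, "'"))
  if (is.null(excl)) NULL else suppressWarnings(restrict_exclusions(excl, regions))
}

load_panel <- function(panel) {
  if (inherits(panel, "hap_panel")) return(panel)
  parse_variant_table(panel)
}

#' Run the network stage of the pipeline
#'
#' Parses (or accepts) a panel, trims it to a region preset, builds the
#' weighted median-joining network, extracts the maximum-parsimony trees,
#' and reports back-mutation counts with and without the hotspot exclusion
#' set. Output files (edge list TSV, GraphML, DOT, a summary TSV) are
#' written when `out_dir` is given.
#'
#' @param panel a [hap_panel()] or a path to a variant-table TSV.
#' @param regions region preset name (`"hvr1_315"`, `"hvr1_hvr2"`) or a
#'   region list.
#' @param exclusions `"network"`, `"rho"` or `"none"`.
#' @param rates a [site_rates()] table, a path to one, or `NULL` for the
#'   synthetic default.
#' @param epsilon weighted network tolerance.
#' @param annotate_pos np whose allele fractions annotate nodes (e.g. a
#'   diagnostic coding-region position typed outside the sequenced window);
#'   `NULL` to skip.
#' @param out_dir output directory or `NULL`.
#' @param size_cap exact MP search cap, see [mp_extract()].
#' @return list with `network`, `mp` (trees, pruned, n_trees),
#'   `back_mutations` (named: with/without exclusions), invisibly.
#' @export
run_network <- function(panel, regions = "hvr1_315", exclusions = "network",
                        rates = NULL, epsilon = 0L, annotate_pos = NULL,
                        out_dir = NULL, size_cap = 25L) {
  full_panel <- load_panel(panel)
  if (!length(full_panel$haplotypes)) stop("empty panel")
  reg <- if (is.character(regions)) region_preset(regions) else as_region_list(regions)
  if (is.character(rates)) rates <- read_site_rates(rates)
  if (is.null(rates)) rates <- synthetic_site_rates(reg)
  trimmed <- trim_to_regions(full_panel, reg)
  ws <- weight_scheme(rates)
  excl <- if (is.character(exclusions)) resolve_exclusions(exclusions, reg) else exclusions

  run_one <- function(ex) {
    net <- build_mj(trimmed, mj_params(epsilon, ws, ex))
    mp <- mp_extract(net, size_cap = size_cap)
    bm <- vapply(mp$trees, count_back_mutations, integer(1))
    list(net = net, mp = mp, back = if (length(bm)) min(bm) else NA_integer_)
  }
  with_ex <- run_one(excl)
  without_ex <- if (is.null(excl)) with_ex else run_one(NULL)

  net <- with_ex$net
  if (!is.null(annotate_pos))
    net <- annotate_state_fractions(net, full_panel, annotate_pos)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_edge_tsv(net, file.path(out_dir, "network_edges.tsv"))
    export_graphml(net, file.path(out_dir, "network.graphml"))
    export_dot(net, file.path(out_dir, "network.dot"), annotate_pos)
    utils::write.table(
      data.frame(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
                 n_mp_trees = with_ex$mp$n_trees,
                 mp_length = if (length(with_ex$mp$trees))
                   with_ex$mp$trees[[1]]$total_weighted_length else NA,
                 back_mutations_excluded = with_ex$back,
                 back_mutations_raw = without_ex$back),
      file.path(out_dir, "network_summary.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(network = net, mp = with_ex$mp,
                 back_mutations = c(with_exclusions = with_ex$back,
                                    without_exclusions = without_ex$back)))
}

#' Run the dating stage of the pipeline
#'
#' Dates one or more root lineages on an MP tree under one or more rate
#' conventions, mirroring the usual results-table layout (one row per
#' lineage x rate with rho, sigma, TMRCA and its standard error).
#'
#' @param tree an `mp_tree` (e.g. from [run_network()]'s `mp$trees[[1]]`
#'   or [star_tree()]).
#' @param root_motifs named list of motif token vectors; names label the
#'   rows.
#' @param rate_cfgs list of [rate_config()]s.
#' @param populations optional character vector: restrict the dating to
#'   tips sampled from these populations (the tree is rebuilt is not
#'   attempted; sampled multiplicities are re-derived from the panel), via
#'   `panel`.
#' @param panel panel used to re-derive multiplicities when `populations`
#'   is given.
#' @param out_file TSV path or `NULL`.
#' @return data.frame with columns lineage, rate, rho, sigma, n_tips,
#'   tmrca_years, delta_t_years.
#' @export
run_date <- function(tree, root_motifs, rate_cfgs, populations = NULL,
                     panel = NULL, out_file = NULL) {
  if (!is.null(populations)) {
    if (is.null(panel)) stop("population filtering requires the panel")
    keep <- vapply(panel$haplotypes, function(h)
      !is.na(h$population) && h$population %in% populations, logical(1))
    sub <- hap_panel(panel$haplotypes[keep], panel$reference_label)
    if (!length(sub$haplotypes)) stop("no haplotypes from the requested populations")
    tree <- retally_tree(tree, sub)
  }
  rows <- list()
  for (nm in names(root_motifs)) for (cfg in rate_cfgs) {
    dr <- date_lineage(tree, root_motifs[[nm]], cfg, lineage = nm)
    rows[[length(rows) + 1L]] <- as.data.frame(dr)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_file))
    utils::write.table(out, out_file, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

## recompute node multiplicities/membership from a (sub)panel
retally_tree <- function(tree, panel) {
  sigs <- vapply(panel$haplotypes, hap_signature, character(1))
  tree$nodes <- lapply(tree$nodes, function(nd) {
    hit <- names(sigs)[sigs == hap_signature(nd$hap)]
    nd$members <- hit
    nd$multiplicity <- length(hit)
    nd$sampled <- length(hit) > 0L
    nd
  })
  tree
}

#' Run the geographic-dispersion stage of the pipeline
#'
#' Builds lineage occurrence records from the panel and compares the
#' pooled interpopulation distances of two lineage classes (ancestral vs
#' derived by default; set `by_state_at` to compare the carriers of the
#' alleles at one position).
#'
#' @param panel a [hap_panel()] (with population ids) or a TSV path.
#' @param sites a [population_sites()] table or TSV path.
#' @param root_motif motif tokens defining the ancestral lineage.
#' @param by_state_at optional np for allele-defined classes.
#' @param classes the two class labels to compare (defaults to
#'   ancestral/derived, or the two most frequent states when
#'   `by_state_at` is given).
#' @param out_file TSV path or `NULL`.
#' @return list with `occurrences`, per-class summaries, and `test` (a
#'   `geo_test` or `NULL`).
#' @export
run_geo <- function(panel, sites, root_motif, by_state_at = NULL,
                    classes = NULL, out_file = NULL) {
  panel <- load_panel(panel)
  if (is.character(sites)) sites <- read_population_sites(sites)
  occ <- classify_lineages(panel, root_motif, by_state_at)
  if (is.null(occ) || !nrow(occ)) stop("no classifiable haplotypes (missing population ids?)")
  if (is.null(classes)) {
    classes <- if (is.null(by_state_at)) c("ancestral", "derived")
               else names(sort(table(occ$class), decreasing = TRUE))[1:2]
  }
  s1 <- lineage_distances(occ, sites, classes[1])
  s2 <- lineage_distances(occ, sites, classes[2])
  test <- if (length(s1$distances) && length(s2$distances))
    mann_whitney(s1$distances, s2$distances) else {
      warning("test skipped: a class has no interpopulation distances")
      NULL
    }
  if (!is.null(out_file)) {
    df <- data.frame(class = classes,
                     n_distances = c(length(s1$distances), length(s2$distances)),
                     mean_km = c(s1$mean_km, s2$mean_km),
                     frac_below_1000km = c(s1$frac_below_1000km, s2$frac_below_1000km),
                     U = if (is.null(test)) NA else test$U,
                     Z = if (is.null(test)) NA else test$Z,
                     p = if (is.null(test)) NA else test$p)
    utils::write.table(df, out_file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(occurrences = occ, summary1 = s1, summary2 = s2,
       classes = classes, test = test)
}

#' Simulate a panel and write it in pipeline-readable form
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory; the variant table, coordinates TSV and
#'   the simulation truth (JSON) are written there.
#' @return the simulation (list `panel`, `sites`, `truth`), invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  sim <- simulate_panel(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bounds <- as.vector(region_mat(cfg$regions)) # boundary columns preserve
  writeLines(write_variant_table(sim$panel, extra_positions = bounds),
             file.path(out_dir, "panel.tsv"))  # region-wide missingness
  utils::write.table(data.frame(population_id = sim$sites$id,
                                lat = sim$sites$lat, lon = sim$sites$lon,
                                label = sim$sites$label),
                     file.path(out_dir, "coordinates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- unclass(sim$truth)
  truth$hit_counts <- NULL # large; per-tip totals suffice downstream
  truth$tree <- NULL
  truth$n_mutations <- as.integer(rowSums(sim$truth$hit_counts %% 2L == 1L))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
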
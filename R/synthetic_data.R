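#' Synthetic reference alleles
#'
#' The generator works against a synthetic reference: the base at np is a
#' fixed function of the position, and each site mutates by toggling
#' between the reference base and its transition partner (A<->G, C<->T),
#' which is what produces back mutations at repeatedly hit sites.
#'
#' @param pos integer positions.
#' @return reference base(s).
#' @export
synthetic_ref_base <- function(pos) c("A", "C", "G", "T")[(pos %% 4L) + 1L]

transition_partner <- function(base) c(A = "G", C = "T", G = "A", T = "C")[base]

#' Default root motif for simulated panels
#'
#' A control-region-style founder motif: the classic C1d-like combination
#' of two HVR-II and five HVR-I substitutions (np 73, 194, 263, 16051,
#' 16223, 16298, 16325, 16327), restricted to the simulated regions, with
#' derived alleles taken as the transition partner of the synthetic
#' reference.
#'
#' @param regions simulated region list.
#' @return character vector of motif tokens.
#' @export
default_root_motif <- function(regions = region_preset("hvr1_hvr2")) {
  pos <- c(73L, 194L, 263L, 16051L, 16223L, 16298L, 16325L, 16327L)
  pos <- pos[pos_in_intervals(pos, region_mat(as_region_list(regions)))]
  paste0(pos, transition_partner(synthetic_ref_base(pos)))
}

#' Simulation configuration
#'
#' Defaults emulate a literature-compiled control-region panel: 170
#' sequences over the joint HVR-I+II window of which roughly 40% lack
#' HVR-II data, descending from a single founder motif on a star
#' (expansion) genealogy of root age 300 generations, mutated site-by-site
#' under heterogeneous relative rates with a minority of hotspot sites
#' 3-6x above average, and sampled from populations on a continent-scale
#' coordinate grid on which carriers of any one derived lineage are
#' geographically more clustered (dispersal sigma 800 km) than carriers of
#' the ancestral motif (2000 km). Lineage identity for the dispersal model
#' is the haplotype observed in the standard 315-bp HVR-I window (np
#' 16051-16365), the window in which compiled panels are comparable and in
#' which the downstream dispersion analysis pools lineages. A Yule
#' genealogy is available for structured (non-expansion) scenarios.
#'
#' @param n_tips number of sampled sequences.
#' @param genealogy_model `"star"` or `"yule"`.
#' @param T_true root age in generations.
#' @param mu mutations/base/million generations (the genealogical rate
#'   convention used for simulation).
#' @param per_site_rates a [site_rates()] table of relative rates.
#' @param regions simulated regions.
#' @param root_motif motif tokens (see [parse_motif()]).
#' @param n_populations number of population sites on the grid.
#' @param dispersal_sigma_ancestral,dispersal_sigma_derived dispersal
#'   standard deviations, km.
#' @param missing_hvr2_fraction fraction of tips lacking HVR-II coverage.
#' @param seed integer seed governing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 170L, genealogy_model = c("star", "yule"),
                       T_true = 300, mu = 11.7,
                       per_site_rates = NULL,
                       regions = region_preset("hvr1_hvr2"),
                       root_motif = default_root_motif(regions),
                       n_populations = 60L,
                       dispersal_sigma_ancestral = 2000,
                       dispersal_sigma_derived = 800,
                       missing_hvr2_fraction = 0.4,
                       seed = 1L) {
  genealogy_model <- match.arg(genealogy_model)
  regions <- as_region_list(regions)
  if (is.null(per_site_rates)) per_site_rates <- synthetic_site_rates(regions)
  stopifnot(n_tips >= 1L, T_true >= 0, mu >= 0, n_populations >= 1L,
            dispersal_sigma_ancestral > 0, dispersal_sigma_derived > 0,
            missing_hvr2_fraction >= 0, missing_hvr2_fraction <= 1)
  if (!region_length(regions)) stop("degenerate configuration: no sites to mutate")
  structure(list(n_tips = as.integer(n_tips), genealogy_model = genealogy_model,
                 T_true = T_true, mu = mu, per_site_rates = per_site_rates,
                 regions = regions, root_motif = root_motif,
                 n_populations = as.integer(n_populations),
                 dispersal_sigma_ancestral = dispersal_sigma_ancestral,
                 dispersal_sigma_derived = dispersal_sigma_derived,
                 missing_hvr2_fraction = missing_hvr2_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## continent-scale sampling frame (Americas-like bounding box)
SIM_BOX <- list(lat = c(-55, 55), lon = c(-130, -35))

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  expr
}

#' Simulate a haplotype panel with geography
#'
#' Draws a genealogy of root age `T_true`, places mutations site-by-site
#' as Poisson processes with intensity `mu * 1e-6 * relative_rate` per
#' generation (recurrent hits toggle the state, so hotspot sites generate
#' back/parallel mutations), removes HVR-II coverage from a configured
#' fraction of tips, assigns tips to populations on a coordinate grid with
#' class-specific dispersal, and emits the panel in the same representation
#' the real pipeline reads.
#'
#' @param cfg a [sim_config()].
#' @return list with `panel` (a [hap_panel()]), `sites` (a
#'   [population_sites()] table) and `truth` (a `sim_truth` list: the
#'   genealogy model, true root age, per-tip hit counts per site,
#'   population assignments and lineage classes).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- region_mat(cfg$regions)
    pos <- sort(unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1]:m[i, 2])))
    rel <- rep(1, length(pos))
    hit_idx <- match(pos, cfg$per_site_rates$pos)
    rel[!is.na(hit_idx)] <- cfg$per_site_rates$rate[hit_idx[!is.na(hit_idx)]]
    lam <- cfg$mu * 1e-6 * rel           # per site per generation
    n <- cfg$n_tips

    motif_v <- parse_motif(cfg$root_motif)
    if (any(!motif_v$pos %in% pos)) stop("root motif outside simulated regions")
    root_tog <- pos %in% motif_v$pos[motif_v$kind == "sub"]

    if (cfg$genealogy_model == "star") {
      hits <- matrix(stats::rpois(n * length(pos), rep(lam * cfg$T_true, each = n)),
                     nrow = n)
      tree <- "star"
    } else {
      tree <- ape::reorder.phylo(ape::rphylo(n, birth = 1, death = 0), "cladewise")
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length / depth * cfg$T_true
      ne <- nrow(tree$edge)
      ehits <- matrix(stats::rpois(ne * length(pos),
                                   rep(lam, each = ne) * tree$edge.length),
                      nrow = ne)
      ## accumulate hits root -> tip; cladewise edge order is a preorder, so
      ## each edge's parent row has already been filled
      nn <- max(tree$edge)
      acc <- matrix(0L, nn, length(pos))
      for (k in seq_len(ne)) {
        acc[tree$edge[k, 2], ] <- acc[tree$edge[k, 1], ] + ehits[k, ]
      }
      hits <- acc[seq_len(n), , drop = FALSE]
    }
    tog <- sweep(hits %% 2L == 1L, 2, root_tog, FUN = "xor")

    ids <- sprintf("T%03d", seq_len(n))
    n_missing <- round(cfg$missing_hvr2_fraction * n)
    hvr2_rows <- which(m[, 2] < 16000L)
    missing_tips <- if (length(hvr2_rows) && n_missing > 0)
      sort(sample.int(n, n_missing)) else integer(0)

    ## geography ------------------------------------------------------------
    grid <- population_sites(sprintf("P%02d", seq_len(cfg$n_populations)),
                             stats::runif(cfg$n_populations, SIM_BOX$lat[1], SIM_BOX$lat[2]),
                             stats::runif(cfg$n_populations, SIM_BOX$lon[1], SIM_BOX$lon[2]))
    ## lineage identity for dispersal: the HVR-I-window haplotype
    geo_win <- pos >= 16051L & pos <= 16365L
    if (!any(geo_win)) geo_win <- rep(TRUE, length(pos))
    sig <- apply(tog[, geo_win, drop = FALSE], 1,
                 function(x) paste(which(x), collapse = ","))
    root_sig <- paste(which(root_tog[geo_win]), collapse = ",")
    classes <- ifelse(sig == root_sig, "ancestral", "derived")
    centers <- list()
    centers[[root_sig]] <- c(mean(SIM_BOX$lat), mean(SIM_BOX$lon))
    tip_pop <- character(n)
    for (i in seq_len(n)) {
      s <- sig[i]
      if (is.null(centers[[if (nzchar(s)) s else "(root)"]])) {
        centers[[if (nzchar(s)) s else "(root)"]] <-
          c(stats::runif(1, SIM_BOX$lat[1], SIM_BOX$lat[2]),
            stats::runif(1, SIM_BOX$lon[1], SIM_BOX$lon[2]))
      }
      ctr <- centers[[if (nzchar(s)) s else "(root)"]]
      sd_km <- if (classes[i] == "ancestral") cfg$dispersal_sigma_ancestral
               else cfg$dispersal_sigma_derived
      lat <- ctr[1] + stats::rnorm(1, 0, sd_km / 111.32)
      lon <- ctr[2] + stats::rnorm(1, 0, sd_km / (111.32 * max(cos(ctr[1] * pi / 180), 0.2)))
      lat <- min(max(lat, SIM_BOX$lat[1]), SIM_BOX$lat[2])
      lon <- min(max(lon, SIM_BOX$lon[1]), SIM_BOX$lon[2])
      tip_pop[i] <- grid$id[which.min(haversine_km(lat, lon, grid$lat, grid$lon))]
    }

    ## assemble haplotypes ---------------------------------------------------
    haps <- vector("list", n)
    for (i in seq_len(n)) {
      cov <- m
      if (i %in% missing_tips) cov <- m[-hvr2_rows, , drop = FALSE]
      p <- pos[tog[i, ]]
      p <- p[pos_in_intervals(p, cov)]
      rf <- synthetic_ref_base(p)
      haps[[i]] <- haplotype(ids[i],
                             variants(p, rep("sub", length(p)), rf,
                                      transition_partner(rf)),
                             covered = interval_regions(cov),
                             population = tip_pop[i])
    }
    panel <- hap_panel(haps)
    truth <- structure(list(model = cfg$genealogy_model, tree = tree,
                            true_T = cfg$T_true,
                            hit_counts = hits, site_pos = pos,
                            tip_ids = ids, tip_populations = tip_pop,
                            tip_classes = classes,
                            missing_hvr2 = ids[missing_tips],
                            root_motif = cfg$root_motif),
                       class = "sim_truth")
    list(panel = panel, sites = grid, truth = truth)
  })
}

#' Occurrence records straight from a simulation
#'
#' Convenience wrapper: classifies the simulated panel against the
#' configured root motif (see [classify_lineages()]).
#'
#' @param sim result of [simulate_panel()].
#' @return occurrence data.frame.
#' @export
sim_occurrences <- function(sim) {
  classify_lineages(sim$panel, sim$truth$root_motif)
}

#' Coverage of the true age by rho-based confidence intervals
#'
#' Runs the dating pipeline end-to-end on `n_reps` independently simulated
#' star panels (star genealogies make the expectation of rho exact):
#' simulate, connect every haplotype to the known founder motif
#' ([star_tree()]), compute rho, its Saillard variance and the TMRCA under
#' `rate_cfg`, and record whether `T_hat +/- 2 dT` covers the truth.
#' Replicate `r` uses `seed + r`.
#'
#' @param cfg a [sim_config()] with `genealogy_model = "star"`.
#' @param rate_cfg a genealogical [rate_config()]; its `L` must match the
#'   simulated region length.
#' @param n_reps number of replicates.
#' @return list with `coverage`, `n_reps`, and a per-replicate data.frame
#'   `results` (`rho`, `sigma`, `tmrca_years`, `delta_t_years`, `covered`).
#' @export
recovery_experiment <- function(cfg, rate_cfg, n_reps = 200L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(rate_cfg, "rate_config"))
  if (cfg$genealogy_model != "star")
    stop("recovery_experiment requires a star genealogy")
  if (rate_cfg$mode != "genealogical")
    stop("recovery_experiment requires a genealogical rate convention")
  truth_years <- cfg$T_true * rate_cfg$generation_years
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    sim <- simulate_panel(cfg_r)
    tr <- star_tree(sim$panel, cfg$root_motif)
    rs <- rho_stat(tr, "root", rate_cfg$site_exclusions)
    s2 <- saillard_variance(tr, "root", rate_cfg$site_exclusions)
    dr <- tmrca(rs$rho, sqrt(s2), rate_cfg, rs$n_tips)
    covered <- !is.na(dr$delta_t_years) &&
      abs(dr$tmrca_years - truth_years) <= 2 * dr$delta_t_years
    rows[[r]] <- data.frame(rep = r, rho = dr$rho, sigma = dr$sigma,
                            tmrca_years = dr$tmrca_years,
                            delta_t_years = dr$delta_t_years, covered = covered)
  }
  results <- do.call(rbind, rows)
  list(coverage = mean(results$covered), n_reps = n_reps,
       truth_years = truth_years, results = results)
}
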
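test_that("rho equals the mean root-to-tip mutation count", {
  # star: n tips one mutation away -> rho = 1 whatever n
  for (n in c(2, 5, 9)) {
    st <- star_tree(mk_panel(vapply(seq_len(n), function(i)
      paste0(c(rep("A", i - 1), "G", rep("A", n - i)), collapse = ""),
      character(1))), character(0))
    rs <- rho_stat(st)
    expect_equal(rs$rho, 1)
    expect_equal(rs$n_tips, n)
  }
  # mixed depths: two tips at 1, two at 3 -> (1+1+3+3)/4 = 2
  tmix <- mk_tree(c(r = NA, a = 1L, b = 1L, c = 1L, d = 1L),
                  rep("r", 4), c("a", "b", "c", "d"),
                  list("101s", "102s", c("103s", "104s", "105s"),
                       c("106s", "107s", "108s")), root = "r")
  expect_equal(rho_stat(tmix)$rho, 2)
  # serial path r - a - b: (1 + 2) / 2 = 1.5
  tpath <- mk_tree(c(r = NA, a = 1L, b = 1L), c("r", "a"), c("a", "b"),
                   list("101s", "102s"), root = "r")
  expect_equal(rho_stat(tpath)$rho, 1.5)
  # multiplicities weight the average
  tw <- mk_tree(c(r = NA, a = 3L, b = 1L), c("r", "r"), c("a", "b"),
                list("101s", c("102s", "103s")), root = "r")
  expect_equal(rho_stat(tw)$rho, (3 * 1 + 1 * 2) / 4)
  expect_error(rho_stat(tpath, root = "zz"), "not a node")
})

test_that("excluded sites drop out of path mutation counts", {
  tr <- mk_tree(c(r = NA, a = 1L), "r", "a",
                list(c("16093s", "101s", "310.1i")), root = "r")
  expect_equal(rho_stat(tr)$rho, 3)
  expect_equal(rho_stat(tr, exclusions = exclusion_set(16093))$rho, 2)
  expect_equal(rho_stat(tr, exclusions = exclusion_set(16093, "all"))$rho, 1)
})

test_that("the Saillard variance matches its closed forms", {
  # star with n unit tips: sigma^2 = 1/n
  for (n in c(2, 4, 7)) {
    st <- star_tree(mk_panel(vapply(seq_len(n), function(i)
      paste0(c(rep("A", i - 1), "G", rep("A", n - i)), collapse = ""),
      character(1))), character(0))
    expect_equal(saillard_variance(st), 1 / n)
  }
  # single tip k mutations away: sigma^2 = k
  t1 <- mk_tree(c(r = NA, a = 1L), "r", "a",
                list(c("101s", "102s", "103s")), root = "r")
  expect_equal(saillard_variance(t1), 3)
  # zero-mutation tree (tip folded into root): sigma^2 = 0 and rho = 0
  t0 <- star_tree(mk_panel(c("AA", "AA")), character(0))
  expect_equal(saillard_variance(t0), 0)
  expect_equal(rho_stat(t0)$rho, 0)
})

test_that("rho on the tree equals direct root mismatches without back mutations", {
  # property over simulated panels whose sites mutated at most once
  found <- 0L; seed <- 0L
  while (found < 60L && seed < 400L) {
    seed <- seed + 1L
    cfg <- sim_config(n_tips = 3L + (seed %% 18L), genealogy_model = "star",
                      T_true = 250, regions = region_preset("hvr1_315"),
                      missing_hvr2_fraction = 0, n_populations = 5L,
                      seed = 6000L + seed)
    sim <- simulate_panel(cfg)
    if (any(colSums(sim$truth$hit_counts) > 1L)) next  # recurrence: skip
    found <- found + 1L
    st <- star_tree(sim$panel, cfg$root_motif)
    expect_equal(rho_stat(st, mode = "path")$rho,
                 rho_stat(st, mode = "mismatch")$rho)
  }
  expect_gte(found, 50L)
})

test_that("TMRCA conversion follows the linear rate laws", {
  cfg <- rate_genealogical(L = 315)
  d <- tmrca(1.484, 0.513, cfg)
  # closed form: rho / (L mu 1e-6) generations x 25 yr
  expect_equal(d$tmrca_years, 1.484 / (315 * 11.7e-6) * 25)
  expect_equal(d$delta_t_years / d$tmrca_years, d$sigma / d$rho)
  # doubling L halves the age exactly
  d2 <- tmrca(1.484, 0.513, rate_genealogical(L = 630))
  expect_equal(d2$tmrca_years * 2, d$tmrca_years)
  # phylogenetic mode converts straight to years
  dp <- tmrca(1, 0.5, rate_phylogenetic(L = 315))
  expect_equal(dp$tmrca_years, 1 / (315 * 9.883e-2 * 1e-6))
  # rho = 0: age 0, undefined standard error
  d0 <- tmrca(0, 0, cfg)
  expect_equal(d0$tmrca_years, 0)
  expect_true(is.na(d0$delta_t_years))
  # generation span scales genealogical ages linearly
  d30 <- tmrca(1.484, 0.513, rate_genealogical(L = 315, generation_years = 30))
  expect_equal(d30$tmrca_years / d$tmrca_years, 30 / 25)
})

test_that("date_lineage roots at the motif node and restricts to subtrees", {
  # root + two tips; dating from the overall root reproduces rho_stat
  p <- mk_panel(c("GA", "GG", "GC"))        # shared 101G motif
  st <- star_tree(p, "101G")
  cfg <- rate_genealogical(L = 315)
  d <- date_lineage(st, "101G", cfg)
  rs <- rho_stat(st)
  expect_equal(d$rho, rs$rho)
  expect_equal(d$n_tips, rs$n_tips)
  # sub-root with one descendant two mutations away: rho = 2, sigma = sqrt(2)
  tsub <- mk_tree(c(r = NA, m = NA, x = 1L, o = 1L),
                  c("r", "m", "r"), c("m", "x", "o"),
                  list("101s", c("102s", "103s"), "104s"), root = "r")
  tsub$nodes[[2]]$hap <- haplotype("m", variants(101, "sub", "A", "G"))
  d2 <- date_lineage(tsub, "101G", cfg)
  expect_equal(d2$rho, 2)
  expect_equal(d2$sigma, sqrt(2))
  expect_equal(d2$n_tips, 1)
  # unmatched and ambiguous motifs raise informative errors
  expect_error(date_lineage(st, "105G", cfg), "no node matches")
  tdup <- star_tree(mk_panel(c("GA", "GG")), character(0))
  expect_error(date_lineage(tdup, character(0), cfg), NA)
})

test_that("population-filtered dating differs only through the tip subset", {
  cfg0 <- sim_config(n_tips = 40L, genealogy_model = "star", T_true = 300,
                     regions = region_preset("hvr1_315"),
                     missing_hvr2_fraction = 0, n_populations = 4L, seed = 99L)
  sim <- simulate_panel(cfg0)
  st <- star_tree(sim$panel, cfg0$root_motif)
  rcfg <- rate_genealogical(L = 315)
  full <- run_date(st, list(root = cfg0$root_motif), list(rcfg))
  pops <- unique(sim$truth$tip_populations)[1:2]
  sub <- run_date(st, list(root = cfg0$root_motif), list(rcfg),
                  populations = pops, panel = sim$panel)
  keep <- sim$truth$tip_populations %in% pops
  expect_equal(sub$n_tips, sum(keep))
  # recomputing rho directly over the kept tips agrees
  manual <- mean(rowSums(sim$truth$hit_counts[keep, ] %% 2L == 1L))
  expect_equal(sub$rho, manual)
  expect_false(isTRUE(all.equal(sub$rho, full$rho)))
})
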
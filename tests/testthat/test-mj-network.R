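test_that("the minimum-spanning network reproduces small closed-form cases", {
  # two single-step neighbours of AA: a star with 2 unit edges
  n3 <- build_msn(mk_panel(c("AA", "AG", "GA")))
  expect_equal(nrow(n3$edges), 2L)
  expect_setequal(paste(n3$edges$from, n3$edges$to),
                  c("H01 H02", "H01 H03"))
  # four haplotypes at the corners of a square: the 4-cycle of unit links
  n4 <- build_msn(mk_panel(c("AA", "AG", "GA", "GG")))
  expect_equal(nrow(n4$edges), 4L)
  expect_true(all(n4$edges$weight == 1))
  expect_setequal(paste(n4$edges$from, n4$edges$to),
                  c("H01 H02", "H01 H03", "H02 H04", "H03 H04"))
  # identical haplotypes collapse into one multi-sequence node
  n1 <- build_msn(mk_panel(c("AG", "AG", "AG")))
  expect_length(n1$nodes, 1L)
  expect_equal(n1$nodes[[1]]$multiplicity, 3L)
  expect_equal(nrow(n1$edges), 0L)
})

test_that("the HVR-I network links the ancestral motif to each derived lineage", {
  p <- trim_to_regions(parse_variant_table(uruguay_panel_path()),
                       region_preset("hvr1_315"))
  net <- build_msn(p, mj_params())
  ids <- vapply(net$nodes, `[[`, character(1), "id")
  # KP079 carries the bare ancestral motif and collapses with KC049/KC161/KC163
  anc <- ids[vapply(net$nodes, function(nd) "KC049" %in% nd$members, logical(1))]
  expect_length(anc, 1L)
  expect_equal(net$nodes[[match(anc, ids)]]$multiplicity, 4L)
  # every other node is reachable, and the motif node touches unit edges
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = ids))
  expect_equal(igraph::components(g)$no, 1L)
  expect_true(anc %in% c(net$edges$from, net$edges$to))
})

test_that("median vectors are added only when they shorten the network", {
  # triplet whose majority consensus is already sampled: no new node
  nm <- build_mj(mk_panel(c("AAA", "AAG", "AGG")))
  expect_length(nm$nodes, 3L)
  # three haplotypes pairwise two steps apart: Steiner point CCT appears
  nS <- build_mj(mk_panel(c("CCC", "CTT", "TCT")))
  expect_length(nS$nodes, 4L)
  med <- Filter(function(nd) !nd$sampled, nS$nodes)
  expect_length(med, 1L)
  expect_equal(med[[1]]$multiplicity, 0L)
  expect_equal(rhonet:::hap_signature(med[[1]]$hap), "101s=C;102s=C;103s=T")
  expect_equal(nrow(nS$edges), 3L)
  expect_true(all(nS$edges$weight == 1))
  # all medians of the 4-cycle are sampled at epsilon = 0: nothing added
  expect_length(build_mj(mk_panel(c("AA", "AG", "GA", "GG")))$nodes, 4L)
})

test_that("median-joining networks span the MSN links of the sampled nodes", {
  # every MSN(sampled) link is either kept or replaced by an equally short
  # path through median vectors
  for (seed in 1:12) {
    p <- mk_random_panel(n = 6, k = 7, p = 0.4, seed = seed)
    msn <- build_msn(p)
    mj <- build_mj(p)
    ids <- vapply(mj$nodes, `[[`, character(1), "id")
    g <- igraph::graph_from_data_frame(
      cbind(mj$edges[, 1:2], weight = mj$edges$weight), directed = FALSE,
      vertices = data.frame(name = ids))
    dmat <- igraph::distances(g)
    for (r in seq_len(nrow(msn$edges))) {
      expect_lte(dmat[msn$edges$from[r], msn$edges$to[r]], msn$edges$weight[r])
    }
    # and the MJ node set contains every sampled node
    expect_true(all(vapply(msn$nodes, `[[`, character(1), "id") %in% ids))
  }
})

test_that("network structure is invariant to input order", {
  p <- parse_variant_table(uruguay_panel_path())
  tr <- trim_to_regions(p, region_preset("hvr1_315"))
  rev_panel <- hap_panel(rev(tr$haplotypes))
  canon <- function(net) {
    sig <- vapply(net$nodes, function(nd) rhonet:::hap_signature(nd$hap),
                  character(1))
    names(sig) <- vapply(net$nodes, `[[`, character(1), "id")
    e <- apply(cbind(sig[net$edges$from], sig[net$edges$to]), 1,
               function(x) paste(sort(x), collapse = " | "))
    sort(paste(e, net$edges$weight))
  }
  expect_identical(canon(build_mj(tr)), canon(build_mj(rev_panel)))
})

test_that("weighted networks prefer links through slow sites", {
  # two routes between AA and GG; site 101 is a hotspot (weight 2),
  # site 102 average (weight 8): distances become asymmetric
  ws <- weight_scheme(site_rates(c(101, 102), c(4, 1)))
  p <- mk_panel(c("AA", "GA", "AG", "GG"))
  net <- build_msn(p, mj_params(weights = ws))
  expect_equal(sort(unique(net$edges$weight)), c(2, 8))
  # the hotspot edge weight equals the site weight
  lab <- vapply(net$labels, paste, character(1), collapse = ",")
  expect_true(all(net$edges$weight[lab == "101s"] == 2))
  expect_true(all(net$edges$weight[lab == "102s"] == 8))
})

test_that("node annotations report allele fractions at a typed position", {
  p <- parse_variant_table(uruguay_panel_path())
  tr <- trim_to_regions(p, region_preset("hvr1_315"))
  net <- annotate_state_fractions(build_msn(tr), p, 7697)
  ids <- vapply(net$nodes, `[[`, character(1), "id")
  anc <- net$nodes[[which(vapply(net$nodes, function(nd)
    "KP079" %in% nd$members, logical(1)))]]
  fr <- anc$annotations[["7697"]]
  # KC049/KP079 carry 7697A; KC161/KC163 carry it too (all typed A)
  expect_equal(unname(fr[["A"]]), 1)
})
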
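test_that("the printed variant table parses to the expected variant sets", {
  p <- parse_variant_table(uruguay_panel_path())
  expect_length(p$haplotypes, 15L)

  # HVR-I-only record: six substitutions, HVR-II columns blank -> one
  # missing interval spanning the blank column run
  kp079 <- p$haplotypes[["KP079"]]
  expect_setequal(
    paste0(kp079$variants$pos, kp079$variants$alt),
    c("7697A", "16051G", "16223T", "16298C", "16325C", "16327T"))
  expect_false(any(rhonet:::pos_in_intervals(c(64, 195, 310, 350), kp079$covered)))
  expect_true(all(rhonet:::pos_in_intervals(c(63, 351, 7697, 16051), kp079$covered)))

  # full record with indels: 249d, 290-291d, 315 insertion
  kc004 <- p$haplotypes[["KC004"]]
  expect_true(all(c("249d", "290d", "291d", "315.1i") %in%
                  variant_keys(kc004$variants)))
  expect_equal(kc004$variants$alt[variant_keys(kc004$variants) == "315.1i"], "C")

  # isolated blank cells become single-site missing intervals
  ury <- p$haplotypes[["UryAr010"]]
  expect_false(rhonet:::pos_in_intervals(7697, ury$covered))
  expect_false(rhonet:::pos_in_intervals(64, ury$covered))
  expect_true(rhonet:::pos_in_intervals(65, ury$covered))
})

test_that("parse errors and warnings fire on malformed cells", {
  tab <- c("Sample ID\tPop\t100\t200",
           "rCRS\t\tA\tC",
           "S1\tX\tZ\t.")
  expect_error(parse_variant_table(tab), "S1.*unknown cell symbol")
  # a cell equal to the reference allele warns and records nothing
  tab2 <- c("Sample ID\tPop\t100\t200", "rCRS\t\tA\tC", "S1\tX\tA\tT")
  expect_warning(p <- parse_variant_table(tab2), "equals reference")
  expect_equal(variant_keys(p$haplotypes$S1$variants), "200s")
  # duplicate position column
  expect_error(parse_variant_table(c("Sample ID\t100\t100",
                                     "rCRS\tA\tA", "S1\t.\t.")),
               "duplicate position column")
  # all-dots row: empty variant set, full coverage
  tab3 <- c("Sample ID\tPop\t100\t200", "rCRS\t\tA\tC", "S1\tX\t.\t.")
  h <- parse_variant_table(tab3)$haplotypes$S1
  expect_equal(nrow(h$variants), 0L)
  expect_equal(h$covered, cbind(1L, 16569L), ignore_attr = TRUE)
})

test_that("parse -> serialize -> parse is idempotent on the packaged table", {
  p1 <- parse_variant_table(uruguay_panel_path())
  p2 <- parse_variant_table(write_variant_table(p1))
  expect_equal(p2, p1)
  # and through JSON, losslessly
  expect_equal(panel_from_json(panel_to_json(p1)), p1)
})

test_that("trimming to the 315-bp HVR-I window drops HVR-II and coding variants", {
  p <- parse_variant_table(uruguay_panel_path())
  tr <- trim_to_regions(p, region_preset("hvr1_315"))
  kc004 <- tr$haplotypes[["KC004"]]
  expect_setequal(paste0(kc004$variants$pos, kc004$variants$alt),
                  c("16051G", "16223T", "16287T", "16298C", "16311C",
                    "16325C", "16327T"))
  # trim to the full reference range is the identity
  expect_equal(trim_to_regions(p, region_preset("full")), p, ignore_attr = TRUE)
  # sequential trims compose like intersection
  r1 <- list(region(16051, 16365)); r2 <- list(region(16100, 16400))
  expect_equal(trim_to_regions(trim_to_regions(p, r1), r2)$haplotypes,
               trim_to_regions(p, list(region(16100, 16365)))$haplotypes)
  # a fully missing haplotype is retained and flagged
  tr2 <- trim_to_regions(p, list(region(64, 64)))
  expect_true("KP079" %in% attr(tr2, "flagged"))
  expect_equal(nrow(tr2$haplotypes$KP079$variants), 0L)
  expect_error(trim_to_regions(p, list()), "empty region")
})

test_that("pairwise distances count events at jointly covered keys", {
  p <- parse_variant_table(uruguay_panel_path())
  # self-distance zero
  expect_equal(pairwise_distance(p$haplotypes$KC004, p$haplotypes$KC004)$distance, 0)
  # two printed rows differing at np 195 and the 310 insertion
  d <- pairwise_distance(p$haplotypes$KC161, p$haplotypes$KC163)
  expect_equal(d$distance, 2)
  expect_setequal(unlist(d$keys), c("195s", "310.1i"))
  # manual column-wise diff of rows KC043 and KC150
  d2 <- pairwise_distance(p$haplotypes$KC043, p$haplotypes$KC150)
  expect_equal(d2$distance, 5)
  expect_setequal(unlist(d2$keys),
                  c("350s", "16259s", "16266s", "16271s", "16311s"))
  # a contiguous 290-291 deletion counts once by default, twice when split
  a <- haplotype("a", variants(c(290, 291), c("del", "del"), c("A", "A"),
                               c("", "")))
  b <- haplotype("b", variants())
  d3 <- pairwise_distance(a, b)
  expect_equal(d3$distance, 1)
  expect_equal(unname(sapply(d3$keys, paste, collapse = "+")), "290d+291d")
  expect_equal(pairwise_distance(a, b, merge_deletions = FALSE)$distance, 2)
  # weights scale the contribution
  ws <- weight_scheme(site_rates(195, 2.0))
  expect_equal(pairwise_distance(p$haplotypes$KC161, p$haplotypes$KC163,
                                 weights = ws)$distance, 6 + 8)
  # exclusions silence keys
  expect_equal(pairwise_distance(p$haplotypes$KC161, p$haplotypes$KC163,
                                 excluded = exclusion_set(195, "all"))$distance, 0)
})

test_that("pairwise distance is a metric on substitution-only haplotypes", {
  set.seed(42)
  p <- mk_random_panel(8, 12, seed = 7)
  hs <- p$haplotypes
  for (rep in 1:20) {
    tri <- sample(length(hs), 3)
    dab <- pairwise_distance(hs[[tri[1]]], hs[[tri[2]]])$distance
    dba <- pairwise_distance(hs[[tri[2]]], hs[[tri[1]]])$distance
    dbc <- pairwise_distance(hs[[tri[2]]], hs[[tri[3]]])$distance
    dac <- pairwise_distance(hs[[tri[1]]], hs[[tri[3]]])$distance
    expect_identical(dab, dba)
    expect_gte(dab + dbc, dac)
    expect_gte(dab, 0)
  }
})

test_that("FASTA export applies variants and round-trips substitutions", {
  reg <- region(101, 110)
  ref <- "ACGTACGTAC"
  p <- hap_panel(list(
    haplotype("empty", variants()),
    haplotype("sub1", variants(101, "sub", "A", "G")),
    haplotype("indel", variants(c(103, 105), c("del", "ins"), c("G", ""),
                                c("", "T"))),
    haplotype("gap", variants(), covered = list(region(101, 105)))))
  fa <- export_fasta(p, ref, reg)
  expect_equal(fa[2], ref)                      # identity
  expect_equal(fa[4], paste0("G", substr(ref, 2, 10)))  # first base only
  expect_equal(fa[6], "ACTATCGTAC")             # del 103, ins T after 105
  expect_equal(fa[8], "ACGTANNNNN")             # missing tail as N
  # round-trip recovers the variant set for substitution-only haplotypes
  v <- diff_against_reference(fa[4], ref, reg)
  expect_equal(variant_keys(v), "101s")
  expect_equal(v$alt, "G")
  expect_error(export_fasta(hap_panel(list(haplotype("x",
    variants(99, "sub", "A", "G")))), ref, reg), "outside")
  # cross-check with an independent FASTA reader when available
  skip_if_not_installed("Biostrings")
  tf <- tempfile(fileext = ".fa"); writeLines(fa, tf)
  ss <- Biostrings::readDNAStringSet(tf)
  expect_equal(unname(as.character(ss["sub1"])), fa[4])
})
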
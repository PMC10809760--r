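test_that("module completeness counts covered steps, empty set gives zero", {
  mod4 <- list("a", "b", "c", "d")
  expect_equal(module_completeness(c("a", "c"), mod4), 0.5)
  expect_equal(module_completeness(character(0), mod4), 0)
  mod <- list(c("a", "b"), "c", "d")
  expect_equal(module_completeness(c("b", "d"), mod), 2 / 3)
})

test_that("the 50% cutoff is inclusive and module flags respect it", {
  mods <- list(cytc_oxidase = list("a", "b", "c", "d"),
               cbb3_oxidase = list("e", "f", "g"),
               bd_oxidase = list("h", "i"))
  # exactly half the steps passes (>=, not >)
  fl <- classify_aerobic(c("a", "b"), mods)
  expect_true(fl[["has_cytc_oxidase"]])
  # under half fails
  fl <- classify_aerobic(c("e"), mods)
  expect_false(fl[["has_cbb3"]])
  fl <- classify_aerobic(c("e", "f"), mods)
  expect_true(fl[["has_cbb3"]])
  expect_error(classify_aerobic("a", mods[1:2]), "bd_oxidase",
               class = "hadalguilds_config_error")
})

test_that("taxon override marks ammonia-oxidizing archaea aerobic without oxidase hits", {
  mods <- default_oxidase_modules()
  woes <- "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Woeseiales;f__Woeseiaceae;g__;s__"
  npum <- "d__Archaea;p__Thermoproteota;c__Nitrososphaeria;o__Nitrosopumilales;f__Nitrosopumilaceae;g__;s__"
  fl <- classify_aerobic(c("coxA", "coxB", "coxC"), mods, woes)
  expect_true(fl[["has_cytc_oxidase"]])
  expect_false(fl[["taxon_override_aerobic"]])
  fl <- classify_aerobic(c("amoA", "amoB"), mods, npum)
  expect_false(any(fl[c("has_cytc_oxidase", "has_cbb3", "has_bd")]))
  expect_true(fl[["taxon_override_aerobic"]])
})

test_that("nitrogen and sulfur marker rules match their printed thresholds", {
  fl <- classify_nitrogen(c("narG", "narH"))
  expect_true(fl[["narGHI"]])
  expect_false(classify_nitrogen("narG")[["narGHI"]])
  expect_true(classify_nitrogen("norB")[["norBC"]])
  expect_true(classify_nitrogen("nirK")[["nirKS"]])
  expect_false(classify_nitrogen("napA")[["napAB"]])
  expect_true(all(!classify_nitrogen(character(0))))
  expect_true(classify_sulfur(c("dsrA", "dsrB")))
  expect_false(classify_sulfur("dsrA"))
  expect_true(classify_sulfur("dsrA", require_both = FALSE))
})

test_that("rule engine equals the brute-force oracle on random gene sets", {
  withr::local_seed(11)
  for (i in 1:500) {
    genes <- random_gene_set(gene_universe)
    got <- classify_nitrogen(genes)
    want <- oracle_rule_flags(genes)
    for (k in c("napAB", "narGHI", "nrfAH", "nirBD", "nirKS", "norBC",
                "nosZ", "full_denitrifier")) {
      expect_identical(unname(got[[k]]), want[[k]])
    }
    expect_identical(classify_sulfur(genes), want$dsrAB)
  }
})

test_that("capability flags are monotone in gene content, fermenter antitone", {
  withr::local_seed(23)
  full_universe <- c(gene_universe, "coxA", "coxB", "coxC", "ccoN", "ccoO",
                     "ccoP", "cydA", "cydB", "cydX", "nrfA", "nrfH", "nirB",
                     "nirD")
  caps <- function(genes) {
    aer <- classify_aerobic(genes)
    nit <- classify_nitrogen(genes)
    aerobic <- any(aer[c("has_cytc_oxidase", "has_cbb3", "has_bd")])
    nitrogen <- any(nit[1:7])
    sul <- classify_sulfur(genes)
    c(aerobic = aerobic, nitrogen = nitrogen, sulfur = sul,
      fermenter = !(aerobic || nitrogen || sul))
  }
  for (i in 1:100) {
    g1 <- random_gene_set(full_universe, 0.25)
    extra <- random_gene_set(setdiff(full_universe, g1), 0.3)
    c1 <- caps(g1)
    c2 <- caps(c(g1, extra))
    expect_true(all(c2[c("aerobic", "nitrogen", "sulfur")] >=
                    c1[c("aerobic", "nitrogen", "sulfur")]))
    expect_true(c2[["fermenter"]] <= c1[["fermenter"]])
  }
})

test_that("classify_guilds reproduces planted archetypes and handles duals", {
  cfg <- tiny_sim_config()
  sim <- simulate_catalog(cfg, seed = 99)
  asn <- suppressWarnings(classify_guilds(sim$catalog, sim$gene_table,
                                          sim$metal_flags))
  gt <- sim$ground_truth
  expect_identical(asn$aerobic, gt$aerobic)
  expect_identical(asn$nitrogen, gt$nitrogen)
  expect_identical(asn$sulfur_resp, gt$sulfur_resp)
  expect_identical(asn$metal_resp, gt$metal_resp)
  expect_identical(asn$fermenter, gt$fermenter)
  dual <- asn[gt$archetype == "aerobe_nitrogen", ]
  expect_true(all(dual$aerobic & dual$nitrogen))
  expect_true(all(asn$fermenter == !(asn$aerobic | asn$nitrogen |
                                     asn$sulfur_resp | asn$metal_resp)))
  # MAGs with no annotations are classified from an empty gene set, with warning
  expect_warning(classify_guilds(sim$catalog, sim$gene_table, sim$metal_flags),
                 "empty gene set")
})

test_that("guild overlap partitions non-fermenters and sums to the MAG total", {
  asn <- tibble::tibble(
    mag_id = c("a", "b", "c"),
    aerobic = c(TRUE, TRUE, FALSE), nitrogen = c(FALSE, TRUE, FALSE),
    sulfur_resp = FALSE, metal_resp = FALSE,
    fermenter = c(FALSE, FALSE, TRUE))
  ov <- guild_overlap(asn)
  expect_equal(ov$n[ov$region == "aerobic"], 1L)
  expect_equal(ov$n[ov$region == "aerobic+nitrogen"], 1L)
  expect_equal(ov$n[ov$region == "fermenter"], 1L)
  expect_equal(sum(ov$n), 3L)

  all_ferm <- tibble::tibble(mag_id = letters[1:4], aerobic = FALSE,
                             nitrogen = FALSE, sulfur_resp = FALSE,
                             metal_resp = FALSE, fermenter = TRUE)
  ov <- guild_overlap(all_ferm)
  expect_equal(ov$n[ov$region == "fermenter"], 4L)
  expect_true(all(ov$n[ov$region != "fermenter"] == 0L))

  withr::local_seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    caps <- matrix(runif(n * 4) < 0.4, n, 4,
                   dimnames = list(NULL, c("aerobic", "nitrogen",
                                           "sulfur_resp", "metal_resp")))
    asn <- tibble::as_tibble(as.data.frame(caps))
    asn$mag_id <- sprintf("m%02d", seq_len(n))
    asn$fermenter <- !(asn$aerobic | asn$nitrogen | asn$sulfur_resp |
                       asn$metal_resp)
    ov <- guild_overlap(asn)
    want <- oracle_overlap_counts(asn)
    for (r in names(want)) {
      expect_equal(ov$n[ov$region == r], unname(want[r]), ignore_attr = TRUE)
    }
    expect_equal(sum(ov$n), n)
  }
})
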
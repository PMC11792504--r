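single_key_protein <- function() {
  data.frame(protein_id = "P1", species = "SpX", ko_id = "K00009",
             pathways = "pA", log2fc_shrunk = 1.2, p_adj = 0.01,
             stringsAsFactors = FALSE)
}

simple_maps <- function() {
  function_maps(
    data.frame(ko_id = c("K00009", "K00010"), pathway_id = c("pA", "pB")),
    data.frame(pathway_id = c("pA", "pB"), main_category = "Metabolism",
               subcategory = c("m1", "m2")))
}

test_that("a single key protein yields the single-edge graph", {
  cat1 <- protein_catalog(data.frame(
    protein_id = "P1", family = "FamX", genus = "GenX", species = "SpX",
    strain = "StX", annotated = TRUE, ko_id = "K00009"))
  rt <- build_routes(character(), single_key_protein(), cat1, simple_maps(),
                     enriched_pathways = "pA")
  expect_setequal(rt$nodes$id, c("SpX", "K00009", "pA"))
  expect_equal(nrow(rt$edges), 2)
  expect_equal(rt$groups$pathway_id, "pA")
  expect_equal(rt$groups$species, "SpX")
})

test_that("empty key proteins give an empty graph with a warning", {
  cat1 <- tiny_catalog()
  expect_warning(rt <- build_routes("SpX1", NULL, cat1, simple_maps(), "pA"),
                 "empty key-protein set")
  expect_equal(nrow(rt$edges), 0)
  expect_equal(nrow(rt$groups), 0)
})

test_that("relaxing the protein threshold never removes edges", {
  d <- study_design(10)
  cm <- make_catalog(small_spec(), seed = 61)
  tr <- plant_truth(cm, n_da_species = 0, n_enriched_pathways = 2,
                    lfc_de = 2, seed = 61)
  mod <- intensity_model(sigma = 0.4, p_zero = 0.1, shared_fraction = 0,
                         within_strain_shared = 0)
  b <- simulate_metaproteome(d, mod, cm$catalog, cm$maps, tr, seed = 62)
  cls <- classify_peptides(b$peptides, b$catalog)
  pel <- compute_pel(cls$retained, b$catalog, samples = d$sample)
  cnt <- pel_to_counts(split_annotation(pel, b$catalog)$annotated)
  da <- da_analysis(cnt, d, threshold = 0.1)
  tk <- targeted_kos(da, tr$enriched_sets, cnt, d, b$catalog, b$maps)
  key05 <- tk$key_proteins[tk$key_proteins$p_adj < 0.05, ]
  key10 <- tk$key_proteins
  r05 <- suppressWarnings(build_routes(character(), key05, b$catalog,
                                       b$maps, tr$enriched_sets))
  r10 <- suppressWarnings(build_routes(character(), key10, b$catalog,
                                       b$maps, tr$enriched_sets))
  e05 <- do.call(paste, r05$edges)
  e10 <- do.call(paste, r10$edges)
  expect_true(all(e05 %in% e10))
})

test_that("route graphs are byte-identical given identical upstream tables", {
  cat1 <- tiny_catalog()
  key <- data.frame(protein_id = c("A1", "C1"), species = c("SpX1", "SpY1"),
                    ko_id = "K00001", pathways = "pA",
                    log2fc_shrunk = 1, p_adj = 0.02)
  maps <- function_maps(
    data.frame(ko_id = "K00001", pathway_id = "pA"),
    data.frame(pathway_id = "pA", main_category = "Metabolism",
               subcategory = "m1"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  r1 <- build_routes(character(), key, cat1, maps, "pA")
  r2 <- build_routes(character(), key, cat1, maps, "pA")
  write_routes(r1, edges_path = f1)
  write_routes(r2, edges_path = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  ## group containment: groups only contain key-protein or abundant species
  expect_true(all(r1$groups$species %in% key$species))
})

test_that("taxon-evidence edges require anchoring and expression", {
  cat2 <- protein_catalog(data.frame(
    protein_id = c("P1", "Q1"),
    family = c("FamX", "FamY"), genus = c("GenX", "GenY"),
    species = c("SpX", "SpY"), strain = c("StX", "StY"),
    annotated = TRUE, ko_id = "K00009"))
  pel <- matrix(c(5, 3), 2, 1, dimnames = list(c("P1", "Q1"), "s1"))
  ## SpY is abundant, expresses K00009 via Q1, and the KO is anchored by SpX
  rt <- build_routes("SpY", single_key_protein(), cat2, simple_maps(), "pA",
                     pel = pel)
  tax_edges <- rt$edges[rt$edges$evidence == "taxon", ]
  expect_equal(tax_edges$from, "SpY")
  expect_true(all(c("SpX", "SpY") %in%
                    rt$groups$species[rt$groups$pathway_id == "pA"]))
  ## without expression there is no taxon edge
  pel0 <- pel; pel0["Q1", ] <- 0
  rt0 <- build_routes("SpY", single_key_protein(), cat2, simple_maps(), "pA",
                      pel = pel0)
  expect_false("SpY" %in% rt0$edges$from)
})

test_that("bubble tables report explicit zeros and exact group means", {
  md <- data.frame(sample = paste0("s", 1:4),
                   group = rep(c("g1", "g2"), each = 2))
  pel <- rbind(P1 = c(10, 10, 0, 0), P2 = c(1, 3, 5, 7))
  colnames(pel) <- md$sample
  bt <- bubble_table(c("P1", "P2"), pel, md)
  expect_equal(bt$mean_pel[bt$protein_id == "P1" & bt$group == "g1"], 10)
  expect_equal(bt$mean_pel[bt$protein_id == "P1" & bt$group == "g2"], 0)
  expect_equal(bt$mean_pel[bt$protein_id == "P2" & bt$group == "g2"], 6)
  ## brute force over all cells
  for (i in seq_len(nrow(bt))) {
    smp <- md$sample[md$group == bt$group[i]]
    expect_equal(bt$mean_pel[i], mean(pel[bt$protein_id[i], smp]))
  }
  expect_error(bubble_table("P9", pel, md), "absent")
})

test_that("route graphs export to igraph/GraphML", {
  cat1 <- tiny_catalog()
  key <- data.frame(protein_id = "A1", species = "SpX1", ko_id = "K00001",
                    pathways = "pA", log2fc_shrunk = 1, p_adj = 0.02)
  maps <- function_maps(
    data.frame(ko_id = "K00001", pathway_id = "pA"),
    data.frame(pathway_id = "pA", main_category = "Metabolism",
               subcategory = "m1"))
  rt <- build_routes(character(), key, cat1, maps, "pA")
  g <- routes_igraph(rt)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  gm <- withr::local_tempfile(fileext = ".graphml")
  write_routes(rt, graphml_path = gm)
  expect_true(file.exists(gm))
  expect_match(readLines(gm, n = 2)[2], "graphml", ignore.case = TRUE)
})
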
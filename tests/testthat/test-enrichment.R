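test_that("functional categorization counts multi-membership correctly", {
  cat6 <- tiny_catalog()
  kp <- data.frame(ko_id = c("K00001", "K00001", "K00002", "K00003"),
                   pathway_id = c("pA", "pB", "pA", "pC"))
  pc <- data.frame(pathway_id = c("pA", "pB", "pC"),
                   main_category = c("Metabolism", "Metabolism", "Cellular"),
                   subcategory = c("m1", "m2", "c1"))
  maps <- function_maps(kp, pc)
  prof <- categorize_functions(cat6, maps)
  ## A1 and C1 share K00001 (pA+pB); A2 has K00002 (pA); D1 has K00003 (pC)
  pw <- prof$pathway_counts
  expect_equal(pw$n_proteins[pw$pathway_id == "pA"], 3)
  expect_equal(pw$n_proteins[pw$pathway_id == "pB"], 2)
  expect_equal(pw$n_proteins[pw$pathway_id == "pC"], 1)
  ## a protein in two pathways of one category counts once for the category
  cc <- prof$category_counts
  expect_equal(cc$n_proteins[cc$main_category == "Metabolism"], 3)

  ## brute-force join on a synthetic catalog
  cm <- make_catalog(small_spec(), seed = 43)
  prof2 <- categorize_functions(cm$catalog, cm$maps)
  j <- merge(cm$catalog[!is.na(cm$catalog$ko_id), c("protein_id", "ko_id")],
             cm$maps$ko_pathway, by = "ko_id")
  bf <- table(j$pathway_id)
  got <- stats::setNames(prof2$pathway_counts$n_proteins,
                         prof2$pathway_counts$pathway_id)
  expect_equal(got[names(bf)], unclass(bf)[names(bf)], ignore_attr = TRUE)
})

test_that("unmapped KOs are reported, not silently dropped", {
  cat6 <- tiny_catalog()
  kp <- data.frame(ko_id = "K00001", pathway_id = "pA")
  pc <- data.frame(pathway_id = "pA", main_category = "Metabolism",
                   subcategory = "m1")
  prof <- categorize_functions(cat6, function_maps(kp, pc))
  expect_true(all(c("K00002", "K00003") %in% prof$unmapped_kos))
  expect_equal(prof$n_unmapped_proteins, 2)
})

test_that("signed gene statistics follow sign(lfc) * -log10(p)", {
  da <- data.frame(feature_id = c("a", "b", "c", "d"),
                   log2fc_shrunk = c(1, -1, 3, 0.5),
                   p = c(0.01, 0.01, 1, NA))
  gs <- gene_stats(da)
  expect_equal(gs[["a"]], 2)
  expect_equal(gs[["b"]], -2)
  expect_equal(gs[["c"]], 0)     # p = 1 gives 0 regardless of sign
  expect_false("d" %in% names(gs))
})

test_that("directional enrichment is calibrated by construction", {
  set.seed(47)
  pool <- stats::setNames(stats::rnorm(40), paste0("g", 1:40))
  ## a set whose mean equals the pool mean: p near 0.5 (null by construction)
  bal <- names(sort(pool))[seq(1, 40, by = 2)]   # alternating ranks
  memb <- data.frame(set_id = "bal", feature_id = bal)
  e <- enrich_sets(pool, memb, n_perm = 2000, seed = 1)
  expect_gt(e$p_dir_up, 0.3); expect_lt(e$p_dir_up, 0.7)
  ## planted coordinated up-shift: minimal attainable p
  up <- stats::setNames(c(stats::rnorm(40), stats::rnorm(8, 4)),
                        paste0("g", 1:48))
  memb2 <- data.frame(set_id = "up", feature_id = paste0("g", 41:48))
  e2 <- enrich_sets(up, memb2, n_perm = 999, seed = 1)
  expect_equal(e2$p_dir_up, 1 / 1000)
  expect_error(enrich_sets(pool, memb, n_perm = 50), "n_perm < 100")
})

test_that("enrichment p matches exhaustive enumeration on a tiny pool", {
  pool <- stats::setNames(c(-1.2, 0.3, 0.8, 1.5, -0.4, 2.1), paste0("g", 1:6))
  memb <- data.frame(set_id = "s1", feature_id = c("g3", "g4", "g6"))
  e <- enrich_sets(pool, memb, method = "exhaustive")
  ## oracle: all 20 subsets of size 3
  obs <- mean(pool[c("g3", "g4", "g6")])
  all_means <- utils::combn(pool, 3, FUN = mean)
  expect_equal(e$p_dir_up, mean(all_means >= obs - 1e-12))
  ## Monte-Carlo agrees within sampling error
  emc <- enrich_sets(pool, memb, n_perm = 20000, seed = 2)
  expect_lt(abs(emc$p_dir_up - e$p_dir_up), 0.02)
})

test_that("enrichment is invariant to relabeling proteins consistently", {
  set.seed(53)
  pool <- stats::setNames(stats::rnorm(30), paste0("g", 1:30))
  memb <- data.frame(set_id = rep(c("s1", "s2"), c(5, 6)),
                     feature_id = paste0("g", 1:11))
  e1 <- enrich_sets(pool, memb, n_perm = 500, seed = 9)
  relabel <- stats::setNames(paste0("h", 30:1), paste0("g", 1:30))
  pool2 <- stats::setNames(pool, relabel[names(pool)])
  memb2 <- data.frame(set_id = memb$set_id,
                      feature_id = relabel[memb$feature_id])
  e2 <- enrich_sets(pool2, memb2, n_perm = 500, seed = 9)
  expect_equal(e1$stat, e2$stat)
  expect_equal(e1$p_dir_up, e2$p_dir_up)
})

test_that("small sets are excluded by min_set_size", {
  pool <- stats::setNames(stats::rnorm(20), paste0("g", 1:20))
  memb <- data.frame(set_id = rep(c("tiny", "ok"), c(2, 4)),
                     feature_id = paste0("g", 1:6))
  e <- enrich_sets(pool, memb, min_set_size = 3, n_perm = 200, seed = 1)
  expect_equal(e$set_id, "ok")
})

test_that("targeted KOs intersect with significant proteins correctly", {
  d <- study_design(10)
  cm <- make_catalog(small_spec(), seed = 59)
  tr <- plant_truth(cm, n_da_species = 0, n_enriched_pathways = 1,
                    lfc_de = 3, seed = 59)
  mod <- intensity_model(sigma = 0.1, p_zero = 0, shared_fraction = 0,
                         within_strain_shared = 0)
  b <- simulate_metaproteome(d, mod, cm$catalog, cm$maps, tr, seed = 60)
  cls <- classify_peptides(b$peptides, b$catalog)
  pel <- compute_pel(cls$retained, b$catalog, samples = d$sample)
  cnt <- pel_to_counts(split_annotation(pel, b$catalog)$annotated)
  da <- da_analysis(cnt, d, threshold = 0.1)
  tk <- targeted_kos(da, tr$enriched_sets, cnt, d, b$catalog, b$maps)
  ## planted KOs are targeted
  planted_kos <- unique(b$catalog$ko_id[match(names(tr$de_proteins),
                                              b$catalog$protein_id)])
  cand <- intersect(planted_kos,
                    b$maps$ko_pathway$ko_id[b$maps$ko_pathway$pathway_id %in%
                                              tr$enriched_sets])
  expect_true(all(cand %in% tk$targeted_kos))
  ## containment: key proteins are significant, positive, and KO-mapped
  sig <- flag_positive(da, 0.1)$feature_id
  expect_true(all(tk$key_proteins$protein_id %in% sig))
  expect_true(all(tk$key_proteins$ko_id %in% tk$targeted_kos))
  ## a targeted KO with no significant member proteins yields no key proteins
  fake_da <- da
  fake_da$p_adj <- 1   # nothing significant
  tk2 <- targeted_kos(fake_da, tr$enriched_sets, cnt, d, b$catalog, b$maps)
  expect_equal(nrow(tk2$key_proteins), 0)
  expect_gt(length(tk2$targeted_kos), 0)
})
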
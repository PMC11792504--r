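#' Functional categorization of the catalog
#'
#' Joins KO-mapped proteins to pathways and categories. A protein contributes
#' one count to every pathway its KO maps to (multi-membership), and one
#' count per distinct main category / subcategory it touches, so category
#' counts are at least the unique protein count of their pathways. KOs with
#' no pathway mapping are tallied as unmapped.
#'
#' @param catalog protein catalog.
#' @param maps function maps.
#' @param top_n size of the top-pathway table (by protein count).
#' @return list with `pathway_counts`, `category_counts`,
#'   `subcategory_counts`, `top_pathways`, `n_unmapped_proteins`,
#'   `unmapped_kos`.
#' @export
categorize_functions <- function(catalog, maps, top_n = 20) {
  withko <- catalog[!is.na(catalog$ko_id), c("protein_id", "ko_id")]
  j <- merge(withko, maps$ko_pathway, by = "ko_id")
  j <- merge(j, maps$pathway_category, by = "pathway_id")
  unmapped_kos <- setdiff(withko$ko_id, maps$ko_pathway$ko_id)
  n_unmapped <- sum(withko$ko_id %in% unmapped_kos)

  pw <- as.data.frame(table(j$pathway_id), stringsAsFactors = FALSE)
  names(pw) <- c("pathway_id", "n_proteins")
  pw <- merge(pw, maps$pathway_category, by = "pathway_id")
  pw <- pw[order(-pw$n_proteins, pw$pathway_id), ]
  rownames(pw) <- NULL

  cc <- unique(j[, c("protein_id", "main_category")])
  cat_counts <- as.data.frame(table(cc$main_category), stringsAsFactors = FALSE)
  names(cat_counts) <- c("main_category", "n_proteins")
  sc <- unique(j[, c("protein_id", "main_category", "subcategory")])
  sub_counts <- stats::aggregate(protein_id ~ main_category + subcategory,
                                 data = sc, FUN = length)
  names(sub_counts)[3] <- "n_proteins"

  list(pathway_counts = pw,
       category_counts = cat_counts[order(-cat_counts$n_proteins), ],
       subcategory_counts = sub_counts,
       top_pathways = utils::head(pw, top_n),
       n_unmapped_proteins = n_unmapped,
       unmapped_kos = sort(unmapped_kos))
}

#' Signed per-protein statistic for enrichment
#'
#' `sign(log2FC_shrunk) * (-log10 p)`, with p floored at 1e-300; p = 1 gives
#' 0 regardless of sign. Features with missing p (all-zero) are dropped.
#'
#' @param da differential-abundance results (`mp_da`).
#' @return named numeric vector of statistics.
#' @export
gene_stats <- function(da) {
  ok <- !is.na(da$p)
  p <- pmax(da$p[ok], 1e-300)
  stats::setNames(sign(da$log2fc_shrunk[ok]) * (-log10(p)), da$feature_id[ok])
}

#' Directional gene-set enrichment
#'
#' Tests each set for a coordinated up-shift: the set statistic is the mean
#' member statistic and the null is formed by drawing same-size member sets
#' from the statistic pool ("distinct updirectional" p-value). Monte-Carlo
#' p = (1 + #\{null >= observed\}) / (1 + n_perm); with
#' `method = "exhaustive"` all subsets of the pool are enumerated and
#' p is the exact tail fraction. BH correction across sets.
#'
#' @param stats named statistic vector from [gene_stats()].
#' @param membership data.frame with columns `set_id`, `feature_id`.
#' @param min_set_size smallest testable set (default 3).
#' @param n_perm permutations (>= 100 enforced for the Monte-Carlo method).
#' @param seed integer seed.
#' @param method `"permutation"` or `"exhaustive"`.
#' @return data.frame: `set_id`, `size`, `stat`, `p_dir_up`, `p_adj`.
#' @export
enrich_sets <- function(stats, membership, min_set_size = 3, n_perm = 10000,
                        seed = NULL, method = c("permutation", "exhaustive")) {
  method <- match.arg(method)
  if (method == "permutation" && n_perm < 100)
    stop("n_perm < 100 refused; increase permutations")
  if (!is.null(seed)) set.seed(as.integer(seed))
  pool <- stats[is.finite(stats)]
  memb <- membership[membership$feature_id %in% names(pool), ]
  sets <- split(memb$feature_id, memb$set_id)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) >= min_set_size]
  if (!length(sets))
    return(data.frame(set_id = character(), size = integer(),
                      stat = numeric(), p_dir_up = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  sizes <- sort(unique(lengths(sets)))
  null_means <- list()
  for (k in sizes) {
    null_means[[as.character(k)]] <- if (method == "exhaustive") {
      combn_means(pool, k)
    } else {
      vapply(seq_len(n_perm), function(i) mean(sample(pool, k)), 0)
    }
  }
  out <- data.frame(
    set_id = names(sets), size = lengths(sets),
    stat = vapply(sets, function(f) mean(pool[f]), 0),
    stringsAsFactors = FALSE)
  out$p_dir_up <- vapply(seq_len(nrow(out)), function(i) {
    nm <- null_means[[as.character(out$size[i])]]
    if (method == "exhaustive") mean(nm >= out$stat[i] - 1e-12)
    else (1 + sum(nm >= out$stat[i])) / (1 + n_perm)
  }, 0)
  out <- out[order(out$set_id), ]
  out$p_adj <- adjust_bh(out$p_dir_up)
  rownames(out) <- NULL
  out
}

combn_means <- function(pool, k) {
  if (choose(length(pool), k) > 2e5)
    stop("pool too large for exhaustive enumeration")
  utils::combn(pool, k, FUN = mean)
}

#' KO-level tests over enriched pathways
#'
#' Candidate KOs are all KOs of the enriched pathways. For each, member
#' protein counts are summed and tested with the same negative-binomial LRT
#' as the protein stage; a KO is targeted when its raw LRT p < `ko_p`. Key
#' proteins are the significant positively associated proteins
#' (p_adj < `protein_threshold`, shrunken log2FC > 0) whose KO is targeted.
#' KOs with all-zero counts are skipped and reported.
#'
#' @param da_proteins protein-level `mp_da`.
#' @param enriched_pathways character vector of enriched pathway IDs.
#' @param counts protein-level count matrix used by the DA stage.
#' @param metadata sample metadata.
#' @param catalog,maps catalog and function maps.
#' @param design model design, see [nb_lrt()].
#' @param ko_p raw-p threshold for targeted KOs.
#' @param protein_threshold BH threshold for key proteins.
#' @return list with `ko_results`, `targeted_kos`, `key_proteins`
#'   (protein_id, species, ko_id, pathways, log2fc_shrunk, p_adj),
#'   `skipped_kos`.
#' @export
targeted_kos <- function(da_proteins, enriched_pathways, counts, metadata,
                         catalog, maps, design = "interaction",
                         ko_p = 0.05, protein_threshold = 0.1) {
  if (!length(enriched_pathways)) stop("enriched pathway list is empty")
  kp <- maps$ko_pathway
  cand <- sort(unique(kp$ko_id[kp$pathway_id %in% enriched_pathways]))
  ko_of <- catalog$ko_id[match(rownames(counts), catalog$protein_id)]
  keep <- !is.na(ko_of) & ko_of %in% cand
  if (!any(keep)) {
    warning("no catalog protein under the candidate KOs has counts")
    return(list(ko_results = NULL, targeted_kos = character(),
                key_proteins = NULL, skipped_kos = character()))
  }
  ko_counts <- rowsum(counts[keep, , drop = FALSE], group = ko_of[keep])
  zero <- rowSums(ko_counts) == 0
  skipped <- rownames(ko_counts)[zero]
  ko_counts <- ko_counts[!zero, , drop = FALSE]
  storage.mode(ko_counts) <- "integer"
  res <- nb_lrt(ko_counts, metadata, design = design,
                sf = size_factors(counts))
  res$targeted <- !is.na(res$p) & res$p < ko_p
  tko <- res$feature_id[res$targeted]

  sig <- flag_positive(da_proteins, protein_threshold)
  sig_ko <- catalog$ko_id[match(sig$feature_id, catalog$protein_id)]
  kp_keep <- !is.na(sig_ko) & sig_ko %in% tko
  key <- sig[kp_keep, c("feature_id", "log2fc_shrunk", "p_adj")]
  names(key)[1] <- "protein_id"
  key$species <- catalog$species[match(key$protein_id, catalog$protein_id)]
  key$ko_id <- sig_ko[kp_keep]
  key$pathways <- vapply(key$ko_id, function(k) {
    paste(sort(intersect(kp$pathway_id[kp$ko_id == k], enriched_pathways)),
          collapse = ";")
  }, "")
  key <- key[order(key$protein_id),
             c("protein_id", "species", "ko_id", "pathways",
               "log2fc_shrunk", "p_adj")]
  rownames(key) <- NULL
  list(ko_results = res, targeted_kos = tko, key_proteins = key,
       skipped_kos = skipped)
}
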
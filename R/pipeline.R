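#' Pipeline configuration
#'
#' @param outdir output directory.
#' @param seed integer seed (mandatory; drives every stochastic stage).
#' @param taxon_p_adj,protein_p_adj,enrichment_p,ko_p significance thresholds
#'   (all in (0, 1)): taxon BH 0.05, protein BH 0.1, directional enrichment
#'   0.05, KO-level raw 0.05 by default.
#' @param n_perm_permanova,n_perm_enrich permutation counts.
#' @param design model design for the DA stage, see [nb_lrt()].
#' @param n_subjects_per_arm study size.
#' @param sim named list of overrides for [intensity_model()].
#' @param cat_spec named list of overrides for [catalog_spec()].
#' @param truth `mp_truth` or `NULL` (null simulation).
#' @param input_dir when not `NULL`, the pipeline ingests an existing bundle
#'   directory instead of simulating.
#' @return validated config list (class `mp_config`).
#' @export
pipeline_config <- function(outdir, seed,
                            taxon_p_adj = 0.05, protein_p_adj = 0.1,
                            enrichment_p = 0.05, ko_p = 0.05,
                            n_perm_permanova = 999, n_perm_enrich = 2000,
                            design = "interaction",
                            n_subjects_per_arm = 10,
                            sim = list(), cat_spec = list(),
                            truth = NULL, input_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("validation error: seed is mandatory")
  thr <- c(taxon_p_adj = taxon_p_adj, protein_p_adj = protein_p_adj,
           enrichment_p = enrichment_p, ko_p = ko_p)
  bad <- thr <= 0 | thr >= 1
  if (any(bad)) stop("validation error: threshold out of (0,1): ",
                     paste(names(thr)[bad], collapse = ", "))
  if (n_perm_permanova < 1 || n_perm_enrich < 100)
    stop("validation error: permutation counts too small")
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              taxon_p_adj = taxon_p_adj, protein_p_adj = protein_p_adj,
              enrichment_p = enrichment_p, ko_p = ko_p,
              n_perm_permanova = n_perm_permanova,
              n_perm_enrich = n_perm_enrich, design = design,
              n_subjects_per_arm = n_subjects_per_arm,
              sim = sim, cat_spec = cat_spec, truth = truth,
              input_dir = input_dir)
  class(cfg) <- "mp_config"
  cfg
}

#' Read a YAML pipeline configuration
#'
#' Keys mirror the arguments of [pipeline_config()]; anything passed in
#' `...` overrides the file.
#'
#' @param path YAML file.
#' @param ... overrides.
#' @return `mp_config`.
#' @export
read_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  ov <- list(...)
  y[names(ov)] <- ov
  do.call(pipeline_config, y)
}

stage_files <- function(outdir) list(
  simulate = file.path(outdir, "input",
                       c("peptides.tsv", "catalog.tsv", "ko_pathway.tsv",
                         "pathway_category.tsv", "metadata.tsv", "truth.json")),
  infer = file.path(outdir, c("pel.tsv", "counts_table.tsv")),
  profile = file.path(outdir, c("abundance_species.tsv", "abundance_family.tsv",
                                "composition_groups.tsv")),
  diversity = file.path(outdir, c("alpha.tsv", "alpha_regression.tsv",
                                  "bray_curtis.tsv", "pcoa.tsv",
                                  "permanova.json")),
  diffabund = file.path(outdir, c("da_species.tsv", "da_proteins.tsv")),
  enrich = file.path(outdir, c("enrichment.tsv", "pathway_counts.tsv",
                               "ko_results.tsv", "key_proteins.tsv")),
  routes = file.path(outdir, c("routes.graphml", "route_edges.tsv",
                               "route_groups.tsv", "bubble.tsv")),
  report = file.path(outdir, "consistency_report.tsv"))

#' Run the full pipeline
#'
#' Executes the stages in dependency order: simulate (or ingest) -> infer ->
#' profile -> diversity -> diffabund -> enrich -> routes -> report. Every
#' output is recorded in a manifest with an md5 checksum; with
#' `resume = TRUE`, stages whose outputs already exist are skipped and their
#' artifacts re-read, so deleting one intermediate regenerates it (and its
#' downstream) only.
#'
#' @param config `mp_config`.
#' @param resume skip stages whose outputs all exist.
#' @param strict fail (error) when the consistency report has failing checks.
#' @param quiet suppress stage log lines.
#' @return invisibly, a list with `manifest` (file, md5) and `status`.
#' @export
run_pipeline <- function(config, resume = FALSE, strict = FALSE,
                         quiet = TRUE) {
  stopifnot(inherits(config, "mp_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sf <- stage_files(outdir)
  log <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S"), " [", ..., "]")
  done <- function(stage) resume && all(file.exists(sf[[stage]]))

  ## --- simulate / ingest ---
  indir <- file.path(outdir, "input")
  if (!done("simulate")) {
    log("simulate")
    if (!is.null(config$input_dir)) {
      dir.create(indir, showWarnings = FALSE)
      file.copy(list.files(config$input_dir, full.names = TRUE), indir,
                overwrite = TRUE)
    } else {
      design <- study_design(config$n_subjects_per_arm)
      spec <- do.call(catalog_spec, config$cat_spec)
      model <- do.call(intensity_model, config$sim)
      cm <- make_catalog(spec, seed = config$seed)
      bundle <- simulate_metaproteome(design, model, cm$catalog, cm$maps,
                                      truth = config$truth, seed = config$seed)
      write_bundle(bundle, indir)
    }
  }
  bundle <- read_bundle(indir)
  md <- bundle$metadata

  ## --- infer: strain-specific filter + PEL ---
  if (!done("infer")) {
    log("infer")
    cls <- classify_peptides(bundle$peptides, bundle$catalog)
    pel <- compute_pel(cls$retained, bundle$catalog, samples = md$sample)
    tab <- tabulate_counts(cls$retained, pel, bundle$catalog, md)
    pel_df <- data.frame(protein_id = rownames(pel), pel,
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(pel_df, sf$infer[1])
    write_tsv(tab, sf$infer[2])
  }
  pel_df <- read_tsv(sf$infer[1])
  pel <- as.matrix(pel_df[, -1, drop = FALSE])
  rownames(pel) <- pel_df$protein_id
  counts_table <- read_tsv(sf$infer[2])

  ## --- profile ---
  if (!done("profile")) {
    log("profile")
    for (lv in c("species", "family")) {
      ab <- rollup(pel, bundle$catalog, lv)
      write_tsv(data.frame(taxon = rownames(ab), ab, check.names = FALSE),
                file.path(outdir, paste0("abundance_", lv, ".tsv")))
    }
    sp <- rollup(pel, bundle$catalog, "species")
    write_tsv(group_composition(rollup(pel, bundle$catalog, "family"), md),
              sf$profile[3])
  }
  ab_df <- read_tsv(sf$profile[1])
  sp_ab <- as.matrix(ab_df[, -1, drop = FALSE]); rownames(sp_ab) <- ab_df$taxon

  ## --- diversity ---
  if (!done("diversity")) {
    log("diversity")
    al <- alpha_diversity(sp_ab)
    write_tsv(al, sf$diversity[1])
    write_tsv(alpha_regression(al, md), sf$diversity[2])
    D <- bray_curtis(sp_ab)
    write_tsv(data.frame(sample = rownames(D), D, check.names = FALSE),
              sf$diversity[3])
    pc <- pcoa_ordination(D, k = 2)
    write_tsv(data.frame(sample = rownames(pc$coords), pc$coords,
                         check.names = FALSE), sf$diversity[4])
    pm <- permanova(D, md$arm[match(colnames(sp_ab), md$sample)],
                    n_perm = config$n_perm_permanova, seed = config$seed)
    jsonlite::write_json(unclass(pm), sf$diversity[5], auto_unbox = TRUE,
                         digits = NA)
  }

  ## --- differential abundance ---
  if (!done("diffabund")) {
    log("diffabund")
    sp_counts <- pel_to_counts(sp_ab)
    da_sp <- da_analysis(sp_counts, md, design = config$design,
                         threshold = config$taxon_p_adj)
    write_tsv(as.data.frame(da_sp), sf$diffabund[1])
    ann <- split_annotation(pel, bundle$catalog)$annotated
    pr_counts <- pel_to_counts(ann)
    da_pr <- da_analysis(pr_counts, md, design = config$design,
                         threshold = config$protein_p_adj)
    write_tsv(as.data.frame(da_pr), sf$diffabund[2])
  }
  da_sp <- read_tsv(sf$diffabund[1])
  da_pr <- read_tsv(sf$diffabund[2])
  class(da_pr) <- c("mp_da", "data.frame")

  ## --- enrichment ---
  ann <- split_annotation(pel, bundle$catalog)$annotated
  pr_counts <- pel_to_counts(ann)
  if (!done("enrich")) {
    log("enrich")
    prof <- categorize_functions(bundle$catalog, bundle$maps)
    write_tsv(prof$pathway_counts, sf$enrich[2])
    gs <- gene_stats(da_pr)
    ko_of <- bundle$catalog$ko_id[match(names(gs), bundle$catalog$protein_id)]
    memb <- merge(data.frame(feature_id = names(gs), ko_id = ko_of,
                             stringsAsFactors = FALSE),
                  bundle$maps$ko_pathway, by = "ko_id")
    memb <- data.frame(set_id = memb$pathway_id, feature_id = memb$feature_id,
                       stringsAsFactors = FALSE)
    enr <- enrich_sets(gs, memb, n_perm = config$n_perm_enrich,
                       seed = config$seed)
    write_tsv(enr, sf$enrich[1])
    enriched <- enr$set_id[enr$p_dir_up < config$enrichment_p]
    if (length(enriched)) {
      tk <- targeted_kos(da_pr, enriched, pr_counts, md, bundle$catalog,
                         bundle$maps, design = config$design,
                         ko_p = config$ko_p,
                         protein_threshold = config$protein_p_adj)
      write_tsv(tk$ko_results, sf$enrich[3])
      write_tsv(tk$key_proteins, sf$enrich[4])
    } else {
      write_tsv(data.frame(), sf$enrich[3])
      write_tsv(data.frame(protein_id = character(), species = character(),
                           ko_id = character(), pathways = character(),
                           log2fc_shrunk = numeric(), p_adj = numeric()),
                sf$enrich[4])
    }
  }
  enr <- read_tsv(sf$enrich[1])
  key <- read_tsv(sf$enrich[4])

  ## --- routes ---
  if (!done("routes")) {
    log("routes")
    abundant <- da_sp$feature_id[!is.na(da_sp$p_adj) &
                                   da_sp$p_adj < config$taxon_p_adj &
                                   da_sp$log2fc_shrunk > 0]
    enriched <- enr$set_id[enr$p_dir_up < config$enrichment_p]
    rt <- suppressWarnings(
      build_routes(abundant, key, bundle$catalog, bundle$maps, enriched,
                   pel = pel))
    write_routes(rt, sf$routes[1], sf$routes[2], sf$routes[3])
    if (nrow(key)) {
      write_tsv(bubble_table(intersect(key$protein_id, rownames(pel)),
                             pel, md), sf$routes[4])
    } else {
      write_tsv(data.frame(protein_id = character(), group = character(),
                           mean_pel = numeric()), sf$routes[4])
    }
  }

  ## --- report ---
  if (!done("report")) {
    log("report")
    rep <- consistency_report(counts_table, strict = strict)
    write_tsv(rep, sf$report)
  }
  rep <- read_tsv(sf$report)
  if (strict && !all(rep$pass)) stop("consistency report FAILED")

  files <- sort(unlist(sf, use.names = FALSE))
  files <- files[file.exists(files)]
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest,
                 status = if (all(rep$pass)) "ok" else "failed-checks"))
}

#' Consistency checks on the count summary table
#'
#' Verifies the Table-1-style arithmetic on [tabulate_counts()] output:
#' annotated + unannotated = total in every count column and group,
#' mean = total / n_samples, and grand totals equal the sum over groups.
#'
#' @param tab output of [tabulate_counts()].
#' @param strict stop on any failing check.
#' @return data.frame `check`, `value`, `pass` with attribute
#'   `grand_totals`.
#' @export
consistency_report <- function(tab, strict = FALSE) {
  checks <- list()
  add <- function(name, value, pass) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = value, pass = pass, stringsAsFactors = FALSE)
  }
  tol <- 1e-8
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    rget <- function(cls, col) sub[sub$class == cls, col]
    for (col in c("spectral_total", "peptide_total", "n_proteins")) {
      ok <- abs(rget("annotated", col) + rget("unannotated", col) -
                  rget("total", col)) < tol
      add(paste0(g, ": annotated+unannotated=total (", col, ")"),
          rget("total", col), ok)
    }
    for (kind in c("spectral", "peptide")) {
      ok <- abs(rget("total", paste0(kind, "_mean")) -
                  rget("total", paste0(kind, "_total")) /
                  rget("total", "n_samples")) < tol
      add(paste0(g, ": mean=total/n (", kind, ")"),
          rget("total", paste0(kind, "_mean")), ok)
    }
  }
  tot <- tab[tab$class == "total", ]
  gt_spec <- sum(tot$spectral_total)
  gt_pep <- sum(tot$peptide_total)
  add("grand total spectral counts", gt_spec, TRUE)
  add("grand total unique peptide counts", gt_pep, TRUE)
  out <- do.call(rbind, checks)
  attr(out, "grand_totals") <- c(spectral = gt_spec, peptides = gt_pep)
  if (strict && !all(out$pass)) {
    stop("consistency report FAILED: ",
         paste(out$check[!out$pass], collapse = "; "))
  }
  out
}
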
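#' Two-arm, two-phase study design
#'
#' A placebo-controlled prebiotic trial layout: each subject belongs to one
#' arm (CMH or PB) and contributes exactly one sample per phase (baseline,
#' treatment), giving the four groups bPB, bCMH, tPB, tCMH.
#'
#' @param n_subjects_per_arm subjects per arm (default 10, i.e. 40 samples).
#' @return sample metadata data.frame with columns `sample`, `subject`,
#'   `arm`, `phase`, `group` (class `mp_design`).
#' @export
study_design <- function(n_subjects_per_arm = 10) {
  if (!is.numeric(n_subjects_per_arm) || n_subjects_per_arm < 1)
    stop("validation error: need at least 1 subject per arm")
  n <- as.integer(n_subjects_per_arm)
  subj <- c(sprintf("PB%02d", seq_len(n)), sprintf("CMH%02d", seq_len(n)))
  arm <- rep(c("PB", "CMH"), each = n)
  md <- expand.grid(subject = subj, phase = c("baseline", "treatment"),
                    stringsAsFactors = FALSE)
  md$arm <- arm[match(md$subject, subj)]
  md$group <- paste0(ifelse(md$phase == "baseline", "b", "t"), md$arm)
  md$sample <- paste0(md$group, "_", md$subject)
  md <- md[order(md$group, md$subject), c("sample", "subject", "arm", "phase", "group")]
  rownames(md) <- NULL
  class(md) <- c("mp_design", "data.frame")
  md
}

#' Catalog size specification for the synthetic generator
#'
#' Defaults mirror the study scale loosely: 15 candidate gut-bacterial
#' families, 2 species per genus and 3 strains per species.
#'
#' @param families character vector of family names.
#' @param genera_per_family,species_per_genus,strains_per_species,proteins_per_strain sizes.
#' @param annotated_frac fraction of proteins with an assigned function.
#' @param ko_frac fraction of annotated proteins carrying a KO.
#' @param n_kos,n_pathways size of the KO universe and pathway set.
#' @return list of class `mp_catalog_spec`.
#' @export
catalog_spec <- function(families = gut_families(),
                         genera_per_family = 1, species_per_genus = 2,
                         strains_per_species = 3, proteins_per_strain = 8,
                         annotated_frac = 0.975, ko_frac = 0.4,
                         n_kos = 60, n_pathways = 20) {
  out <- list(families = families, genera_per_family = genera_per_family,
              species_per_genus = species_per_genus,
              strains_per_species = strains_per_species,
              proteins_per_strain = proteins_per_strain,
              annotated_frac = annotated_frac, ko_frac = ko_frac,
              n_kos = n_kos, n_pathways = n_pathways)
  class(out) <- "mp_catalog_spec"
  out
}

#' The 15 candidate gut bacterial families
#'
#' Families used for the reference search space of the gut metaproteome.
#'
#' @return character vector of 15 family names.
#' @export
gut_families <- function() {
  c("Acidaminococcaceae", "Bacteroidaceae", "Bifidobacteriaceae",
    "Clostridiaceae", "Coriobacteriaceae", "Enterobacteriaceae",
    "Erysipelotrichaceae", "Eubacteriaceae", "Lachnospiraceae",
    "Lactobacillaceae", "Prevotellaceae", "Rikenellaceae",
    "Ruminococcaceae", "Streptococcaceae", "Veillonellaceae")
}

#' Generate a synthetic protein catalog and function maps
#'
#' @param spec [catalog_spec()].
#' @param seed integer seed.
#' @return list with `catalog` (`mp_catalog`) and `maps` (`mp_maps`).
#' @export
make_catalog <- function(spec = catalog_spec(), seed = 1) {
  set.seed(as.integer(seed))
  fam <- spec$families
  stem <- sub("aceae$", "", fam)
  rows <- list()
  pid <- 0L
  for (f in seq_along(fam)) {
    for (g in seq_len(spec$genera_per_family)) {
      genus <- paste0(stem[f], "_g", g)
      for (s in seq_len(spec$species_per_genus)) {
        species <- paste0(genus, "_sp", s)
        for (st in seq_len(spec$strains_per_species)) {
          strain <- paste0(species, "_st", st)
          n <- spec$proteins_per_strain
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = sprintf("P%06d", pid + seq_len(n)),
            family = fam[f], genus = genus, species = species,
            strain = strain, stringsAsFactors = FALSE)
          pid <- pid + n
        }
      }
    }
  }
  cat_df <- do.call(rbind, rows)
  np <- nrow(cat_df)
  cat_df$annotated <- stats::runif(np) < spec$annotated_frac
  kos <- sprintf("K%05d", seq_len(spec$n_kos))
  cat_df$ko_id <- NA_character_
  has_ko <- cat_df$annotated & stats::runif(np) < spec$ko_frac
  cat_df$ko_id[has_ko] <- sample(kos, sum(has_ko), replace = TRUE)

  pw <- sprintf("path%03d", seq_len(spec$n_pathways))
  mains <- c("Metabolism", "Genetic Information Processing",
             "Environmental Information Processing", "Cellular Processes",
             "Human Diseases", "Organismal Systems")
  main_of <- sample(rep(mains, length.out = spec$n_pathways))
  pc <- data.frame(pathway_id = pw, main_category = main_of,
                   subcategory = paste0(main_of, " / sub",
                                        stats::ave(seq_along(pw), main_of, FUN = seq_along)),
                   stringsAsFactors = FALSE)
  n_extra <- stats::rbinom(spec$n_kos, 1, 0.3)
  kp <- data.frame(
    ko_id = rep(kos, 1 + n_extra),
    pathway_id = unlist(lapply(seq_len(spec$n_kos), function(i)
      sample(pw, 1 + n_extra[i]))),
    stringsAsFactors = FALSE)
  kp <- unique(kp[order(kp$ko_id, kp$pathway_id), ])
  rownames(kp) <- NULL
  list(catalog = protein_catalog(cat_df), maps = function_maps(kp, pc))
}

#' Intensity model for the synthetic generator
#'
#' Peptide intensities are zero-inflated log-normal: per-protein location on
#' the log scale, a per-peptide offset, i.i.d. residual noise per
#' (peptide, sample), and missing-at-random dropout applied independently per
#' (peptide, sample). Planted effects multiply intensities of
#' treatment-phase CMH samples by `2^log2FC`.
#'
#' @param meanlog,sdlog_protein mean and SD of per-protein log-intensity
#'   locations (natural log of arbitrary MS intensity units).
#' @param sdlog_peptide SD of per-peptide offsets.
#' @param sigma residual SD of log-intensity per (peptide, sample).
#' @param p_zero dropout probability in `[0, 1)`.
#' @param peptides_per_protein mean peptides per protein (min 1).
#' @param shared_fraction fraction of peptides additionally matched to a
#'   protein of another strain (these are taxonomically ambiguous and are
#'   discarded by the filter).
#' @param within_strain_shared fraction of peptides additionally matched to a
#'   second protein of the same strain (retained).
#' @return list of class `mp_intensity_model`.
#' @export
intensity_model <- function(meanlog = 14, sdlog_protein = 1,
                            sdlog_peptide = 0.5, sigma = 0.6,
                            p_zero = 0.3, peptides_per_protein = 3,
                            shared_fraction = 0.1,
                            within_strain_shared = 0.05) {
  stopifnot(p_zero >= 0, p_zero < 1, shared_fraction >= 0, shared_fraction < 1,
            peptides_per_protein >= 1, sigma >= 0)
  out <- list(meanlog = meanlog, sdlog_protein = sdlog_protein,
              sdlog_peptide = sdlog_peptide, sigma = sigma, p_zero = p_zero,
              peptides_per_protein = peptides_per_protein,
              shared_fraction = shared_fraction,
              within_strain_shared = within_strain_shared)
  class(out) <- "mp_intensity_model"
  out
}

#' Planted ground truth
#'
#' @param da_taxa named numeric: species name -> true log2 fold change
#'   (treatment-phase CMH vs everything else).
#' @param de_proteins named numeric: protein_id -> true log2FC.
#' @param enriched_sets character vector of pathway IDs with a planted
#'   coordinated up-shift of their member proteins.
#' @param planted_routes named list: pathway ID -> character vector of
#'   species designated cooperative on that pathway.
#' @return list of class `mp_truth`.
#' @export
planted_truth <- function(da_taxa = numeric(), de_proteins = numeric(),
                          enriched_sets = character(),
                          planted_routes = list()) {
  stopifnot(all(is.finite(da_taxa)), all(is.finite(de_proteins)))
  route_sp <- unique(unlist(planted_routes, use.names = FALSE))
  out <- list(da_taxa = da_taxa, de_proteins = de_proteins,
              enriched_sets = enriched_sets, planted_routes = planted_routes,
              route_species = route_sp)
  class(out) <- "mp_truth"
  out
}

#' Plant a coherent truth on a catalog
#'
#' Chooses `n_da_species` species to shift at the taxon level, and plants a
#' coordinated protein-level up-shift on every KO-mapped protein of
#' `n_enriched_pathways` pathways. Planted routes record, per enriched
#' pathway, the species owning the shifted proteins.
#'
#' @param cat_maps output of [make_catalog()].
#' @param n_da_species number of differentially abundant species.
#' @param lfc_da log2FC magnitude for planted species (alternating sign).
#' @param n_enriched_pathways pathways given a coordinated up-shift.
#' @param lfc_de log2FC for planted proteins of enriched pathways.
#' @param seed integer seed.
#' @return `mp_truth`.
#' @export
plant_truth <- function(cat_maps, n_da_species = 4, lfc_da = 2,
                        n_enriched_pathways = 1, lfc_de = 2, seed = 1) {
  set.seed(as.integer(seed))
  catalog <- cat_maps$catalog
  maps <- cat_maps$maps
  sp <- sample(unique(catalog$species), n_da_species)
  da <- stats::setNames(rep_len(c(lfc_da, -lfc_da), n_da_species), sp)
  ## enriched pathways: pick pathways with enough KO-mapped proteins
  kp <- maps$ko_pathway
  prot_pw <- merge(catalog[!is.na(catalog$ko_id), c("protein_id", "species", "ko_id")],
                   kp, by = "ko_id")
  sizes <- table(prot_pw$pathway_id)
  eligible <- names(sizes)[sizes >= 5]
  pws <- sample(eligible, min(n_enriched_pathways, length(eligible)))
  de <- numeric(); routes <- list()
  for (p in pws) {
    memb <- prot_pw[prot_pw$pathway_id == p, ]
    de <- c(de, stats::setNames(rep(lfc_de, nrow(memb)), memb$protein_id))
    routes[[p]] <- sort(unique(memb$species))
  }
  de <- de[!duplicated(names(de))]
  planted_truth(da_taxa = da, de_proteins = de, enriched_sets = pws,
                planted_routes = routes)
}

#' Simulate a metaproteomic study bundle
#'
#' Generates a peptide-evidence table under the zero-inflated log-normal
#' intensity model with planted taxon/protein effects. Identical seeds give
#' identical bundles; catalog, intensity and dropout stages draw from named
#' substreams derived from the master seed so each can be regenerated
#' independently.
#'
#' @param design [study_design()].
#' @param model [intensity_model()].
#' @param catalog,maps from [make_catalog()].
#' @param truth [planted_truth()]; `NULL` means no planted effects.
#' @param seed integer master seed.
#' @return list (class `mp_bundle`) with `peptides`, `catalog`, `maps`,
#'   `metadata`, `truth`.
#' @export
simulate_metaproteome <- function(design, model = intensity_model(),
                                  catalog, maps, truth = NULL, seed = 1) {
  if (is.null(truth)) truth <- planted_truth()
  if (nrow(design) < 4) stop("validation error: design too small")
  ss <- substream_seeds(seed, 3L)

  ## --- peptide skeleton (substream 1) ---
  set.seed(ss[1])
  np <- nrow(catalog)
  n_pep <- 1L + stats::rpois(np, model$peptides_per_protein - 1)
  prot_idx <- rep(seq_len(np), n_pep)
  m <- length(prot_idx)
  pep_id <- sprintf("PEP%07d", seq_len(m))
  strain_of <- catalog$strain[prot_idx]
  primary <- catalog$protein_id[prot_idx]

  ## cross-strain sharing: ambiguous peptides (discarded downstream)
  shared <- stats::runif(m) < model$shared_fraction
  extra <- rep(NA_character_, m)
  if (any(shared)) {
    cand <- sample.int(np, sum(shared), replace = TRUE)
    ## ensure the extra match is a different strain
    same <- catalog$strain[cand] == strain_of[shared]
    while (any(same)) {
      cand[same] <- sample.int(np, sum(same), replace = TRUE)
      same <- catalog$strain[cand] == strain_of[shared]
    }
    extra[shared] <- catalog$protein_id[cand]
  }
  ## within-strain sharing: second protein of the same strain (retained)
  wshare <- !shared & stats::runif(m) < model$within_strain_shared
  if (any(wshare)) {
    idx <- which(wshare)
    strains <- split(catalog$protein_id, catalog$strain)
    for (i in idx) {
      pool <- setdiff(strains[[strain_of[i]]], primary[i])
      if (length(pool)) extra[i] <- pool[sample.int(length(pool), 1)]
    }
  }
  protein_ids <- ifelse(is.na(extra), primary, paste(primary, extra, sep = ";"))

  ## --- intensities (substream 2) ---
  set.seed(ss[2])
  ns <- nrow(design)
  mu_prot <- stats::rnorm(np, model$meanlog, model$sdlog_protein)
  pep_off <- stats::rnorm(m, 0, model$sdlog_peptide)
  ## planted log2FC per protein = protein effect + its species' taxon effect
  lfc <- rep(0, np)
  if (length(truth$de_proteins)) {
    j <- match(names(truth$de_proteins), catalog$protein_id)
    lfc[j[!is.na(j)]] <- lfc[j[!is.na(j)]] + truth$de_proteins[!is.na(j)]
  }
  if (length(truth$da_taxa)) {
    j <- match(catalog$species, names(truth$da_taxa))
    lfc <- lfc + ifelse(is.na(j), 0, truth$da_taxa[j])
  }
  treated <- design$arm == "CMH" & design$phase == "treatment"
  loc <- outer(mu_prot[prot_idx] + pep_off, rep(0, ns), `+`)
  loc <- loc + outer(lfc[prot_idx] * log(2), as.numeric(treated), `*`)
  logint <- loc + matrix(stats::rnorm(m * ns, 0, model$sigma), m, ns)

  ## --- dropout (substream 3) ---
  set.seed(ss[3])
  keep <- matrix(stats::runif(m * ns) >= model$p_zero, m, ns)

  obs <- which(keep)
  row_i <- ((obs - 1L) %% m) + 1L
  col_i <- ((obs - 1L) %/% m) + 1L
  peptides <- data.frame(
    peptide = pep_id[row_i],
    protein_ids = protein_ids[row_i],
    sample = design$sample[col_i],
    intensity = exp(logint[obs]),
    stringsAsFactors = FALSE)
  peptides <- peptides[order(peptides$peptide, peptides$sample), ]
  rownames(peptides) <- NULL

  out <- list(peptides = peptides, catalog = catalog, maps = maps,
              metadata = as.data.frame(design), truth = truth)
  class(out) <- "mp_bundle"
  out
}

#' Simulate a null bundle (no planted effects)
#'
#' @param design [study_design()].
#' @param seed integer seed.
#' @param model [intensity_model()].
#' @param spec [catalog_spec()].
#' @return `mp_bundle` with empty truth.
#' @export
make_null <- function(design = study_design(), seed = 1,
                      model = intensity_model(), spec = catalog_spec()) {
  cm <- make_catalog(spec, seed = seed)
  simulate_metaproteome(design, model, cm$catalog, cm$maps,
                        truth = planted_truth(), seed = seed)
}

#' Write a bundle to a directory
#'
#' Emits `peptides.tsv`, `catalog.tsv`, `ko_pathway.tsv`,
#' `pathway_category.tsv`, `metadata.tsv` and the planted-truth record
#' `truth.json`.
#'
#' @param bundle `mp_bundle`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(
    write_tsv(bundle$peptides, file.path(dir, "peptides.tsv")),
    write_catalog(bundle$catalog, file.path(dir, "catalog.tsv")),
    write_function_maps(bundle$maps, file.path(dir, "ko_pathway.tsv"),
                        file.path(dir, "pathway_category.tsv")),
    write_tsv(bundle$metadata, file.path(dir, "metadata.tsv")))
  tj <- file.path(dir, "truth.json")
  tr <- bundle$truth
  ## named vectors as JSON objects so names survive the round trip
  payload <- list(da_taxa = as.list(tr$da_taxa),
                  de_proteins = as.list(tr$de_proteins),
                  enriched_sets = tr$enriched_sets,
                  planted_routes = lapply(tr$planted_routes, as.list))
  jsonlite::write_json(payload, tj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(p, tj))
}

#' Read a bundle from a directory written by [write_bundle()]
#'
#' @param dir directory.
#' @return `mp_bundle`.
#' @export
read_bundle <- function(dir) {
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- planted_truth(
    da_taxa = if (length(tr$da_taxa)) unlist(tr$da_taxa) else numeric(),
    de_proteins = if (length(tr$de_proteins)) unlist(tr$de_proteins) else numeric(),
    enriched_sets = as.character(unlist(tr$enriched_sets)),
    planted_routes = lapply(tr$planted_routes, as.character))
  out <- list(
    peptides = read_peptides(file.path(dir, "peptides.tsv")),
    catalog = read_catalog(file.path(dir, "catalog.tsv")),
    maps = read_function_maps(file.path(dir, "ko_pathway.tsv"),
                              file.path(dir, "pathway_category.tsv")),
    metadata = read_tsv(file.path(dir, "metadata.tsv")),
    truth = truth)
  class(out) <- "mp_bundle"
  out
}
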
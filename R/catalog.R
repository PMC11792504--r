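#' Protein reference catalog
#'
#' The catalog carries, for every protein accession, a four-level strain
#' resolved lineage (family / genus / species / strain), an annotation flag
#' (`TRUE` = protein ID with an assigned function) and an optional KEGG
#' Orthology (KO) accession. All downstream taxonomic inference relies on the
#' catalog: a peptide is taxonomically informative only when every protein it
#' matches belongs to a single strain.
#'
#' @param df data.frame with columns `protein_id`, `family`, `genus`,
#'   `species`, `strain`, `annotated` (logical), `ko_id` (character, `NA`
#'   when absent).
#' @return the validated catalog (class `mp_catalog`).
#' @export
protein_catalog <- function(df) {
  req <- c("protein_id", "family", "genus", "species", "strain", "annotated", "ko_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("catalog is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$protein_id <- as.character(df$protein_id)
  df$annotated <- as.logical(df$annotated)
  df$ko_id <- as.character(df$ko_id)
  df$ko_id[!is.na(df$ko_id) & df$ko_id == ""] <- NA_character_
  validate_catalog(df)
  class(df) <- c("mp_catalog", "data.frame")
  df
}

#' Validate catalog invariants
#'
#' Checks that all lineage levels are non-empty, protein IDs are unique, and
#' the lineage is consistent: a strain never appears under two different
#' species (and likewise up the lineage). Names are compared exactly and
#' case-sensitively.
#'
#' @param df catalog data.frame.
#' @return `TRUE` invisibly; stops with an integrity error otherwise.
#' @export
validate_catalog <- function(df) {
  if (nrow(df) == 0) stop("catalog is empty")
  lev <- c("family", "genus", "species", "strain")
  for (l in lev) {
    bad <- is.na(df[[l]]) | !nzchar(df[[l]])
    if (any(bad)) stop("integrity error: empty ", l, " for protein(s) ",
                       paste(utils::head(df$protein_id[bad], 3), collapse = ", "))
  }
  dup <- duplicated(df$protein_id)
  if (any(dup)) stop("integrity error: duplicate protein_id: ",
                     paste(unique(df$protein_id[dup])[1:min(3, sum(dup))], collapse = ", "))
  ## lineage consistency: each strain maps to exactly one (family,genus,species)
  key <- unique(df[, lev])
  for (child in c("strain", "species", "genus")) {
    parent <- lev[match(child, lev) - 1L]
    tab <- unique(key[, c(parent, child)])
    dupc <- duplicated(tab[[child]])
    if (any(dupc)) stop("integrity error: ", child, " '",
                        tab[[child]][dupc][1],
                        "' appears under more than one ", parent)
  }
  if (any(is.na(df$annotated))) stop("integrity error: annotated flag must be TRUE/FALSE")
  invisible(TRUE)
}

#' Read a protein catalog
#'
#' Two dialects are supported. `tsv`: tab-delimited with the columns of
#' [protein_catalog()]. `fasta`: headers of the form
#' `>protein_id|family|genus|species|strain|{0,1}|KOxxxxx` where the trailing
#' KO field is omitted when no KO is assigned and `|` is forbidden inside
#' names.
#'
#' @param path file path.
#' @param format `"tsv"` or `"fasta"`.
#' @return catalog (class `mp_catalog`).
#' @export
read_catalog <- function(path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(path)
    if (!"ko_id" %in% names(df)) df$ko_id <- NA_character_
    return(protein_catalog(df))
  }
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  n <- lengths(parts)
  bad <- which(n < 6L | n > 7L)
  if (length(bad)) stop("parse error: malformed FASTA header at record ", bad[1],
                        ": '", hdr[bad[1]], "'")
  get <- function(i) vapply(parts, `[[`, "", i)
  ann <- get(6)
  if (!all(ann %in% c("0", "1"))) {
    stop("parse error: annotation flag must be 0/1 at record ",
         which(!ann %in% c("0", "1"))[1])
  }
  ko <- vapply(parts, function(p) if (length(p) == 7L) p[[7]] else NA_character_, "")
  protein_catalog(data.frame(
    protein_id = get(1), family = get(2), genus = get(3),
    species = get(4), strain = get(5),
    annotated = ann == "1", ko_id = ko, stringsAsFactors = FALSE))
}

#' Write a protein catalog
#'
#' @param catalog catalog.
#' @param path output file.
#' @param format `"tsv"` or `"fasta"`.
#' @param sequences named character of protein sequences for FASTA output;
#'   a placeholder sequence is written when absent.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("tsv", "fasta"),
                          sequences = NULL) {
  format <- match.arg(format)
  if (format == "tsv") return(write_tsv(as.data.frame(catalog), path))
  nm <- names(catalog)[1:5]
  fields <- do.call(paste, c(unname(as.data.frame(catalog)[nm]), sep = "|"))
  hdr <- paste0(fields, "|", as.integer(catalog$annotated),
                ifelse(is.na(catalog$ko_id), "", paste0("|", catalog$ko_id)))
  if (is.null(sequences)) {
    sequences <- rep("MKAAAKQLV", nrow(catalog))
  } else {
    sequences <- unname(sequences[catalog$protein_id])
  }
  x <- Biostrings::AAStringSet(sequences)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read KO/pathway function maps
#'
#' @param ko_pathway_path TSV with columns `ko_id`, `pathway_id` (one row per
#'   KO-pathway membership; a KO may map to several pathways).
#' @param pathway_category_path TSV with columns `pathway_id`,
#'   `main_category`, `subcategory`.
#' @return list with elements `ko_pathway` and `pathway_category`
#'   (class `mp_maps`).
#' @export
read_function_maps <- function(ko_pathway_path, pathway_category_path) {
  function_maps(read_tsv(ko_pathway_path), read_tsv(pathway_category_path))
}

#' Construct/validate function maps
#'
#' Every pathway referenced by `ko_pathway` must carry a category.
#'
#' @param ko_pathway data.frame `ko_id`, `pathway_id`.
#' @param pathway_category data.frame `pathway_id`, `main_category`,
#'   `subcategory`.
#' @return `mp_maps` list.
#' @export
function_maps <- function(ko_pathway, pathway_category) {
  stopifnot(all(c("ko_id", "pathway_id") %in% names(ko_pathway)),
            all(c("pathway_id", "main_category", "subcategory") %in%
                  names(pathway_category)))
  ko_pathway <- unique(ko_pathway[, c("ko_id", "pathway_id")])
  orphan <- setdiff(ko_pathway$pathway_id, pathway_category$pathway_id)
  if (length(orphan)) stop("integrity error: pathway without category: ",
                           paste(utils::head(orphan, 3), collapse = ", "))
  if (anyDuplicated(pathway_category$pathway_id))
    stop("integrity error: duplicate pathway_id in category map")
  out <- list(ko_pathway = ko_pathway, pathway_category = pathway_category)
  class(out) <- "mp_maps"
  out
}

#' Write function maps
#'
#' @param maps `mp_maps`.
#' @param ko_pathway_path,pathway_category_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_function_maps <- function(maps, ko_pathway_path, pathway_category_path) {
  write_tsv(maps$ko_pathway, ko_pathway_path)
  write_tsv(maps$pathway_category, pathway_category_path)
  invisible(c(ko_pathway_path, pathway_category_path))
}

#' Count catalog entries by annotation status
#'
#' @param catalog catalog.
#' @return named numeric: `annotated`, `unannotated`, `total`
#'   (annotated + unannotated == total always).
#' @export
count_by_annotation <- function(catalog) {
  if (nrow(catalog) == 0) stop("empty catalog")
  a <- sum(catalog$annotated)
  u <- sum(!catalog$annotated)
  c(annotated = a, unannotated = u, total = a + u)
}
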
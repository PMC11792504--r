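#' Read a peptide-evidence table
#'
#' Canonical columns: `peptide`, `protein_ids` (semicolon-separated protein
#' accessions), `sample`, `intensity`. A search-engine protein-groups style
#' table with columns `Sequence`, `Proteins`, `Raw file`/`Sample`,
#' `Intensity` is accepted and converted.
#'
#' @param path TSV path.
#' @return data.frame in canonical form.
#' @export
read_peptides <- function(path) {
  df <- read_tsv(path)
  alias <- c(Sequence = "peptide", Proteins = "protein_ids",
             `Raw file` = "sample", Sample = "sample", Intensity = "intensity")
  hit <- names(alias) %in% names(df)
  if (any(hit)) names(df)[match(names(alias)[hit], names(df))] <- alias[hit]
  req <- c("peptide", "protein_ids", "sample", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("peptide table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[req]
  df$intensity <- as.numeric(df$intensity)
  if (any(is.na(df$intensity) | df$intensity < 0))
    stop("peptide intensities must be non-negative")
  if (any(is.na(df$protein_ids) | !nzchar(df$protein_ids)))
    stop("peptide with empty protein match set")
  df
}

#' Classify peptides as strain-specific or ambiguous
#'
#' A peptide is retained if and only if all its matched proteins belong to a
#' single bacterial strain; peptides whose matches span several strains carry
#' no taxonomic signal and are discarded. A peptide matching several proteins
#' of one strain is retained and later contributes to each matched protein.
#'
#' @param peptides canonical peptide table.
#' @param catalog protein catalog.
#' @return list with `retained` and `discarded` data.frames
#'   (disjoint; their union is the input).
#' @export
classify_peptides <- function(peptides, catalog) {
  ids <- strsplit(peptides$protein_ids, ";", fixed = TRUE)
  flat <- unlist(ids, use.names = FALSE)
  idx <- match(flat, catalog$protein_id)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    row <- rep(seq_along(ids), lengths(ids))[bad]
    stop("lookup error: unknown protein ID '", flat[bad],
         "' for peptide '", peptides$peptide[row], "'")
  }
  strain <- catalog$strain[idx]
  g <- rep(seq_along(ids), lengths(ids))
  n_strain <- vapply(split(strain, g), function(s) length(unique(s)), 1L)
  keep <- n_strain == 1L
  list(retained = peptides[keep, , drop = FALSE],
       discarded = peptides[!keep, , drop = FALSE])
}

#' Compute protein expression levels (PELs)
#'
#' PEL of protein p in sample s is the maximum intensity over the retained
#' strain-specific peptides matching p in s; a peptide matching several
#' proteins of one strain contributes to each. Undetected cells are 0 (never
#' `NA`), as downstream taxonomic sums require explicit zeros.
#'
#' @param retained retained peptide table from [classify_peptides()].
#' @param catalog protein catalog.
#' @param samples optional character vector of sample IDs defining (and
#'   ordering) the columns; defaults to the samples present.
#' @return numeric matrix, rows = proteins with at least one retained
#'   peptide, columns = samples.
#' @export
compute_pel <- function(retained, catalog, samples = NULL) {
  ids <- strsplit(retained$protein_ids, ";", fixed = TRUE)
  n <- lengths(ids)
  long <- data.frame(
    protein_id = unlist(ids, use.names = FALSE),
    sample = rep(retained$sample, n),
    intensity = rep(retained$intensity, n),
    stringsAsFactors = FALSE)
  if (is.null(samples)) samples <- sort(unique(long$sample))
  prots <- sort(unique(long$protein_id))
  unknown <- setdiff(prots, catalog$protein_id)
  if (length(unknown)) stop("lookup error: unknown protein ID ", unknown[1])
  m <- matrix(0, length(prots), length(samples),
              dimnames = list(prots, samples))
  key <- paste(long$protein_id, long$sample, sep = "\r")
  mx <- tapply(long$intensity, key, max)
  parts <- strsplit(names(mx), "\r", fixed = TRUE)
  ri <- match(vapply(parts, `[[`, "", 1), prots)
  ci <- match(vapply(parts, `[[`, "", 2), samples)
  ok <- !is.na(ci)
  m[cbind(ri[ok], ci[ok])] <- mx[ok]
  m
}

#' Split a PEL matrix by annotation status
#'
#' @param pel PEL matrix.
#' @param catalog protein catalog.
#' @return list of matrices `annotated` and `unannotated` (row-disjoint
#'   partition; either may have zero rows).
#' @export
split_annotation <- function(pel, catalog) {
  ann <- catalog$annotated[match(rownames(pel), catalog$protein_id)]
  if (anyNA(ann)) stop("PEL matrix row not present in catalog")
  list(annotated = pel[ann, , drop = FALSE],
       unannotated = pel[!ann, , drop = FALSE])
}

#' Per-group peptide/protein count summary
#'
#' Table-1 style summary: per sample group and annotation class, the total
#' spectral count (number of retained peptide observations), the total unique
#' peptide count (distinct peptide-protein pairs), the number of detected
#' proteins, and per-sample mean and SD of the per-sample counts. The mean is
#' total / n_samples by construction; SD uses the n-1 denominator and is 0
#' (with a warning) for single-sample groups. A peptide observation counts as
#' annotated when any of its matched proteins is annotated.
#'
#' @param retained retained peptide table.
#' @param pel PEL matrix.
#' @param catalog protein catalog.
#' @param metadata sample metadata with `sample` and `group`.
#' @return data.frame with one row per (group, class), class in
#'   annotated/unannotated/total.
#' @export
tabulate_counts <- function(retained, pel, catalog, metadata) {
  stopifnot(all(retained$sample %in% metadata$sample))
  ids <- strsplit(retained$protein_ids, ";", fixed = TRUE)
  ann_of <- function(pids) any(catalog$annotated[match(pids, catalog$protein_id)])
  row_ann <- vapply(ids, ann_of, TRUE)
  grp <- metadata$group[match(retained$sample, metadata$sample)]
  groups <- unique(metadata$group)

  ## unique (peptide, protein) pairs, expanded
  n <- lengths(ids)
  pairs <- data.frame(peptide = rep(retained$peptide, n),
                      protein_id = unlist(ids, use.names = FALSE),
                      sample = rep(retained$sample, n),
                      stringsAsFactors = FALSE)
  pairs$ann <- catalog$annotated[match(pairs$protein_id, catalog$protein_id)]
  pairs$grp <- metadata$group[match(pairs$sample, metadata$sample)]

  ann_pel <- split_annotation(pel, catalog)
  out <- list()
  for (g in groups) {
    smp <- metadata$sample[metadata$group == g]
    ns <- length(smp)
    if (ns == 1) warning("group ", g, ": single sample, SD reported as 0")
    for (cls in c("annotated", "unannotated", "total")) {
      in_cls <- switch(cls, annotated = row_ann, unannotated = !row_ann,
                       total = rep(TRUE, length(row_ann)))
      rows <- grp == g & in_cls
      per_sample <- vapply(smp, function(s) sum(rows & retained$sample == s), 1)
      pin <- switch(cls, annotated = pairs$ann, unannotated = !pairs$ann,
                    total = rep(TRUE, nrow(pairs)))
      sub <- pairs[pin & pairs$grp == g, c("peptide", "protein_id", "sample")]
      pp_per_sample <- vapply(smp, function(s) {
        nrow(unique(sub[sub$sample == s, c("peptide", "protein_id")]))
      }, 1)
      pp_total <- sum(pp_per_sample)
      mat <- switch(cls, annotated = ann_pel$annotated,
                    unannotated = ann_pel$unannotated, total = pel)
      npro <- sum(rowSums(mat[, intersect(colnames(mat), smp), drop = FALSE]) > 0)
      sdv <- function(x) if (length(x) > 1) stats::sd(x) else 0
      out[[length(out) + 1L]] <- data.frame(
        group = g, class = cls, n_samples = ns,
        spectral_total = sum(per_sample),
        spectral_mean = sum(per_sample) / ns, spectral_sd = sdv(per_sample),
        peptide_total = pp_total,
        peptide_mean = pp_total / ns, peptide_sd = sdv(pp_per_sample),
        n_proteins = npro, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
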
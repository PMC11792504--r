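#' Roll PELs up the taxonomy
#'
#' Sums protein expression levels over all proteins sharing a taxon at the
#' requested level, per sample. Summation is exact; taxa whose detected
#' proteins are all zero in a sample keep an explicit 0 cell.
#'
#' @param pel PEL matrix (rows = proteins).
#' @param catalog protein catalog.
#' @param level one of `"family"`, `"genus"`, `"species"`.
#' @return numeric matrix, rows = taxa at `level`, columns = samples.
#' @export
rollup <- function(pel, catalog, level = c("species", "genus", "family")) {
  level <- match.arg(level)
  taxon <- catalog[[level]][match(rownames(pel), catalog$protein_id)]
  if (anyNA(taxon)) stop("PEL matrix row not present in catalog")
  out <- rowsum(pel, group = taxon, reorder = TRUE)
  out[order(rownames(out)), , drop = FALSE]
}

#' Relative abundance per sample
#'
#' @param tab taxon abundance matrix (taxa x samples).
#' @return matrix of the same shape with each column summing to 1.
#' @export
relative_abundance <- function(tab) {
  tot <- colSums(tab)
  if (any(tot <= 0)) stop("all-zero sample: ",
                          colnames(tab)[which(tot <= 0)[1]])
  sweep(tab, 2, tot, "/")
}

#' Group-pooled composition profile
#'
#' Pools samples within each group by summing PELs, then normalizes, giving a
#' stacked-composition table (group x taxon x relative abundance).
#'
#' @param tab taxon abundance matrix.
#' @param metadata sample metadata with `sample` and `group`.
#' @return long data.frame with columns `group`, `taxon`, `rel_abundance`.
#' @export
group_composition <- function(tab, metadata) {
  grp <- metadata$group[match(colnames(tab), metadata$sample)]
  if (anyNA(grp)) stop("sample missing from metadata")
  pooled <- t(rowsum(t(tab), group = grp))
  rel <- relative_abundance(pooled)
  out <- data.frame(
    group = rep(colnames(rel), each = nrow(rel)),
    taxon = rep(rownames(rel), ncol(rel)),
    rel_abundance = as.vector(rel), stringsAsFactors = FALSE)
  out[order(out$group, out$taxon), ]
}
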
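# Independent brute-force oracles and tiny fixtures, kept deliberately
# separate from the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_catalog <- function() {
  protein_catalog(data.frame(
    protein_id = c("A1", "A2", "B1", "C1", "C2", "D1"),
    family  = c("FamX", "FamX", "FamX", "FamY", "FamY", "FamY"),
    genus   = c("GenX", "GenX", "GenX", "GenY", "GenY", "GenY"),
    species = c("SpX1", "SpX1", "SpX2", "SpY1", "SpY1", "SpY2"),
    strain  = c("StX1a", "StX1a", "StX2a", "StY1a", "StY1b", "StY2a"),
    annotated = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    ko_id = c("K00001", "K00002", NA, "K00001", NA, "K00003"),
    stringsAsFactors = FALSE))
}

random_peptide_table <- function(catalog, n, samples, seed) {
  set.seed(seed)
  pick <- function() {
    k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    paste(sample(catalog$protein_id, k), collapse = ";")
  }
  data.frame(
    peptide = sprintf("pep%03d", sample(seq_len(n), n)),
    protein_ids = replicate(n, pick()),
    sample = sample(samples, n, replace = TRUE),
    intensity = round(stats::rlnorm(n, 5, 1), 3),
    stringsAsFactors = FALSE)
}

## row-by-row reimplementation of the strain-uniqueness filter
bf_classify <- function(peptides, catalog) {
  keep <- logical(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pids <- strsplit(peptides$protein_ids[i], ";")[[1]]
    strains <- catalog$strain[match(pids, catalog$protein_id)]
    keep[i] <- length(unique(strains)) == 1
  }
  keep
}

## group-by max over expanded (protein, sample) pairs
bf_pel <- function(retained, samples) {
  cells <- list()
  for (i in seq_len(nrow(retained))) {
    for (pid in strsplit(retained$protein_ids[i], ";")[[1]]) {
      key <- paste(pid, retained$sample[i])
      cells[[key]] <- max(cells[[key]] %||% 0, retained$intensity[i])
    }
  }
  prots <- sort(unique(vapply(strsplit(names(cells), " "), `[[`, "", 1)))
  m <- matrix(0, length(prots), length(samples),
              dimnames = list(prots, samples))
  for (key in names(cells)) {
    kp <- strsplit(key, " ")[[1]]
    if (kp[2] %in% samples) m[kp[1], kp[2]] <- cells[[key]]
  }
  m
}

bf_rollup <- function(pel, catalog, level) {
  tax <- catalog[[level]][match(rownames(pel), catalog$protein_id)]
  taxa <- sort(unique(tax))
  m <- matrix(0, length(taxa), ncol(pel), dimnames = list(taxa, colnames(pel)))
  for (i in seq_len(nrow(pel))) m[tax[i], ] <- m[tax[i], ] + pel[i, ]
  m
}

bf_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

## step-up BH written independently of p.adjust
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## PERMANOVA pseudo-F from the Gower-centered distance partition
bf_permanova_f <- function(D, labels) {
  n <- nrow(D)
  ss_total <- sum(D^2) / (2 * n)
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ss_within <- ss_within + sum(D[idx, idx]^2) / (2 * length(idx))
  }
  a <- length(unique(labels))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

## all permutations of 1:n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

small_design <- function(n = 5) study_design(n)

small_spec <- function(...) {
  catalog_spec(genera_per_family = 1, species_per_genus = 1,
               strains_per_species = 2, proteins_per_strain = 4,
               ko_frac = 0.6, n_kos = 30, n_pathways = 10, ...)
}
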
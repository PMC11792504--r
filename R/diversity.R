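#' Alpha diversity per sample
#'
#' Observed taxa (count of positive cells), Shannon index in natural-log
#' units, and Simpson index as 1 - sum(p_i^2), computed on species-level PEL
#' compositions without rarefying (intensities are continuous).
#'
#' @param tab taxon abundance matrix (taxa x samples), typically species
#'   level.
#' @return data.frame with columns `sample`, `observed`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(tab) {
  if (any(colSums(tab) <= 0))
    stop("all-zero sample: ", colnames(tab)[which(colSums(tab) <= 0)[1]])
  x <- t(tab)
  data.frame(
    sample = colnames(tab),
    observed = as.integer(vegan::specnumber(x)),
    shannon = as.numeric(vegan::diversity(x, index = "shannon")),
    simpson = as.numeric(vegan::diversity(x, index = "simpson")),
    stringsAsFactors = FALSE)
}

#' Linear-model test of an arm effect on alpha diversity
#'
#' Ordinary least squares of each index on an arm indicator (CMH vs PB) with
#' phase as a covariate; two-sided p from the t statistic of the arm term.
#'
#' @param alphas output of [alpha_diversity()].
#' @param metadata sample metadata with `sample`, `arm`, `phase`.
#' @return data.frame with one row per index: `index`, `estimate`, `se`, `p`.
#' @export
alpha_regression <- function(alphas, metadata) {
  md <- metadata[match(alphas$sample, metadata$sample), ]
  if (length(unique(md$arm)) < 2 || min(table(md$arm)) < 2)
    stop("need at least 2 samples per arm")
  arm <- factor(md$arm, levels = c("PB", "CMH"))
  phase <- factor(md$phase)
  out <- lapply(c("observed", "shannon", "simpson"), function(ix) {
    y <- alphas[[ix]]
    fit <- if (nlevels(phase) > 1) stats::lm(y ~ arm + phase) else stats::lm(y ~ arm)
    if (qr(stats::model.matrix(fit))$rank < ncol(stats::model.matrix(fit)))
      stop("singular design in alpha regression")
    co <- suppressWarnings(summary(fit)$coefficients)
    est <- co["armCMH", 1]; se <- co["armCMH", 2]; p <- co["armCMH", 4]
    ## degenerate zero-residual fit: a null effect has p 1, a perfect split 0
    scale <- mean(abs(y)) + stats::sd(y) + 1e-300
    if (!is.finite(p) || suppressWarnings(summary(fit)$sigma) / scale < 1e-10)
      p <- if (abs(est) / scale < 1e-8) 1 else 0
    data.frame(index = ix, estimate = est, se = se, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bray-Curtis distance matrix
#'
#' D(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over taxa, per sample pair.
#'
#' @param tab taxon abundance matrix (taxa x samples), non-negative.
#' @return symmetric samples x samples matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(tab) {
  if (any(tab < 0)) stop("negative abundance")
  if (any(colSums(tab) <= 0))
    stop("all-zero sample: ", colnames(tab)[which(colSums(tab) <= 0)[1]])
  as.matrix(vegan::vegdist(t(tab), method = "bray"))
}

#' Principal coordinates analysis
#'
#' Classical scaling of a distance matrix via double centering. Eigenvalues
#' are returned sorted descending including negative ones; axes for
#' non-positive eigenvalues are dropped, with a warning when fewer than `k`
#' positive axes exist.
#'
#' @param D distance matrix.
#' @param k number of requested axes.
#' @return list with `coords` (samples x k') and `eigenvalues`.
#' @export
pcoa_ordination <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > npos) {
    warning("only ", npos, " positive eigenvalues; returning ", npos, " axes")
    k <- npos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coords = coords, eigenvalues = sort(eig, decreasing = TRUE))
}

#' PERMANOVA (ADONIS) on a distance matrix
#'
#' Partitions the distance matrix sum of squares by a grouping factor
#' (Gower-centered partition) and assesses significance by label
#' permutation: p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param D distance matrix.
#' @param labels group label per sample (ordered as D).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed making the permutations reproducible.
#' @param permutations optional explicit permutation matrix (rows =
#'   permutations of `1:n`), overriding `n_perm`; used e.g. for exhaustive
#'   enumeration on tiny instances.
#' @return list (class `mp_permanova`) with `f`, `r2`, `p`, `n_perm`.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  D <- as.matrix(D)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    stop("need >= 2 groups with >= 2 samples each")
  if (is.null(permutations) && n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  df <- data.frame(g = factor(labels))
  perm <- permutations %||% n_perm
  fit <- vegan::adonis2(stats::as.dist(D) ~ g, data = df, permutations = perm)
  out <- list(f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1],
              n_perm = if (is.matrix(perm)) nrow(perm) else n_perm)
  class(out) <- "mp_permanova"
  out
}

#' @export
print.mp_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$f, x$r2, x$p, x$n_perm))
  invisible(x)
}
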
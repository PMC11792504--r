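#' Convert a PEL matrix to integer pseudo-counts
#'
#' The differential-abundance stage models counts; PEL intensities are scaled
#' by one global factor so the median positive cell is near `target_median`,
#' then rounded half-up. A single global factor (rather than per-sample
#' scaling) preserves between-sample depth differences so that size-factor
#' normalization remains meaningful.
#'
#' @param pel non-negative matrix (features x samples).
#' @param target_median target median of positive scaled cells.
#' @return integer matrix of the same shape.
#' @export
pel_to_counts <- function(pel, target_median = 100) {
  pos <- pel[pel > 0]
  if (!length(pos)) stop("no positive cells")
  sc <- target_median / stats::median(pos)
  m <- round_half_up(pel * sc)
  storage.mode(m) <- "integer"
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the median ratio of its counts to the per-feature
#' geometric-mean reference, over features positive in all samples. If no
#' feature is positive everywhere, falls back to per-sample medians over the
#' features positive in that sample (with a warning). Size factors are
#' rescaled to geometric mean 1.
#'
#' @param counts non-negative matrix (features x samples).
#' @return positive numeric vector, one per sample.
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    ref <- rowMeans(lg[allpos, , drop = FALSE])
    s <- apply(lg[allpos, , drop = FALSE], 2, function(col) exp(stats::median(col - ref)))
  } else {
    warning("no feature positive in all samples; using positive-subset ratios")
    ref <- apply(lg, 1, function(r) mean(r[is.finite(r)]))
    s <- apply(lg, 2, function(col) {
      ok <- is.finite(col) & is.finite(ref)
      if (!any(ok)) stop("sample with no positive counts")
      exp(stats::median(col[ok] - ref[ok]))
    })
  }
  s / exp(mean(log(s)))
}

## design matrices for the tested contrast
da_design_matrices <- function(metadata, design = c("interaction", "arm")) {
  design <- match.arg(design)
  arm <- as.integer(metadata$arm == "CMH")
  if (design == "interaction") {
    phase <- as.integer(metadata$phase == "treatment")
    full <- cbind(intercept = 1, phase = phase, treat = arm * phase)
    reduced <- full[, 1:2, drop = FALSE]
  } else {
    full <- cbind(intercept = 1, treat = arm)
    reduced <- full[, 1, drop = FALSE]
  }
  if (qr(full)$rank < ncol(full)) stop("design matrix not full rank")
  list(full = full, reduced = reduced)
}

## Pearson moment estimator of NB dispersion: solve
## sum((y-mu)^2 / (mu + a*mu^2)) = n - p  for a, with mu from a Poisson fit.
pearson_dispersion <- function(y, mu, p, floor = 1e-8, ceiling = 100) {
  f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - (length(y) - p)
  if (f(floor) <= 0) return(floor)
  if (f(ceiling) > 0) return(ceiling)
  stats::uniroot(f, c(floor, ceiling), tol = 1e-6)$root
}

## Empirical-Bayes smoothing of per-feature log-dispersions toward the
## parametric mean-dispersion trend a(mu) = a0 + a1/mu. The shrinkage weight
## balances the sampling variance of a Pearson log-dispersion on n - p
## residual df (~ 2/(n-p)) against the cross-feature spread around the trend.
smooth_dispersions <- function(alphas, base_means, n, p, floor = 1e-8) {
  ok <- is.finite(alphas) & is.finite(base_means) & base_means > 0
  if (sum(ok) < 10) return(alphas)
  fit <- tryCatch(stats::lm(alphas[ok] ~ I(1 / base_means[ok])),
                  error = function(e) NULL)
  if (is.null(fit)) return(alphas)
  trend <- pmax(stats::coef(fit)[1] + stats::coef(fit)[2] / base_means, floor)
  la <- log(pmax(alphas, floor))
  ltr <- log(trend)
  v_samp <- 2 / (n - p)
  tau2 <- max(0, stats::var((la - ltr)[ok]) - v_samp)
  w <- v_samp / (v_samp + tau2)
  out <- exp((1 - w) * la + w * ltr)
  out[!ok] <- alphas[!ok]
  out
}

## one NB GLM fit with fixed dispersion; returns loglik, coefs, se
nb_glm_fixed <- function(y, X, offset, theta) {
  fam <- MASS::negative.binomial(theta = theta, link = "log")
  fit <- suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                         control = list(maxit = 50)))
  mu <- fit$fitted.values
  ll <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) matrix(NA, ncol(X), ncol(X)))
  list(ll = ll, coef = fit$coefficients, se = sqrt(diag(cov)),
       converged = fit$converged)
}

#' Negative-binomial likelihood-ratio tests per feature
#'
#' For each feature a negative-binomial GLM with log link and size-factor
#' offsets is fitted under the full and the reduced design; the treatment
#' effect is assessed by the chi-square tail of twice the log-likelihood
#' difference. Dispersion is estimated per feature by the Pearson moment
#' estimator (Pearson chi-square equated to its residual degrees of freedom,
#' with the mean from a Poisson fit), floored at `alpha_floor` and, by
#' default, smoothed toward the parametric mean-dispersion trend
#' `a(mu) = a0 + a1/mu` with an empirical-Bayes weight. Features that fail to
#' converge are flagged and given p = 1 (conservative); all-zero features get
#' `NA` p-values and are excluded from multiple-testing correction
#' downstream.
#'
#' @param counts non-negative integer matrix (features x samples).
#' @param metadata sample metadata with `sample`, `arm`, `phase`, aligned to
#'   the columns of `counts`.
#' @param design `"interaction"` (intercept + phase + arm:phase, testing the
#'   treatment term; the default) or `"arm"` (simple arm contrast).
#' @param sf size factors; computed by [size_factors()] when `NULL`.
#' @param alpha_floor lower bound for the dispersion.
#' @param trend_smooth smooth per-feature dispersions toward the
#'   mean-dispersion trend (default TRUE; needs >= 10 features).
#' @return data.frame: `feature_id`, `base_mean` (mean of normalized
#'   counts), `log2fc_raw`, `lfc_se`, `p`, `converged`.
#' @export
nb_lrt <- function(counts, metadata, design = c("interaction", "arm"),
                   sf = NULL, alpha_floor = 1e-8, trend_smooth = TRUE) {
  stopifnot(ncol(counts) == nrow(metadata))
  if (any(counts < 0)) stop("counts must be non-negative")
  dm <- da_design_matrices(metadata, design)
  Xf <- dm$full; Xr <- dm$reduced
  if (is.null(sf)) sf <- size_factors(counts)
  off <- log(sf)
  n <- ncol(counts); pfull <- ncol(Xf)
  norm_counts <- sweep(counts, 2, sf, "/")
  feat <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  nf <- nrow(counts)

  ## pass 1: per-feature dispersion from the full-model Poisson fit
  alphas <- rep(NA_real_, nf)
  bms <- rowMeans(norm_counts)
  for (i in seq_len(nf)) {
    y <- as.numeric(counts[i, ])
    if (all(y == 0)) next
    alphas[i] <- tryCatch({
      pois <- suppressWarnings(stats::glm.fit(Xf, y, family = stats::poisson(),
                                              offset = off))
      pearson_dispersion(y, pmax(pois$fitted.values, 1e-8), pfull,
                         floor = alpha_floor)
    }, error = function(e) NA_real_)
  }
  if (trend_smooth && sum(is.finite(alphas)) >= 10)
    alphas <- smooth_dispersions(alphas, bms, n, pfull, floor = alpha_floor)

  ## pass 2: NB fits under full and reduced designs, chi-square LRT
  res <- lapply(seq_len(nf), function(i) {
    y <- as.numeric(counts[i, ])
    bm <- bms[i]
    if (all(y == 0)) {
      return(data.frame(feature_id = feat[i], base_mean = 0, log2fc_raw = 0,
                        lfc_se = NA_real_, p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    tryCatch({
      theta <- min(1 / max(alphas[i], alpha_floor, na.rm = TRUE), 1e8)
      ff <- nb_glm_fixed(y, Xf, off, theta)
      fr <- nb_glm_fixed(y, Xr, off, theta)
      lrt <- max(0, 2 * (ff$ll - fr$ll))
      p <- stats::pchisq(lrt, df = pfull - ncol(Xr), lower.tail = FALSE)
      b <- ff$coef[pfull] / log(2)
      se <- ff$se[pfull] / log(2)
      conv <- isTRUE(ff$converged) && isTRUE(fr$converged) && is.finite(b) &&
        is.finite(se)
      if (!conv) { p <- 1; b <- 0; se <- NA_real_ }
      data.frame(feature_id = feat[i], base_mean = bm, log2fc_raw = b,
                 lfc_se = se, p = min(max(p, 1e-300), 1), converged = conv,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(feature_id = feat[i], base_mean = bm, log2fc_raw = 0,
                 lfc_se = NA_real_, p = 1, converged = FALSE,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  if (any(!out$converged))
    attr(out, "n_nonconverged") <- sum(!out$converged)
  out
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Normal prior centered at zero; its variance is estimated from the
#' cross-feature distribution of raw effects (moment estimator
#' `mean(lfc^2) - mean(se^2)`, floored at a small positive value so that the
#' boundary estimate tau2 = 0 does not erase effect directions). The
#' posterior mean `lfc * tau2 / (tau2 + se^2)` never exceeds the raw effect
#' in magnitude. Features without a finite SE are returned unshrunken; a
#' single feature offers nothing to pool and is returned unshrunken with a
#' warning.
#'
#' @param lfc raw log2 fold changes.
#' @param se their standard errors.
#' @return shrunken log2 fold changes.
#' @export
shrink_lfc <- function(lfc, se) {
  stopifnot(length(lfc) == length(se))
  ok <- is.finite(se) & is.finite(lfc)
  if (sum(ok) <= 1) {
    warning("fewer than 2 features with finite SE; returning unshrunken effects")
    return(lfc)
  }
  tau2 <- max(mean(lfc[ok]^2) - mean(se[ok]^2), 1e-8)
  out <- lfc
  out[ok] <- lfc[ok] * tau2 / (tau2 + se[ok]^2)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH over the non-missing p-values; `NA` entries are
#' propagated and do not count toward the number of tests.
#'
#' @param p p-values in (0, 1] (NA allowed).
#' @return adjusted p-values (p_adj >= p elementwise).
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must be in (0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Differential abundance analysis
#'
#' Full stage: pseudo-counts are normalized with median-of-ratios size
#' factors, each feature is tested with a negative-binomial LRT, raw effects
#' are shrunken with a zero-centered normal prior, and BH correction is
#' applied. `positively_associated` flags features with shrunken log2FC > 0
#' and p_adj below `threshold`.
#'
#' @param counts integer matrix (features x samples).
#' @param metadata sample metadata.
#' @param design see [nb_lrt()].
#' @param threshold BH significance threshold for the positive-association
#'   flag (0.05 for taxa, 0.1 for proteins by convention).
#' @return data.frame of class `mp_da`, ordered by feature ID:
#'   `feature_id`, `base_mean`, `log2fc_raw`, `log2fc_shrunk`, `lfc_se`,
#'   `p`, `p_adj`, `positively_associated`.
#' @export
da_analysis <- function(counts, metadata, design = c("interaction", "arm"),
                        threshold = 0.05) {
  res <- nb_lrt(counts, metadata, design)
  res$log2fc_shrunk <- shrink_lfc(res$log2fc_raw, res$lfc_se)
  res$p_adj <- adjust_bh(res$p)
  res <- res[order(res$feature_id), ]
  rownames(res) <- NULL
  res$positively_associated <- !is.na(res$p_adj) &
    res$log2fc_shrunk > 0 & res$p_adj < threshold
  attr(res, "threshold") <- threshold
  attr(res, "design") <- match.arg(design)
  class(res) <- c("mp_da", "data.frame")
  res
}

#' Filter positively associated features
#'
#' Keeps features with shrunken log2FC strictly greater than 0 and BH
#' adjusted p strictly below `threshold`.
#'
#' @param results `mp_da` (or compatible) results table.
#' @param threshold BH threshold.
#' @return subset of `results`.
#' @export
flag_positive <- function(results, threshold = 0.05) {
  keep <- !is.na(results$p_adj) & results$log2fc_shrunk > 0 &
    results$p_adj < threshold
  results[keep, , drop = FALSE]
}

#' @export
print.mp_da <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Differential abundance (%s design): %d features, %d positively associated at p_adj < %g\n",
              attr(x, "design"), nrow(x), sum(x$positively_associated), thr))
  invisible(x)
}

#' @export
summary.mp_da <- function(object, ...) {
  print(object)
  cat(sprintf("  tested: %d  (all-zero excluded: %d, non-converged: %d)\n",
              sum(!is.na(object$p)), sum(is.na(object$p)),
              sum(!object$converged & !is.na(object$p))))
  invisible(object)
}
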
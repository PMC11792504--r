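test_that("alpha indices match their analytic values", {
  tab <- cbind(u = c(1, 1, 1, 1), single = c(3, 0, 0, 0))
  rownames(tab) <- paste0("t", 1:4)
  al <- alpha_diversity(tab)
  expect_equal(al$observed, c(4L, 1L))
  expect_equal(al$shannon, c(log(4), 0))
  expect_equal(al$simpson, c(0.75, 0))

  ## random compositions against direct formula evaluation
  set.seed(11)
  for (r in 1:25) {
    x <- stats::rexp(8) * stats::rbinom(8, 1, 0.8)
    if (sum(x) == 0) x[1] <- 1
    m <- matrix(x, dimnames = list(paste0("t", 1:8), "s"))
    a <- alpha_diversity(m)
    p <- x[x > 0] / sum(x)
    expect_equal(a$observed, sum(x > 0))
    expect_equal(a$shannon, -sum(p * log(p)))
    expect_equal(a$simpson, 1 - sum((x / sum(x))^2))
    ## scale invariance
    a2 <- alpha_diversity(m * 7.3)
    expect_equal(a2$shannon, a$shannon)
    expect_equal(a2$simpson, a$simpson)
  }
  expect_error(alpha_diversity(cbind(z = c(0, 0))), "all-zero sample")
})

test_that("alpha regression handles null, planted, and degenerate cases", {
  md <- data.frame(sample = paste0("s", 1:40),
                   arm = rep(c("PB", "CMH"), each = 20),
                   phase = rep(c("baseline", "treatment"), 20))
  ## identical values in both arms: slope 0, p 1
  al <- data.frame(sample = md$sample, observed = 5L, shannon = 1.2,
                   simpson = 0.5)
  fit <- alpha_regression(al, md)
  expect_equal(fit$estimate, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$p, c(1, 1, 1), tolerance = 1e-8)

  ## planted arm shift recovered within 3 SE (large n)
  set.seed(5)
  md2 <- data.frame(sample = paste0("x", 1:200),
                    arm = rep(c("PB", "CMH"), each = 100),
                    phase = rep(c("baseline", "treatment"), 100))
  shift <- 0.4
  al2 <- data.frame(sample = md2$sample,
                    observed = round(stats::rnorm(200, 20, 2)),
                    shannon = stats::rnorm(200, 2, 0.3) +
                      shift * (md2$arm == "CMH"),
                    simpson = stats::runif(200, 0.5, 0.9))
  fit2 <- alpha_regression(al2, md2)
  sh <- fit2[fit2$index == "shannon", ]
  expect_lt(abs(sh$estimate - shift), 3 * sh$se)

  ## two samples per arm runs and reports a finite (wide) SE
  md3 <- data.frame(sample = paste0("y", 1:4),
                    arm = rep(c("PB", "CMH"), each = 2), phase = "baseline")
  al3 <- data.frame(sample = md3$sample, observed = c(3L, 4L, 5L, 3L),
                    shannon = c(1, 1.2, 1.4, 0.9),
                    simpson = c(.5, .6, .7, .4))
  expect_true(all(is.finite(alpha_regression(al3, md3)$se)))
  expect_error(alpha_regression(al3[1:2, ], md3[1:2, ]), "2 samples per arm")
})

test_that("Bray-Curtis matches the hand formula and its bounds", {
  tab <- cbind(a = c(1, 2, 0), b = c(1, 2, 0), c = c(0, 0, 5))
  rownames(tab) <- paste0("t", 1:3)
  D <- bray_curtis(tab)
  expect_equal(D["a", "b"], 0)            # identical samples
  expect_equal(D["a", "c"], 1)            # disjoint supports
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  set.seed(19)
  for (r in 1:25) {
    m <- matrix(stats::rexp(12), 6, 2, dimnames = list(NULL, c("x", "y")))
    D2 <- bray_curtis(m)
    expect_equal(D2["x", "y"], bf_bray(m[, 1], m[, 2]))
    expect_gte(D2["x", "y"], 0); expect_lte(D2["x", "y"], 1)
  }
})

test_that("PCoA recovers planted Euclidean geometry", {
  ## three equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  pc3 <- pcoa_ordination(D3, k = 2)
  ev <- pc3$eigenvalues[pc3$eigenvalues > 1e-10]
  expect_equal(length(ev), 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-10)

  ## planted 2-D coordinates recovered up to rotation/reflection
  set.seed(23)
  X <- matrix(stats::rnorm(20), 10, 2)
  D <- as.matrix(stats::dist(X))
  pc <- pcoa_ordination(D, k = 2)
  Y <- pc$coords
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Yc, Xc))
  rot <- Yc %*% sv$u %*% t(sv$v)
  expect_lt(max(abs(rot - Xc)), 1e-8)

  ## duplicate samples coincide
  Xd <- rbind(X, X[1, ])
  pcd <- pcoa_ordination(as.matrix(stats::dist(Xd)), k = 2)
  expect_equal(pcd$coords[11, ], pcd$coords[1, ], tolerance = 1e-8)

  ## requesting more axes than positive eigenvalues truncates with warning
  expect_warning(pcoa_ordination(D3, k = 3), "positive eigenvalues")
})

test_that("PERMANOVA p matches exhaustive enumeration on a tiny instance", {
  set.seed(31)
  X <- rbind(matrix(stats::rnorm(6, 0), 3, 2), matrix(stats::rnorm(6, 1.5), 3, 2))
  D <- as.matrix(stats::dist(X))
  labels <- rep(c("g1", "g2"), each = 3)
  ## oracle: pseudo-F over all 20 distinct assignments of 3+3 labels
  combos <- utils::combn(6, 3)
  f_obs <- bf_permanova_f(D, labels)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep("g2", 6); lab[idx] <- "g1"
    bf_permanova_f(D, lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  ## implementation with the full exhaustive permutation set
  pm <- permanova(D, labels, permutations = all_perms(6))
  expect_equal(pm$f, f_obs, tolerance = 1e-10)
  expect_lt(abs(pm$p - p_exact), 0.005)
})

test_that("PERMANOVA behaves at the extremes and under relabeling", {
  set.seed(41)
  X <- rbind(matrix(stats::rnorm(20, 0, 0.01), 10, 2),
             matrix(stats::rnorm(20, 50, 0.01), 10, 2))
  D <- as.matrix(stats::dist(X))
  labels <- rep(c("a", "b"), each = 10)
  pm <- permanova(D, labels, n_perm = 199, seed = 3)
  expect_equal(pm$p, 1 / 200)
  expect_gt(pm$r2, 0.99)
  ## group-name invariance and seed reproducibility
  pm2 <- permanova(D, rep(c("zzz", "qqq"), each = 10), n_perm = 199, seed = 3)
  expect_equal(pm2$p, pm$p)
  expect_equal(pm2$r2, pm$r2)
  expect_error(permanova(D, labels, n_perm = 0), "n_perm")
  expect_error(permanova(D, rep("a", 20)), "2 groups")
})
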
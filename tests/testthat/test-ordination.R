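test_that("RDA recovers exact closed-form cases", {
  # noiseless linear function of a 2-level factor -> R2 = 1
  g <- factor(rep(c("a", "b"), each = 6))
  y <- cbind(ifelse(g == "a", 1, -1), ifelse(g == "a", 2, 0))
  res <- rda(y, g, n_perm = 99, seed = 1)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(res$p_perm, 1 / 100)

  # the adjusted-R2 identity: n = 10, p = 1, R2 = 0.5 -> 0.4375
  expect_equal(1 - (1 - 0.5) * (10 - 1) / (10 - 1 - 1), 0.4375)
  set.seed(2)
  y2 <- matrix(rnorm(10 * 3), 10)
  g2 <- factor(rep(c("a", "b"), each = 5))
  res2 <- rda(y2, g2, n_perm = 99, seed = 1)
  expect_equal(res2$r2_adjusted,
               1 - (1 - res2$r2) * (10 - 1) / (10 - 1 - 1))
  expect_equal(res2$n_constraint_df, 1)
})

test_that("RDA agrees with vegan on R2 and pseudo-F", {
  set.seed(5)
  y <- matrix(rnorm(24 * 6), 24)
  g <- factor(rep(letters[1:3], each = 8))
  ours <- rda(y, g, n_perm = 199, seed = 1)
  vfit <- vegan::rda(y ~ g)
  expect_equal(ours$r2, unname(vegan::RsquareAdj(vfit)$r.squared),
               tolerance = 1e-10)
  expect_equal(ours$r2_adjusted, unname(vegan::RsquareAdj(vfit)$adj.r.squared),
               tolerance = 1e-10)
  set.seed(1)
  vperm <- vegan::anova.cca(vfit, permutations = 199)
  expect_equal(ours$pseudo_f, vperm$F[1], tolerance = 1e-10)
})

test_that("RDA invariances and error contracts hold", {
  set.seed(6)
  y <- matrix(rnorm(18 * 4), 18)
  g <- factor(rep(c("x", "y", "z"), each = 6))
  r1 <- rda(y, g, n_perm = 49, seed = 3)
  # relabeling factor levels does not change R2
  g2 <- factor(as.integer(g), labels = c("q", "r", "s")[c(3, 1, 2)])
  r2 <- rda(y, g2, n_perm = 49, seed = 3)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-12)
  # adding a constant to response columns does not change R2
  r3 <- rda(sweep(y, 2, c(5, -2, 0.5, 100), "+"), g, n_perm = 49, seed = 3)
  expect_equal(r1$r2, r3$r2, tolerance = 1e-12)

  # collinear constraint errors, naming the dropped column
  bad <- data.frame(g = g, gg = g)
  expect_error(rda(y, bad, n_perm = 49), "collinear")
})

test_that("partial RDA removes the conditioned effect", {
  set.seed(7)
  z <- factor(rep(c("p", "q"), 12))
  g <- factor(rep(c("a", "b"), each = 12))
  y <- matrix(rnorm(24 * 5), 24) + 3 * (as.integer(z) - 1.5)
  full <- rda(y, data.frame(z = z), n_perm = 99, seed = 1)
  part <- rda(y, g, condition = data.frame(z = z), n_perm = 99, seed = 1)
  expect_gt(full$r2, 0.5)
  expect_lt(part$r2, 0.2)
  expect_gt(part$p_perm, 0.05)
})

test_that("Bray-Curtis distances match the direct formula", {
  m <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0))
  colnames(m) <- c("a", "b", "c")
  d <- as.matrix(bray_curtis_matrix(m))
  expect_equal(d["s1", "s2"], 0.5)       # (1+0+1)/(1+2+1)
  expect_equal(d["s1", "s3"], 0)         # identical samples
  m2 <- rbind(s1 = c(2, 0), s2 = c(0, 3))
  expect_equal(as.matrix(bray_curtis_matrix(m2))["s1", "s2"], 1)
  expect_error(bray_curtis_matrix(rbind(s1 = c(0, 0), s2 = c(1, 1))),
               "all-zero")
  expect_error(bray_curtis_matrix(rbind(s1 = c(-1, 2), s2 = c(1, 1))),
               "non-negative")
})

test_that("PERMANOVA matches the Gower partition formula on a small instance", {
  set.seed(8)
  x <- rbind(matrix(rnorm(12, 0), 4), matrix(rnorm(12, 1.2), 4),
             matrix(rnorm(12, -1), 4))
  rownames(x) <- paste0("s", 1:12)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  d <- dist(x)
  res <- permanova(d, g, n_perm = 199, seed = 1)

  # direct sums-of-squares partition from squared distances
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  ss_tot <- sum(dm[upper.tri(dm)]) / n
  ss_within <- sum(vapply(levels(g), function(l) {
    sub <- dm[g == l, g == l]
    sum(sub[upper.tri(sub)]) / sum(g == l)
  }, 0))
  ss_between <- ss_tot - ss_within
  f_direct <- (ss_between / (3 - 1)) / (ss_within / (n - 3))
  expect_equal(res$pseudo_f, f_direct, tolerance = 1e-9)
  expect_equal(res$r2, ss_between / ss_tot, tolerance = 1e-9)

  # on Euclidean distances this equals the MANOVA trace pseudo-F from
  # coordinates
  xc <- scale(x, scale = FALSE)
  ss_fit <- sum((stats::fitted(stats::lm(xc ~ g)))^2)
  ss_res <- sum(stats::residuals(stats::lm(xc ~ g))^2)
  f_manova <- (ss_fit / 2) / (ss_res / (n - 3))
  expect_equal(res$pseudo_f, f_manova, tolerance = 1e-9)
})

test_that("PERMANOVA behaves on separated and duplicated data", {
  set.seed(31)
  x <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 20, 0.05), 5))
  rownames(x) <- paste0("s", 1:10)
  g <- rep(c("a", "b"), each = 5)
  res <- permanova(dist(x), g, n_perm = 199, seed = 2)
  expect_gt(res$r2, 0.99)
  # only the two perfect splits reach the observed F, so p sits at the
  # bottom of the permutation distribution
  expect_lte(res$p_perm, 0.02)

  # duplicating every sample with the same labels leaves R2 unchanged
  x2 <- rbind(x, x); rownames(x2) <- paste0("s", 1:20)
  res2 <- permanova(dist(x2), c(g, g), n_perm = 99, seed = 2)
  expect_equal(res2$r2, res$r2, tolerance = 1e-9)

  expect_error(permanova(dist(x), c("a", rep("b", 9)), n_perm = 99),
               "singleton")
  expect_error(permanova(dist(x), rep("a", 10), n_perm = 99), "2 groups")
})

test_that("pairwise PERMANOVA runs each two-group comparison", {
  ds <- small_synth(seed = 21)
  f <- suppressWarnings(rarefy(ds$fungal, 4000, seed = 1))
  meta <- ds$meta[match(sample_ids(f), ds$meta$sample_id), ]
  res <- permanova_pairwise(
    f$counts, meta$treatment,
    pairs = list(c("BASELINE", "PA"), c("BASELINE", "AA")),
    n_perm = 99, seed = 5, adjust = TRUE)
  expect_equal(nrow(res), 2)
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_true(all(res$q >= res$p))
})
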
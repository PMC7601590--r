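test_that("taxonomy filter keeps exactly the matching lineages", {
  tab <- toy_table()
  kept <- filter_taxonomy(tab, "Neocallimastigomycota")
  expect_setequal(taxon_ids(kept), c("t1", "t3"))
  expect_identical(kept$counts, tab$counts[, c("t1", "t3")])

  all_kept <- filter_taxonomy(tab, "k__")
  expect_identical(all_kept$counts, tab$counts)

  expect_warning(none <- filter_taxonomy(tab, "neocallimastigomycota"),
                 "no taxon")
  expect_equal(ncol(none$counts), 0)   # case-sensitive by contract
})

test_that("prevalence filter uses the ceiling boundary on presence", {
  m <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  m[1:5, "a"] <- 1      # 5 of 10 = exactly 50%
  m[1:4, "b"] <- 1      # 4 of 10
  m[, "c"] <- 2         # ubiquitous
  tab <- count_table(m)
  expect_setequal(taxon_ids(filter_prevalence(tab, 0.5)), c("a", "c"))
  expect_setequal(taxon_ids(filter_prevalence(tab, 1.0)), "c")
})

test_that("rarefaction hits the target depth exactly and is seed-stable", {
  set.seed(99)
  m <- matrix(rpois(5 * 20, 60), 5, 20,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:20)))
  m[, 7] <- 0                      # absent taxon stays absent
  m[3, ] <- 0; m[3, 1] <- 10       # sample far below depth: dropped
  tab <- count_table(m)
  expect_warning(r <- rarefy(tab, 500, seed = 7), "below depth")
  expect_true(all(rowSums(r$counts) == 500))
  expect_true(all(r$counts[, "t7"] == 0))
  expect_false("s3" %in% sample_ids(r))
  expect_warning(r2 <- rarefy(tab, 500, seed = 7), "below depth")
  expect_identical(r$counts, r2$counts)

  # a sample exactly at depth is returned unchanged
  tot <- rowSums(m)[1]
  expect_warning(rexact <- rarefy(tab, tot, seed = 1))
  expect_identical(rexact$counts["s1", ], m[1, ])

  expect_error(rarefy(tab, 1e7), "cannot rarefy")
})

test_that("rarefaction preserves hypergeometric expectations", {
  counts <- c(a = 400, b = 100, c = 25, d = 475)
  tab <- count_table(matrix(rep(counts, each = 1), 1, 4,
                            dimnames = list("s1", names(counts))))
  draws <- t(vapply(1:300, function(s) rarefy(tab, 200, seed = s)$counts[1, ],
                    numeric(4)))
  expected <- 200 * counts / sum(counts)
  se <- sqrt(200 * (counts / sum(counts)) * (1 - counts / sum(counts)) *
               (sum(counts) - 200) / (sum(counts) - 1)) / sqrt(300)
  expect_true(all(abs(colMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("zero replacement reduces to closure when there are no zeros", {
  m <- matrix(c(5, 3, 2, 1, 4, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  comp <- replace_zeros_bayesian(count_table(m))
  expect_equal(comp$values, m / rowSums(m))
})

test_that("zero replacement is multiplicative and matches the posterior formula", {
  m <- matrix(c(6, 3, 1,
                8, 0, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  tab <- count_table(m)
  comp <- replace_zeros_bayesian(tab, s = 1)
  expect_equal(unname(rowSums(comp$values)), c(1, 1))
  expect_true(all(comp$values > 0))
  # ratios among observed taxa preserved within the imputed sample
  expect_equal(comp$values["s2", "a"] / comp$values["s2", "c"], 8 / 2)
  # hand computation: prior t_b = mean rel. abundance of b where present
  # = (3/10), renormalized over prior vector t = (mean_a, mean_b, mean_c)
  t_raw <- c(a = mean(c(6 / 10, 8 / 10)), b = 3 / 10,
             c = mean(c(1 / 10, 2 / 10)))
  t_norm <- t_raw / sum(t_raw)
  expect_equal(unname(comp$values["s2", "b"]),
               unname(t_norm["b"] * 1 / (10 + 1)))
})

test_that("imputed values that reach observed proportions are shrunk", {
  # with a strong prior (s = 10) the posterior for the abundant-where-
  # present taxon c overshoots the smallest observed proportion
  m <- matrix(c(50, 10, 40,
                9, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  expect_warning(comp <- replace_zeros_bayesian(count_table(m), s = 10),
                 "shrunk")
  expect_lt(comp$values["s2", "c"], comp$values["s2", "b"])
  expect_equal(unname(rowSums(comp$values)), c(1, 1))
})

test_that("CLR rows sum to zero and match the direct formula", {
  comp <- replace_zeros_bayesian(toy_table())
  clr <- clr_transform(comp)
  expect_true(all(abs(rowSums(clr$values)) < 1e-9))

  x <- c(0.8, 0.2)
  direct <- log(x) - mean(log(x))
  expect_equal(unname(clr_transform(matrix(x, 1, 2,
    dimnames = list("s", c("a", "b"))))$values[1, ]), direct)

  u <- matrix(1 / 4, 1, 4, dimnames = list("s", letters[1:4]))
  expect_equal(unname(clr_transform(u)$values[1, ]), rep(0, 4))

  expect_error(clr_transform(matrix(c(0, 1), 1, 2,
    dimnames = list("s", c("a", "b")))), "strictly positive")
})

test_that("CLR of closed data is invariant to count scaling", {
  m <- matrix(c(5, 3, 2, 10, 1, 9), 2, 3,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  tab1 <- count_table(m)
  tab2 <- count_table(m * 7)
  c1 <- clr_transform(replace_zeros_bayesian(tab1))
  c2 <- clr_transform(replace_zeros_bayesian(tab2))
  expect_equal(c1$values, c2$values, tolerance = 1e-12)
})
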
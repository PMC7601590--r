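test_that("all four association measures match brute-force references", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(8:30, 1)
    x <- round(rexp(n), sample(1:3, 1))   # occasional ties and zeros
    y <- round(rexp(n), sample(1:3, 1))
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(association_score(x, y, "spearman"), spearman_bf(x, y),
                 tolerance = 1e-12)
    expect_equal(association_score(x, y, "kendall"), kendall_bf(x, y),
                 tolerance = 1e-12)
    expect_equal(association_score(x, y, "bray_curtis"), bray_bf(x, y),
                 tolerance = 1e-12)
    expect_equal(association_score(x, y, "kld"), kld_bf(x, y),
                 tolerance = 1e-12)
  }
})

test_that("association measures hit their identity values", {
  x <- c(0.1, 0.4, 0.2, 0.3, 0.25, 0.15)
  expect_equal(association_score(x, x, "spearman"), 1)
  expect_equal(association_score(x, x, "kendall"), 1)
  expect_equal(association_score(x, x, "bray_curtis"), 0)
  expect_equal(association_score(x, x, "kld"), 0)
  expect_equal(association_score(x, max(x) + min(x) - x, "spearman"), -1)
  expect_true(is.na(association_score(rep(1, 6), x, "spearman")))
})

test_that("the ReBoot null is centred, seed-stable, and renormalization is benign for tiny taxa", {
  set.seed(3)
  n <- 40
  x <- rexp(n); y <- rexp(n)
  other <- rep(100, n)           # pair is a negligible fraction
  r1 <- reboot_null(x, y, other, "spearman", b_perm = 400, seed = 7)
  r2 <- reboot_null(x, y, other, "spearman", b_perm = 400, seed = 7)
  expect_identical(r1, r2)
  expect_lt(abs(r1$null_mean), 3 * r1$null_sd / sqrt(400) + 0.02)
  # with a negligible pair, re-closure is a no-op
  r3 <- reboot_null(x, y, other, "spearman", b_perm = 400, seed = 7,
                    renormalize = FALSE)
  expect_equal(r1$null_mean, r3$null_mean, tolerance = 0.02)
  expect_warning(reboot_null(x, y, other, "spearman", b_perm = 50),
                 "unstable")
})

test_that("bootstrap distributions are seed-stable and cover the observed score", {
  set.seed(4)
  x <- rexp(20); y <- x + rnorm(20, 0, 0.05)
  b1 <- bootstrap_distribution(x, y, "spearman", b_boot = 300, seed = 2)
  b2 <- bootstrap_distribution(x, y, "spearman", b_boot = 300, seed = 2)
  expect_identical(b1, b2)
  expect_gt(b1$boot_mean, 0.9)
  expect_lt(b1$boot_sd, 0.1)
  expect_lte(b1$ci[1], b1$ci[2])

  cover <- vapply(1:50, function(s) {
    set.seed(s + 100)
    x <- rexp(20); y <- rexp(20)
    obs <- association_score(x, y, "spearman")
    ci <- bootstrap_distribution(x, y, "spearman", b_boot = 200,
                                 seed = s)$ci
    obs >= ci[1] && obs <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.94)
})

test_that("Gauss-curve p-values follow the null-vs-bootstrap z-score", {
  # boot mean equal to null mean -> p = 1
  expect_equal(measure_pvalue(0.5, 0.2, 0.2, 0.1, "spearman")$p, 1)
  # a 1.96-sd separation -> p = 0.05
  expect_equal(measure_pvalue(0.5, 0.196, 0, 0.1, "spearman")$p, 0.05,
               tolerance = 1e-3)
  # symmetric in the sign of z
  expect_equal(measure_pvalue(0.5, 0.3, 0, 0.1, "spearman")$p,
               measure_pvalue(0.5, -0.3, 0, 0.1, "spearman")$p)
  # direction: sign for correlations, null-relative for dissimilarities
  expect_equal(measure_pvalue(-0.4, 0, -0.4, 0.1, "spearman")$direction,
               "EXCLUSION")
  expect_equal(measure_pvalue(0.9, 0.6, 0.9, 0.05, "bray_curtis")$direction,
               "EXCLUSION")
  expect_equal(measure_pvalue(0.3, 0.6, 0.3, 0.05, "bray_curtis")$direction,
               "COPRESENCE")
  # zero bootstrap sd -> undefined p
  expect_true(is.na(measure_pvalue(0.5, 0.2, 0.4, 0, "spearman")$p))
})

test_that("Brown's method matches Fisher at zero covariance and collapses under total dependence", {
  # Fisher: X = -2 ln(0.05) * 2 = 11.98, df 4
  expect_equal(browns_merge(c(0.05, 0.05)),
               pchisq(-2 * sum(log(c(0.05, 0.05))), df = 4,
                      lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(browns_merge(c(0.05, 0.05)), 0.01747866, tolerance = 1e-6)
  expect_equal(browns_merge(rep(1, 4)), 1)
  # perfect dependence: duplicated p with cov 4 returns the single p
  for (p in c(0.5, 0.07, 1e-4))
    expect_equal(browns_merge(c(p, p), matrix(4, 2, 2)), p,
                 tolerance = 1e-10)
  expect_warning(browns_merge(c(0.1, 0.1), matrix(9, 2, 2)), "clipped")
})

test_that("BH step-up used for edge q-values matches direct enumeration", {
  p <- c(0.01, 0.02, 0.04, 0.40)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04 * 4 / 3, 0.40))
  set.seed(9)
  for (i in 1:20) {
    pv <- runif(sample(3:15, 1))
    expect_equal(p.adjust(pv, "BH"), bh_bf(pv), tolerance = 1e-12)
  }
  # idempotent and monotone
  q <- bh_bf(runif(10))
  expect_equal(bh_bf(q) <= 1, rep(TRUE, 10))
  expect_true(all(diff(sort(q)) >= -1e-15))
})

test_that("a single strong planted coupling is recovered with its direction", {
  ds <- generate_dataset(synth_config(
    n_fungal_taxa = 10, n_bacterial_taxa = 20, n_hubs = 1,
    partners_per_hub = 4, coupling_strength = 2, coupling_sign_mix = 1,
    noise_sd = 0.2, treatment_effects = NULL, frac_offtarget_fungal = 0,
    dropout_extra = 0, seed = 31))
  f <- filter_prevalence(suppressWarnings(rarefy(ds$fungal, 5000, seed = 1)), 0.5)
  b <- filter_prevalence(suppressWarnings(rarefy(ds$bacterial, 20000, seed = 2)), 0.5)
  nw <- conet(f, b, b_perm = 200, b_boot = 200, seed = 3)
  tr <- ds$truth$planted_edges
  found <- paste(nw$edges$fungal_taxon, nw$edges$bacterial_taxon)
  hit <- paste(tr$fungal_taxon, tr$bacterial_taxon) %in% found
  expect_gte(mean(hit), 0.75)
  rec <- merge(nw$edges, tr, by = c("fungal_taxon", "bacterial_taxon"))
  expect_true(all(rec$direction == "EXCLUSION"))
  # the hub is the top node by degree
  expect_equal(find_hubs(nw, 1)[1], ds$truth$hubs)
})

test_that("tightening the edge rule never adds edges", {
  ds <- small_synth(seed = 8)
  f <- filter_prevalence(suppressWarnings(rarefy(ds$fungal, 4000, seed = 1)), 0.5)
  b <- filter_prevalence(suppressWarnings(rarefy(ds$bacterial, 15000, seed = 2)), 0.5)
  ctx <- network_context(f, b)
  sc <- score_candidates(ctx, b_perm = 150, b_boot = 150, seed = 3)
  e3 <- build_network(sc, alpha = 0.05, min_support = 3)$edges
  e4 <- build_network(sc, alpha = 0.05, min_support = 4)$edges
  e_tight <- build_network(sc, alpha = 0.01, min_support = 3)$edges
  key <- function(e) paste(e$fungal_taxon, e$bacterial_taxon)
  expect_true(all(key(e4) %in% key(e3)))
  expect_true(all(key(e_tight) %in% key(e3)))
})

test_that("hub extraction and union follow degree with deterministic ties", {
  mk_edge <- function(f, b, p = 1e-4) data.frame(
    fungal_taxon = f, bacterial_taxon = b, direction = "EXCLUSION",
    n_support = 3L, supporting_measures = "spearman|kendall|kld",
    p_merged = p, q = p, passed_ci = TRUE, stringsAsFactors = FALSE)
  star <- do.call(rbind, lapply(paste0("B", 1:5), function(b) mk_edge("F1", b)))
  extra <- mk_edge("F2", "B1")
  nodes <- data.frame(taxon = c("F1", "F2", paste0("B", 1:5)),
                      kingdom = c("fungi", "fungi", rep("bacteria", 5)),
                      stringsAsFactors = FALSE)
  nw <- structure(list(nodes = nodes, edges = rbind(star, extra),
                       candidates = rbind(star, extra), stratum = "overall",
                       alpha = 0.05, min_support = 3), class = "conetwork")
  expect_equal(find_hubs(nw, 1), "F1")

  nw2 <- nw; nw2$edges <- rbind(mk_edge("F9", "B1"), mk_edge("F9", "B2"))
  expect_setequal(hub_union(list(nw, nw2), k = 1), c("F1", "F9"))

  empty <- nw; empty$edges <- star[0, ]
  expect_warning(h <- find_hubs(empty), "no edges")
  expect_length(h, 0)
  expect_warning(ef <- exclusion_fraction(empty), "undefined")
  expect_true(is.na(ef))
})

test_that("exclusion fraction counts EXCLUSION edges", {
  mk <- function(dirs) {
    e <- data.frame(fungal_taxon = paste0("F", seq_along(dirs)),
                    bacterial_taxon = paste0("B", seq_along(dirs)),
                    direction = dirs, n_support = 3L,
                    supporting_measures = "spearman|kendall|kld",
                    p_merged = 1e-3, q = 1e-3, passed_ci = TRUE,
                    stringsAsFactors = FALSE)
    structure(list(nodes = data.frame(taxon = c(e$fungal_taxon,
                                                e$bacterial_taxon),
                                      kingdom = "fungi"),
                   edges = e, candidates = e, stratum = "x",
                   alpha = 0.05, min_support = 3), class = "conetwork")
  }
  expect_equal(exclusion_fraction(mk(rep("EXCLUSION", 4))), 1)
  expect_equal(exclusion_fraction(mk(c("EXCLUSION", "EXCLUSION",
                                       "COPRESENCE", "COPRESENCE"))), 0.5)
})
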
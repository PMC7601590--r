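test_that("blocked permutation ANOVA hits its degenerate and extreme cases", {
  block <- factor(rep(paste0("S", 1:4), each = 2))
  group <- factor(rep(c("a", "b"), 4))
  # identical values within each steer -> F = 0, p = 1
  y0 <- as.numeric(rep(1:4, each = 2))
  res0 <- perm_anova_blocked(y0, group, block, b = 199, seed = 1)
  expect_equal(res0$f_stat, 0)
  expect_equal(res0$p_perm, 1)

  # large planted shift, tiny noise -> the smallest attainable p; with
  # 8 two-sample blocks the identity and the all-blocks flip are the only
  # sign patterns reaching the observed F, so the exact p is 2/256
  set.seed(2)
  block8 <- factor(rep(paste0("S", 1:8), each = 2))
  group8 <- factor(rep(c("a", "b"), 8))
  y1 <- as.numeric(rep(1:8, each = 2)) + ifelse(group8 == "b", 10, 0) +
    rnorm(16, 0, 0.01)
  res1 <- perm_anova_blocked(y1, group8, block8, b = 399, seed = 1)
  ex1 <- perm_anova_blocked(y1, group8, block8, exact = TRUE)
  expect_lte(ex1$p_perm, 2 / 256)       # identity + possibly the full flip
  expect_gte(ex1$p_perm, 1 / 256)
  expect_lte(res1$p_perm, 0.05)
})

test_that("exact blocked p matches the lm-based enumeration oracle", {
  set.seed(3)
  for (i in 1:25) {
    nb <- sample(2:3, 1)
    per <- sample(2:3, 1)
    block <- factor(rep(paste0("S", seq_len(nb)), each = per))
    group <- factor(unlist(lapply(seq_len(nb),
                                  function(j) sample(letters[seq_len(per)]))))
    y <- rnorm(nb * per)
    ours <- perm_anova_blocked(y, group, block, exact = TRUE)
    oracle <- blocked_anova_enum_p(y, group, block)
    expect_equal(ours$p_perm, oracle, tolerance = 1e-9)
    expect_equal(ours$f_stat, anova_f_lm(y, group, block), tolerance = 1e-9)
  }
})

test_that("with a single block the test reduces to a free-permutation one-way ANOVA", {
  set.seed(4)
  y <- rnorm(7)
  group <- factor(c("a", "a", "b", "b", "b", "c", "c"))
  block <- factor(rep("S1", 7))
  ours <- perm_anova_blocked(y, group, block, exact = TRUE)
  # free permutation oracle over all 7! orderings
  f_obs <- summary(stats::aov(y ~ group))[[1]]$`F value`[1]
  expect_equal(ours$f_stat, f_obs, tolerance = 1e-9)
  oracle <- blocked_anova_enum_p(y, group, block)
  expect_equal(ours$p_perm, oracle, tolerance = 1e-9)
})

test_that("differential abundance flags planted shifts and is deterministic", {
  cfg <- synth_config(n_fungal_taxa = 15, n_bacterial_taxa = 15,
                      n_hubs = 2, partners_per_hub = 3,
                      treatment_effects = list(frac_affected = 0.3,
                                               effect_size = 2),
                      frac_offtarget_fungal = 0, seed = 12)
  ds <- generate_dataset(cfg)
  tab <- suppressWarnings(rarefy(ds$fungal, 4000, seed = 1))
  meta <- ds$meta[ds$meta$sample_id %in% sample_ids(tab), ]
  tab <- count_table(tab$counts[meta$sample_id, , drop = FALSE],
                     tab$taxonomy)
  clr <- clr_transform(replace_zeros_bayesian(tab))
  res1 <- run_diffabund(clr, tab, meta, b = 199, seed = 5)
  res2 <- run_diffabund(clr, tab, meta, b = 199, seed = 5)
  expect_identical(res1$p_perm, res2$p_perm)
  expect_true(all(res1$q >= res1$p_perm - 1e-12))

  affected <- unique(ds$truth$group_effects$taxon[
    ds$truth$group_effects$kingdom == "fungi" &
      abs(ds$truth$group_effects$shift) > 1.5])
  affected <- intersect(affected, res1$taxon)
  expect_gt(mean(res1$flagged[res1$taxon %in% affected]), 0.5)
})

test_that("pairwise follow-up applies BH within each contrast", {
  ds <- small_synth(seed = 6,
                    treatment_effects = list(frac_affected = 0.4,
                                             effect_size = 1.5))
  tab <- suppressWarnings(rarefy(ds$fungal, 4000, seed = 1))
  meta <- ds$meta[ds$meta$sample_id %in% sample_ids(tab), ]
  tab <- count_table(tab$counts[meta$sample_id, , drop = FALSE],
                     tab$taxonomy)
  clr <- clr_transform(replace_zeros_bayesian(tab))
  fu <- pairwise_followup(clr, meta, taxon_ids(tab))
  expect_true(all(c("taxon", "contrast", "p", "q") %in% names(fu)))
  expect_true(any(grepl("BASELINE_vs_", fu$contrast)))
  for (ct in unique(fu$contrast)) {
    sel <- fu$contrast == ct & !is.na(fu$p)
    if (sum(sel) > 1)
      expect_equal(fu$q[sel], p.adjust(fu$p[sel], "BH"), tolerance = 1e-12)
  }
})

test_that("group labels combine diet and bloat with baseline kept apart", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     steer_id = c("S1", "S1", "S2"),
                     period = c(0, 1, 1),
                     treatment = c("BASELINE", "AS", "AS"),
                     bloat = c("NA", "B", "NB"))
  g <- diet_bloat_groups(meta)
  expect_equal(unname(g), c("BASELINE", "AS.B", "AS.NB"))
})
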
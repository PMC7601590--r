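# Independent brute-force reference implementations used as oracles.
# These deliberately avoid the package's code paths (and the C++ engine).

midrank_bf <- function(x) rank(x, ties.method = "average")

pearson_bf <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

spearman_bf <- function(x, y) pearson_bf(midrank_bf(x), midrank_bf(y))

kendall_bf <- function(x, y) {
  n <- length(x)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      num <- num + sx * sy; dx <- dx + sx^2; dy <- dy + sy^2
    }
  }
  num / sqrt(dx * dy)
}

bray_bf <- function(x, y) sum(abs(x - y)) / sum(x + y)

# mirrors the definition: profiles normalized across samples with a
# pseudocount of 1% of the profile mean
kld_bf <- function(x, y) {
  ex <- 0.01 * mean(x); ey <- 0.01 * mean(y)
  xt <- (x + ex) / sum(x + ex)
  yt <- (y + ey) / sum(y + ey)
  0.5 * sum((xt - yt) * log(xt / yt))
}

# step-up BH by direct minimization over the tail
bh_bf <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    i <- ord[k]
    q[i] <- min(1, min(p[ord[k:m]] * m / seq(k, m)))
  }
  q
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcox_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# blocked-permutation ANOVA oracle: F from lm(), p by exhaustive
# enumeration of within-block permutations of the response
anova_f_lm <- function(y, group, block) {
  if (nlevels(factor(block)) < 2) {
    fit1 <- stats::lm(y ~ group)
    fit0 <- stats::lm(y ~ 1)
  } else {
    fit1 <- stats::lm(y ~ block + group)
    fit0 <- stats::lm(y ~ block)
  }
  stats::anova(fit0, fit1)$F[2]
}

blocked_anova_enum_p <- function(y, group, block) {
  group <- factor(group); block <- factor(block)
  pos <- split(seq_along(y), block)
  perms_of <- function(k) {
    if (k == 1) return(list(1L))
    out <- list()
    for (i in seq_len(k)) {
      for (s in perms_of(k - 1L)) {
        rest <- seq_len(k)[-i]
        out[[length(out) + 1]] <- c(i, rest[s])
      }
    }
    out
  }
  combos <- list(seq_along(y))
  for (p in pos) {
    if (length(p) < 2) next
    newc <- list()
    for (cl in combos) {
      for (pm in perms_of(length(p))) {
        v <- cl; v[p] <- cl[p][pm]
        newc[[length(newc) + 1]] <- v
      }
    }
    combos <- newc
  }
  f_obs <- anova_f_lm(y, group, block)
  f_all <- vapply(combos, function(ix) anova_f_lm(y[ix], group, block), 0)
  mean(f_all >= f_obs - 1e-12)
}

# small toy count table fixture
toy_table <- function() {
  m <- matrix(c(5, 0, 3, 2,
                1, 4, 0, 6,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("t1", "t2", "t3", "t4")))
  count_table(m, taxonomy = c(
    "k__Fungi;p__Neocallimastigomycota;g__Piromyces",
    "k__Fungi;p__Ascomycota;g__Other",
    "k__Fungi;p__Neocallimastigomycota;g__Caecomyces",
    "k__Bacteria;p__Bacteroidetes;g__Prevotella"))
}

# small paired dataset for fast end-to-end stages
small_synth <- function(seed = 1, ...) {
  generate_dataset(synth_config(
    n_fungal_taxa = 12, n_bacterial_taxa = 24,
    depth_fungal = c(meanlog = log(12000), sdlog = 0.3),
    depth_bacterial = c(meanlog = log(40000), sdlog = 0.3),
    n_hubs = 2, partners_per_hub = 3,
    frac_offtarget_fungal = 0, seed = seed, ...))
}
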
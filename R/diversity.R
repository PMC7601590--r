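#' Chao1 richness estimator
#'
#' Classic Chao1: `S_obs + F1^2 / (2 F2)` with F1/F2 the singleton and
#' doubleton counts; when no doubletons are present the bias-corrected form
#' `S_obs + F1 (F1 - 1) / 2` is used (configurable to always use the
#' bias-corrected estimator `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`).
#'
#' @param counts non-negative integer vector of per-taxon counts for one
#'   sample.
#' @param bias_corrected use the bias-corrected form for all inputs.
#' @return the estimated richness (always `>= S_obs`).
#' @export
chao1 <- function(counts, bias_corrected = FALSE) {
  counts <- check_counts_vec(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
}

#' Shannon diversity index
#'
#' `-sum(p_i log p_i)` over the positive proportions, natural log by
#' default.
#'
#' @inheritParams chao1
#' @param base logarithm base (default `exp(1)`).
#' @return the index (0 iff exactly one taxon is present).
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts_vec(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

check_counts_vec <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || all(counts == 0))
    stop("counts must be non-negative with at least one positive entry")
  counts
}

#' Per-sample alpha diversity of a count table
#'
#' @param table a [count_table()].
#' @param base log base for Shannon.
#' @return data.frame with columns `sample_id`, `s_obs`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  data.frame(sample_id = rownames(m),
             s_obs = rowSums(m > 0),
             chao1 = apply(m, 1, chao1),
             shannon = apply(m, 1, shannon, base = base),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon signed-rank test for matched pairs
#'
#' Pairs two measurement vectors by their names (steer IDs); unmatched
#' entries are dropped with a warning.  Zero differences are removed
#' (Wilcoxon convention) and tied absolute differences receive midranks.
#' The two-sided p-value is computed by exact enumeration of the signed-rank
#' distribution for up to 25 effective pairs (a dynamic program over the
#' 2^n sign assignments, valid under ties), and by the normal approximation
#' with tie correction beyond that.
#'
#' @param paired_a,paired_b numeric vectors named by steer ID.
#' @return list with `statistic` (V, the positive-rank sum), `n_eff`
#'   (non-zero differences) and `p` (two-sided).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (is.null(names(paired_a)) || is.null(names(paired_b)))
    stop("paired vectors must be named by steer ID")
  common <- intersect(names(paired_a), names(paired_b))
  if (length(common) == 0) stop("no overlapping steers between the two vectors")
  if (length(common) < length(paired_a) || length(common) < length(paired_b))
    warning("dropping ", length(paired_a) + length(paired_b) - 2 * length(common),
            " unmatched sample(s)")
  d <- paired_a[common] - paired_b[common]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; signed-rank test undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(r, v)
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - n * (n + 1) / 4) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = v, n_eff = n, p = min(1, p))
}

# exact two-sided p for the positive-rank sum v given midranks r,
# by convolution over all 2^n sign assignments (doubled ranks are integers)
signed_rank_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1)       # f[s + 1] = #assignments with doubled sum s
  f[1] <- 1
  for (rk in r2) {
    g <- f
    g[(rk + 1):(tot + 1)] <- g[(rk + 1):(tot + 1)] + f[1:(tot + 1 - rk)]
    f <- g
  }
  f <- f / sum(f)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(f[seq_len(v2 + 1)])
  p_ge <- sum(f[(v2 + 1):(tot + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Spearman rank correlation with p-value
#'
#' Pearson correlation of midranks; the p-value uses the t approximation
#' with `n - 2` degrees of freedom, or exact enumeration of all rank
#' permutations for `n <= 9`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho` and `p` (two-sided).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (var(rank(x)) == 0 || var(rank(y)) == 0)
    stop("zero variance in ranks; correlation undefined")
  rho <- cor(x, y, method = "spearman")
  if (n <= 9) {
    p <- spearman_exact_p_cpp(x, y)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (!is.finite(tt)) 1 / choose(n, 2) else 2 * pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = min(1, p))
}

#' Matched diversity comparisons across the crossover design
#'
#' Computes per-sample alpha diversity, averages replicate samples of a
#' steer within a phase, and runs the study's comparisons: baseline vs each
#' grazing treatment (matched-pairs signed-rank, by steer), baseline vs
#' AS-bloat and AS-no-bloat subsets, and bloat vs no-bloat within AS
#' (rank-sum, since those are different steers).
#'
#' @param table a [count_table()] (typically the rarefied fungal table).
#' @param meta validated metadata covering the table's samples.
#' @param indices which indices to test.
#' @return data.frame with columns `index`, `contrast`, `n`, `statistic`,
#'   `p`.
#' @export
diversity_tests <- function(table, meta, indices = c("chao1", "shannon")) {
  div <- alpha_diversity(table)
  meta <- validate_metadata(meta)
  div <- merge(div, meta, by = "sample_id")
  phase_mean <- function(sub, col)
    tapply(sub[[col]], sub$steer_id, mean)
  base <- div[div$treatment == "BASELINE", ]
  out <- list()
  add <- function(index, contrast, res, n)
    out[[length(out) + 1]] <<- data.frame(
      index = index, contrast = contrast, n = n,
      statistic = res$statistic, p = res$p, stringsAsFactors = FALSE)
  groups <- list(PA = quote(treatment == "PA"),
                 AA = quote(treatment == "AA"),
                 `AS` = quote(treatment == "AS"),
                 `AS.B` = quote(treatment == "AS" & bloat == "B"),
                 `AS.NB` = quote(treatment == "AS" & bloat == "NB"))
  for (index in indices) {
    a0 <- phase_mean(base, index)
    for (g in names(groups)) {
      sub <- div[eval(groups[[g]], div), ]
      if (nrow(sub) == 0) next
      b <- phase_mean(sub, index)
      # steers missing one side of the contrast are expected in the
      # crossover (missed samplings), so the pairing drop is silent here
      res <- tryCatch(
        withCallingHandlers(
          wilcoxon_signed_rank(b, a0),
          warning = function(w) {
            if (grepl("unmatched", conditionMessage(w)))
              invokeRestart("muffleWarning")
          }),
        error = function(e) NULL)
      if (!is.null(res))
        add(index, paste0("BASELINE_vs_", g), res, res$n_eff)
    }
    bl <- div[div$treatment == "AS" & div$bloat == "B", ]
    nb <- div[div$treatment == "AS" & div$bloat == "NB", ]
    if (nrow(bl) >= 2 && nrow(nb) >= 2) {
      wt <- suppressWarnings(
        stats::wilcox.test(phase_mean(bl, index), phase_mean(nb, index)))
      add(index, "AS.B_vs_AS.NB",
          list(statistic = unname(wt$statistic), p = wt$p.value),
          length(unique(c(bl$steer_id, nb$steer_id))))
    }
  }
  do.call(rbind, out)
}

#' Cross-kingdom diversity correlation
#'
#' Spearman correlation between the fungal and bacterial Shannon indices of
#' the shared samples, the check for whether fungal and bacterial diversity
#' track each other.
#'
#' @param fungal,bacterial [count_table()]s (rarefied).
#' @param index `"shannon"` or `"chao1"`.
#' @return list with `rho`, `p` and `n` (shared samples).
#' @export
diversity_correlation <- function(fungal, bacterial, index = "shannon") {
  df <- alpha_diversity(fungal)
  db <- alpha_diversity(bacterial)
  common <- intersect(df$sample_id, db$sample_id)
  if (length(common) < 3) stop("fewer than 3 shared samples")
  res <- spearman_correlation(df[[index]][match(common, df$sample_id)],
                              db[[index]][match(common, db$sample_id)])
  c(res, list(n = length(common)))
}
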
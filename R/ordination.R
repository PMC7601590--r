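#' Redundancy analysis with a permutation test
#'
#' Constrained ordination of a multivariate response (typically a CLR
#' matrix) on a design: the response is column-centred and projected onto
#' the dummy-coded constraint by least squares; R-squared is the fitted
#' sum of squares over the total, and the adjusted value is
#' `1 - (1 - R2) (n - 1) / (n - 1 - p)` with `p` the constraint degrees of
#' freedom.  With `condition` given, both the response and the constraint
#' are first residualized on the condition design (partial RDA), and the
#' permutation test permutes those residuals under the reduced model
#' (Freedman-Lane); without a condition, rows of the centred response are
#' permuted freely.
#'
#' @param y a `clr_matrix`, or a numeric matrix (samples x variables).
#' @param constraint factor, vector or data.frame of explanatory variables.
#' @param condition optional covariate design to partial out (e.g. dietary
#'   treatment and bloat status when testing hub fungi).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return an `rda_result` list: `r2`, `r2_adjusted`, `pseudo_f`, `p_perm`,
#'   `n_samples`, `n_constraint_df`.
#' @export
rda <- function(y, constraint, condition = NULL, n_perm = 999, seed = 1L) {
  ym <- if (inherits(y, "clr_matrix")) y$values else as.matrix(y)
  n <- nrow(ym)
  yc <- scale(ym, center = TRUE, scale = FALSE)
  x <- design_matrix(constraint, n)
  z <- if (!is.null(condition)) design_matrix(condition, n) else NULL
  df_cond <- 0L
  if (!is.null(z)) {
    qz <- qr(z)
    df_cond <- qz$rank
    yc <- qr.resid(qz, yc)
    x <- qr.resid(qz, x)
  }
  qx <- qr(x)
  p <- qx$rank
  if (p < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(p + 1):ncol(x)]]
    stop("constraint collinear after residualization; dropped column(s): ",
         paste(dropped, collapse = ", "))
  }
  df_res <- n - 1L - df_cond - p
  if (df_res < 1) stop("not enough samples for the requested model")
  ss_tot <- sum(yc^2)
  if (ss_tot <= 0) stop("response has no variance")
  ss_fit <- min(sum(qr.fitted(qx, yc)^2), ss_tot)
  r2 <- ss_fit / ss_tot
  ss_res <- max(ss_tot - ss_fit, 0)
  f_obs <- if (ss_res == 0) Inf else (ss_fit / p) / (ss_res / df_res)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- yc[sample.int(n), , drop = FALSE]
    if (!is.null(z)) yp <- qr.resid(qz, yp)
    ssf <- sum(qr.fitted(qx, yp)^2)
    sst <- sum(yp^2)
    fb <- if (sst - ssf <= 0) Inf else (ssf / p) / ((sst - ssf) / df_res)
    if (fb >= f_obs * (1 - 1e-12) - 1e-12) exceed <- exceed + 1L
  }
  structure(list(r2 = r2,
                 r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - 1 - p),
                 pseudo_f = f_obs,
                 p_perm = (1 + exceed) / (n_perm + 1),
                 n_samples = n, n_constraint_df = p),
            class = "rda_result")
}

design_matrix <- function(v, n) {
  if (is.matrix(v)) {
    stopifnot(nrow(v) == n)
    m <- v
  } else {
    df <- if (is.data.frame(v)) v else data.frame(.v = v)
    stopifnot(nrow(df) == n)
    df[] <- lapply(df, function(col)
      if (is.character(col)) factor(col) else col)
    m <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  }
  scale(m, center = TRUE, scale = FALSE)
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "RDA: R2 = %.4f (adj %.4f), pseudo-F = %.3f, p = %.4g (n = %d, df = %d)\n",
    x$r2, x$r2_adjusted, x$pseudo_f, x$p_perm, x$n_samples,
    x$n_constraint_df))
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` over taxa, computed on
#' counts or relative abundances.
#'
#' @param x a [count_table()], `composition`, or non-negative matrix
#'   (samples x taxa).
#' @return a `dist` object.
#' @export
bray_curtis_matrix <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts
       else if (inherits(x, "composition")) x$values
       else as.matrix(x)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "),
         " (distance undefined)")
  vegan::vegdist(m, method = "bray")
}

#' PERMANOVA (ADONIS) on a distance matrix
#'
#' One-factor permutational multivariate ANOVA: sums of squares are
#' partitioned from the (Gower-centred) squared distances, pseudo-F is
#' `(SS_between / (g - 1)) / (SS_within / (n - g))`, and the p-value comes
#' from permuting group labels.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param grouping factor of group labels (>= 2 groups, each >= 2 samples).
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return a `permanova_result` list: `r2`, `pseudo_f`, `p_perm`.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(d)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(table(grouping) < 2))
    stop("singleton group(s): ",
         paste(names(which(table(grouping) < 2)), collapse = ", "))
  set.seed(seed)
  fit <- vegan::adonis2(d ~ g, data = data.frame(g = grouping),
                        permutations = n_perm)
  structure(list(r2 = fit$R2[1], pseudo_f = fit$F[1],
                 p_perm = fit$`Pr(>F)`[1]),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g\n",
              x$r2, x$pseudo_f, x$p_perm))
  invisible(x)
}

#' Pairwise PERMANOVA comparisons
#'
#' Runs a two-group PERMANOVA on the sample subset of every requested pair
#' of groups (the ADONIS-style pairwise follow-up), optionally
#' BH-correcting the family of p-values.
#'
#' @param x a [count_table()], `composition` or matrix from which
#'   Bray-Curtis distances are computed per subset.
#' @param grouping group label per sample.
#' @param pairs list of 2-vectors of group labels; default all pairs.
#' @param n_perm permutations per comparison (default 999).
#' @param seed RNG seed.
#' @param adjust apply BH across the pairwise family.
#' @return data.frame with `group_a`, `group_b`, `n`, `r2`, `pseudo_f`,
#'   `p`, and `q` when `adjust` is `TRUE`.
#' @export
permanova_pairwise <- function(x, grouping, pairs = NULL, n_perm = 999,
                               seed = 1L, adjust = FALSE) {
  m <- if (inherits(x, "count_table")) x$counts
       else if (inherits(x, "composition")) x$values
       else as.matrix(x)
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(m))
  if (is.null(pairs)) {
    lv <- unique(grouping)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    sel <- grouping %in% pr
    res <- permanova(bray_curtis_matrix(m[sel, , drop = FALSE]),
                     grouping[sel], n_perm = n_perm,
                     seed = seed + i)
    data.frame(group_a = pr[1], group_b = pr[2], n = sum(sel),
               r2 = res$r2, pseudo_f = res$pseudo_f, p = res$p_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q <- p.adjust(out$p, method = "BH")
  out
}
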
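#' Diet/bloat-status group labels
#'
#' The differential-abundance factor of the analysis: `BASELINE` for the
#' hay occasion, otherwise `treatment.bloat` (so with the study's bloat
#' pattern the levels are BASELINE, PA.B, AA.NB, AS.B and AS.NB).
#'
#' @param meta validated metadata.
#' @return character vector of group labels, named by sample ID.
#' @export
diet_bloat_groups <- function(meta) {
  meta <- validate_metadata(meta)
  g <- ifelse(meta$treatment == "BASELINE", "BASELINE",
              paste(meta$treatment, meta$bloat, sep = "."))
  names(g) <- meta$sample_id
  g
}

#' Blocked permutation ANOVA for one taxon
#'
#' Tests a group effect on a response with steer as a blocking factor: the
#' F statistic comes from the two-way additive least-squares fit
#' (`response ~ block + group`), and the null distribution from permuting
#' the response within each steer block (equivalently, permuting group
#' labels within blocks), which respects the repeated-measures structure
#' of the crossover without a variance-component fit.
#'
#' @param values numeric response (e.g. one taxon's CLR abundances).
#' @param group group factor (diet/bloat combination).
#' @param block blocking factor (steer).
#' @param b number of permutations (>= 199); ignored when `exact` is TRUE.
#' @param seed RNG seed.
#' @param exact enumerate all within-block permutations instead of random
#'   sampling (feasible for small designs; errors beyond 500,000
#'   combinations).  The exact p is the fraction of enumerated
#'   permutations, including the identity, with `F* >= F`.
#' @return list with `f_stat`, `df_group`, `df_resid`, `p_perm`.
#' @export
perm_anova_blocked <- function(values, group, block, b = 4999, seed = 1L,
                               exact = FALSE) {
  stopifnot(exact || b >= 199)
  group <- factor(group)
  block <- factor(block)
  n <- length(values)
  stopifnot(length(group) == n, length(block) == n)
  if (any(table(group) == 0)) stop("empty group level")
  if (nlevels(group) < 2) stop("need at least 2 groups")

  # residualize on block, then project on the group space orthogonal to it
  r <- values - ave(values, block)
  g <- stats::model.matrix(~ group)[, -1, drop = FALSE]
  g <- g - apply(g, 2, function(col) ave(col, block))
  qg <- qr(g)
  df_group <- qg$rank
  if (df_group == 0)
    stop("group is confounded with block; no within-block contrast")
  qmat <- qr.Q(qg)[, seq_len(df_group), drop = FALSE]
  ssw <- sum(r^2)
  ssg <- sum(crossprod(qmat, r)^2)
  df_resid <- n - nlevels(block) - df_group
  if (df_resid < 1) stop("no residual degrees of freedom")
  if (ssw <= 1e-300)     # response constant within every block
    return(list(f_stat = 0, df_group = df_group, df_resid = df_resid,
                p_perm = 1))
  f_obs <- (ssg / df_group) / ((ssw - ssg) / df_resid)

  if (exact) {
    idx <- within_block_all_perms(block)
    ssg_perm <- colSums(crossprod(qmat, matrix(r[idx], n))^2)
    f_perm <- (ssg_perm / df_group) / ((ssw - ssg_perm) / df_resid)
    p <- mean(f_perm >= f_obs - 1e-12)
  } else {
    set.seed(seed)
    idx <- within_block_perms(block, b)
    ssg_perm <- colSums(crossprod(qmat, matrix(r[idx], n))^2)
    f_perm <- (ssg_perm / df_group) / ((ssw - ssg_perm) / df_resid)
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (b + 1)
  }
  list(f_stat = f_obs, df_group = df_group, df_resid = df_resid, p_perm = p)
}

# all permutations of 1..k
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# n x N matrix of indices: the full cartesian product of within-block
# permutations
within_block_all_perms <- function(block) {
  n <- length(block)
  pos <- split(seq_len(n), block)
  total <- prod(vapply(pos, function(p) factorial(length(p)), 0))
  if (total > 5e5)
    stop("exact enumeration infeasible: ", total, " permutations")
  cols <- list(seq_len(n))
  for (p in pos) {
    if (length(p) < 2) next
    pm <- all_perms(length(p))
    newcols <- vector("list", length(cols) * nrow(pm))
    k <- 0
    for (cl in cols) {
      for (r in seq_len(nrow(pm))) {
        k <- k + 1
        v <- cl
        v[p] <- cl[p][pm[r, ]]
        newcols[[k]] <- v
      }
    }
    cols <- newcols
  }
  do.call(cbind, cols)
}

# n x b matrix of indices permuting positions within each block
within_block_perms <- function(block, b) {
  n <- length(block)
  pos <- split(seq_len(n), block)
  idx <- matrix(seq_len(n), n, b)
  for (p in pos) {
    if (length(p) < 2) next
    for (j in seq_len(b)) idx[p, j] <- p[sample.int(length(p))]
  }
  idx
}

#' Differential abundance across diet/bloat groups
#'
#' Runs the per-taxon blocked permutation ANOVA on CLR abundances for all
#' taxa passing a prevalence filter on the source counts, then applies BH
#' correction across taxa.  Taxa with q below `alpha` are flagged for the
#' matched-pairs follow-up.
#'
#' @param clr a `clr_matrix` (samples x taxa).
#' @param counts the source [count_table()] used for the prevalence filter
#'   (the analysis uses presence in at least 10% of samples).
#' @param meta validated metadata covering the samples.
#' @param min_prevalence presence fraction (default 0.10).
#' @param b permutations per taxon (default 4999).
#' @param seed RNG seed.
#' @param alpha FDR threshold for flagging (default 0.05).
#' @return a `diffabund_result`: data.frame with `taxon`, `f_stat`,
#'   `p_perm`, `q`, `flagged`, plus per-group mean CLR columns
#'   (`mean.<group>`).
#' @export
run_diffabund <- function(clr, counts, meta, min_prevalence = 0.10,
                          b = 4999, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(clr, "clr_matrix"))
  meta <- validate_metadata(meta)
  v <- clr$values
  meta <- meta[match(rownames(v), meta$sample_id), ]
  if (any(is.na(meta$sample_id)))
    stop("metadata does not cover all CLR samples")
  keep <- taxon_ids(filter_prevalence(counts, min_prevalence))
  keep <- intersect(keep, colnames(v))
  v <- v[, keep, drop = FALSE]

  grp <- factor(diet_bloat_groups(meta))
  blk <- factor(meta$steer_id)
  res <- lapply(seq_along(keep), function(i)
    perm_anova_blocked(v[, i], grp, blk, b = b,
                       seed = derive_seed(seed, i)))
  out <- data.frame(taxon = keep,
                    f_stat = vapply(res, `[[`, 0, "f_stat"),
                    p_perm = vapply(res, `[[`, 0, "p_perm"),
                    stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p_perm, method = "BH")
  out$flagged <- out$q < alpha
  gm <- t(apply(v, 2, function(col) tapply(col, grp, mean)))
  colnames(gm) <- paste0("mean.", colnames(gm))
  out <- cbind(out, gm, row.names = NULL)
  class(out) <- c("diffabund_result", "data.frame")
  out
}

#' Matched-pairs follow-up for flagged taxa
#'
#' For every flagged taxon, compares the baseline occasion to each
#' diet/bloat combination with the matched-pairs Wilcoxon signed-rank test
#' (pairing by steer, averaging a steer's replicates within a phase), and
#' bloat vs no-bloat within the alfalfa-sainfoin diet with the rank-sum
#' test (different steers).  BH correction is applied across taxa within
#' each contrast.
#'
#' @param clr a `clr_matrix`.
#' @param meta validated metadata.
#' @param flagged_taxa taxa to follow up (e.g.
#'   `subset(diffabund, flagged)$taxon`).
#' @param min_pairs minimum effective pairs for a result (default 3;
#'   contrasts below this are reported as `NA`).
#' @return data.frame with `taxon`, `contrast`, `n`, `median_diff`, `p`,
#'   `q` (BH within contrast).
#' @export
pairwise_followup <- function(clr, meta, flagged_taxa, min_pairs = 3) {
  stopifnot(inherits(clr, "clr_matrix"))
  meta <- validate_metadata(meta)
  v <- clr$values
  meta <- meta[match(rownames(v), meta$sample_id), ]
  grp <- diet_bloat_groups(meta)
  lv <- setdiff(unique(grp), "BASELINE")
  contrasts <- c(paste0("BASELINE_vs_", lv),
                 if (all(c("AS.B", "AS.NB") %in% lv)) "AS.B_vs_AS.NB")
  steer_mean <- function(taxon, sel)
    tapply(v[sel, taxon], meta$steer_id[sel], mean)
  rows <- list()
  for (ct in contrasts) {
    for (tx in flagged_taxa) {
      if (startsWith(ct, "BASELINE_vs_")) {
        g <- sub("BASELINE_vs_", "", ct)
        a <- steer_mean(tx, grp == g)
        b0 <- steer_mean(tx, grp == "BASELINE")
        common <- intersect(names(a), names(b0))
        if (length(common) < min_pairs ||
            all(a[common] - b0[common] == 0)) {
          rows[[length(rows) + 1]] <- data.frame(
            taxon = tx, contrast = ct, n = length(common),
            median_diff = if (length(common)) stats::median(a[common] - b0[common]) else NA_real_,
            p = NA_real_, stringsAsFactors = FALSE)
          next
        }
        res <- suppressWarnings(wilcoxon_signed_rank(a, b0))
        rows[[length(rows) + 1]] <- data.frame(
          taxon = tx, contrast = ct, n = res$n_eff,
          median_diff = stats::median(a[common] - b0[common]),
          p = res$p, stringsAsFactors = FALSE)
      } else {
        a <- steer_mean(tx, grp == "AS.B")
        b0 <- steer_mean(tx, grp == "AS.NB")
        if (length(a) < 2 || length(b0) < 2) next
        wt <- suppressWarnings(stats::wilcox.test(a, b0))
        rows[[length(rows) + 1]] <- data.frame(
          taxon = tx, contrast = ct, n = length(a) + length(b0),
          median_diff = stats::median(a) - stats::median(b0),
          p = wt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- NA_real_
  for (ct in unique(out$contrast)) {
    sel <- out$contrast == ct & !is.na(out$p)
    out$q[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 100000) * 10007 + 97 * i) %% 2147483629L
}
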
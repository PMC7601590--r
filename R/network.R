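MEASURES <- c("spearman", "kendall", "bray_curtis", "kld")
CORR_MEASURES <- c("spearman", "kendall")

#' Pairwise association score between two taxa
#'
#' The four ensemble measures used for co-occurrence inference, computed on
#' two per-sample relative-abundance profiles: Spearman (Pearson of
#' midranks), Kendall tau-b, Bray-Curtis (`sum|x-y| / sum(x+y)` over
#' samples), and the symmetrized Kullback-Leibler divergence of the
#' across-sample-normalized profiles (with a pseudocount so zeros are
#' defined).
#'
#' @param x,y non-negative numeric vectors over the same samples
#'   (length >= 4).
#' @param measure one of `"spearman"`, `"kendall"`, `"bray_curtis"`,
#'   `"kld"`.
#' @return the score; `NA` for a correlation on a zero-variance vector.
#' @export
association_score <- function(x, y, measure = MEASURES) {
  measure <- match.arg(measure)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  pair_score_cpp(as.numeric(x), as.numeric(y),
                 match(measure, MEASURES) - 1L)
}

#' Build the concatenated cross-kingdom abundance context
#'
#' Restricts the fungal and bacterial tables to their shared samples,
#' closes each kingdom to relative abundances (the two libraries are
#' sequenced separately, so their depths are not comparable), and
#' concatenates them with equal per-kingdom weight, so every sample row of
#' the combined composition sums to 1.  This is the composition inside
#' which the ReBoot null re-closes samples after shuffling a pair.
#'
#' @param fungal,bacterial [count_table()]s (after rarefaction and the
#'   prevalence filter).
#' @return list with matrices `F` and `B` (samples x taxa, each kingdom
#'   summing to 0.5 per row), `tot` (row totals of the combined
#'   composition), and `samples`.
#' @export
network_context <- function(fungal, bacterial) {
  common <- intersect(rownames(fungal$counts), rownames(bacterial$counts))
  if (length(common) < 8)
    stop("need at least 8 shared samples for network inference; have ",
         length(common))
  fm <- closure(fungal$counts[common, , drop = FALSE]) / 2
  bm <- closure(bacterial$counts[common, , drop = FALSE]) / 2
  list(F = fm, B = bm, tot = rowSums(fm) + rowSums(bm), samples = common)
}

#' ReBoot permutation null for one pair
#'
#' Shuffles the two taxa independently across samples; for the correlation
#' measures the per-sample composition is re-closed with the shuffled
#' values in place before scoring, which is what makes the null honest
#' under compositionality.  Returns the null mean and SD over `b_perm`
#' iterations.
#'
#' @param x,y relative-abundance vectors of the pair.
#' @param other per-sample abundance mass of all other taxa in the
#'   composition (so the closed total is `other + x + y`).
#' @param measure association measure.
#' @param b_perm number of permutations (default 1000; fewer than 100
#'   triggers an instability warning).
#' @param seed RNG seed.
#' @param renormalize re-close compositions for correlation measures.
#' @return list with `null_mean` and `null_sd`.
#' @export
reboot_null <- function(x, y, other, measure = MEASURES, b_perm = 1000,
                        seed = 1L, renormalize = TRUE) {
  measure <- match.arg(measure)
  if (b_perm < 100) warning("b_perm < 100 gives an unstable null")
  set.seed(seed)
  res <- ensemble_scan_cpp(matrix(x, ncol = 1), matrix(y, ncol = 1),
                           as.numeric(other + x + y), b_perm, 0L, 0.95,
                           renormalize)[[measure]]
  list(null_mean = res$null_mean[1, 1], null_sd = res$null_sd[1, 1])
}

#' Bootstrap distribution of an association score
#'
#' Resamples samples with replacement, rescoring the pair each time;
#' degenerate resamples (zero variance) are skipped and counted.
#'
#' @inheritParams reboot_null
#' @param b_boot bootstrap iterations (default 1000).
#' @param ci_level CI level (default 0.95, percentile).
#' @return list with `boot_mean`, `boot_sd`, `ci` (length-2), `skipped`.
#' @export
bootstrap_distribution <- function(x, y, measure = MEASURES, b_boot = 1000,
                                   ci_level = 0.95, seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(length(x) >= 8)
  set.seed(seed)
  res <- ensemble_scan_cpp(matrix(x, ncol = 1), matrix(y, ncol = 1),
                           as.numeric(x + y), 0L, b_boot, ci_level,
                           FALSE)[[measure]]
  list(boot_mean = res$boot_mean[1, 1], boot_sd = res$boot_sd[1, 1],
       ci = c(res$ci_lo[1, 1], res$ci_hi[1, 1]),
       skipped = res$skipped_boot[1, 1])
}

#' Gauss-curve p-value for one measure
#'
#' The measure-specific p-value is the two-sided probability of the null
#' value (the mean of the permutation null) under a Gaussian with the mean
#' and SD of the bootstrap distribution:
#' `p = 2 pnorm(-|null_mean - boot_mean| / boot_sd)`.  Direction comes from
#' the observed score: the sign for correlations; for dissimilarities,
#' observed above the null mean means mutual exclusion, below means
#' co-presence.
#'
#' @param observed observed score(s).
#' @param null_mean,boot_mean,boot_sd null and bootstrap moments
#'   (vectorized).
#' @param measure which measure the scores belong to.
#' @return list with `p` and `direction`
#'   (`"COPRESENCE"`/`"EXCLUSION"`/`"NONE"`); `p` is `NA` where
#'   `boot_sd` is 0 or any moment is missing.
#' @export
measure_pvalue <- function(observed, null_mean, boot_mean, boot_sd,
                           measure = MEASURES) {
  measure <- match.arg(measure)
  z <- (null_mean - boot_mean) / boot_sd
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z) | boot_sd <= 0] <- NA_real_
  if (measure %in% CORR_MEASURES) {
    direction <- ifelse(observed > 0, "COPRESENCE",
                        ifelse(observed < 0, "EXCLUSION", "NONE"))
  } else {
    direction <- ifelse(observed > null_mean, "EXCLUSION",
                        ifelse(observed < null_mean, "COPRESENCE", "NONE"))
  }
  direction[is.na(observed) | is.na(null_mean)] <- NA_character_
  list(p = p, direction = direction)
}

#' Brown's method for merging dependent p-values
#'
#' Fisher's statistic `X = sum(-2 log p_i)` is referred to a scaled
#' chi-square whose first two moments match `X` under dependence:
#' `E = 2k`, `Var = 4k + 2 sum_{i<j} cov_ij`, scale `c = Var / (2E)` and
#' `df = 2 E^2 / Var`, where `cov_ij` is the covariance of the
#' `-2 log p` statistics.  With all covariances zero this is exactly
#' Fisher's method; with perfect dependence (`cov = 4`) it collapses to
#' the single p-value.
#'
#' @param p vector of >= 2 p-values in (0, 1].
#' @param cov covariance matrix of the `-2 log p` statistics (only the
#'   off-diagonal entries are used); entries are clipped to `[0, 4]` with a
#'   warning if outside.
#' @return the merged p-value.
#' @export
browns_merge <- function(p, cov = NULL) {
  k <- length(p)
  stopifnot(k >= 2, all(p > 0), all(p <= 1))
  if (is.null(cov)) cov <- matrix(0, k, k)
  cov <- as.matrix(cov)
  off <- cov[upper.tri(cov)]
  if (any(off < 0 | off > 4)) {
    warning("covariance terms outside [0, 4] clipped")
    off <- pmin(pmax(off, 0), 4)
  }
  x <- sum(-2 * log(p))
  e <- 2 * k
  v <- 4 * k + 2 * sum(off)
  cc <- v / (2 * e)
  f <- 2 * e^2 / v
  pchisq(x / cc, df = f, lower.tail = FALSE)
}

#' Score all cross-kingdom candidate pairs
#'
#' Runs the full ensemble scan (observed scores, ReBoot null, bootstrap)
#' for every fungus x bacterium pair of the context, then converts the
#' moments to per-measure p-values and directions.
#'
#' @param ctx a [network_context()].
#' @param b_perm,b_boot permutation and bootstrap iterations (defaults
#'   1000, the analysis settings).
#' @param ci_level bootstrap CI level.
#' @param seed RNG seed.
#' @param renormalize apply composition re-closure to correlation-measure
#'   nulls.
#' @return a `candidate_scores` list: the raw per-measure scan plus `p`
#'   and `direction` matrices per measure, with taxa in dimnames.
#' @export
score_candidates <- function(ctx, b_perm = 1000, b_boot = 1000,
                             ci_level = 0.95, seed = 1L,
                             renormalize = TRUE) {
  set.seed(seed)
  scan <- ensemble_scan_cpp(ctx$F, ctx$B, ctx$tot, b_perm, b_boot,
                            ci_level, renormalize)
  for (m in MEASURES) {
    for (f in names(scan[[m]]))
      dimnames(scan[[m]][[f]]) <- list(colnames(ctx$F), colnames(ctx$B))
    pv <- measure_pvalue(scan[[m]]$observed, scan[[m]]$null_mean,
                         scan[[m]]$boot_mean, scan[[m]]$boot_sd, m)
    scan[[m]]$p <- pv$p
    dirm <- matrix(pv$direction, nrow(pv$p), ncol(pv$p),
                   dimnames = dimnames(pv$p))
    scan[[m]]$direction <- dirm
  }
  structure(list(measures = scan, fungal_taxa = colnames(ctx$F),
                 bacterial_taxa = colnames(ctx$B), n_samples = nrow(ctx$F),
                 ci_level = ci_level),
            class = "candidate_scores")
}

#' Assemble the co-occurrence network from scored candidates
#'
#' Per pair, valid measures are partitioned by direction and support is
#' counted within the majority direction; the supporting p-values are
#' merged with Brown's method (the covariance of the `-2 log p` statistics
#' estimated empirically across all candidate pairs, per measure pair), BH
#' correction is applied across all candidate pairs, and an edge is
#' retained iff it is supported by at least `min_support` measures, its
#' merged q is below `alpha`, and every supporting observed score lies
#' inside its bootstrap CI.
#'
#' @param scores a `candidate_scores` from [score_candidates()].
#' @param alpha FDR threshold on the merged q (default 0.05).
#' @param min_support minimum agreeing measures (default 3).
#' @param stratum label for the network (e.g. `"overall"`, `"bloat"`).
#' @return a `conetwork`: list with `nodes` (taxon, kingdom, degree),
#'   `edges` (one row per retained edge) and `candidates` (all scored
#'   pairs with merged p and q, for auditing).
#' @export
build_network <- function(scores, alpha = 0.05, min_support = 3,
                          stratum = "overall") {
  stopifnot(inherits(scores, "candidate_scores"))
  sc <- scores$measures
  nf <- length(scores$fungal_taxa)
  nb <- length(scores$bacterial_taxa)
  npair <- nf * nb

  pmat <- sapply(MEASURES, function(m) as.vector(sc[[m]]$p))
  dmat <- sapply(MEASURES, function(m) as.vector(sc[[m]]$direction))
  omat <- sapply(MEASURES, function(m) as.vector(sc[[m]]$observed))
  lomat <- sapply(MEASURES, function(m) as.vector(sc[[m]]$ci_lo))
  himat <- sapply(MEASURES, function(m) as.vector(sc[[m]]$ci_hi))
  if (npair == 1) {                       # sapply drops to vector
    pmat <- matrix(pmat, 1); dmat <- matrix(dmat, 1)
    omat <- matrix(omat, 1); lomat <- matrix(lomat, 1)
    himat <- matrix(himat, 1)
  }

  # Empirical dependence of the four -2 log p statistics, estimated from
  # the null-like bulk of candidate pairs (all per-measure p > 0.05):
  # Brown's method needs the covariance under the null, and genuinely
  # associated pairs, where every measure goes small together, would
  # inflate it towards total dependence.
  w <- -2 * log(pmat)
  covw <- matrix(0, 4, 4, dimnames = list(MEASURES, MEASURES))
  if (npair >= 3) {
    nullish <- apply(pmat, 1, function(r) all(is.na(r) | r > 0.05) &&
                       sum(!is.na(r)) >= 2)
    rows <- if (sum(nullish) >= 30) w[nullish, , drop = FALSE] else w
    cw <- suppressWarnings(stats::cov(rows, use = "pairwise.complete.obs"))
    cw[!is.finite(cw)] <- 0
    covw <- pmin(pmax(cw, 0), 4)
  }

  fidx <- rep(seq_len(nf), times = nb)
  bidx <- rep(seq_len(nb), each = nf)
  p_merged <- rep(NA_real_, npair)
  n_support <- integer(npair)
  direction <- rep(NA_character_, npair)
  support_str <- rep("", npair)
  passed_ci <- rep(NA, npair)

  for (i in seq_len(npair)) {
    valid <- which(!is.na(pmat[i, ]) & !is.na(dmat[i, ]) &
                     dmat[i, ] != "NONE")
    if (length(valid) == 0) next
    tab <- table(dmat[i, valid])
    if (length(tab) > 1 && tab[1] == tab[2]) {   # tied directions: no edge
      n_support[i] <- max(tab)
      next
    }
    maj <- names(which.max(tab))
    sup <- valid[dmat[i, valid] == maj]
    direction[i] <- maj
    n_support[i] <- length(sup)
    support_str[i] <- paste(MEASURES[sup], collapse = "|")
    p_merged[i] <- if (length(sup) == 1) pmat[i, sup] else
      browns_merge(pmin(pmax(pmat[i, sup], 1e-300), 1),
                   covw[sup, sup, drop = FALSE])
    passed_ci[i] <- all(omat[i, sup] >= lomat[i, sup] &
                          omat[i, sup] <= himat[i, sup])
  }

  q <- rep(NA_real_, npair)
  has_p <- !is.na(p_merged)
  q[has_p] <- p.adjust(p_merged[has_p], method = "BH")

  cand <- data.frame(
    fungal_taxon = scores$fungal_taxa[fidx],
    bacterial_taxon = scores$bacterial_taxa[bidx],
    direction = direction, n_support = n_support,
    supporting_measures = support_str,
    p_merged = p_merged, q = q, passed_ci = passed_ci,
    stringsAsFactors = FALSE)

  keep <- !is.na(q) & n_support >= min_support & q < alpha &
    !is.na(passed_ci) & passed_ci
  edges <- cand[keep, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(
    taxon = c(scores$fungal_taxa, scores$bacterial_taxa),
    kingdom = rep(c("fungi", "bacteria"), c(nf, nb)),
    stringsAsFactors = FALSE)
  deg <- table(c(edges$fungal_taxon, edges$bacterial_taxon))
  nodes$degree <- as.integer(deg[nodes$taxon])
  nodes$degree[is.na(nodes$degree)] <- 0L

  structure(list(nodes = nodes, edges = edges, candidates = cand,
                 stratum = stratum, alpha = alpha,
                 min_support = min_support),
            class = "conetwork")
}

#' @export
print.conetwork <- function(x, ...) {
  cat(sprintf("conetwork [%s]: %d nodes, %d edges (%d candidates)\n",
              x$stratum, nrow(x$nodes), nrow(x$edges), nrow(x$candidates)))
  if (nrow(x$edges) > 0)
    cat(sprintf("  exclusion fraction: %.2f\n", exclusion_fraction(x)))
  invisible(x)
}

#' Full cross-kingdom network inference
#'
#' Convenience wrapper: builds the context, scores all candidate pairs and
#' assembles the network.
#'
#' @inheritParams network_context
#' @inheritParams score_candidates
#' @inheritParams build_network
#' @return a `conetwork`.
#' @export
conet <- function(fungal, bacterial, b_perm = 1000, b_boot = 1000,
                  min_support = 3, alpha = 0.05, ci_level = 0.95,
                  seed = 1L, renormalize = TRUE, stratum = "overall") {
  ctx <- network_context(fungal, bacterial)
  scores <- score_candidates(ctx, b_perm = b_perm, b_boot = b_boot,
                             ci_level = ci_level, seed = seed,
                             renormalize = renormalize)
  build_network(scores, alpha = alpha, min_support = min_support,
                stratum = stratum)
}

#' Overall and bloat-stratified networks
#'
#' Infers the overall network on all shared samples and, additionally, one
#' network per bloat stratum (bloat / no-bloat grazing samples; baseline
#' samples carry no bloat score and are excluded from the strata).
#'
#' @inheritParams conet
#' @param meta validated metadata.
#' @param min_prevalence per-stratum node prevalence filter (default 0.5,
#'   applied to each stratum's sample subset).
#' @return named list of `conetwork`s: `overall`, `bloat`, `no_bloat`
#'   (strata with too few samples are omitted).
#' @export
conet_strata <- function(fungal, bacterial, meta, b_perm = 1000,
                         b_boot = 1000, min_support = 3, alpha = 0.05,
                         ci_level = 0.95, seed = 1L, renormalize = TRUE,
                         min_prevalence = 0.5) {
  meta <- validate_metadata(meta)
  out <- list(overall = conet(fungal, bacterial, b_perm, b_boot,
                              min_support, alpha, ci_level, seed,
                              renormalize, stratum = "overall"))
  strata <- list(bloat = "B", no_bloat = "NB")
  for (s in names(strata)) {
    ids <- meta$sample_id[meta$bloat == strata[[s]]]
    keep_f <- intersect(ids, rownames(fungal$counts))
    keep_b <- intersect(ids, rownames(bacterial$counts))
    if (length(intersect(keep_f, keep_b)) < 8) next
    fs <- filter_prevalence(
      count_table(fungal$counts[keep_f, , drop = FALSE], fungal$taxonomy),
      min_prevalence)
    bs <- filter_prevalence(
      count_table(bacterial$counts[keep_b, , drop = FALSE],
                  bacterial$taxonomy),
      min_prevalence)
    out[[s]] <- conet(fs, bs, b_perm, b_boot, min_support, alpha,
                      ci_level, seed + match(s, names(strata)),
                      renormalize, stratum = s)
  }
  out
}

#' Hub taxa of a network
#'
#' The top-`k` nodes by degree.  Ties are broken by the summed |z| of the
#' incident edges' merged p-values, then by taxon ID; when the k-th place
#' is still tied, all tied taxa are returned.
#'
#' @param network a `conetwork`.
#' @param k hubs to report (default 4, the analysis convention).
#' @return character vector of hub taxon IDs (empty, with a warning, for
#'   an edgeless network).
#' @export
find_hubs <- function(network, k = 4) {
  stopifnot(inherits(network, "conetwork"))
  e <- network$edges
  if (nrow(e) == 0) {
    warning("network has no edges; no hubs")
    return(character(0))
  }
  z <- stats::qnorm(pmin(pmax(e$p_merged, 1e-300), 1) / 2,
                    lower.tail = FALSE)
  inc <- data.frame(taxon = c(e$fungal_taxon, e$bacterial_taxon),
                    z = rep(z, 2), stringsAsFactors = FALSE)
  agg <- aggregate(z ~ taxon, inc, function(v) c(length(v), sum(v)))
  deg <- agg$z[, 1]; zsum <- agg$z[, 2]
  ord <- order(-deg, -zsum, agg$taxon)
  k <- min(k, length(ord))
  # extend through ties at the k-th place
  cut_deg <- deg[ord[k]]; cut_z <- zsum[ord[k]]
  keep <- seq_along(ord) <= k |
    (deg[ord] == cut_deg & zsum[ord] == cut_z)
  agg$taxon[ord[keep]]
}

#' Union of hubs across stratified networks
#'
#' @param networks list of `conetwork`s (e.g. from [conet_strata()]).
#' @param k hubs per network.
#' @return de-duplicated character vector of hub taxa.
#' @export
hub_union <- function(networks, k = 4) {
  unique(unlist(lapply(networks, function(nw)
    tryCatch(find_hubs(nw, k), warning = function(w) character(0)))))
}

#' Fraction of mutual-exclusion edges
#'
#' @param network a `conetwork` with at least one edge.
#' @return fraction of edges whose direction is `EXCLUSION`; `NA` with a
#'   warning for an empty network.
#' @export
exclusion_fraction <- function(network) {
  stopifnot(inherits(network, "conetwork"))
  if (nrow(network$edges) == 0) {
    warning("empty network; exclusion fraction undefined")
    return(NA_real_)
  }
  mean(network$edges$direction == "EXCLUSION")
}
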
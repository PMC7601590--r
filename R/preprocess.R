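#' Keep taxa whose lineage matches a taxonomic group
#'
#' Retains taxa whose lineage string contains `lineage_prefix` at any rank
#' (fixed-string, case-sensitive match).  Used to restrict the fungal table
#' to the strictly anaerobic rumen fungi (phylum Neocallimastigomycota)
#' before rarefaction.
#'
#' @param table a [count_table()] with populated taxonomy.
#' @param lineage_prefix string to look for, e.g. `"Neocallimastigomycota"`.
#' @return the filtered `count_table` (warns if no taxon matches).
#' @export
filter_taxonomy <- function(table, lineage_prefix) {
  stopifnot(inherits(table, "count_table"))
  keep <- grepl(lineage_prefix, table$taxonomy, fixed = TRUE)
  if (!any(keep))
    warning("no taxon lineage contains '", lineage_prefix, "'; empty table")
  count_table(table$counts[, keep, drop = FALSE], table$taxonomy[keep])
}

#' Prevalence filter
#'
#' A taxon is kept iff its count is positive in at least
#' `ceiling(min_fraction * n_samples)` samples.  The analysis uses 0.5 for
#' the co-occurrence network nodes and 0.1 for differential abundance.
#'
#' @param table a [count_table()].
#' @param min_fraction required presence fraction in (0, 1].
#' @return the filtered `count_table`.
#' @export
filter_prevalence <- function(table, min_fraction) {
  stopifnot(inherits(table, "count_table"),
            min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * nrow(table$counts))
  keep <- colSums(table$counts > 0) >= need
  count_table(table$counts[, keep, drop = FALSE], table$taxonomy[keep])
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads (multivariate hypergeometric).  Samples whose total is below
#' `depth` are dropped with a warning; a sample exactly at `depth` is
#' returned unchanged.  The study depths are 25,000 reads for 16S and 7,000
#' for the Neocallimastigomycota-filtered ITS table.
#'
#' @param table a [count_table()].
#' @param depth target depth (reads per sample), >= 1.
#' @param seed integer seed making the subsample reproducible.
#' @return a rarefied `count_table`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"), depth >= 1)
  tot <- rowSums(table$counts)
  low <- tot < depth
  if (all(low))
    stop("all samples have fewer than ", depth, " reads; cannot rarefy")
  if (any(low))
    warning(sum(low), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(table$counts)[low], collapse = ", "))
  m <- table$counts[!low, , drop = FALSE]
  set.seed(seed)
  at <- rowSums(m) == depth
  if (any(!at))
    withCallingHandlers(
      m[!at, ] <- vegan::rrarefy(m[!at, , drop = FALSE], depth),
      # rrarefy's heuristic fires whenever the smallest positive count
      # exceeds 1; these are genuine counts, so the alarm is spurious
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  count_table(m, table$taxonomy)
}

#' Bayesian-multiplicative zero replacement
#'
#' Replaces count zeros by posterior-expected small proportions and rescales
#' the observed parts multiplicatively, so that ratios among observed taxa
#' are preserved (the property CLR analysis requires).  For sample j with
#' total n_j, a zero cell of taxon i is imputed as `t_i * s / (n_j + s)`
#' where the prior weight `t_i` is taxon i's mean relative abundance over
#' the samples where it is present and `s` is the prior strength (default
#' 1).  Non-zero proportions are then shrunk by the factor
#' `1 - sum(imputed)` so the row still sums to one.  If an imputed value
#' would reach the sample's smallest observed proportion it is shrunk by
#' 0.65 (repeatedly if needed) with a warning.
#'
#' @param table a [count_table()]; every sample needs a positive total and
#'   every taxon a presence somewhere.
#' @param s prior strength (default 1).
#' @return a `composition` object: list with `values` (samples x taxa,
#'   strictly positive, rows summing to 1) and `taxonomy`.
#' @export
replace_zeros_bayesian <- function(table, s = 1) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  if (any(rowSums(m) == 0)) stop("sample(s) with no positive count")
  if (any(colSums(m) == 0)) stop("taxon (taxa) absent from every sample")
  prop <- m / rowSums(m)
  pres <- m > 0
  t_i <- colSums(prop) / colSums(pres)      # mean rel. abundance where present
  t_i <- t_i / sum(t_i)                     # renormalized prior over taxa
  n_j <- rowSums(m)
  out <- prop
  shrunk <- FALSE
  for (j in seq_len(nrow(m))) {
    z <- !pres[j, ]
    if (!any(z)) next
    imp <- t_i[z] * s / (n_j[j] + s)
    minobs <- min(prop[j, !z])
    while (any(imp >= minobs)) {
      imp[imp >= minobs] <- imp[imp >= minobs] * 0.65
      shrunk <- TRUE
    }
    out[j, z] <- imp
    out[j, !z] <- prop[j, !z] * (1 - sum(imp))
  }
  if (shrunk)
    warning("some imputed proportions reached an observed value; shrunk by 0.65")
  structure(list(values = out, taxonomy = table$taxonomy),
            class = "composition")
}

#' Simple closure to relative abundances
#'
#' Divides each sample's counts by its total.  Unlike
#' [replace_zeros_bayesian()] this keeps zeros; it is the input expected by
#' the co-occurrence network stage.
#'
#' @param table a [count_table()].
#' @return matrix of relative abundances (rows sum to 1).
#' @export
closure <- function(table) {
  m <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  if (any(rowSums(m) == 0)) stop("sample(s) with no positive count")
  m / rowSums(m)
}

#' Centred log-ratio transform
#'
#' Maps each strictly positive composition row x to
#' `log(x_i) - mean(log(x))`, so every row of the result sums to zero and
#' the transform is invariant to sample-wise rescaling of the input.
#'
#' @param comp a `composition` from [replace_zeros_bayesian()], or a
#'   strictly positive matrix.
#' @return a `clr_matrix`: list with `values` (rows sum to 0) and
#'   `taxonomy` when available.
#' @export
clr_transform <- function(comp) {
  v <- if (inherits(comp, "composition")) comp$values else as.matrix(comp)
  if (any(v <= 0)) stop("CLR requires strictly positive input; impute zeros first")
  lv <- log(v)
  res <- lv - rowMeans(lv)
  structure(list(values = res,
                 taxonomy = if (inherits(comp, "composition")) comp$taxonomy),
            class = "clr_matrix")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("composition: %d samples x %d taxa (rows sum to 1)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat(sprintf("clr_matrix: %d samples x %d taxa (rows sum to 0)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Standard preprocessing for one kingdom
#'
#' Convenience wrapper running the default order used throughout the
#' analysis: optional taxonomy filter, rarefaction, then prevalence filter
#' on the rarefied table.
#'
#' @param table a [count_table()].
#' @param rarefy_depth rarefaction depth (reads).
#' @param min_prevalence presence fraction for [filter_prevalence()].
#' @param taxonomy_keep optional lineage substring for [filter_taxonomy()].
#' @param seed seed passed to [rarefy()].
#' @return the processed `count_table`.
#' @export
preprocess_table <- function(table, rarefy_depth, min_prevalence,
                             taxonomy_keep = NULL, seed = 1L) {
  if (!is.null(taxonomy_keep)) table <- filter_taxonomy(table, taxonomy_keep)
  table <- rarefy(table, rarefy_depth, seed = seed)
  filter_prevalence(table, min_prevalence)
}
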
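#' @useDynLib ruminet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pchisq pnorm pt rbinom rlnorm rmultinom rnorm runif
#'   sd var quantile p.adjust complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' Construct an ASV count table
#'
#' `count_table` is the package's canonical container for an ASV table: a
#' samples x taxa matrix of non-negative integer counts plus one taxonomy
#' lineage string per taxon (semicolon-delimited ranks, possibly empty).
#' Internally samples are always rows; on-disk amplicon exports usually have
#' taxa as rows, which [read_count_table()] transposes on read.
#'
#' @param counts integer matrix, samples x taxa, with unique row and column
#'   names.
#' @param taxonomy character vector of lineage strings, one per taxon.
#'   Defaults to empty lineages.
#' @return an object of class `count_table` with fields `counts` (matrix) and
#'   `taxonomy` (named character vector).
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at sample '%s', taxon '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 counts[bad[1, 1], bad[1, 2]]))
  storage.mode(counts) <- "double"   # counts may exceed .Machine$integer.max in totals
  if (is.null(taxonomy)) taxonomy <- rep("", ncol(counts))
  if (length(taxonomy) != ncol(counts))
    stop("taxonomy length (", length(taxonomy), ") != taxon count (", ncol(counts), ")")
  taxonomy <- as.character(taxonomy)
  names(taxonomy) <- colnames(counts)
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, total count %.0f\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Sample and taxon identifiers of a table
#'
#' @param x a `count_table`, `composition` or `clr_matrix`.
#' @return character vector of IDs.
#' @export
sample_ids <- function(x) rownames(if (is.list(x)) x$counts %||% x$values else x)

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(if (is.list(x)) x$counts %||% x$values else x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ASV count table from a tab-separated file
#'
#' Reads the common amplicon export dialect: taxa as rows with a first ID
#' column (conventionally `#ASV_ID`) and an optional final `taxonomy` column,
#' or the transposed samples-as-rows layout.  Cells must be non-negative
#' integers; offending cells are reported by sample and taxon ID.
#'
#' @param path path to a TSV file.
#' @param orientation `"taxa_rows"` (default, amplicon convention) or
#'   `"samples_rows"`.
#' @return a [count_table()] in the canonical samples x taxa orientation.
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an ID column and at least one data column")
  ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  if (orientation == "taxa_rows" && tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- df[[ncol(df)]]
    df <- df[, -ncol(df), drop = FALSE]
  }
  suppressWarnings(num <- vapply(df, as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(df)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rn <- rownames(num)[bad[1, 1]]; cn <- colnames(num)[bad[1, 2]]
    if (orientation == "taxa_rows")
      stop(sprintf("invalid count at sample '%s', taxon '%s'", cn, rn))
    stop(sprintf("invalid count at sample '%s', taxon '%s'", rn, cn))
  }
  if (orientation == "taxa_rows") num <- t(num)
  count_table(num, taxonomy = taxonomy)
}

#' Write an ASV count table as TSV
#'
#' @param table a [count_table()].
#' @param path output path.
#' @param orientation on-disk layout; default taxa as rows with a trailing
#'   `taxonomy` column (the amplicon convention).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path,
                              orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(table, "count_table"))
  if (orientation == "taxa_rows") {
    out <- data.frame(`#ASV_ID` = colnames(table$counts),
                      t(table$counts),
                      taxonomy = unname(table$taxonomy),
                      check.names = FALSE)
  } else {
    out <- data.frame(sample_id = rownames(table$counts), table$counts,
                      check.names = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TREATMENTS <- c("BASELINE", "PA", "AA", "AS")
BLOAT_LEVELS <- c("B", "NB", "NA")

#' Read or validate sample metadata
#'
#' Metadata rows describe the crossover design: one sample per steer per
#' occasion, with `period` 0 denoting the pre-grazing baseline (alfalfa hay)
#' and treatments `PA` (pure alfalfa), `AA` (alfalfa + Alfasure) and `AS`
#' (alfalfa-sainfoin).  Bloat status is the dichotomized field score (`B` /
#' `NB`); baseline samples carry `NA` since bloat is only scored on pasture.
#'
#' @param path TSV file with columns `sample_id`, `steer_id`, `period`,
#'   `treatment`, `bloat`.
#' @return a `data.frame` with those columns, validated.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param meta a data.frame to validate in place of a file.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "steer_id", "period", "treatment", "bloat")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  meta$sample_id <- as.character(meta$sample_id)
  meta$steer_id <- as.character(meta$steer_id)
  meta$period <- as.integer(meta$period)
  meta$treatment <- as.character(meta$treatment)
  meta$bloat <- as.character(meta$bloat)
  meta$bloat[is.na(meta$bloat)] <- "NA"
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  badt <- setdiff(unique(meta$treatment), TREATMENTS)
  if (length(badt) > 0) stop("unknown treatment token(s): ", paste(badt, collapse = ", "))
  badb <- setdiff(unique(meta$bloat), BLOAT_LEVELS)
  if (length(badb) > 0) stop("unknown bloat token(s): ", paste(badb, collapse = ", "))
  if (any(is.na(meta$period)) || any(meta$period < 0))
    stop("period must be a non-negative integer (0 = baseline)")
  if (any(meta$treatment == "BASELINE" & meta$bloat != "NA"))
    stop("BASELINE samples must have bloat = NA (bloat is only scored on pasture)")
  key <- paste(meta$steer_id, meta$period)
  if (anyDuplicated(key))
    stop("duplicate (steer, period) combination: ", key[duplicated(key)][1])
  meta
}

#' Write sample metadata as TSV
#' @param meta validated metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  write.table(validate_metadata(meta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

EDGE_COLUMNS <- c("fungal_taxon", "bacterial_taxon", "direction",
                  "supporting_measures", "n_support", "p_merged", "q", "passed_ci")

#' Write and read co-occurrence edge lists
#'
#' One row per retained fungus-bacterium edge: the taxon pair, direction
#' (`COPRESENCE` or `EXCLUSION`), the pipe-separated list of supporting
#' association measures, the Brown-merged p-value, its BH-adjusted q, and
#' whether all supporting observed scores sat inside their bootstrap CIs.
#'
#' @param edges a data.frame of edges as produced by [build_network()]
#'   (`network$edges`).
#' @param path output path.
#' @param taxa optional character vector of known taxon IDs; edges naming
#'   other taxa are an error.
#' @return `path` invisibly for the writer; an edge data.frame for the reader.
#' @export
write_edge_list <- function(edges, path, taxa = NULL) {
  if (nrow(edges) == 0) {
    edges <- as.data.frame(setNames(rep(list(character(0)), length(EDGE_COLUMNS)),
                                    EDGE_COLUMNS))
  }
  miss <- setdiff(EDGE_COLUMNS, names(edges))
  if (length(miss) > 0) stop("edge list missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(taxa)) {
    unk <- setdiff(c(edges$fungal_taxon, edges$bacterial_taxon), taxa)
    if (length(unk) > 0) stop("edges reference unknown taxa: ", paste(unk, collapse = ", "))
  }
  out <- edges[, EDGE_COLUMNS]
  if (nrow(out) > 0)
    for (col in c("p_merged", "q"))  # full precision so readback is exact
      out[[col]] <- sprintf("%.17g", as.numeric(out[[col]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(fungal_taxon = "character",
                                  bacterial_taxon = "character",
                                  direction = "character",
                                  supporting_measures = "character",
                                  n_support = "integer",
                                  p_merged = "numeric", q = "numeric",
                                  passed_ci = "logical"))
  df
}

#' Export a co-occurrence network as GraphML
#'
#' Nodes carry a `kingdom` attribute (`fungi` / `bacteria`); edges carry the
#' direction, merged p, q and support count.
#'
#' @param network a `conetwork` from [build_network()].
#' @param path output path.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a `conetwork` to an igraph object
#' @param network a `conetwork`.
#' @return an igraph graph with node `kingdom` and edge statistics attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "conetwork"))
  nodes <- network$nodes
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges) > 0)
      data.frame(from = edges$fungal_taxon, to = edges$bacterial_taxon,
                 direction = edges$direction, p_merged = edges$p_merged,
                 q = edges$q, n_support = edges$n_support,
                 stringsAsFactors = FALSE)
    else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = nodes$taxon, kingdom = nodes$kingdom,
                          stringsAsFactors = FALSE))
  g
}
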
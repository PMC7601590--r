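#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].  Inputs
#' are either file paths (`fungal`, `bacterial`, `metadata` TSVs) or a
#' `simulate` block (a [synth_config()] or list of its arguments).  The
#' remaining fields carry the analysis constants: rarefaction depths 7,000
#' (fungal) / 25,000 (bacterial) reads, node prevalence 0.50 for the
#' network and 0.10 for differential abundance, edge rule
#' (`min_support` 3, `alpha` 0.05, 95% bootstrap CI) and resampling sizes.
#'
#' @param paths list with `fungal`, `bacterial`, `metadata` file paths, or
#'   `NULL` to simulate.
#' @param simulate a [synth_config()] (or argument list) used when no
#'   paths are given.
#' @param depth_fungal,depth_bacterial rarefaction depths.
#' @param prevalence_network,prevalence_diffabund presence fractions.
#' @param taxonomy_keep lineage substring retained in the fungal table
#'   (default `"Neocallimastigomycota"`; `NULL` disables).
#' @param alpha significance/FDR threshold.
#' @param min_support minimum agreeing measures per edge.
#' @param b_perm,b_boot network permutation/bootstrap iterations.
#' @param b_anova permutations per taxon in differential abundance.
#' @param n_perm_ordination permutations for RDA/PERMANOVA.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(paths = NULL, simulate = synth_config(),
                            depth_fungal = 7000, depth_bacterial = 25000,
                            prevalence_network = 0.50,
                            prevalence_diffabund = 0.10,
                            taxonomy_keep = "Neocallimastigomycota",
                            alpha = 0.05, min_support = 3,
                            b_perm = 1000, b_boot = 1000, b_anova = 4999,
                            n_perm_ordination = 999, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(depth_fungal >= 1, depth_bacterial >= 1,
            prevalence_network > 0, prevalence_network <= 1,
            prevalence_diffabund > 0, prevalence_diffabund <= 1)
  if (is.null(paths)) {
    if (is.list(simulate) && !inherits(simulate, "synth_config"))
      cfg$simulate <- do.call(synth_config, simulate)
  } else {
    miss <- setdiff(c("fungal", "bacterial", "metadata"), names(paths))
    if (length(miss) > 0)
      stop("paths must name fungal, bacterial and metadata files; missing: ",
           paste(miss, collapse = ", "))
    absent <- !vapply(paths[c("fungal", "bacterial", "metadata")],
                      file.exists, TRUE)
    if (any(absent))
      stop("input file(s) not found: ",
           paste(unlist(paths)[absent], collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate` mapping mirrors [synth_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(synth_config, y$simulate)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing, diversity, ordination, network
#' inference and differential abundance, writing each stage's outputs as
#' plain TSV/JSON/GraphML under `out_dir` together with a machine-readable
#' manifest (stage, derived seed, parameters, output MD5 hashes).  The
#' same configuration and master seed reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ruminet", seed = config$seed, stages = list())
  stage_seed <- function(stage)
    derive_seed(config$seed, match(stage, c("simulate", "preprocess",
                                            "diversity", "ordination",
                                            "network", "diffabund")))
  note <- function(stage, seed, params, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage, seed = seed, parameters = params,
      outputs = as.list(tools::md5sum(file.path(out_dir, files))))
  }
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    name
  }

  # -- inputs --------------------------------------------------------------
  if (is.null(config$paths)) {
    scfg <- config$simulate
    scfg$seed <- stage_seed("simulate")
    ds <- generate_dataset(scfg)
    write_count_table(ds$fungal, file.path(out_dir, "fungal_counts.tsv"))
    write_count_table(ds$bacterial, file.path(out_dir, "bacterial_counts.tsv"))
    write_metadata(ds$meta, file.path(out_dir, "metadata.tsv"))
    jsonlite::write_json(ds$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    note("simulate", scfg$seed, scfg[!vapply(scfg, is.function, TRUE)],
         c("fungal_counts.tsv", "bacterial_counts.tsv", "metadata.tsv",
           "truth.json"))
    fungal <- ds$fungal; bacterial <- ds$bacterial; meta <- ds$meta
  } else {
    meta <- read_metadata(config$paths$metadata)
    fungal <- read_count_table(config$paths$fungal)
    bacterial <- read_count_table(config$paths$bacterial)
  }

  # -- preprocess ----------------------------------------------------------
  sd2 <- stage_seed("preprocess")
  fungal_p <- preprocess_table(fungal, config$depth_fungal,
                               config$prevalence_network,
                               taxonomy_keep = config$taxonomy_keep,
                               seed = sd2)
  bacterial_p <- preprocess_table(bacterial, config$depth_bacterial,
                                  config$prevalence_network, seed = sd2 + 1L)
  meta <- meta[meta$sample_id %in%
                 intersect(sample_ids(fungal_p), sample_ids(bacterial_p)), ]
  fungal_p$counts <- fungal_p$counts[meta$sample_id, , drop = FALSE]
  bacterial_p$counts <- bacterial_p$counts[meta$sample_id, , drop = FALSE]
  write_count_table(fungal_p, file.path(out_dir, "fungal_processed.tsv"))
  write_count_table(bacterial_p, file.path(out_dir, "bacterial_processed.tsv"))
  note("preprocess", sd2,
       config[c("depth_fungal", "depth_bacterial", "prevalence_network",
                "taxonomy_keep")],
       c("fungal_processed.tsv", "bacterial_processed.tsv"))

  # -- diversity -----------------------------------------------------------
  div <- alpha_diversity(fungal_p)
  dtests <- diversity_tests(fungal_p, meta)
  dcor <- diversity_correlation(fungal_p, bacterial_p)
  tsv(div, "diversity.tsv")
  tsv(dtests, "diversity_tests.tsv")
  jsonlite::write_json(dcor, file.path(out_dir, "diversity_correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  note("diversity", NA, list(),
       c("diversity.tsv", "diversity_tests.tsv",
         "diversity_correlation.json"))

  # -- ordination ----------------------------------------------------------
  sd4 <- stage_seed("ordination")
  clr_f <- clr_transform(replace_zeros_bayesian(fungal_p))
  clr_b <- clr_transform(replace_zeros_bayesian(bacterial_p))
  grp <- diet_bloat_groups(meta)
  rda_overall <- rda(clr_f, factor(meta$treatment),
                     n_perm = config$n_perm_ordination, seed = sd4)
  adonis_pairs <- permanova_pairwise(
    fungal_p, grp,
    pairs = lapply(setdiff(unique(grp), "BASELINE"),
                   function(g) c("BASELINE", g)),
    n_perm = config$n_perm_ordination, seed = sd4 + 1L)
  ord <- rbind(
    data.frame(model = "rda_treatment_fungal", r2 = rda_overall$r2,
               r2_adjusted = rda_overall$r2_adjusted,
               pseudo_f = rda_overall$pseudo_f, p = rda_overall$p_perm,
               stringsAsFactors = FALSE))
  tsv(ord, "ordination_rda.tsv")
  tsv(adonis_pairs, "ordination_pairwise_adonis.tsv")
  note("ordination", sd4, list(n_perm = config$n_perm_ordination),
       c("ordination_rda.tsv", "ordination_pairwise_adonis.tsv"))

  # -- network -------------------------------------------------------------
  sd5 <- stage_seed("network")
  nets <- conet_strata(fungal_p, bacterial_p, meta,
                       b_perm = config$b_perm, b_boot = config$b_boot,
                       min_support = config$min_support,
                       alpha = config$alpha, seed = sd5,
                       min_prevalence = config$prevalence_network)
  files <- character(0)
  summ <- list()
  for (s in names(nets)) {
    files <- c(files, tsv(nets[[s]]$edges, paste0("edges_", s, ".tsv")))
    write_graphml(nets[[s]], file.path(out_dir, paste0("network_", s,
                                                       ".graphml")))
    files <- c(files, paste0("network_", s, ".graphml"))
    summ[[s]] <- list(
      n_edges = nrow(nets[[s]]$edges),
      exclusion_fraction = suppressWarnings(exclusion_fraction(nets[[s]])),
      hubs = tryCatch(find_hubs(nets[[s]]), warning = function(w) character(0)))
  }
  hubs <- hub_union(nets)
  tsv(data.frame(taxon = hubs, stringsAsFactors = FALSE), "hubs.tsv")
  jsonlite::write_json(summ, file.path(out_dir, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  note("network", sd5,
       config[c("b_perm", "b_boot", "min_support", "alpha")],
       c(files, "hubs.tsv", "network_summary.json"))

  # hub RDA: bacterial variation explained by hub fungi CLR, adjusted for
  # diet and bloat status
  if (length(hubs) > 0) {
    hub_clr <- clr_f$values[, intersect(hubs, colnames(clr_f$values)),
                            drop = FALSE]
    if (ncol(hub_clr) > 0) {
      hub_rda <- tryCatch(
        rda(clr_b, hub_clr,
            condition = data.frame(treatment = meta$treatment,
                                   bloat = meta$bloat),
            n_perm = config$n_perm_ordination, seed = sd5 + 7L),
        error = function(e) NULL)
      if (!is.null(hub_rda)) {
        tsv(data.frame(model = "partial_rda_hubs_bacterial",
                       r2 = hub_rda$r2, r2_adjusted = hub_rda$r2_adjusted,
                       pseudo_f = hub_rda$pseudo_f, p = hub_rda$p_perm),
            "ordination_hub_rda.tsv")
      }
    }
  }

  # -- differential abundance ---------------------------------------------
  sd6 <- stage_seed("diffabund")
  da_counts <- rarefy(if (is.null(config$taxonomy_keep)) fungal else
    filter_taxonomy(fungal, config$taxonomy_keep),
    config$depth_fungal, seed = sd2)
  da_counts <- count_table(
    da_counts$counts[intersect(rownames(da_counts$counts), meta$sample_id),
                     , drop = FALSE],
    da_counts$taxonomy)
  da_counts <- filter_prevalence(da_counts, config$prevalence_diffabund)
  clr_da <- clr_transform(replace_zeros_bayesian(da_counts))
  da <- run_diffabund(clr_da, da_counts, meta,
                      min_prevalence = config$prevalence_diffabund,
                      b = config$b_anova, seed = sd6, alpha = config$alpha)
  tsv(as.data.frame(da), "diffabund.tsv")
  fu <- pairwise_followup(clr_da, meta, da$taxon[da$flagged])
  if (!is.null(fu)) tsv(fu, "diffabund_pairwise.tsv")
  note("diffabund", sd6,
       list(min_prevalence = config$prevalence_diffabund,
            b = config$b_anova),
       c("diffabund.tsv", if (!is.null(fu)) "diffabund_pairwise.tsv"))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
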
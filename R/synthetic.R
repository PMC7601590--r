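#' Configuration for the synthetic crossover generator
#'
#' Defaults emulate the grazing trial the pipeline targets: 12 ruminally
#' fistulated steers in a 3x3 crossover (three 4-steer groups rotating
#' through pure alfalfa PA, alfalfa + Alfasure AA and alfalfa-sainfoin AS
#' over three periods) preceded by a shared alfalfa-hay baseline occasion,
#' with a handful of missed samplings so the default run yields 44 samples
#' (12 baseline + 11 PA + 10 AA + 11 AS).  Fungal and bacterial libraries
#' are sequenced separately, so per-sample totals are drawn from independent
#' lognormals whose means match typical ITS / 16S depths for this design
#' (about 110k and 55k reads).
#'
#' Cross-kingdom structure is planted through latent factors: each hub
#' fungus carries a standard-normal per-sample factor with loading
#' `+coupling_strength`; each of its bacterial partners loads
#' `sign * coupling_strength` on the same factor, with a
#' `coupling_sign_mix` fraction of partners negative (mutual exclusion).
#'
#' @param n_steers number of steers (default 12).
#' @param n_fungal_taxa,n_bacterial_taxa taxa per kingdom (defaults 30, 120).
#' @param depth_fungal,depth_bacterial lognormal `c(meanlog, sdlog)` of
#'   per-sample sequencing totals.
#' @param n_hubs number of hub fungi with planted partners (default 5).
#' @param partners_per_hub bacterial partners per hub (default 8).
#' @param coupling_strength latent-factor loading magnitude (default 1.5).
#' @param coupling_sign_mix fraction of negative (exclusion) couplings
#'   (default 0.8).
#' @param treatment_effects `NULL` for none, or
#'   `list(frac_affected=, effect_size=)`: the fraction of taxa per kingdom
#'   receiving a grazing-treatment log-fold shift, and the SD of those
#'   shifts (natural-log scale).  The defaults (0.4, 1.5) put the
#'   baseline-vs-pasture PERMANOVA R-squared of the fungal table around
#'   0.4, the diet-effect magnitude this crossover design is expected to
#'   show.
#' @param base_sd SD of per-taxon baseline log-abundances (controls
#'   composition skew; default 1.5).
#' @param steer_sd SD of per-(steer, taxon) random effects (default 0.1:
#'   animal identity is a minor variance component next to diet and
#'   residual day-to-day variation; see the vignette for why the network
#'   stage is sensitive to this).
#' @param noise_sd SD of per-observation log-abundance noise (default 0.3).
#' @param dropout_extra probability of forcing a structural zero in a
#'   (sample, taxon) cell before count draws (default 0.05).
#' @param sample_dropout named integer vector: grazing samples to drop at
#'   random per treatment (default `c(PA=1, AA=2, AS=1)`, reproducing the
#'   trial's missed samplings).
#' @param bloat_prob named probabilities of bloat by grazing treatment
#'   (default PA always bloats, AA never, AS half - the pattern poloxalene
#'   and sainfoin condensed tannins are expected to produce).
#' @param frac_offtarget_fungal fraction of fungal taxa assigned
#'   non-Neocallimastigomycota lineages, exercising the taxonomy filter
#'   (default 0.15).
#' @param seed integer RNG seed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_steers = 12,
                         n_fungal_taxa = 30,
                         n_bacterial_taxa = 120,
                         depth_fungal = c(meanlog = log(110000), sdlog = 0.55),
                         depth_bacterial = c(meanlog = log(55000), sdlog = 0.33),
                         n_hubs = 5,
                         partners_per_hub = 8,
                         coupling_strength = 1.5,
                         coupling_sign_mix = 0.8,
                         treatment_effects = list(frac_affected = 0.4,
                                                  effect_size = 1.5),
                         base_sd = 1.5,
                         steer_sd = 0.1,
                         noise_sd = 0.3,
                         dropout_extra = 0.05,
                         sample_dropout = c(PA = 1, AA = 2, AS = 1),
                         bloat_prob = c(PA = 1.0, AA = 0.0, AS = 0.5),
                         frac_offtarget_fungal = 0.15,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_steers >= 2, n_fungal_taxa >= 2, n_bacterial_taxa >= 2,
            coupling_strength >= 0,
            coupling_sign_mix >= 0, coupling_sign_mix <= 1,
            steer_sd >= 0, noise_sd >= 0,
            dropout_extra >= 0, dropout_extra < 1)
  if (n_hubs * partners_per_hub > n_bacterial_taxa)
    stop("n_hubs * partners_per_hub (", n_hubs * partners_per_hub,
         ") exceeds n_bacterial_taxa (", n_bacterial_taxa, ")")
  class(cfg) <- "synth_config"
  cfg
}

FUNGAL_GENERA <- c("Neocallimastix", "Caecomyces", "Orpinomyces", "Piromyces",
                   "Neocallimastigaceae_unclassified", "Cyllamyces",
                   "Anaeromyces", "Buwchfawromyces")
BACTERIAL_PHYLA <- c("Bacteroidetes", "Firmicutes", "Fibrobacteres",
                     "Spirochaetes", "Proteobacteria")

crossover_metadata <- function(cfg) {
  steers <- sprintf("S%02d", seq_len(cfg$n_steers))
  # three groups rotate PA/AA/AS across the three grazing periods
  latin <- rbind(c("PA", "AA", "AS"), c("AA", "AS", "PA"), c("AS", "PA", "AA"))
  grp <- ((seq_len(cfg$n_steers) - 1L) %% 3L) + 1L
  rows <- list(data.frame(sample_id = paste0(steers, ".P0"), steer_id = steers,
                          period = 0L, treatment = "BASELINE", bloat = "NA",
                          stringsAsFactors = FALSE))
  for (p in 1:3) {
    rows[[p + 1L]] <- data.frame(
      sample_id = paste0(steers, ".P", p), steer_id = steers, period = p,
      treatment = latin[cbind(grp, p)], bloat = "NA", stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  graze <- meta$treatment != "BASELINE"
  meta$bloat[graze] <- ifelse(
    runif(sum(graze)) < cfg$bloat_prob[meta$treatment[graze]], "B", "NB")
  # missed samplings, per treatment
  drop <- character(0)
  for (tr in names(cfg$sample_dropout)) {
    k <- cfg$sample_dropout[[tr]]
    if (k > 0) {
      cand <- meta$sample_id[meta$treatment == tr]
      drop <- c(drop, sample(cand, min(k, length(cand))))
    }
  }
  meta <- meta[!meta$sample_id %in% drop, , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

fungal_taxonomy <- function(ids, off_target) {
  n <- length(ids)
  genus <- sample(FUNGAL_GENERA, n, replace = TRUE)
  lin <- paste0("k__Fungi;p__Neocallimastigomycota;c__Neocallimastigomycetes;",
                "o__Neocallimastigales;f__Neocallimastigaceae;g__", genus,
                ";s__", sub("^F", "sp", ids))
  if (off_target > 0) {
    k <- sample(n, round(off_target * n))
    lin[k] <- paste0("k__Fungi;p__",
                     sample(c("Ascomycota", "Basidiomycota"), length(k),
                            replace = TRUE),
                     ";c__;o__;f__;g__;s__", sub("^F", "sp", ids[k]))
  }
  lin
}

bacterial_taxonomy <- function(ids) {
  paste0("k__Bacteria;p__",
         sample(BACTERIAL_PHYLA, length(ids), replace = TRUE,
                prob = c(0.54, 0.29, 0.07, 0.04, 0.06)),
         ";c__;o__;f__;g__;s__", sub("^B", "sp", ids))
}

# latent log-abundance -> multinomial counts for one kingdom
sample_kingdom_counts <- function(lat, depth_par, dropout_extra) {
  n <- nrow(lat)
  depth <- round(rlnorm(n, depth_par[[1]], depth_par[[2]]))
  counts <- matrix(0, n, ncol(lat), dimnames = dimnames(lat))
  for (s in seq_len(n)) {
    p <- exp(lat[s, ] - max(lat[s, ]))
    if (dropout_extra > 0) {
      z <- runif(length(p)) < dropout_extra
      if (all(z)) z[which.max(p)] <- FALSE
      p[z] <- 0
    }
    counts[s, ] <- rmultinom(1, depth[s], p / sum(p))
  }
  list(counts = counts, depth = depth)
}

#' Generate a paired synthetic fungal/bacterial dataset
#'
#' Draws the full crossover dataset: metadata, one fungal and one bacterial
#' count table over the same samples, and the ground truth of planted
#' fungus-bacterium couplings and realized treatment shifts.  Latent
#' log-abundance of taxon t in sample s is
#' `base_t + treatment shift + steer effect + sum_k L_tk f_ks + noise`,
#' with counts drawn multinomially at a lognormal per-sample depth from the
#' within-kingdom softmax - a logistic-normal-multinomial model in which
#' planted couplings are latent-factor loadings with controlled sign.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `fungal` and `bacterial` ([count_table()]s),
#'   `meta` (metadata data.frame) and `truth` (list with `planted_edges`,
#'   `group_effects`, `hubs`, `seed`).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  meta <- crossover_metadata(cfg)
  n <- nrow(meta)
  fid <- sprintf("F%03d", seq_len(cfg$n_fungal_taxa))
  bid <- sprintf("B%03d", seq_len(cfg$n_bacterial_taxa))
  ftax <- fungal_taxonomy(fid, cfg$frac_offtarget_fungal)
  btax <- bacterial_taxonomy(bid)
  target <- grepl("Neocallimastigomycota", ftax)

  base_f <- rnorm(cfg$n_fungal_taxa, 0, cfg$base_sd)
  base_b <- rnorm(cfg$n_bacterial_taxa, 0, cfg$base_sd)

  # Planted couplings: hubs among target fungi, disjoint bacterial
  # partners.  Coupled taxa are drawn from the interquartile range of
  # baseline abundance: a coupled taxon that dominates its kingdom's
  # composition would drag every other taxon's relative abundance along
  # through closure, so the planted edges would no longer be the dataset's
  # dominant cross-kingdom structure.
  mid <- function(base, ok = rep(TRUE, length(base))) {
    qs <- stats::quantile(base, c(0.25, 0.75))
    cand <- which(ok & base >= qs[1] & base <= qs[2])
    if (length(cand) == 0) which(ok) else cand
  }
  planted <- data.frame(fungal_taxon = character(0),
                        bacterial_taxon = character(0), sign = integer(0))
  hubs <- character(0)
  Lf <- matrix(0, cfg$n_fungal_taxa, max(cfg$n_hubs, 1))
  Lb <- matrix(0, cfg$n_bacterial_taxa, max(cfg$n_hubs, 1))
  if (cfg$n_hubs > 0 && cfg$coupling_strength > 0) {
    elig_f <- mid(base_f, target)
    if (length(elig_f) < cfg$n_hubs) elig_f <- which(target)
    hub_idx <- sample(elig_f, cfg$n_hubs)
    hubs <- fid[hub_idx]
    elig_b <- mid(base_b)
    if (length(elig_b) < cfg$n_hubs * cfg$partners_per_hub)
      elig_b <- seq_len(cfg$n_bacterial_taxa)
    partner_idx <- matrix(sample(elig_b, cfg$n_hubs * cfg$partners_per_hub),
                          nrow = cfg$n_hubs)
    n_edges <- cfg$n_hubs * cfg$partners_per_hub
    signs <- sample(rep(c(-1L, 1L),
                        c(round(cfg$coupling_sign_mix * n_edges),
                          n_edges - round(cfg$coupling_sign_mix * n_edges))))
    e <- 0L
    for (h in seq_len(cfg$n_hubs)) {
      Lf[hub_idx[h], h] <- cfg$coupling_strength
      for (j in seq_len(cfg$partners_per_hub)) {
        e <- e + 1L
        Lb[partner_idx[h, j], h] <- signs[e] * cfg$coupling_strength
        planted <- rbind(planted, data.frame(
          fungal_taxon = fid[hub_idx[h]],
          bacterial_taxon = bid[partner_idx[h, j]], sign = signs[e],
          stringsAsFactors = FALSE))
      }
    }
  }

  # realized treatment shifts (natural-log scale), recorded in truth
  shifts <- data.frame(taxon = character(0), kingdom = character(0),
                       treatment = character(0), shift = numeric(0))
  shift_mat <- function(ids, kingdom) {
    m <- matrix(0, length(ids), 4, dimnames = list(ids, TREATMENTS))
    te <- cfg$treatment_effects
    if (!is.null(te) && te$frac_affected > 0 && te$effect_size > 0) {
      aff <- sample(length(ids), round(te$frac_affected * length(ids)))
      for (tr in c("PA", "AA", "AS")) {
        m[aff, tr] <- rnorm(length(aff), 0, te$effect_size)
        shifts <<- rbind(shifts, data.frame(
          taxon = ids[aff], kingdom = kingdom, treatment = tr,
          shift = m[aff, tr], stringsAsFactors = FALSE))
      }
    }
    m
  }
  sf <- shift_mat(fid, "fungi")
  sb <- shift_mat(bid, "bacteria")

  steers <- unique(meta$steer_id)
  se_f <- matrix(rnorm(length(steers) * cfg$n_fungal_taxa, 0, cfg$steer_sd),
                 length(steers), dimnames = list(steers, fid))
  se_b <- matrix(rnorm(length(steers) * cfg$n_bacterial_taxa, 0, cfg$steer_sd),
                 length(steers), dimnames = list(steers, bid))
  fac <- matrix(rnorm(n * max(cfg$n_hubs, 1)), n)  # shared latent factors

  lat_f <- matrix(rep(base_f, each = n), n, dimnames = list(meta$sample_id, fid))
  lat_b <- matrix(rep(base_b, each = n), n, dimnames = list(meta$sample_id, bid))
  lat_f <- lat_f + t(sf[, meta$treatment, drop = FALSE])
  lat_b <- lat_b + t(sb[, meta$treatment, drop = FALSE])
  lat_f <- lat_f + se_f[meta$steer_id, , drop = FALSE]
  lat_b <- lat_b + se_b[meta$steer_id, , drop = FALSE]
  lat_f <- lat_f + fac %*% t(Lf)
  lat_b <- lat_b + fac %*% t(Lb)
  lat_f <- lat_f + matrix(rnorm(n * cfg$n_fungal_taxa, 0, cfg$noise_sd), n)
  lat_b <- lat_b + matrix(rnorm(n * cfg$n_bacterial_taxa, 0, cfg$noise_sd), n)

  kf <- sample_kingdom_counts(lat_f, cfg$depth_fungal, cfg$dropout_extra)
  kb <- sample_kingdom_counts(lat_b, cfg$depth_bacterial, cfg$dropout_extra)

  list(fungal = count_table(kf$counts, ftax),
       bacterial = count_table(kb$counts, btax),
       meta = meta,
       truth = list(planted_edges = planted, group_effects = shifts,
                    hubs = hubs, depth_fungal = kf$depth,
                    depth_bacterial = kb$depth, seed = cfg$seed))
}

#' Generate a matched null dataset
#'
#' Same design and marginal structure as [generate_dataset()] but with
#' couplings and treatment effects forced to zero - the type-I-error
#' harness for the network and differential-abundance stages.
#'
#' @param cfg a [synth_config()]; `coupling_strength` and
#'   `treatment_effects` are overridden.
#' @return as [generate_dataset()]; `truth$planted_edges` has zero rows.
#' @export
null_dataset <- function(cfg = synth_config()) {
  cfg$coupling_strength <- 0
  cfg$n_hubs <- 0L
  cfg$treatment_effects <- NULL
  generate_dataset(cfg)
}
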
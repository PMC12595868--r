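#' Synthetic study design
#'
#' Describes the factorial design the generator emulates: two crops
#' (perennial Kernza vs annual wheat) grown in three countries, sampled
#' in two years at two rhizosphere depths, with country-specific plot
#' (replicate) counts and one missing country x year x depth cell, for
#' 64 rhizosphere libraries under the defaults. Planted structure (core
#' taxa, crop indicators, preferentially recruited taxa, database
#' category members) gives every downstream analysis a known truth.
#'
#' Effects act multiplicatively on the log scale of the cell's
#' composition; the year perturbation is scaled per crop
#' (`year_effect`), which is how one crop is generated with a more
#' stable (lower inter-annual turnover) rhizomicrobiome. Planted core
#' ASVs are exempt from the random factor perturbations: core taxa are,
#' by construction, the consistently present and abundant members.
#'
#' @param n_asv Number of rhizosphere ASVs (default 400).
#' @param depth_reads Sequencing depth per rhizosphere library (default
#'   20000; multinomial draws conserve it exactly).
#' @param replicates Named integer vector of plots per country.
#' @param country_effect,depth_effect,crop_effect Log-scale s.d. of the
#'   respective per-ASV perturbations.
#' @param year_effect Named per-crop log-scale s.d. of the shared
#'   year-2 perturbation (default Kernza 0.08 < wheat 0.65: the perennial
#'   crop is generated with several-fold less inter-annual turnover).
#' @param base_log_sd Log-s.d. of the base (cell-independent)
#'   composition.
#' @param sample_log_sd Log-s.d. of per-library compositional noise
#'   (plot-to-plot heterogeneity within a cell). This is the main
#'   residual-variance dial: the default is calibrated so the PERMANOVA
#'   variance partition of a generated study sits at the field scale
#'   (country R-squared around 0.08, year and depth a few percent, crop
#'   marginal).
#' @param dirichlet_theta Dirichlet concentration for per-sample
#'   compositional noise (larger = less overdispersion).
#' @param core_share Expected per-cell read share of each planted core
#'   ASV (default 0.0035, i.e. 3.5 times the 0.001 abundance threshold);
#'   the other crop's cores sit 30-fold below it.
#' @param indicator_fold Fold-change of planted crop indicators in their
#'   crop (default 4).
#' @param ewas_fold Fold-change of planted grassland/rhizosphere
#'   category ASVs in Kernza (default 2).
#' @param seed_origin_fraction Named per-crop fraction of the endosphere
#'   community drawn from seed-borne ASVs absent from the rhizosphere
#'   (default Kernza 0.2 < wheat 0.4, so Kernza recruits more of its
#'   endophytes from the rhizosphere).
#' @param preferential_weight Endosphere recruitment weight multiplier of
#'   planted preferential ASVs in their favoured crop (default 10).
#' @param endo_k Endosphere libraries per surface rhizosphere library.
#' @param endo_depth Sequencing depth per endosphere library.
#' @param n_seed_asv Number of seed-borne endosphere-only ASVs.
#' @param n_decoy Decoy sequences in the synthetic indicator database.
#' @param seed Integer seed; the whole fixture is a pure function of the
#'   design.
#' @return A `syn_design` list.
#' @export
synthetic_design <- function(n_asv = 400, depth_reads = 20000,
                             replicates = c(SE = 4, BE = 4, FR = 1),
                             country_effect = 0.45,
                             year_effect = c(Kernza = 0.08, wheat = 0.65),
                             depth_effect = 0.35,
                             crop_effect = 0.02,
                             base_log_sd = 1.2,
                             sample_log_sd = 1.0,
                             dirichlet_theta = 1000,
                             core_share = 0.0035,
                             indicator_fold = 4,
                             ewas_fold = 2,
                             seed_origin_fraction = c(Kernza = 0.2,
                                                      wheat = 0.4),
                             preferential_weight = 10,
                             endo_k = 3, endo_depth = 5000,
                             n_seed_asv = 80, n_decoy = 200,
                             seed = 1L) {
  stopifnot(n_asv >= 100, depth_reads > 0, all(replicates >= 1),
            country_effect >= 0, all(year_effect >= 0), depth_effect >= 0,
            crop_effect >= 0, endo_k >= 1)
  ids <- sprintf("asv_%04d", seq_len(n_asv))
  design <- list(
    crops = c("Kernza", "wheat"),
    countries = names(replicates),
    years = c(2021L, 2022L),
    depths = c("5-15", "25-35"),
    # deepest layer unsampled in the first country's first year, as in
    # compacted-soil field campaigns; exercises unbalanced-data paths
    missing_cells = data.frame(country = names(replicates)[1],
                               year = 2021L, depth = "25-35"),
    replicates = replicates,
    n_asv = n_asv, depth_reads = depth_reads,
    country_effect = country_effect, year_effect = year_effect,
    depth_effect = depth_effect, crop_effect = crop_effect,
    base_log_sd = base_log_sd, sample_log_sd = sample_log_sd,
    dirichlet_theta = dirichlet_theta,
    core_share = core_share,
    indicator_fold = indicator_fold, ewas_fold = ewas_fold,
    seed_origin_fraction = seed_origin_fraction,
    preferential_weight = preferential_weight,
    endo_k = endo_k, endo_depth = endo_depth,
    n_seed_asv = n_seed_asv, n_decoy = n_decoy,
    seed = as.integer(seed),
    planted = list(
      core_shared = ids[1:5],
      core = list(Kernza = ids[6:8], wheat = ids[9:10]),
      indicators = list(Kernza = ids[11:16], wheat = ids[17:22]),
      preferential = list(Kernza = ids[23:24], wheat = ids[25:26]),
      db_categories = list(grassland = ids[27:41],
                           rhizosphere = ids[42:56],
                           no_till = ids[57:71],
                           organic_horizon = ids[72:86])
    )
  )
  # every ASV given a deliberate crop differential (indicator recall's
  # complement: the false-positive family excludes these)
  design$planted$crop_biased <- sort(unique(c(
    unlist(design$planted$core), unlist(design$planted$indicators),
    design$planted$db_categories$grassland,
    design$planted$db_categories$rhizosphere)))
  class(design) <- "syn_design"
  design
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# per-cell expected composition on the raw (pre-noise) scale
cell_weights <- function(design, z, crop, country, year, depth) {
  # the year perturbation is applied symmetrically (-half in year 1,
  # +half in year 2) so a crop's inter-annual turnover scales with its
  # year_effect without shifting its across-year mean composition
  year_sign <- if (year == design$years[2]) 0.5 else -0.5
  lw <- z$base +
    z$country[, country] +
    year_sign * design$year_effect[[crop]] * z$year +
    (depth == design$depths[2]) * design$depth_effect * z$depth +
    (crop == "Kernza") * design$crop_effect * z$crop
  pl <- design$planted
  w <- exp(lw)
  # planted cores, indicators and grassland/rhizosphere category members
  # are pinned at exact expected shares: cores are stable everywhere
  # (own/shared at core_share; the other crop's cores 30x below it, under
  # the abundance threshold); indicators hold a 0.075% base share lifted
  # indicator_fold-fold in their crop; the two Kernza-associated database
  # categories hold 0.05% per member lifted ewas_fold-fold in Kernza
  core_own <- c(pl$core_shared, pl$core[[crop]])
  core_other <- setdiff(unlist(pl$core), pl$core[[crop]])
  ind_own <- pl$indicators[[crop]]
  ind_other <- setdiff(unlist(pl$indicators), ind_own)
  db_boost <- c(pl$db_categories$grassland, pl$db_categories$rhizosphere)
  db_share <- 0.0005 * if (crop == "Kernza") design$ewas_fold else 1
  share <- c(
    stats::setNames(rep(design$core_share, length(core_own)), core_own),
    stats::setNames(rep(design$core_share * 0.03, length(core_other)),
                    core_other),
    stats::setNames(rep(0.00075 * design$indicator_fold, length(ind_own)),
                    ind_own),
    stats::setNames(rep(0.00075, length(ind_other)), ind_other),
    stats::setNames(rep(db_share, length(db_boost)), db_boost),
    # preferential recruits: moderately abundant, identical in both crops
    stats::setNames(rep(0.001, length(unlist(pl$preferential))),
                    unlist(pl$preferential)))
  rest <- sum(w[setdiff(names(w), names(share))])
  w[names(share)] <- share / (1 - sum(share)) * rest
  w / sum(w)
}

#' Generate a synthetic rhizosphere ASV table
#'
#' Builds the full factorial sample sheet (minus the design's missing
#' cell), a per-cell composition from log-scale factor effects, and
#' Dirichlet-multinomial counts at the configured depth. Representative
#' 250-nt sequences with a fixed 5-nt primer-like prefix are attached so
#' sequence trimming and database matching are exercised non-trivially.
#'
#' @param design A `syn_design`.
#' @return A list: `table` (`asv_tbl` with sequences), `metadata`
#'   tibble, and `truth` (planted structure and effect settings).
#' @export
generate_rhizosphere <- function(design) {
  stopifnot(inherits(design, "syn_design"))
  set.seed(design$seed)
  n <- design$n_asv
  ids <- sprintf("asv_%04d", seq_len(n))
  z <- list(
    base = stats::rnorm(n, 0, design$base_log_sd),
    country = matrix(stats::rnorm(n * length(design$countries), 0,
                                  design$country_effect),
                     n, dimnames = list(ids, design$countries)),
    year = stats::rnorm(n), depth = stats::rnorm(n),
    crop = stats::rnorm(n)
  )
  names(z$base) <- names(z$year) <- names(z$depth) <- names(z$crop) <- ids
  # preferential recruits are planted with exactly equal expected
  # rhizosphere abundance in both crops
  z$crop[unlist(design$planted$preferential)] <- 0

  core_all <- match(c(design$planted$core_shared,
                      unlist(design$planted$core)), ids)
  grid <- expand.grid(crop = design$crops, country = design$countries,
                      year = design$years, depth = design$depths,
                      stringsAsFactors = FALSE)
  mc <- design$missing_cells
  drop <- interaction(grid$country, grid$year, grid$depth) %in%
    interaction(mc$country, mc$year, mc$depth)
  grid <- grid[!drop, , drop = FALSE]

  rows <- list(); meta <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- cell_weights(design, z, g$crop, g$country, g$year, g$depth)
    for (r in seq_len(design$replicates[[g$country]])) {
      # plot-level heterogeneity, then fine-grained Dirichlet noise;
      # core taxa, the consistent community fraction, fluctuate with
      # strongly damped plot noise
      zs <- stats::rnorm(n, 0, design$sample_log_sd)
      zs[core_all] <- 0.3 * zs[core_all]
      ps <- p * exp(zs)
      ps <- ps / sum(ps)
      q <- stats::rgamma(n, shape = design$dirichlet_theta * ps)
      q <- q / sum(q)
      sid <- sprintf("R_%s_%s_%d_%s_p%d",
                     substr(g$crop, 1, 1), g$country, g$year,
                     gsub("-", "t", g$depth), r)
      rows[[sid]] <- as.integer(stats::rmultinom(1, design$depth_reads, q))
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, crop = g$crop, country = g$country,
        year = g$year, depth = g$depth, compartment = "rhizosphere",
        pair_id = sid)
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- ids
  sequences <- stats::setNames(paste0("GTGCC", rand_dna(n, 245)), ids)
  tbl <- asv_table(counts, sequences = sequences)
  truth <- c(design$planted, list(
    year_effect = design$year_effect,
    seed_origin_fraction = design$seed_origin_fraction,
    seed = design$seed))
  list(table = tbl, metadata = dplyr::bind_rows(meta), truth = truth)
}

#' Generate paired endosphere libraries
#'
#' For every surface-layer rhizosphere library, `endo_k` endosphere
#' libraries are drawn by re-weighting the rhizosphere composition with
#' the crop's recruitment weights (planted preferential ASVs carry a
#' `preferential_weight`-fold weight in their favoured crop), mixing in
#' a per-crop `seed_origin_fraction` of seed-borne ASVs absent from the
#' rhizosphere, then multinomial sampling at `endo_depth`. `pair_id`
#' links each endosphere library to its source.
#'
#' @param design A `syn_design`.
#' @param rhizo Rhizosphere `asv_tbl` from [generate_rhizosphere()].
#' @param metadata Its metadata.
#' @return A list: `table` (`asv_tbl`, columns = rhizosphere ASVs plus
#'   seed ASVs), `metadata` tibble.
#' @export
generate_endosphere <- function(design, rhizo, metadata) {
  stopifnot(inherits(design, "syn_design"), design$endo_k >= 1)
  set.seed(design$seed + 1L)
  m <- asv_matrix(rhizo)
  seed_ids <- sprintf("seed_%03d", seq_len(design$n_seed_asv))
  seed_w <- exp(stats::rnorm(design$n_seed_asv, 0, 1))
  seed_p <- seed_w / sum(seed_w)
  surface <- metadata$sample_id[metadata$depth == design$depths[1] &
                                  metadata$compartment == "rhizosphere"]
  all_ids <- c(colnames(m), seed_ids)
  rows <- list(); meta <- list()
  for (sid in surface) {
    md <- metadata[metadata$sample_id == sid, ]
    w <- m[sid, ]
    pref <- design$planted$preferential[[md$crop]]
    w[pref] <- w[pref] * design$preferential_weight
    p_rh <- w / sum(w)
    f <- design$seed_origin_fraction[[md$crop]]
    p <- c((1 - f) * p_rh, f * seed_p)
    for (k in seq_len(design$endo_k)) {
      eid <- sprintf("E_%s_e%d", sid, k)
      rows[[eid]] <- as.integer(stats::rmultinom(1, design$endo_depth, p))
      meta[[eid]] <- tibble::tibble(
        sample_id = eid, crop = md$crop, country = md$country,
        year = md$year, depth = md$depth, compartment = "endosphere",
        pair_id = sid)
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- all_ids
  seqs <- c(asv_sequences(rhizo),
            stats::setNames(paste0("GTGCC", rand_dna(design$n_seed_asv, 245)),
                            seed_ids))
  list(table = asv_table(counts, sequences = seqs),
       metadata = dplyr::bind_rows(meta))
}

#' Generate a synthetic indicator database
#'
#' The database holds the trimmed (5'-less-5-nt) sequences of the
#' design's planted category ASVs, each annotated with its category and
#' a random indicator value, plus decoy sequences that occur nowhere in
#' the table — so the expected match rate is exactly the planted
#' fraction.
#'
#' @param design A `syn_design`.
#' @param table An `asv_tbl` with representative sequences.
#' @return An indicator-database tibble (`sequence`, `category`,
#'   `indicator_value`).
#' @export
generate_indicator_db <- function(design, table) {
  sq <- asv_sequences(table)
  if (is.null(sq)) stop("table lacks representative sequences")
  set.seed(design$seed + 2L)
  cats <- design$planted$db_categories
  planted <- dplyr::bind_rows(lapply(names(cats), function(cat) {
    tibble::tibble(sequence = unname(trim_prefix(sq[cats[[cat]]])),
                   category = cat)
  }))
  decoys <- tibble::tibble(
    sequence = rand_dna(design$n_decoy, 245),
    category = sample(names(cats), design$n_decoy, replace = TRUE))
  db <- dplyr::bind_rows(planted, decoys)
  db$indicator_value <- stats::runif(nrow(db), 0.35, 1)
  validate_indicator_db(db)
}
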
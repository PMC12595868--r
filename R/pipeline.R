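#' Run the full rhizomicrobiome analysis pipeline
#'
#' Orchestrates filter -> normalize -> alpha/beta diversity -> PERMANOVA
#' -> mu_D stability -> delta-RA -> core membership -> indicator
#' analysis -> recruitment -> environment-wide association on files
#' named in a YAML configuration, writing tidy TSV outputs plus a JSON
#' run manifest (package version, seed, thresholds, input checksums)
#' that suffices to reproduce the run. Stages whose inputs are not
#' configured are skipped; a failing stage aborts with a stage-named
#' error.
#'
#' @param config Path to a YAML file or an equivalent nested list. Keys:
#'   `input` (`counts`, `metadata`, optional `sequences`,
#'   `endo_counts`, `endo_metadata`, `indicator_db`, `endophyte_set`),
#'   `filters` (`min_samples`, `min_fraction_of_total`), `permanova`
#'   (`factors`, `n_perm`), `indval` (`factor`, `n_perm`, `alpha`,
#'   `min_stat`), `core` (`min_total_ra`, `min_occupancy`), `stability`
#'   (`group_by`), `seed`, `outdir`.
#' @param outdir Output directory (overrides the config).
#' @param seed Integer seed (overrides the config).
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  outdir <- outdir %||% cfg$outdir %||% stop("no output directory configured")
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  tsv <- function(df, name) {
    df <- df[!vapply(df, is.list, logical(1))]
    utils::write.table(as.data.frame(df), file.path(outdir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  inp <- cfg$input
  if (is.null(inp$counts) || is.null(inp$metadata)) {
    stop("config must name input counts and metadata paths")
  }
  for (p in unlist(inp)) {
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  }

  tbl <- stage("read", {
    x <- read_asv_table(inp$counts)
    if (!is.null(inp$sequences)) {
      attr(x, "sequences") <- read_asv_sequences(inp$sequences)
    }
    x
  })
  md <- stage("read", read_sample_metadata(inp$metadata))
  flt <- cfg$filters %||% list()
  tbl <- stage("filter", {
    x <- filter_sparsity(tbl, flt$min_samples %||% 3)
    filter_low_abundance(x, flt$min_fraction_of_total %||% 0)
  })
  cpt <- stage("normalize", normalize_cpt(tbl))

  stage("alpha", tsv(alpha_diversity(tbl), "alpha_diversity.tsv"))
  d <- stage("beta", bray_curtis(cpt))
  utils::write.table(as.matrix(d), file.path(outdir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  pmv <- cfg$permanova %||% list()
  factors <- pmv$factors %||% c("year", "country", "crop", "depth")
  perm <- stage("permanova",
                permanova(d, md, factors, n_perm = pmv$n_perm %||% 999,
                          seed = seed))
  tsv(perm, "permanova.tsv")

  stb <- cfg$stability %||% list()
  mu <- stage("stability", group_mean_dissimilarity(
    d, md, stb$group_by %||% c("crop", "year")))
  tsv(mu[setdiff(names(mu), "values")], "mu_d_cells.tsv")
  tsv(stage("stability", compare_mu_d(mu)), "mu_d_tests.tsv")
  crops <- sort(unique(md$crop[md$compartment == "rhizosphere"]))
  for (cr in crops) {
    dra <- stage("stability", delta_ra_stability(cpt, md, cr))
    tsv(dra$per_asv, paste0("delta_ra_", cr, ".tsv"))
  }

  core_cfg <- cfg$core %||% list()
  cores <- lapply(crops, function(cr) stage("core", core_set(
    tbl, md, cr, min_total_ra = core_cfg$min_total_ra %||% 0.001,
    min_occupancy = core_cfg$min_occupancy %||% 0.90)))
  names(cores) <- crops
  for (cr in crops) tsv(cores[[cr]], paste0("core_", cr, ".tsv"))
  if (length(crops) == 2) {
    ov <- core_overlap(cores[[1]], cores[[2]])
    tsv(ov$counts, "core_overlap.tsv")
  }

  iv_cfg <- cfg$indval %||% list()
  iv <- stage("indval", indval(cpt, md, iv_cfg$factor %||% "crop",
                               n_perm = iv_cfg$n_perm %||% 10000,
                               seed = seed))
  tsv(iv, "indval.tsv")
  tsv(filter_indicators(iv, iv_cfg$alpha %||% 0.05,
                        iv_cfg$min_stat %||% 0.35), "indicators.tsv")

  if (!is.null(inp$endo_counts)) {
    emd_path <- inp$endo_metadata %||% inp$metadata
    emd <- read_sample_metadata(emd_path)
    endo <- stage("recruitment", read_asv_table(inp$endo_counts))
    rec <- stage("recruitment", pair_overlap(tbl, endo, emd))
    tsv(rec[setdiff(names(rec), "shared")], "recruitment.tsv")
    tsv(recruitment_means(rec), "recruitment_means.tsv")
    cu <- crop_union_overlap(rec)
    tsv(cu[setdiff(names(cu), "asv_ids")], "recruitment_union.tsv")
  }

  if (!is.null(inp$indicator_db) && !is.null(asv_sequences(cpt))) {
    db <- stage("ewas", read_indicator_db(inp$indicator_db))
    matches <- stage("ewas", match_to_db(trim_prefix(asv_sequences(cpt)), db))
    ew <- stage("ewas", category_aggregate_contrast(cpt, md, matches))
    tsv(ew$summary, "ewas.tsv")
    tsv(ew$per_sample, "ewas_per_sample.tsv")
  }

  manifest <- list(
    package = "perenniome",
    version = as.character(utils::packageVersion("perenniome")),
    r_version = R.version.string,
    seed = seed,
    config = cfg[setdiff(names(cfg), "outdir")],
    input_md5 = as.list(tools::md5sum(unlist(inp))),
    provenance = attr(cpt, "provenance")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Recompute the headline study statistics from a deposited dataset
#'
#' Convenience wrapper for re-analysing a deposited rhizosphere dataset
#' laid out as `counts.tsv` (samples x ASVs) and `metadata.tsv` in one
#' directory: applies the standard filters, then recomputes the
#' PERMANOVA variance partition, the per-crop core sets and their
#' overlap, and the between-year mu_D per crop.
#'
#' @param data_dir Directory holding `counts.tsv` and `metadata.tsv`.
#' @param min_samples,min_fraction_of_total Filter settings.
#' @param seed Permutation seed.
#' @return A list: `permanova`, `core_counts`, `core_shared`,
#'   `mu_d_between_year` (named per crop).
#' @export
reproduce_study <- function(data_dir, min_samples = 3,
                            min_fraction_of_total = 0, seed = 1L) {
  counts <- file.path(data_dir, "counts.tsv")
  metadata <- file.path(data_dir, "metadata.tsv")
  if (!file.exists(counts) || !file.exists(metadata)) {
    stop("deposited dataset not found under ", data_dir,
         " (expected counts.tsv and metadata.tsv)")
  }
  tbl <- read_asv_table(counts)
  md <- read_sample_metadata(metadata)
  tbl <- filter_low_abundance(filter_sparsity(tbl, min_samples),
                              min_fraction_of_total)
  cpt <- normalize_cpt(tbl)
  d <- bray_curtis(cpt)
  crops <- sort(unique(md$crop))
  cores <- lapply(crops, function(cr) core_set(tbl, md, cr))
  names(cores) <- crops
  mu <- group_mean_dissimilarity(d, md, c("crop", "year"))
  yrs <- sort(unique(md$year))
  mu_by <- vapply(crops, function(cr) {
    mu$mu_d[mu$cell == sprintf("between:%s.%d|%s.%d", cr, yrs[1], cr, yrs[2])]
  }, numeric(1))
  list(
    permanova = permanova(d, md, c("year", "country", "crop", "depth"),
                          seed = seed),
    core_counts = vapply(cores, function(cs) length(core_members(cs)),
                         integer(1)),
    core_shared = if (length(crops) == 2) {
      length(core_overlap(cores[[1]], cores[[2]])$shared)
    } else NA_integer_,
    mu_d_between_year = mu_by)
}

#' Write a synthetic fixture directory
#'
#' Materialises a [synthetic_design()] as the exact plain-text formats
#' the readers consume — rhizosphere and endosphere count TSVs, a
#' combined metadata TSV, FASTA sequences, the indicator-database TSV —
#' plus a `truth.json` recording all planted structure.
#'
#' @param design A `syn_design`.
#' @param outdir Output directory.
#' @return The output directory, invisibly; attribute `paths` lists the
#'   files written.
#' @export
simulate_fixture <- function(design, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rz <- generate_rhizosphere(design)
  en <- generate_endosphere(design, rz$table, rz$metadata)
  db <- generate_indicator_db(design, rz$table)
  paths <- c(
    counts = file.path(outdir, "rhizosphere_counts.tsv"),
    endo_counts = file.path(outdir, "endosphere_counts.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    sequences = file.path(outdir, "sequences.fasta"),
    indicator_db = file.path(outdir, "indicator_db.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_asv_table(rz$table, paths["counts"])
  write_asv_table(en$table, paths["endo_counts"])
  md <- dplyr::bind_rows(rz$metadata, en$metadata)
  utils::write.table(as.data.frame(md), paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_asv_sequences(c(asv_sequences(en$table)), paths["sequences"])
  utils::write.table(as.data.frame(db), paths["indicator_db"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rz$truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  structure(invisible(outdir), paths = paths)
}
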
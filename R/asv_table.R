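#' Construct an ASV table
#'
#' An ASV table is a tibble with one row per sample: a `sample_id` column
#' followed by one numeric column per amplicon sequence variant (ASV).
#' Representative sequences, when available, travel with the table as a
#' named character attribute so that downstream sequence matching (see
#' [match_to_db()]) needs no side file.
#'
#' @param counts A numeric matrix (samples x ASVs) with row and column
#'   names, or a data frame whose first column is `sample_id`.
#' @param sequences Optional named character vector of representative
#'   sequences; names must be a subset of the ASV identifiers.
#' @param normalized Logical; `TRUE` marks a counts-per-thousand table
#'   produced by [normalize_cpt()].
#'
#' @return A tibble of class `asv_tbl` (and `cpt_tbl` when normalized).
#' @export
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' asv_table(m)
asv_table <- function(counts, sequences = NULL, normalized = FALSE) {
  if (is.data.frame(counts)) {
    stopifnot("sample_id" %in% names(counts))
    if (anyDuplicated(names(counts))) {
      dup <- names(counts)[duplicated(names(counts))]
      stop("duplicate ASV id(s): ", paste(unique(dup), collapse = ", "))
    }
    ids <- as.character(counts[["sample_id"]])
    m <- as.matrix(counts[, -match("sample_id", names(counts)), drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    counts <- m
  }
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("`counts` must carry sample ids as rownames and ASV ids as colnames")
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))]
    stop("duplicate ASV id(s): ", paste(unique(dup), collapse = ", "))
  }
  out <- tibble::as_tibble(as.data.frame(counts, check.names = FALSE),
                           .name_repair = "minimal")
  out <- tibble::add_column(out, sample_id = rownames(counts), .before = 1)
  class(out) <- c(if (normalized) "cpt_tbl", "asv_tbl", class(tibble::tibble()))
  attr(out, "sequences") <- sequences
  attr(out, "normalized") <- normalized
  validate_asv_table(out)
}

#' Validate an ASV table
#'
#' Checks the structural invariants: unique sample and ASV identifiers,
#' finite non-negative abundances, and sequence names (if any) being a
#' subset of the ASV identifiers.
#'
#' @param x An `asv_tbl`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_asv_table <- function(x) {
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  ids <- x$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  aids <- names(x)[names(x) != "sample_id"]
  if (anyDuplicated(aids)) {
    stop("duplicate ASV id(s): ",
         paste(unique(aids[duplicated(aids)]), collapse = ", "))
  }
  m <- asv_matrix(x)
  if (any(!is.finite(m))) stop("non-finite abundance values present")
  if (any(m < 0)) stop("negative abundance values present")
  sq <- attr(x, "sequences")
  if (!is.null(sq)) {
    extra <- setdiff(names(sq), aids)
    if (length(extra)) {
      stop("sequences supplied for unknown ASV id(s): ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  x
}

#' Extract the abundance matrix from an ASV table
#'
#' @param x An `asv_tbl`.
#' @return Numeric matrix, samples in rows (named), ASVs in columns.
#' @export
asv_matrix <- function(x) {
  aids <- setdiff(names(x), "sample_id")
  m <- as.matrix(x[aids])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

#' @rdname asv_matrix
#' @export
asv_ids <- function(x) setdiff(names(x), "sample_id")

#' @rdname asv_matrix
#' @export
sample_ids <- function(x) x$sample_id

#' Representative sequences attached to an ASV table
#'
#' @param x An `asv_tbl`.
#' @return Named character vector or `NULL`.
#' @export
asv_sequences <- function(x) attr(x, "sequences")

# rebuild an asv_tbl from a matrix, carrying attributes from a template
rebuild_asv_tbl <- function(m, template) {
  sq <- attr(template, "sequences")
  if (!is.null(sq)) sq <- sq[intersect(names(sq), colnames(m))]
  out <- asv_table(m, sequences = if (length(sq)) sq,
                   normalized = isTRUE(attr(template, "normalized")))
  attr(out, "provenance") <- attr(template, "provenance")
  out
}

record_provenance <- function(x, step, ...) {
  prov <- attr(x, "provenance") %||% list()
  attr(x, "provenance") <- c(prov, list(c(list(step = step), list(...))))
  x
}

#' Read an ASV table from disk
#'
#' Two plain-text formats are supported: TSV with samples in rows (first
#' column `sample_id`, remaining columns one ASV each) and BIOM JSON
#' (read through the biomformat package; BIOM stores ASVs in rows and is
#' transposed on read). Row and column order follow the file.
#'
#' @param path Path to the table.
#' @param format `"tsv"` or `"biom"`.
#' @return An `asv_tbl`.
#' @export
read_asv_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (names(df)[1] != "sample_id") {
      stop("first column of an ASV TSV must be `sample_id`, found `",
           names(df)[1], "`")
    }
    num <- df[-1]
    bad <- which(!vapply(num, is.numeric, logical(1)))
    if (length(bad)) {
      stop("non-numeric count cell(s) in column(s): ",
           paste(names(num)[bad], collapse = ", "))
    }
    asv_table(df)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    asv_table(m)
  }
}

#' Write an ASV table to TSV
#'
#' Inverse of [read_asv_table()] for the TSV format; a read-back of the
#' written file reproduces the counts bit-exactly.
#'
#' @param x An `asv_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(x, path) {
  df <- as.data.frame(x)[c("sample_id", asv_ids(x))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

required_metadata_cols <- c("sample_id", "crop", "country", "year", "depth",
                            "compartment", "pair_id")

#' Read and validate a sample metadata sheet
#'
#' The sheet is a TSV with mandatory columns `sample_id, crop, country,
#' year, depth, compartment, pair_id`. `pair_id` links each endosphere
#' library to the rhizosphere library collected at the same spot; for
#' rhizosphere rows it is conventionally the sample's own id.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  missing <- setdiff(required_metadata_cols, names(md))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  md$year <- as.integer(md$year)
  md
}

#' Check that a metadata sheet covers an ASV table
#'
#' Verifies that every sample in `x` has exactly one metadata row and,
#' when endosphere samples are present, that each `pair_id` resolves to
#' exactly one rhizosphere sample.
#'
#' @param x An `asv_tbl`.
#' @param metadata Sample metadata tibble.
#' @return `metadata` restricted to the samples of `x`, in table order.
#' @export
align_metadata <- function(x, metadata) {
  missing <- setdiff(setdiff(required_metadata_cols, "pair_id"), names(metadata))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) stop("duplicate metadata sample_id")
  idx <- match(x$sample_id, metadata$sample_id)
  if (anyNA(idx)) {
    stop("no metadata row for sample(s): ",
         paste(utils::head(x$sample_id[is.na(idx)], 5), collapse = ", "))
  }
  metadata[idx, , drop = FALSE]
}

#' Remove sparse ASVs
#'
#' Drops ASVs detected (count > 0) in fewer than `min_samples` samples.
#' The sample set is unchanged; an all-filtered table (zero ASVs) is
#' returned rather than an error.
#'
#' @param x An `asv_tbl`.
#' @param min_samples Minimum number of samples an ASV must be detected in
#'   to be retained. Default 3 (ASVs seen in fewer than 3 samples drop).
#' @return Filtered `asv_tbl`.
#' @export
filter_sparsity <- function(x, min_samples = 3) {
  stopifnot(min_samples >= 1)
  m <- asv_matrix(x)
  keep <- colSums(m > 0) >= min_samples
  record_provenance(rebuild_asv_tbl(m[, keep, drop = FALSE], x),
                    "filter_sparsity", min_samples = min_samples,
                    removed = sum(!keep))
}

#' Remove low-abundance ASVs
#'
#' Drops ASVs whose summed counts fall below a fraction of the grand
#' total. The threshold is deliberately a parameter with no filtering by
#' default (`min_fraction_of_total = 0`): fractions of order 1e-2 remove
#' essentially every ASV in realistic tables, so the value used for a run
#' is an explicit analysis choice recorded in the table's provenance and
#' the run manifest.
#'
#' @param x An `asv_tbl`.
#' @param min_fraction_of_total Fraction of the grand total an ASV's summed
#'   counts must reach; in `[0, 1)`.
#' @return Filtered `asv_tbl`.
#' @export
filter_low_abundance <- function(x, min_fraction_of_total = 0) {
  stopifnot(min_fraction_of_total >= 0, min_fraction_of_total < 1)
  m <- asv_matrix(x)
  if (ncol(m) == 0 || nrow(m) == 0) stop("empty ASV table")
  keep <- colSums(m) / sum(m) >= min_fraction_of_total
  record_provenance(rebuild_asv_tbl(m[, keep, drop = FALSE], x),
                    "filter_low_abundance",
                    min_fraction_of_total = min_fraction_of_total,
                    removed = sum(!keep))
}

#' Counts-per-thousand normalization
#'
#' Scales every sample to 1000 reads: `value[s, a] = 1000 * count[s, a] /
#' sum(count[s, ])`. Samples with zero total are an error (there is no
#' defined composition to scale).
#'
#' @param x An `asv_tbl` of counts.
#' @return A `cpt_tbl` whose rows each sum to 1000.
#' @export
normalize_cpt <- function(x) {
  m <- asv_matrix(x)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(rownames(m)[rs == 0], collapse = ", "))
  }
  out <- rebuild_asv_tbl(1000 * m / rs, x)
  class(out) <- unique(c("cpt_tbl", class(out)))
  attr(out, "normalized") <- TRUE
  record_provenance(out, "normalize_cpt")
}

#' Read representative sequences from FASTA
#'
#' @param path FASTA file whose record ids are ASV ids.
#' @return Named character vector of uppercase sequences.
#' @export
read_asv_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(s)), names(s))
}

#' Write representative sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_sequences <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
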
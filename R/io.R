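#' Write a simulated atlas to plain-text fixture files
#'
#' Serializes every component of an atlas simulation to the documented
#' TSV/JSON formats so the pipeline stages can be exercised from files:
#' `counts.tsv` (gene_id + one integer column per sample), `samples.tsv`
#' (sample_id, subtype, replicate), `genes.tsv` (gene_id, length_bp,
#' category), and, when present, `isoforms.tsv` (gene_id, isoform_id,
#' length_bp, group), `compat.tsv` (sample_id, read_id, isoform_id) and
#' `truth.json` (planted ground truth). Files round-trip losslessly through
#' the `read_*` readers.
#'
#' @param sim An `"atlas_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_atlas_fixture <- function(sim, dir) {
  if (!inherits(sim, "atlas_sim")) {
    stop_atlas("sim must be an atlas_sim", "validation")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop_atlas(sprintf("cannot write to directory '%s'", dir), "io")
  }
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.tsv")
  )
  readr::write_tsv(sim$counts, paths[["counts"]])
  readr::write_tsv(sim$samples, paths[["samples"]])
  readr::write_tsv(sim$genes, paths[["genes"]])
  if (!is.null(sim$isoforms)) {
    paths[["isoforms"]] <- file.path(dir, "isoforms.tsv")
    paths[["compat"]] <- file.path(dir, "compat.tsv")
    readr::write_tsv(sim$isoforms, paths[["isoforms"]])
    readr::write_tsv(sim$compat, paths[["compat"]])
  }
  if (!is.null(sim$truth)) {
    paths[["truth"]] <- file.path(dir, "truth.json")
    jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA)
  }
  invisible(paths)
}

#' Read atlas input files
#'
#' Readers for the plain-text formats written by [write_atlas_fixture()]
#' (or produced by an external counting pipeline). Each validates its
#' schema and returns a tibble.
#'
#' @param path Path to the file.
#' @return A tibble with the documented columns.
#' @name atlas_readers
NULL

#' @rdname atlas_readers
#' @export
read_counts <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tbl)[1] != "gene_id") {
    stop_atlas("counts file must start with a gene_id column", "data")
  }
  tbl <- dplyr::mutate(tbl, dplyr::across(-"gene_id", as.integer))
  check_counts(tbl)
  tbl
}

#' @rdname atlas_readers
#' @export
read_samples <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), subtype = readr::col_character(),
    replicate = readr::col_integer()
  ))
  if (anyDuplicated(tbl$sample_id)) {
    stop_atlas("duplicate sample_id in sample sheet", "data")
  }
  tbl
}

#' @rdname atlas_readers
#' @export
read_genes <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), length_bp = readr::col_integer(),
    category = readr::col_character()
  ))
  if (anyDuplicated(tbl$gene_id)) stop_atlas("duplicate gene_id", "data")
  if (any(tbl$length_bp <= 0)) {
    stop_atlas("gene lengths must be positive", "data")
  }
  tbl
}

#' @rdname atlas_readers
#' @export
read_isoforms <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), isoform_id = readr::col_character(),
    length_bp = readr::col_integer(), group = readr::col_character()
  ))
  if (anyDuplicated(tbl$isoform_id)) stop_atlas("duplicate isoform_id", "data")
  if (any(tbl$length_bp <= 0)) {
    stop_atlas("isoform lengths must be positive", "data")
  }
  tbl
}

#' @rdname atlas_readers
#' @export
read_compat <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), read_id = readr::col_character(),
    isoform_id = readr::col_character()
  ))
}
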
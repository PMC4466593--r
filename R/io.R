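# Plain-text interchange: UTF-8 TSV with '#'-prefixed metadata headers that
# readers skip. Every writer can stamp the config fingerprint and seed so an
# artifact is traceable to the run that produced it.

metadata_header <- function(meta = NULL) {
  base <- c(sprintf("# mirlink %s", as.character(utils::packageVersion("mirlink"))))
  if (!is.null(meta)) {
    base <- c(base, sprintf("# %s: %s", names(meta), vapply(meta, as.character, character(1))))
  }
  base
}

write_tsv_meta <- function(x, path, meta = NULL) {
  readr::write_lines(metadata_header(meta), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read and write expression tables
#'
#' Layout: first column feature id, remaining columns one per sample;
#' tab-separated; `#` metadata lines ignored on read. Ragged rows and
#' duplicate feature ids are schema errors.
#'
#' @param path File path.
#' @param scale Intensity scale flag recorded on the returned table.
#' @param design Optional design tibble; if given, every sample column must
#'   be declared in it.
#' @return `read_expression()` returns an expression tibble;
#'   writers return `path` invisibly.
#' @export
read_expression <- function(path, scale = c("log2", "linear"), design = NULL) {
  scale <- match.arg(scale)
  out <- read_tsv_plain(path)
  if (ncol(out) < 2L) {
    stop_mirlink("Expression TSV needs an id column plus >= 1 sample column.",
                 "mirlink_schema_error")
  }
  out <- as_expression(out, scale)
  if (!is.null(design)) check_design(design, out)
  out
}

#' @rdname read_expression
#' @param m Expression tibble.
#' @param meta Named list written into the `#` metadata header.
#' @param linear Write `2^x` linear-scale intensities instead of log2 (only
#'   meaningful for a log2-flagged table).
#' @export
write_expression <- function(m, path, meta = NULL, linear = FALSE) {
  m <- as_expression(m, expr_scale(m))
  if (linear) {
    x <- expr_matrix(m)
    m <- as_expression(matrix_to_expr(2^x, names(m)[1L]), "linear")
  }
  write_tsv_meta(m, path, c(meta, list(scale = expr_scale(m))))
}

#' Read and write the sample design
#'
#' Two columns: `sample_id`, `group` (`young`/`adult`).
#' @param path File path.
#' @export
read_design <- function(path) {
  check_design(read_tsv_plain(path, readr::cols(sample_id = "c", group = "c")))
}

#' @rdname read_design
#' @param design Design tibble.
#' @param meta Named list for the metadata header.
#' @export
write_design <- function(design, path, meta = NULL) {
  write_tsv_meta(check_design(design), path, meta)
}

#' Read and write interaction tables
#'
#' Columns: `mirna`, `gene`, one 0/1 column per source, `support`.
#' Duplicate pairs are OR-merged on read; a `support` value inconsistent
#' with its own row's flags is a schema error.
#' @param path File path.
#' @param source_names Declared source columns (default: all columns other
#'   than `mirna`, `gene`, `support`).
#' @export
read_interactions <- function(path, source_names = NULL) {
  as_interactions(read_tsv_plain(path), source_names = source_names)
}

#' @rdname read_interactions
#' @param t `interaction_tbl`.
#' @param meta Named list for the metadata header.
#' @export
write_interactions <- function(t, path, meta = NULL) {
  write_tsv_meta(t, path, meta)
}

#' Read and write plain id lists (one id per line)
#'
#' @param path File path.
#' @export
read_id_list <- function(path) {
  lines <- readr::read_lines(path)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' @rdname read_id_list
#' @param ids Character vector.
#' @param meta Named list for the metadata header.
#' @export
write_id_list <- function(ids, path, meta = NULL) {
  readr::write_lines(c(metadata_header(meta), as.character(ids)), path)
  invisible(path)
}

#' Write an enrichment result table
#'
#' @param res An `enrich_result`.
#' @param path File path.
#' @param meta Named list for the metadata header.
#' @export
write_enrichment <- function(res, path, meta = NULL) {
  meta <- c(meta, list(alpha = attr(res, "alpha") %||% NA,
                       family_size = attr(res, "family_size") %||% nrow(res),
                       query_size = attr(res, "query_size") %||% NA))
  write_tsv_meta(as_tibble(res), path, meta)
}

#' Write the whole simulation bundle as plain-text fixture files
#'
#' Writes the gene and miRNA expression TSVs, the design, the interaction
#' table, the pathway GMT, the gene universe list and the ground-truth
#' table into a directory. Everything round-trips losslessly through the
#' package readers (see [read_fixture()]).
#'
#' @param bundle A `mirlink_sim` from [simulate_dataset()].
#' @param out_dir Output directory, created if needed.
#' @param linear Write expression on the linear scale (`2^x`) instead of
#'   log2, to exercise the pipeline's log2 step.
#' @return Named character vector of the seven file paths.
#' @export
write_fixture <- function(bundle, out_dir, linear = FALSE) {
  stopifnot(inherits(bundle, "mirlink_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_mirlink(sprintf("Cannot create output directory '%s'.", out_dir),
                 "mirlink_io_error")
  }
  meta <- list(seed = bundle$params$seed)
  f <- function(name) file.path(out_dir, name)
  truth_tbl <- dplyr::bind_rows(
    tibble(id = bundle$truth$de_mirnas$mirna, role = "de_mirna",
           direction = bundle$truth$de_mirnas$direction,
           shift = bundle$truth$de_mirnas$shift),
    tibble(id = bundle$truth$de_genes_expected$gene, role = "de_gene_expected",
           direction = bundle$truth$de_genes_expected$direction,
           shift = bundle$truth$de_genes_expected$shift),
    tibble(id = paste(bundle$truth$regulons$mirna, bundle$truth$regulons$gene, sep = ":"),
           role = "true_interaction", direction = NA_character_, shift = NA_real_)
  )
  paths <- c(
    genes = write_expression(bundle$genes, f("genes.tsv"), meta, linear = linear),
    mirnas = write_expression(bundle$mirnas, f("mirnas.tsv"), meta, linear = linear),
    design = write_design(bundle$design, f("design.tsv"), meta),
    interactions = write_interactions(bundle$interactions, f("interactions.tsv"), meta),
    gene_sets = write_gmt(bundle$gene_sets, f("pathways.gmt")),
    universe = write_id_list(bundle$universe, f("universe.txt"), meta),
    truth = write_tsv_meta(truth_tbl, f("truth.tsv"), meta)
  )
  paths
}

#' Re-read a fixture directory written by [write_fixture()]
#'
#' @param dir Directory containing the fixture files.
#' @param linear Were the expression tables written on the linear scale?
#' @return A list with elements `genes`, `mirnas`, `design`,
#'   `interactions`, `gene_sets`, `universe` and `truth` (the flat
#'   ground-truth tibble).
#' @export
read_fixture <- function(dir, linear = FALSE) {
  f <- function(name) file.path(dir, name)
  scale <- if (linear) "linear" else "log2"
  design <- read_design(f("design.tsv"))
  list(
    genes = read_expression(f("genes.tsv"), scale, design),
    mirnas = read_expression(f("mirnas.tsv"), scale, design),
    design = design,
    interactions = read_interactions(f("interactions.tsv")),
    gene_sets = read_gmt(f("pathways.gmt")),
    universe = read_id_list(f("universe.txt")),
    truth = read_tsv_plain(f("truth.tsv"))
  )
}
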
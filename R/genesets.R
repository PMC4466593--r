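#' Gene-set collections
#'
#' A collection is a tibble with one row per set: `set_name`, `description`
#' and a `genes` list-column of character vectors. Set members need not all
#' lie in the analysis universe; enrichment trims them at test time and
#' reports how much was trimmed.
#'
#' @param x A data frame with columns `set_name`, `description`, `genes`.
#' @return A tibble of class `"gene_sets"`.
#' @export
#' @examples
#' gs <- as_gene_sets(tibble::tibble(set_name = "s1", description = "toy",
#'                                   genes = list(c("g1", "g2"))))
as_gene_sets <- function(x) {
  if (!is.data.frame(x) || !all(c("set_name", "genes") %in% names(x))) {
    stop_mirlink("Gene sets need `set_name` and `genes` columns.", "mirlink_schema_error")
  }
  x <- as_tibble(x)
  if (!"description" %in% names(x)) x$description <- ""
  if (anyDuplicated(x$set_name)) {
    stop_mirlink("Gene set names must be unique.", "mirlink_schema_error")
  }
  if (!is.list(x$genes)) x$genes <- as.list(x$genes)
  x$genes <- lapply(x$genes, function(g) unique(as.character(g)))
  if (nrow(x) && any(lengths(x$genes) == 0L)) {
    stop_mirlink("Every gene set must contain >= 1 gene.", "mirlink_schema_error")
  }
  new_gene_sets(x[, c("set_name", "description", "genes")])
}

new_gene_sets <- function(x) {
  structure(as_tibble(x), class = c("gene_sets", class(tibble())))
}

#' Read and write gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`, at least three fields per
#' line. Lines starting with `#` are ignored on read.
#'
#' @param path File path.
#' @return `read_gmt()` returns a `gene_sets` tibble; `write_gmt()` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop_mirlink(
      sprintf("GMT line %d has fewer than 3 fields (name, description, >= 1 gene).",
              short[1L]),
      "mirlink_schema_error"
    )
  }
  as_gene_sets(tibble(
    set_name = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) f[-(1:2)])
  ))
}

#' @rdname read_gmt
#' @param sets A `gene_sets` tibble.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets") || is.data.frame(sets))
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sets$genes[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
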
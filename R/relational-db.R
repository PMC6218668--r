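#' Seven-table relational disease database
#'
#' `relational_db()` bundles the seven tables of the compiled disease
#' database -- four entity tables (diseases, genes, phenotypes, proteins)
#' and three link tables (disease--gene associations, phenotype occurrence
#' in diseases, gene--protein relations) -- after validating referential
#' integrity.  All downstream networks are projections of this object.
#'
#' Entity identifiers are namespaced by vocabulary (`"OMIM:..."` /
#' `"DOID:..."` for diseases, `"HP:..."` for phenotypes, gene symbols,
#' protein accessions), so node identifiers can never collide across kinds.
#'
#' Duplicate link rows are dropped silently (the derived graphs are simple).
#' Link rows whose foreign key does not resolve to an entity row are an
#' error under `strict = TRUE`; otherwise they are dropped with a warning
#' giving the number of rows removed per table.
#'
#' @param diseases data frame with columns `disease_id`, `name`, `abbrev`.
#' @param genes data frame with columns `gene_id`, `symbol`, `location`.
#' @param phenotypes data frame with columns `phenotype_id`, `name`.
#' @param proteins data frame with columns `protein_id`, `name`.
#' @param disease_gene link table with columns `disease_id`, `gene_id`.
#' @param phenotype_occurrence link table with columns `disease_id`,
#'   `phenotype_id`.
#' @param related_proteins link table with columns `gene_id`, `protein_id`.
#' @param strict error (rather than drop with a warning) on unresolvable
#'   foreign keys.
#' @return An object of class `relational_db`: a named list of seven
#'   tibbles.
#' @seealso [read_relational_db()], [build_network()],
#'   [phenotype_occurrence_table()]
#' @export
relational_db <- function(diseases, genes, phenotypes, proteins,
                          disease_gene, phenotype_occurrence,
                          related_proteins, strict = TRUE) {
  tabs <- list(
    diseases = diseases, genes = genes, phenotypes = phenotypes,
    proteins = proteins, disease_gene = disease_gene,
    phenotype_occurrence = phenotype_occurrence,
    related_proteins = related_proteins
  )
  for (nm in names(tabs)) {
    missing <- setdiff(db_schema[[nm]], names(tabs[[nm]]))
    if (length(missing)) {
      abort(sprintf("table '%s' is missing required column(s): %s",
                    nm, paste(missing, collapse = ", ")),
            class = "retinet_schema_error")
    }
    tabs[[nm]] <- as_tibble(tabs[[nm]])
  }

  key_of <- c(diseases = "disease_id", genes = "gene_id",
              phenotypes = "phenotype_id", proteins = "protein_id")
  for (nm in names(key_of)) {
    ids <- tabs[[nm]][[key_of[[nm]]]]
    if (any(is.na(ids) | ids == "")) {
      abort(sprintf("table '%s' contains empty %s values", nm, key_of[[nm]]),
            class = "retinet_schema_error")
    }
    if (anyDuplicated(ids)) {
      abort(sprintf("table '%s' contains duplicated %s values", nm, key_of[[nm]]),
            class = "retinet_schema_error")
    }
  }

  fk <- list(
    disease_gene = list(disease_id = "diseases", gene_id = "genes"),
    phenotype_occurrence = list(disease_id = "diseases", phenotype_id = "phenotypes"),
    related_proteins = list(gene_id = "genes", protein_id = "proteins")
  )
  for (nm in names(fk)) {
    tab <- distinct(tabs[[nm]])
    ok <- rep(TRUE, nrow(tab))
    for (col in names(fk[[nm]])) {
      parent <- fk[[nm]][[col]]
      ok <- ok & tab[[col]] %in% tabs[[parent]][[key_of[[parent]]]]
    }
    if (any(!ok)) {
      if (strict) {
        abort(sprintf("table '%s' has %d row(s) with unresolvable foreign keys",
                      nm, sum(!ok)),
              class = "retinet_integrity_error")
      }
      warn(sprintf("dropped %d row(s) of '%s' with unresolvable foreign keys",
                   sum(!ok), nm))
      tab <- tab[ok, , drop = FALSE]
    }
    tabs[[nm]] <- tab
  }

  structure(tabs, class = "relational_db")
}

db_schema <- list(
  diseases = c("disease_id", "name", "abbrev"),
  genes = c("gene_id", "symbol", "location"),
  phenotypes = c("phenotype_id", "name"),
  proteins = c("protein_id", "name"),
  disease_gene = c("disease_id", "gene_id"),
  phenotype_occurrence = c("disease_id", "phenotype_id"),
  related_proteins = c("gene_id", "protein_id")
)

#' @export
print.relational_db <- function(x, ...) {
  cat("<relational_db>\n")
  cat(sprintf("  %d diseases, %d genes, %d phenotypes, %d proteins\n",
              nrow(x$diseases), nrow(x$genes), nrow(x$phenotypes),
              nrow(x$proteins)))
  cat(sprintf("  links: %d disease-gene, %d phenotype occurrence, %d gene-protein\n",
              nrow(x$disease_gene), nrow(x$phenotype_occurrence),
              nrow(x$related_proteins)))
  invisible(x)
}

#' Read the seven database tables from delimited text files
#'
#' @param source either a directory containing files named
#'   `diseases.csv`, `genes.csv`, `phenotypes.csv`, `proteins.csv`,
#'   `disease_gene.csv`, `phenotype_occurrence.csv`,
#'   `related_proteins.csv`, or a named character vector of paths with
#'   those seven names.
#' @param delim field delimiter.
#' @param decimal_mark decimal mark of the dialect (`"."` default; `","`
#'   accepted for tables exported with comma decimals).
#' @param strict passed on to [relational_db()].
#' @return A validated [relational_db()] object.
#' @export
read_relational_db <- function(source, delim = ",", decimal_mark = ".",
                               strict = FALSE) {
  if (length(source) == 1L && is.null(names(source))) {
    if (!dir.exists(source)) {
      abort(sprintf("directory '%s' does not exist", source))
    }
    source <- setNames(file.path(source, paste0(names(db_schema), ".csv")),
                       names(db_schema))
  }
  missing <- setdiff(names(db_schema), names(source))
  if (length(missing)) {
    abort(paste0("no path given for table(s): ", paste(missing, collapse = ", ")))
  }
  loc <- readr::locale(decimal_mark = decimal_mark,
                       grouping_mark = if (decimal_mark == ",") "." else ",")
  tabs <- lapply(source[names(db_schema)], function(p) {
    if (!file.exists(p)) abort(sprintf("file '%s' does not exist", p))
    readr::read_delim(p, delim = delim, locale = loc,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
  })
  relational_db(tabs$diseases, tabs$genes, tabs$phenotypes, tabs$proteins,
                tabs$disease_gene, tabs$phenotype_occurrence,
                tabs$related_proteins, strict = strict)
}

#' Write the seven database tables as delimited text files
#'
#' @param db a [relational_db()].
#' @param dir output directory (created if absent); one `<table>.csv` per
#'   table.
#' @param delim field delimiter.
#' @return Invisibly, the paths written.
#' @export
write_relational_db <- function(db, dir, delim = ",") {
  stopifnot(inherits(db, "relational_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(names(db_schema), ".csv")),
                    names(db_schema))
  for (nm in names(db_schema)) {
    readr::write_delim(db[[nm]], paths[[nm]], delim = delim)
  }
  invisible(paths)
}

#' Rank phenotypes by the number of diseases they occur in
#'
#' Counts, for every phenotype, the number of distinct diseases annotated
#' with it, reproducing the "most common phenotypes occurring in diseases"
#' table of a compiled database.
#'
#' @param db a [relational_db()].
#' @param n optionally keep only the top `n` rows.
#' @return A tibble with columns `phenotype_id`, `name`, `occurrences`,
#'   sorted by `occurrences` descending with ties broken by `phenotype_id`
#'   ascending.
#' @export
phenotype_occurrence_table <- function(db, n = NULL) {
  stopifnot(inherits(db, "relational_db"))
  out <- db$phenotype_occurrence |>
    distinct(.data$disease_id, .data$phenotype_id) |>
    count(.data$phenotype_id, name = "occurrences") |>
    left_join(select(db$phenotypes, "phenotype_id", "name"),
              by = "phenotype_id") |>
    select("phenotype_id", "name", "occurrences") |>
    arrange(desc(.data$occurrences), .data$phenotype_id)
  if (!is.null(n)) out <- slice_head(out, n = n)
  out
}
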
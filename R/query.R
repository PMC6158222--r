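#' In-memory data source
#'
#' The package's single built-in data-source backend: a table of records
#' held in memory, queried with [run_query()]. It stands behind the same
#' declaration surface ([data_source_decl()]) that a remote backend would
#' use.
#'
#' @param records A data frame of records.
#' @return An object of class `nsc_data_source`.
#' @export
in_memory_data_source <- function(records) {
  stopifnot(is.data.frame(records))
  structure(list(backend_id = "memory", records = records),
            class = "nsc_data_source")
}

#' Run a query against a data source
#'
#' Applies the query's filters as a conjunction (a record is kept iff it
#' satisfies every filter) and returns the matching records in their input
#' order (stable), together with the match count. An empty filter list
#' matches all records.
#'
#' @param ds An [in_memory_data_source()].
#' @param q A [query_decl()].
#' @param records Optional data frame overriding the source's records.
#' @return List with elements `records` (data frame) and `count`.
#' @examples
#' ds <- in_memory_data_source(data.frame(label = c("RMEL", "AVAR"), n = 1:2))
#' q <- query_decl("q", list(query_filter("label", "contains", "RME")))
#' run_query(ds, q)$count
#' @export
run_query <- function(ds, q, records = NULL) {
  stopifnot(inherits(ds, "nsc_data_source"), inherits(q, "nsc_query_decl"))
  if (is.null(records)) records <- ds$records
  stopifnot(is.data.frame(records))
  keep <- rep(TRUE, nrow(records))
  for (flt in q$filters) {
    if (!flt$field %in% names(records)) {
      nsc_abort(sprintf("query '%s' filters on unknown field '%s' (schema: %s)",
                        q$id, flt$field, paste(names(records), collapse = ", ")),
                "nsc_query_schema")
    }
    col <- records[[flt$field]]
    keep <- keep & switch(flt$predicate,
      eq = col == flt$operand,
      ne = col != flt$operand,
      lt = col < flt$operand,
      le = col <= flt$operand,
      gt = col > flt$operand,
      ge = col >= flt$operand,
      contains = grepl(flt$operand, as.character(col), fixed = TRUE))
  }
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, count = nrow(out))
}
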
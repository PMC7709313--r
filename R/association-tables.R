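#' Canonicalize entity names
#'
#' Entity names arriving from different source databases disagree in case and
#' spacing ("MiR-21 ", "mir-21"). All registries and association tables in
#' this package are keyed by the canonical form: case-folded, surrounding
#' whitespace stripped, internal runs of whitespace collapsed to one space.
#'
#' @param x Character vector of raw names.
#' @return Character vector of canonical names.
#' @examples
#' canonicalize_name(c("MiR-21 ", "Lung  Cancer"))
#' @export
canonicalize_name <- function(x) {
  stringr::str_squish(stringr::str_to_lower(as.character(x)))
}

#' Read a two-column association table
#'
#' Reads a tab- (or comma-) separated table of entity pairs, e.g.
#' miRNA--disease, miRNA--lncRNA or lncRNA--disease associations. The first
#' column is the left entity, the second the right entity; extra columns are
#' ignored. A header line is detected by the presence of a "mirna", "lncrna"
#' or "disease" token. Names are canonicalized (see [canonicalize_name()])
#' and exact duplicate pairs are dropped, keeping first-seen order.
#'
#' @param path Path to the file.
#' @param col_names Length-2 character vector naming the output columns.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the first line.
#' @param provenance Optional free-text source tag stored as an attribute.
#' @return A tibble with the two requested columns, one row per unique
#'   canonical pair.
#' @export
read_association_table <- function(path, col_names = c("left", "right"),
                                   sep = NULL, provenance = NULL) {
  stopifnot(length(col_names) == 2)
  if (!file.exists(path)) {
    abort(paste0("association table not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("association table is empty: ", path))
  }
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  }
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- any(grepl("mirna|lncrna|disease", tolower(first)))
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0) {
    abort(paste0("association table has a header but no records: ", path))
  }
  fields <- strsplit(body, sep, fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed association line %d in %s: expected >= 2 fields",
      bad[[1]] + has_header, path
    ))
  }
  out <- tibble::tibble(
    !!col_names[[1]] := canonicalize_name(vapply(fields, `[[`, "", 1L)),
    !!col_names[[2]] := canonicalize_name(vapply(fields, `[[`, "", 2L))
  )
  out <- dplyr::distinct(out)
  attr(out, "provenance") <- provenance %||% path
  out
}

#' Write an association table as TSV
#'
#' Inverse of [read_association_table()]: writes the two columns with a
#' header line so a round trip reproduces the same record set.
#'
#' @param table Tibble with two character columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  readr::write_tsv(table[, 1:2], path)
  invisible(path)
}

#' Ordered entity registry from one or more name vectors
#'
#' Builds the ordered universe of canonical entity names used to label matrix
#' axes: first occurrence across the inputs fixes the position.
#'
#' @param ... Character vectors of (raw or canonical) names.
#' @return Character vector of unique canonical names in first-seen order.
#' @export
entity_registry <- function(...) {
  unique(canonicalize_name(c(...)))
}

#' Build a binary incidence matrix from an association table
#'
#' Produces the 0/1 matrix whose entry (i, j) is 1 iff the pair
#' (rows\[i\], cols\[j\]) occurs in `table`. Row i of a miRNA--lncRNA
#' incidence matrix is the interaction profile of miRNA i.
#'
#' @param table Tibble of pairs (first column = rows, second = columns).
#' @param rows,cols Character registries labelling the axes.
#' @param on_missing `"error"` (default) aborts when a table name is absent
#'   from its registry; `"drop"` drops such pairs with a warning.
#' @return Binary matrix with `dimnames = list(rows, cols)`.
#' @export
build_incidence <- function(table, rows, cols,
                            on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  rows <- entity_registry(rows)
  cols <- entity_registry(cols)
  left <- canonicalize_name(table[[1]])
  right <- canonicalize_name(table[[2]])
  i <- match(left, rows)
  j <- match(right, cols)
  miss <- is.na(i) | is.na(j)
  if (any(miss)) {
    culprits <- unique(c(left[is.na(i)], right[is.na(j)]))
    if (on_missing == "error") {
      abort(paste0(
        "names absent from registry: ",
        paste(head(culprits, 5), collapse = ", "),
        if (length(culprits) > 5) " ..." else ""
      ))
    }
    warn(sprintf("dropping %d association(s) with unregistered names",
                 sum(miss)))
    i <- i[!miss]
    j <- j[!miss]
  }
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(i, j)] <- 1
  m
}

#' Restrict lncRNA-disease associations to the tripartite universe
#'
#' The lncRNA-disease table is only usable where both endpoints carry
#' indirect (miRNA-side) information, so pairs whose lncRNA is absent from
#' the miRNA-lncRNA universe or whose disease is absent from the
#' miRNA-disease universe are removed. The surviving pairs define the
#' lncRNA-disease registries.
#'
#' @param ld Tibble of (lncRNA, disease) pairs.
#' @param lncrnas Character registry of lncRNAs with miRNA partners.
#' @param diseases Character registry of diseases with miRNA partners.
#' @return A tibble of surviving unique pairs, with attributes `lncrnas` and
#'   `diseases`: the registries rebuilt from the surviving pairs
#'   (first-seen order).
#' @export
filter_ld_associations <- function(ld, lncrnas, diseases) {
  lncrnas <- entity_registry(lncrnas)
  diseases <- entity_registry(diseases)
  out <- tibble::tibble(
    lncrna = canonicalize_name(ld[[1]]),
    disease = canonicalize_name(ld[[2]])
  )
  out <- dplyr::distinct(out)
  out <- dplyr::filter(out, .data$lncrna %in% lncrnas,
                       .data$disease %in% diseases)
  attr(out, "lncrnas") <- unique(out$lncrna)
  attr(out, "diseases") <- unique(out$disease)
  out
}
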
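#' Read a PPI network from a tab- or whitespace-delimited edge list
#'
#' Each non-comment line names one interaction: two protein IDs separated by
#' whitespace (extra columns are ignored). Lines starting with `#` and blank
#' lines are skipped. Self-loops and duplicate pairs are removed, with a
#' message reporting how many were dropped.
#'
#' @param path Path to the edge-list file (UTF-8).
#' @param quiet Passed on to [ppi_network()].
#' @return A [ppi_network] object.
#' @export
read_ppi_network <- function(path, quiet = FALSE) {
  lines <- read_clean_lines(path)
  if (nrow(lines) == 0L) {
    rlang::abort("empty network")
  }
  fields <- strsplit(lines$text, "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("line %d: expected at least 2 fields",
                         lines$lineno[bad[1]]))
  }
  ppi_network(
    tibble::tibble(from = vapply(fields, `[`, "", 1L),
                   to = vapply(fields, `[`, "", 2L)),
    quiet = quiet
  )
}

#' Read a protein complex catalog
#'
#' One complex per line: an optional leading name field followed by
#' tab/whitespace-separated member IDs. Duplicate members within a line are
#' collapsed, and complexes smaller than `min_size` (after deduplication)
#' are dropped.
#'
#' @param path Path to the catalog file.
#' @param min_size Minimum number of members a complex must have to be kept.
#'   The default of 3 matches the usual gold-standard convention of removing
#'   complexes with fewer than three members.
#' @param named If `TRUE` (default) the first field of each line is the
#'   complex name; otherwise names `C1`, `C2`, ... are assigned.
#' @param skip_fields Number of additional leading fields (after the name,
#'   if any) to ignore before the member IDs start. Lets files written by
#'   [write_complexes()] round-trip: their rank column is the name and the
#'   size and density-score columns are skipped with `skip_fields = 2`.
#' @return A complex catalog: a tibble with columns `complex` (character),
#'   `size` (integer) and `members` (list of character vectors, sorted).
#' @export
read_complex_catalog <- function(path, min_size = 3, named = TRUE,
                                 skip_fields = 0) {
  lines <- read_clean_lines(path)
  fields <- strsplit(lines$text, "[ \t]+")
  first_member <- 1L + as.integer(named) + as.integer(skip_fields)
  out <- vector("list", length(fields))
  names_out <- character(length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < first_member) {
      rlang::abort(sprintf("line %d: complex with zero members",
                           lines$lineno[k]))
    }
    names_out[k] <- if (named) f[1L] else paste0("C", k)
    out[[k]] <- sort(unique(f[first_member:length(f)]))
  }
  keep <- lengths(out) >= min_size
  tibble::tibble(complex = names_out[keep],
                 size = lengths(out[keep]),
                 members = out[keep])
}

#' Write predicted complexes to a tab-delimited file
#'
#' One complex per line: rank, size, density score, then the sorted member
#' IDs, all tab-separated, preceded by a `#` header line. The file can be
#' read back with `read_complex_catalog(path, named = TRUE, skip_fields = 2)`,
#' which recovers identical member sets.
#'
#' @param complexes A [run_mipalm()] fit, a complex catalog tibble with a
#'   `members` list-column, or a bare list of character member vectors.
#' @param path Output file path.
#' @param net Optional [ppi_network] used to compute density scores when
#'   `complexes` does not carry them; otherwise `NA` is written.
#' @return Invisibly, the path.
#' @export
write_complexes <- function(complexes, path, net = NULL) {
  if (inherits(complexes, "mipalm_fit")) {
    members <- complexes$complexes$members
    dscore <- complexes$complexes$density_score
  } else if (is.data.frame(complexes)) {
    members <- complexes$members
    dscore <- complexes$density_score %||% rep(NA_real_, length(members))
  } else {
    members <- complexes
    dscore <- if (!is.null(net)) {
      vapply(members, function(s) density_score(net, s), 0)
    } else {
      rep(NA_real_, length(members))
    }
  }
  members <- lapply(members, function(s) sort(unique(s)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# rank\tsize\tdensity_score\tmembers...", con)
  for (k in seq_along(members)) {
    writeLines(paste(c(k, length(members[[k]]),
                       format(dscore[k], digits = 15),
                       members[[k]]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a protein annotation table
#'
#' Two tab/whitespace-separated columns per line: protein ID and label
#' (a GO slim term or a sub-cellular compartment). Proteins appearing on
#' several lines accumulate label sets.
#'
#' @param path Path to the annotation file.
#' @return An annotation table: a tibble with character columns `protein`
#'   and `label`, one row per distinct (protein, label) pair.
#' @export
read_annotation_table <- function(path) {
  lines <- read_clean_lines(path)
  fields <- strsplit(lines$text, "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("line %d: expected exactly 2 fields",
                         lines$lineno[bad[1]]))
  }
  dplyr::distinct(
    tibble::tibble(protein = vapply(fields, `[`, "", 1L),
                   label = vapply(fields, `[`, "", 2L))
  )
}

#' Label sets of an annotation table
#'
#' @param annotations An annotation table (see [read_annotation_table()]).
#' @param proteins Character vector of proteins to query; unknown proteins
#'   get empty label sets.
#' @return A named list of character label vectors.
#' @export
annotation_sets <- function(annotations, proteins = NULL) {
  ann <- as_annotation(annotations)
  if (is.null(proteins)) proteins <- sort(unique(ann$protein))
  sets <- split(ann$label, ann$protein)
  out <- sets[proteins]
  out[vapply(out, is.null, TRUE)] <- list(character(0))
  stats::setNames(out, proteins)
}

as_annotation <- function(annotations) {
  if (!is.data.frame(annotations) ||
      !all(c("protein", "label") %in% names(annotations))) {
    rlang::abort("`annotations` must have `protein` and `label` columns")
  }
  annotations
}

# read lines, dropping comments and blanks but remembering file line numbers
read_clean_lines <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lineno <- seq_along(raw)
  text <- trimws(raw)
  keep <- nzchar(text) & !startsWith(text, "#")
  tibble::tibble(lineno = lineno[keep], text = text[keep])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
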
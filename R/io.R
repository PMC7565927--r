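## File IO: FASTA (via Biostrings), annotation sidecars, site matrices,
## transition lists and peak tables. All tables are TSV/CSV with header rows;
## coordinates are 1-based inclusive throughout.

#' Read protein sequences from FASTA
#'
#' Headers may carry optional `key=value` tokens after the identifier:
#' `species=` and `taxon_group=` are recognised, e.g.
#' `>wif1_mouse species=Mus_musculus taxon_group=deuterostome`.
#'
#' @param path FASTA file.
#' @param annotations Optional annotation `data.frame` (see
#'   [read_annotations()]); rows are matched to proteins by `protein_id`.
#' @return Named list of [protein_record()]. Signals
#'   `egfofuc_empty_input_error` when the file holds no sequences.
#' @export
read_protein_fasta <- function(path, annotations = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    abort_egfofuc(paste0("no sequences in '", path, "'"), "empty_input_error")
  }
  out <- list()
  for (k in seq_along(seqs)) {
    header <- names(seqs)[k]
    tokens <- strsplit(header, "\\s+")[[1]]
    id <- tokens[1]
    kv <- grep("=", tokens[-1], value = TRUE, fixed = TRUE)
    fields <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    ann <- NULL
    if (!is.null(annotations)) {
      sel <- annotations[annotations$protein_id == id, , drop = FALSE]
      if (nrow(sel) > 0) ann <- sel[, c("slot", "start", "end"), drop = FALSE]
    }
    out[[id]] <- protein_record(
      id, as.character(seqs[[k]]),
      species = if ("species" %in% names(fields)) fields[["species"]] else NA_character_,
      taxon_group = if ("taxon_group" %in% names(fields))
        fields[["taxon_group"]] else "unknown",
      annotations = ann)
  }
  out
}

#' Read a domain annotation sidecar
#'
#' TSV with columns `protein_id`, `slot`, `start`, `end` (1-based inclusive
#' full-protein coordinates).
#'
#' @param path TSV file.
#' @return `data.frame` with those columns.
#' @export
read_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("protein_id", "slot", "start", "end") %in% names(ann)))
  ann
}

SITE_SYMBOL <- c(present = "1", absent = "0", domain_missing = "-",
                 unknown = "?")

#' Read and write site matrices
#'
#' TSV encoding of a species-by-slot site matrix: `1` present, `0` absent,
#' `-` domain missing, `?` unknown; columns `species`, optional
#' `taxon_group`, then one column per slot.
#'
#' @param path TSV file.
#' @return `read_site_matrix`: a `site_matrix` character matrix (attribute
#'   `taxon_group` when the column is present); `write_site_matrix`: the path,
#'   invisibly.
#' @export
read_site_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   check.names = FALSE, colClasses = "character")
  stopifnot("species" %in% names(df))
  taxon <- NULL
  if ("taxon_group" %in% names(df)) {
    taxon <- setNames(df$taxon_group, df$species)
  }
  slot_cols <- setdiff(names(df), c("species", "taxon_group"))
  m <- as.matrix(df[, slot_cols, drop = FALSE])
  rownames(m) <- df$species
  decode <- setNames(names(SITE_SYMBOL), SITE_SYMBOL)
  bad <- !m %in% names(decode)
  if (any(bad)) {
    abort_egfofuc(
      paste0("invalid site symbol(s): ", paste(unique(m[bad]), collapse = ", ")),
      "parse_error")
  }
  m[] <- decode[m]
  class(m) <- c("site_matrix", class(m))
  if (!is.null(taxon)) attr(m, "taxon_group") <- taxon
  m
}

#' @rdname read_site_matrix
#' @param m A `site_matrix`.
#' @export
write_site_matrix <- function(m, path) {
  enc <- matrix(SITE_SYMBOL[m], nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(species = rownames(m), enc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tg <- attr(m, "taxon_group")
  if (!is.null(tg)) {
    df <- cbind(df[, "species", drop = FALSE],
                taxon_group = unname(tg[df$species]),
                df[, -1, drop = FALSE])
  }
  writeLines(
    "# O-fucosylation consensus per EGF-LD slot; 1=present 0=absent -=domain_missing ?=unknown",
    path)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' Read and write MRM transition lists
#'
#' CSV round-trip of [build_mrm_method()] tables (lossless to numeric
#' precision of the text encoding, 15 significant digits).
#'
#' @param transitions An `mrm_method` table.
#' @param path CSV file.
#' @return `write_transitions`: the path invisibly; `read_transitions`: the
#'   table.
#' @export
write_transitions <- function(transitions, path) {
  out <- transitions
  for (col in c("precursor_mz", "fragment_mz")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  class(tr) <- c("mrm_method", class(tr))
  tr
}

#' Read an MRM peak table
#'
#' CSV with columns `transition_id` and `area` (optionally `replicate`).
#'
#' @param path CSV file.
#' @return `data.frame` of class `peak_table`.
#' @export
read_peak_table <- function(path) {
  pt <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transition_id", "area") %in% names(pt)))
  class(pt) <- c("peak_table", class(pt))
  pt
}

#' Write a domain scan table
#'
#' @param table A [scan_protein()] result (rows from one or several
#'   proteins).
#' @param path TSV file.
#' @return The path, invisibly.
#' @export
write_domain_table <- function(table, path) {
  writeLines("# coordinates are 1-based inclusive full-protein positions", path)
  suppressWarnings(
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}
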
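## Pipeline orchestration: one function per stage, each usable directly or
## from the `egfofuc` command-line script. Every stage consumes only explicit
## inputs and returns plain tables/objects; file outputs are optional.

as_protein_list <- function(proteins, annotations = NULL) {
  if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins)) {
    ann <- if (is.character(annotations)) read_annotations(annotations)
    else annotations
    return(read_protein_fasta(proteins, annotations = ann))
  }
  if (inherits(proteins, "protein_record")) return(list(proteins))
  stopifnot(is.list(proteins))
  proteins
}

as_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && file.exists(tree)) return(parse_newick(file = tree))
  parse_newick(text = tree)
}

as_site_matrix <- function(m) {
  if (inherits(m, "site_matrix")) return(m)
  if (is.character(m) && length(m) == 1 && file.exists(m)) {
    return(read_site_matrix(m))
  }
  stopifnot(is.matrix(m))
  m
}

#' Scan proteins for EGF-like domains, consensus sites and compatibility
#'
#' @param proteins FASTA path, a [protein_record()] or a list of them.
#' @param annotations Optional sidecar TSV path or `data.frame`
#'   (`protein_id`, `slot`, `start`, `end`); annotated spans override
#'   detection.
#' @param out Optional TSV output path.
#' @param spacing,bulky_set Passed to [scan_protein()].
#' @return The combined scan `data.frame` (one row per domain).
#' @export
run_scan <- function(proteins, annotations = NULL, out = NULL,
                     spacing = egf_spacing(), bulky_set = c("H", "Y", "D")) {
  prots <- as_protein_list(proteins, annotations)
  tab <- do.call(rbind, c(lapply(prots, scan_protein, spacing = spacing,
                                 bulky_set = bulky_set),
                          list(make.row.names = FALSE)))
  if (!is.null(out)) write_domain_table(tab, out)
  tab
}

#' Build the conservation outputs: site matrix and per-slot logos
#'
#' Groups domains by species (falling back to protein id), builds the
#' species-by-slot site matrix, and for every slot with at least two domains
#' computes the cysteine-anchored alignment and its conservation logo.
#'
#' @param proteins,annotations As in [run_scan()].
#' @param slots Slot labels defining the matrix columns.
#' @param unknown Optional named list (species -> slots with unknown state).
#' @param out_dir Optional output directory (`site_matrix.tsv`,
#'   `logo_<slot>.csv`).
#' @return List with `site_matrix`, `alignments` and `logos` (named by slot).
#' @export
run_conserve <- function(proteins, annotations = NULL,
                         slots = c("I", "II", "III", "IV", "V"),
                         unknown = NULL, out_dir = NULL) {
  prots <- as_protein_list(proteins, annotations)
  domain_sets <- lapply(prots, detect_egf_domains)
  names(domain_sets) <- vapply(prots, function(p) {
    if (!is.na(p$species)) p$species else p$id
  }, character(1))
  m <- build_site_matrix(domain_sets, slots = slots, unknown = unknown)
  all_domains <- unlist(domain_sets, recursive = FALSE)
  alignments <- list(); logos <- list()
  for (slot in slots) {
    doms <- Filter(function(d) identical(as.character(d$slot), slot),
                   all_domains)
    if (length(doms) < 2) next
    aln <- align_domains_by_cysteines(doms)
    alignments[[slot]] <- aln
    logos[[slot]] <- compute_logo(aln)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_site_matrix(m, file.path(out_dir, "site_matrix.tsv"))
    for (slot in names(logos)) {
      write.csv(as.data.frame(logos[[slot]]),
                file.path(out_dir, paste0("logo_", slot, ".csv")),
                row.names = FALSE)
    }
  }
  list(site_matrix = m, alignments = alignments, logos = logos)
}

#' Reconstruct per-slot site gains and losses over a species tree
#'
#' @param site_matrix A `site_matrix`, or TSV path (see
#'   [read_site_matrix()]).
#' @param tree A `phylo`, Newick string or Newick file path.
#' @param resolve Ambiguity rule for [fitch()].
#' @param out_dir Optional output directory (`events.tsv`, `scenario.txt`,
#'   `scenario.json`).
#' @return A [summarize_scenario()] result.
#' @export
run_evolve <- function(site_matrix, tree, resolve = "deltran",
                       out_dir = NULL) {
  m <- as_site_matrix(site_matrix)
  tr <- as_tree(tree)
  scen <- summarize_scenario(m, tr, resolve = resolve)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ev <- scen$events
    if (is.null(ev)) {
      ev <- data.frame(slot = character(), parent = integer(),
                       child = integer(), branch = character(),
                       type = character(), tips = character())
    }
    suppressWarnings(write.table(ev, file.path(out_dir, "events.tsv"),
                                 sep = "\t", quote = FALSE, row.names = FALSE))
    writeLines(scen$report, file.path(out_dir, "scenario.txt"))
    jsonlite::write_json(
      list(table = scen$table, report = scen$report),
      file.path(out_dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
  }
  scen
}

#' Build a glycopeptide MRM transition list from proteins
#'
#' Digests each protein, keeps the peptides that span a consensus acceptor
#' position (the quantitation targets), and emits the transition table for
#' their full glycoform series.
#'
#' @param proteins,annotations As in [run_scan()].
#' @param proteases Character vector among `"trypsin"`, `"thermolysin"`
#'   (default both: co-digestion).
#' @param max_missed Missed cleavages (default 1).
#' @param charges,top_n Passed to [build_mrm_method()].
#' @param peptide_length Inclusive length range of retained peptides
#'   (default `c(5, 30)`).
#' @param out Optional CSV output path.
#' @return The `mrm_method` transition table.
#' @export
run_glyco <- function(proteins, annotations = NULL,
                      proteases = c("trypsin", "thermolysin"),
                      max_missed = 1L, charges = c(2L, 3L), top_n = 6L,
                      peptide_length = c(5L, 30L), out = NULL) {
  prots <- as_protein_list(proteins, annotations)
  rules <- lapply(proteases, function(p) {
    switch(p, trypsin = trypsin(), thermolysin = thermolysin(),
           abort_egfofuc(paste0("unknown protease '", p, "'"), "config_error"))
  })
  pep_rows <- list()
  for (prot in prots) {
    scan <- scan_protein(prot)
    acceptors <- scan$acceptor_pos[!is.na(scan$acceptor_pos)]
    if (length(acceptors) == 0) next
    peps <- digest(prot$sequence, rules, max_missed = max_missed)
    keep <- nchar(peps$sequence) >= peptide_length[1] &
      nchar(peps$sequence) <= peptide_length[2] &
      vapply(seq_len(nrow(peps)), function(k) {
        any(acceptors >= peps$start[k] & acceptors <= peps$end[k])
      }, logical(1))
    peps <- peps[keep, , drop = FALSE]
    if (nrow(peps) == 0) next
    pep_rows[[prot$id]] <- data.frame(
      peptide_id = paste0(prot$id, ":", peps$start, "-", peps$end),
      sequence = peps$sequence, site_present = TRUE,
      stringsAsFactors = FALSE)
  }
  if (length(pep_rows) == 0) {
    abort_egfofuc("no consensus-bearing peptides found", "empty_input_error")
  }
  peptides <- unique(do.call(rbind, c(pep_rows, list(make.row.names = FALSE))))
  method <- build_mrm_method(peptides, charges = charges, top_n = top_n)
  if (!is.null(out)) write_transitions(method, out)
  method
}

#' Quantify site occupancy from a peak table
#'
#' Runs [quantify_site_occupancy()] per peptide and (when present) per
#' replicate, and reports mean and standard deviation of percent
#' O-fucosylation.
#'
#' @param peak_table A `peak_table` `data.frame` or CSV path.
#' @param transitions An `mrm_method` table or CSV path.
#' @param include_extended Passed to [quantify_site_occupancy()].
#' @param out Optional TSV output path.
#' @return `data.frame` with columns `peptide_id`, `n_replicates`,
#'   `mean_percent`, `sd_percent`, `fragment`.
#' @export
run_quant <- function(peak_table, transitions, include_extended = FALSE,
                      out = NULL) {
  if (is.character(peak_table)) peak_table <- read_peak_table(peak_table)
  if (is.character(transitions)) transitions <- read_transitions(transitions)
  if (is.null(peak_table$replicate)) peak_table$replicate <- 1L
  rows <- list()
  for (pid in unique(transitions$peptide_id)) {
    pcts <- c(); frag <- NA_character_
    for (r in unique(peak_table$replicate)) {
      pt <- peak_table[peak_table$replicate == r, , drop = FALSE]
      q <- quantify_site_occupancy(pt, transitions, peptide_id = pid,
                                   include_extended = include_extended)
      pcts <- c(pcts, q$percent_modified)
      frag <- q$fragment
    }
    rows[[pid]] <- data.frame(
      peptide_id = pid, n_replicates = length(pcts),
      mean_percent = mean(pcts),
      sd_percent = if (length(pcts) > 1) stats::sd(pcts) else NA_real_,
      fragment = frag, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out)) {
    suppressWarnings(write.table(res, out, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  }
  res
}

#' Generate a complete synthetic dataset
#'
#' Simulates an ortholog family and writes its FASTA, annotation sidecar,
#' species tree and ground-truth files, so the full pipeline can be run
#' end-to-end against known truth.
#'
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory.
#' @param ... Further arguments to [simulation_config()].
#' @return The [simulate_ortholog_family()] result, with the written paths in
#'   attribute `"paths"`.
#' @export
run_simulate <- function(seed, out_dir, ...) {
  cfg <- simulation_config(seed = seed, ...)
  sim <- simulate_ortholog_family(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(out_dir, "family.fasta"),
             annotations = file.path(out_dir, "annotations.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             truth_matrix = file.path(out_dir, "true_site_matrix.tsv"),
             truth_events = file.path(out_dir, "true_events.tsv"))
  writeLines(unlist(lapply(sim$proteins, function(p) {
    c(paste0(">", p$id, " species=", p$species), p$sequence)
  })), paths[["fasta"]])
  ann <- sim$annotations
  names(ann)[names(ann) == "species"] <- "protein_id"
  suppressWarnings(write.table(ann, paths[["annotations"]], sep = "\t",
                               quote = FALSE, row.names = FALSE))
  write_newick(sim$tree, paths[["tree"]])
  write_site_matrix(sim$truth$site_matrix, paths[["truth_matrix"]])
  ev <- sim$truth$events
  if (is.null(ev)) {
    ev <- data.frame(slot = character(), parent = integer(),
                     child = integer(), type = character(),
                     tips = character())
  }
  suppressWarnings(write.table(ev, paths[["truth_events"]], sep = "\t",
                               quote = FALSE, row.names = FALSE))
  attr(sim, "paths") <- paths
  sim
}
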
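## Seeded synthetic-data generator: ortholog families of multi-EGF-LD
## proteins evolving consensus-site presence/absence along a tree, MRM peak
## tables with known true occupancy, and the packaged sequence fixtures.

ROMAN_SLOTS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")

slot_labels <- function(n) {
  if (n <= length(ROMAN_SLOTS)) ROMAN_SLOTS[seq_len(n)] else as.character(seq_len(n))
}

#' Simulation configuration
#'
#' Parameters of the ortholog-family simulator. Defaults emulate the study
#' conditions of a WIF1-like family: five EGF-like domain slots, a bilaterian-
#' scale leaf count, canonical loop-length ranges with a five-residue C2-C3
#' loop, and rare per-branch site gains/losses.
#'
#' @param seed Mandatory integer seed; every stochastic call is funnelled
#'   through it.
#' @param n_leaves Number of species when no tree is supplied (default 20).
#' @param tree Optional `phylo` to evolve along (branch lengths not used by
#'   the site process, which is per-branch).
#' @param n_slots Number of EGF-like domain slots per protein (default 5).
#' @param loop_min,loop_max Per-loop length ranges used to draw root domains
#'   (loop 2 is pinned to 5 so the consensus is geometrically possible).
#' @param root_site Logical vector (length `n_slots`, recycled) of root site
#'   states; default: site present in slot 2 only (the ancestral
#'   configuration).
#' @param gain_prob,loss_prob Per-branch per-slot probabilities of a site
#'   gain (absent -> present) and loss (present -> absent); defaults 0.03 and
#'   0.05.
#' @param sub_rate Per-branch per-residue substitution probability in the
#'   inter-cysteine loops (default 0.02); substitutions never touch the six
#'   cysteines and toggle the acceptor S/T atomically with the site state.
#' @param occupancy,noise_cv,n_replicates MRM defaults carried in the config
#'   for [simulate_peak_table()]: true modified fraction (default 0.6724),
#'   multiplicative log-normal noise CV (default 0.10) and replicate count
#'   (default 3).
#' @return A validated list of class `simulation_config`. Signals
#'   `egfofuc_config_error` on invalid values.
#' @export
simulation_config <- function(seed, n_leaves = 20L, tree = NULL, n_slots = 5L,
                              loop_min = c(3L, 5L, 3L, 1L, 8L),
                              loop_max = c(8L, 5L, 8L, 1L, 9L),
                              root_site = NULL,
                              gain_prob = 0.03, loss_prob = 0.05,
                              sub_rate = 0.02,
                              occupancy = 0.6724, noise_cv = 0.10,
                              n_replicates = 3L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort_egfofuc("a seed is mandatory for any stochastic call", "config_error")
  }
  if (is.null(root_site)) root_site <- seq_len(n_slots) == 2L
  root_site <- rep_len(as.logical(root_site), n_slots)
  probs <- c(gain_prob, loss_prob, sub_rate)
  if (any(probs < 0 | probs > 1)) {
    abort_egfofuc("probabilities must lie in [0, 1]", "config_error")
  }
  if (occupancy < 0 || occupancy > 1) {
    abort_egfofuc("occupancy must lie in [0, 1]", "config_error")
  }
  if (noise_cv < 0) {
    abort_egfofuc("noise_cv must be non-negative", "config_error")
  }
  if (length(loop_min) != 5 || length(loop_max) != 5 ||
      any(loop_min > loop_max) || loop_min[2] != 5 || loop_max[2] != 5) {
    abort_egfofuc(
      "loop ranges must have length 5 with loop 2 pinned to exactly 5 residues",
      "config_error")
  }
  structure(
    list(seed = as.integer(seed), n_leaves = as.integer(n_leaves), tree = tree,
         n_slots = as.integer(n_slots),
         loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
         root_site = root_site, gain_prob = gain_prob, loss_prob = loss_prob,
         sub_rate = sub_rate, occupancy = occupancy, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates)),
    class = "simulation_config")
}

AA_NO_C <- setdiff(AA_STANDARD, "C")
AA_NO_CST <- setdiff(AA_STANDARD, c("C", "S", "T"))

sample_loop <- function(len) {
  paste(sample(AA_NO_C, len, replace = TRUE), collapse = "")
}

# A domain is held as a list of five loop strings plus the site state; the
# acceptor is the last residue of loop 2.
make_root_domain <- function(cfg, site) {
  lens <- vapply(1:5, function(k) {
    if (cfg$loop_min[k] == cfg$loop_max[k]) cfg$loop_min[k]
    else sample(cfg$loop_min[k]:cfg$loop_max[k], 1L)
  }, integer(1))
  loops <- vapply(lens, sample_loop, character(1))
  loops[2] <- set_acceptor(loops[2], site)
  list(loops = loops, site = site)
}

set_acceptor <- function(loop2, site) {
  acceptor <- if (site) sample(c("S", "T"), 1L) else sample(AA_NO_CST, 1L)
  paste0(substr(loop2, 1, 4), acceptor)
}

mutate_domain <- function(dom, cfg) {
  events <- character(0)
  # Site gain/loss, toggled atomically with the acceptor residue.
  if (dom$site) {
    if (runif(1) < cfg$loss_prob) {
      dom$site <- FALSE
      dom$loops[2] <- set_acceptor(dom$loops[2], FALSE)
      events <- "loss"
    }
  } else if (runif(1) < cfg$gain_prob) {
    dom$site <- TRUE
    dom$loops[2] <- set_acceptor(dom$loops[2], TRUE)
    events <- "gain"
  }
  # Loop substitutions (never the cysteines, never the acceptor slot).
  for (k in 1:5) {
    chars <- aa_chars(dom$loops[k])
    mutable <- seq_along(chars)
    if (k == 2) mutable <- mutable[-length(chars)]
    hit <- mutable[runif(length(mutable)) < cfg$sub_rate]
    if (length(hit) > 0) {
      chars[hit] <- sample(AA_NO_C, length(hit), replace = TRUE)
      dom$loops[k] <- paste(chars, collapse = "")
    }
  }
  list(domain = dom, events = events)
}

domain_string <- function(dom) {
  paste0("C", dom$loops[1], "C", dom$loops[2], "C", dom$loops[3],
         "C", dom$loops[4], "C", dom$loops[5], "C")
}

#' Simulate an ortholog family of multi-EGF-LD proteins
#'
#' Evolves per-slot EGF-like domains along a species tree: presence/absence
#' of the C2-X4-(S/T)-C3 consensus toggles with per-branch gain/loss
#' probabilities (the acceptor residue switches atomically with the state),
#' and loop residues accumulate substitutions that never touch the six
#' cysteines. Leaf domains are embedded in random cysteine-free flanks and
#' linkers to form full proteins with annotations.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ortholog_simulation`: `proteins` (named list
#'   of [protein_record()] with annotations), `tree` (`phylo`),
#'   `annotations` (`data.frame`: species, slot, start, end) and `truth`
#'   (list: `site_matrix` -- species x slot over `present`/`absent`;
#'   `events` -- `data.frame` slot/parent/child/type/tips; `cys` -- named
#'   list species -> slot -> six cysteine positions; `domains` -- leaf domain
#'   strings). Identical seeds give byte-identical output.
#' @export
simulate_ortholog_family <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(config$n_leaves,
                       tip.label = sprintf("sp%02d", seq_len(config$n_leaves)))
    tree$edge.length <- rexp(nrow(tree$edge), rate = 1)
  }
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  children <- node_children(tree)
  slots <- slot_labels(config$n_slots)

  node_doms <- vector("list", n_node)
  node_doms[[root]] <- lapply(seq_len(config$n_slots), function(s) {
    make_root_domain(config, config$root_site[s])
  })
  events <- list()
  # Pre-order walk: children inherit, then mutate.
  stack <- root
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (ch in children[[v]]) {
      doms <- node_doms[[v]]
      for (s in seq_len(config$n_slots)) {
        res <- mutate_domain(doms[[s]], config)
        doms[[s]] <- res$domain
        for (ev in res$events) {
          tips <- if (ch <= n_tip) tree$tip.label[ch] else
            sort(tree$tip.label[phangorn::Descendants(tree, ch, "tips")[[1]]])
          events[[length(events) + 1]] <- data.frame(
            slot = slots[s], parent = v, child = ch, type = ev,
            tips = paste(tips, collapse = ","), stringsAsFactors = FALSE)
        }
      }
      node_doms[[ch]] <- doms
      stack <- c(stack, ch)
    }
  }

  proteins <- list()
  ann_rows <- list()
  cys <- list()
  site_matrix <- matrix("absent", nrow = n_tip, ncol = config$n_slots,
                        dimnames = list(tree$tip.label, slots))
  dom_strings <- list()
  for (i in seq_len(n_tip)) {
    sp <- tree$tip.label[i]
    doms <- node_doms[[i]]
    pieces <- sample_loop(sample(10:20, 1L)) # N-terminal flank, cysteine-free
    pos <- nchar(pieces)
    sp_ann <- list()
    sp_cys <- list()
    sp_dom <- character(config$n_slots)
    for (s in seq_len(config$n_slots)) {
      dstr <- domain_string(doms[[s]])
      start <- pos + 1L
      end <- pos + nchar(dstr)
      local_c <- which(aa_chars(dstr) == "C")
      sp_ann[[s]] <- data.frame(slot = slots[s], start = start, end = end,
                                stringsAsFactors = FALSE)
      sp_cys[[slots[s]]] <- local_c + pos
      sp_dom[s] <- dstr
      site_matrix[sp, s] <- if (doms[[s]]$site) "present" else "absent"
      linker <- sample_loop(sample(4:10, 1L))
      pieces <- paste0(pieces, dstr, linker)
      pos <- nchar(pieces)
    }
    pieces <- paste0(pieces, sample_loop(sample(8:15, 1L)))
    ann <- do.call(rbind, sp_ann)
    proteins[[sp]] <- protein_record(sp, pieces, species = sp,
                                     annotations = ann)
    ann_rows[[sp]] <- cbind(species = sp, ann, stringsAsFactors = FALSE)
    cys[[sp]] <- sp_cys
    dom_strings[[sp]] <- setNames(sp_dom, slots)
  }
  class(site_matrix) <- c("site_matrix", class(site_matrix))
  structure(
    list(proteins = proteins, tree = tree,
         annotations = do.call(rbind, c(ann_rows, list(make.row.names = FALSE))),
         truth = list(
           site_matrix = site_matrix,
           events = if (length(events) > 0)
             do.call(rbind, c(events, list(make.row.names = FALSE)))
           else NULL,
           cys = cys, domains = dom_strings)),
    class = "ortholog_simulation")
}

#' Single-gain binary character on a known branch
#'
#' Deterministic helper for parsimony branch-recovery studies: all leaves
#' below the chosen edge's child are `1`, all others `0` (a single gain, no
#' homoplasy).
#'
#' @param tree A rooted `phylo`.
#' @param edge Row index into `tree$edge` naming the gain branch.
#' @return List with `character` (named leaf states) and `tips` (sorted
#'   leaves below the gain branch).
#' @export
simulate_gain_character <- function(tree, edge) {
  stopifnot(edge >= 1, edge <= nrow(tree$edge))
  child <- tree$edge[edge, 2]
  n_tip <- length(tree$tip.label)
  below <- if (child <= n_tip) child else
    phangorn::Descendants(tree, child, "tips")[[1]]
  states <- setNames(rep("0", n_tip), tree$tip.label)
  states[tree$tip.label[below]] <- "1"
  list(character = states, tips = sort(tree$tip.label[below]))
}

#' Simulate MRM peak tables with known occupancy
#'
#' Generates replicate peak tables for an MRM method: each precursor's
#' transitions get deterministic rank weights (1/rank in method order), the
#' total signal splits between the unmodified form (`1 - occupancy`) and the
#' O-Fuc form (`occupancy`), extended glycoforms get zero area, and every
#' area is multiplied by independent log-normal noise with the requested CV
#' (unit mean). As the CV tends to zero the recovered occupancy equals the
#' truth exactly.
#'
#' @param transitions An [build_mrm_method()] table.
#' @param true_occupancy True modified fraction in \[0, 1\].
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Number of replicate tables.
#' @param seed Mandatory integer seed.
#' @param total_area Total signal per precursor pair (default 1e6).
#' @return `data.frame` with columns `replicate`, `transition_id`, `area`, of
#'   class `peak_table`. Signals `egfofuc_config_error` on invalid inputs.
#' @export
simulate_peak_table <- function(transitions, true_occupancy, noise_cv = 0.10,
                                n_replicates = 3L, seed, total_area = 1e6) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort_egfofuc("a seed is mandatory for any stochastic call", "config_error")
  }
  if (true_occupancy < 0 || true_occupancy > 1) {
    abort_egfofuc("true_occupancy must lie in [0, 1]", "config_error")
  }
  if (noise_cv < 0) {
    abort_egfofuc("noise_cv must be non-negative", "config_error")
  }
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noise_cv^2))
  # Rank weight of each transition within its precursor (method order).
  key <- paste(transitions$peptide_id, transitions$glycoform, transitions$z)
  rank_in_group <- stats::ave(seq_len(nrow(transitions)), key,
                              FUN = function(ix) seq_along(ix))
  weight <- 1 / rank_in_group
  frac <- ifelse(transitions$glycoform == "unmodified", 1 - true_occupancy,
                 ifelse(transitions$glycoform == "O-Fuc", true_occupancy, 0))
  rows <- lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_cv == 0) rep(1, nrow(transitions)) else
      rlnorm(nrow(transitions), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(replicate = r,
               transition_id = transitions$transition_id,
               area = total_area * weight * frac * noise,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("peak_table", class(out))
  out
}

#' Curated WIF1 sequence fixtures
#'
#' The printed mouse WIF1 peptides and consensus motifs used throughout the
#' package tests and examples, plus synthetic full-domain contexts: the
#' residues beyond the published peptides/motifs are invented completions
#' (marked `synthetic`), constructed so each domain carries the documented
#' residue features (H at C2+3, R at C5+1, proline in the C1-C2 loop, Q at
#' C4+1 for EGF-LD V; none of these for EGF-LD III).
#'
#' @return A list with elements `peptides`, `motifs`, `synthetic_domains` and
#'   `contexts` (tryptic contexts embedding the printed peptides).
#' @export
wif1_fixtures <- function() {
  list(
    peptides = c(
      egf3_tryptic = "ANCSTTCFNGGTCFYPGK",
      egf5_tryptic = "GYQGDLCSKPVCEPGCGAHGTCHEPNK",
      egf3_codigest = "FNGGTC",
      egf5_codigest = "VCEPGCGAHGTCHEPNK"),
    peptide_starts = c(
      egf3_tryptic = 244L, egf5_tryptic = 301L,
      egf3_codigest = 251L, egf5_codigest = 311L),
    motifs = c(
      egf3 = "CFNGGTC",
      egf5 = "CGAHGTC",
      platypus_egf1 = "CRNGGSC",
      notch1_egf12 = "CQNDATC"),
    synthetic_domains = c(
      egf3_synthetic = "CSTTCFNGGTCFYPGKCVCNSGYSGDRC",
      egf5_synthetic = "CEPGCGAHGTCHEPNKCQCRSSGDNYGC",
      platypus_egf1_synthetic = "CTTACRNGGSCNDGKCVCNSGYSGDRC",
      platypus_egf3_synthetic = "CSTTCFNGGACFYPGKCVCNSGYSGDRC",
      notch1_egf12_synthetic = "CSTTCQNDATCFYPGKCVCNSGYSGDRC"),
    contexts = c(
      egf3_context = "MSGDSQNKANCSTTCFNGGTCFYPGKSTDEWNG",
      egf5_context = "MSGDSQNRGYQGDLCSKPVCEPGCGAHGTCHEPNKSTDEWNG")
  )
}

#' Write the packaged fixtures to a directory
#'
#' Writes the printed peptides and synthetic domain contexts as FASTA, the
#' curated bilaterian site matrix as TSV and the species tree as Newick --
#' the same files shipped under `inst/extdata/`.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths.
#' @export
emit_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- wif1_fixtures()
  write_fasta <- function(seqs, path) {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  }
  paths <- c(
    peptides = file.path(dir, "wif1_printed_peptides.fasta"),
    domains = file.path(dir, "wif1_synthetic_domains.fasta"),
    site_matrix = file.path(dir, "bilaterian_site_matrix.tsv"),
    tree = file.path(dir, "bilaterian_tree.nwk"))
  write_fasta(fx$peptides, paths[["peptides"]])
  write_fasta(fx$synthetic_domains, paths[["domains"]])
  writeLines(bilaterian_site_matrix_tsv(), paths[["site_matrix"]])
  writeLines(bilaterian_tree_newick(), paths[["tree"]])
  paths
}

# Curated site presence states across bilaterians (1 present, 0 absent,
# '-' domain missing, '?' unknown from a partial sequence).
bilaterian_site_matrix_tsv <- function() {
  c("# O-fucosylation consensus per EGF-LD slot; 1=present 0=absent -=domain_missing ?=unknown",
    "species\ttaxon_group\tI\tII\tIII\tIV\tV",
    "Mus_musculus\tdeuterostome\t0\t0\t1\t0\t1",
    "Homo_sapiens\tdeuterostome\t0\t0\t1\t0\t1",
    "Danio_rerio\tdeuterostome\t0\t0\t1\t0\t1",
    "Xenopus_tropicalis\tdeuterostome\t0\t0\t1\t0\t1",
    "Ornithorhynchus_anatinus\tdeuterostome\t1\t0\t0\t0\t1",
    "Ochotona_princeps\tdeuterostome\t0\t0\t0\t0\t1",
    "Dasypus_novemcinctus\tdeuterostome\t0\t0\t1\t0\t0",
    "Gekko_japonicus\tdeuterostome\t0\t0\t1\t0\t0",
    "Python_bivittatus\tdeuterostome\t0\t0\t0\t0\t0",
    "Thamnophis_sirtalis\tdeuterostome\t0\t0\t0\t0\t0",
    "Strongylocentrotus_purpuratus\tdeuterostome\t0\t1\t0\t?\t?",
    "Saccoglossus_kowalevskii\tdeuterostome\t0\t1\t0\t?\t?",
    "Drosophila_melanogaster\tprotostome\t0\t1\t0\t0\t0",
    "Tribolium_castaneum\tprotostome\t0\t1\t0\t0\t0",
    "Folsomia_candida\tprotostome\t0\t1\t0\t0\t0",
    "Daphnia_pulex\tprotostome\t0\t1\t0\t0\t0",
    "Limulus_polyphemus\tprotostome\t0\t1\t0\t0\t0",
    "Lingula_anatina\tprotostome\t0\t0\t1\t1\t0",
    "Crassostrea_gigas\tprotostome\t0\t1\t0\t0\t-")
}

# Species tree over the same taxa (rooted deuterostomes vs protostomes;
# unit branch lengths).
bilaterian_tree_newick <- function() {
  paste0(
    "(((((((((Mus_musculus:1,Ochotona_princeps:1):1,Homo_sapiens:1):1,",
    "Dasypus_novemcinctus:1):1,Ornithorhynchus_anatinus:1):1,",
    "(Gekko_japonicus:1,(Python_bivittatus:1,Thamnophis_sirtalis:1):1):1):1,",
    "Xenopus_tropicalis:1):1,Danio_rerio:1):1,",
    "(Strongylocentrotus_purpuratus:1,Saccoglossus_kowalevskii:1):1):1,",
    "((((Drosophila_melanogaster:1,Tribolium_castaneum:1):1,",
    "Folsomia_candida:1):1,(Daphnia_pulex:1,Limulus_polyphemus:1):1):1,",
    "(Lingula_anatina:1,Crassostrea_gigas:1):1):1);")
}
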
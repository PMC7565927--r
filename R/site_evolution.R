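## Evolution of O-fucosylation sites over a species tree: Newick IO (via ape),
## midpoint rooting (via phangorn), Fitch parsimony with exact ancestral-state
## resolution, per-branch gain/loss mapping and a per-slot scenario summary.

#' Parse a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] returning a `phylo` object and
#' signalling a package condition on malformed input.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object. Signals
#'   `egfofuc_parse_error` when the text cannot be parsed or leaf labels are
#'   duplicated.
#' @export
#' @examples
#' parse_newick("(A:1,B:2);")
parse_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(file = file)
      else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort_egfofuc(
      paste0("malformed Newick",
             if (!is.null(text)) paste0(" near: ",
                                        substr(text, 1, min(60, nchar(text))))),
      "parse_error")
  }
  if (anyDuplicated(tr$tip.label)) {
    abort_egfofuc("duplicated leaf labels in tree", "parse_error")
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (delegating to [phangorn::midpoint()]); ties between equally long paths are
#' resolved by the deterministic traversal order of the underlying
#' implementation.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A rooted `phylo`. Signals `egfofuc_missing_length_error` when
#'   branch lengths are absent.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort_egfofuc("midpoint rooting requires branch lengths",
                  "missing_length_error")
  }
  phangorn::midpoint(tree)
}

# Validate and encode a binary character (leaf -> "0"/"1"/"?") against a tree.
encode_character <- function(tree, character) {
  if (is.null(names(character))) {
    abort_egfofuc("character states must be named by leaf label",
                  "label_mismatch_error")
  }
  states <- as.character(character)
  names(states) <- names(character)
  missing <- setdiff(tree$tip.label, names(states))
  extra <- setdiff(names(states), tree$tip.label)
  if (length(missing) > 0 || length(extra) > 0) {
    abort_egfofuc(
      paste0("character/tree leaf mismatch",
             if (length(missing) > 0)
               paste0("; missing: ", paste(missing, collapse = ", ")),
             if (length(extra) > 0)
               paste0("; extra: ", paste(extra, collapse = ", "))),
      "label_mismatch_error")
  }
  states <- states[tree$tip.label]
  bad <- !states %in% c("0", "1", "?")
  if (any(bad)) {
    abort_egfofuc(
      paste0("invalid state(s): ", paste(unique(states[bad]), collapse = ", "),
             " (allowed: 0, 1, ?)"),
      "label_mismatch_error")
  }
  states
}

# Children of each node as a list indexed by node number.
node_children <- function(tree) {
  n_node <- max(tree$edge)
  ch <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[k, 2])
  }
  ch
}

#' Fitch parsimony for a binary character on a rooted tree
#'
#' Computes the minimum number of gains plus losses of a binary
#' presence/absence character over a rooted tree (multifurcations allowed),
#' the per-node optimal state sets, one resolved most-parsimonious ancestral
#' labeling, and the per-branch gain/loss events. Ambiguous leaves (`"?"`,
#' e.g. partial sequences) carry the full state set and never force a change
#' on their own.
#'
#' The minimum change count and resolution are obtained from an exact
#' dynamic-programming pass (unit-cost Sankoff): `cost[v, s]` is the minimum
#' number of changes in the subtree of `v` when `v` has state `s`. Any
#' top-down argmin trace attains the global minimum, so both tie-break
#' flavours are exact:
#'
#' * `resolve = "deltran"` (default): on ties, a child keeps its parent's
#'   state, placing changes as late (towards the tips) as possible; an
#'   ambiguous root resolves to `"0"` (absent).
#' * `resolve = "acctran"`: on ties, a child switches state, placing changes
#'   as early as possible; an ambiguous root resolves to `"1"`.
#'
#' @param tree A rooted `phylo`.
#' @param character Named vector (leaf label -> `"0"`, `"1"` or `"?"`; `0`/`1`
#'   numerics are accepted).
#' @param resolve Ambiguity resolution rule, `"deltran"` or `"acctran"`.
#' @return An object of class `fitch_result`: `min_changes`, `state_sets`
#'   (list over node numbers of subtree-optimal state sets), `states` (named
#'   by node number, one resolved labeling), `events` (per-branch
#'   `data.frame`, see [map_events()]), `root_state` and `resolve`. Signals
#'   `egfofuc_label_mismatch_error` on leaf/character mismatches.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' fitch(tr, c(A = 1, B = 1, C = 0, D = 0))$min_changes
fitch <- function(tree, character, resolve = c("deltran", "acctran")) {
  resolve <- match.arg(resolve)
  stopifnot(inherits(tree, "phylo"))
  states <- encode_character(tree, character)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root) != 1) {
    abort_egfofuc("tree must have a single root", "label_mismatch_error")
  }
  children <- node_children(tree)
  # cost[v, s]: min changes in subtree of v given state s in {0, 1}.
  cost <- matrix(Inf, nrow = n_node, ncol = 2)
  for (i in seq_len(n_tip)) {
    cost[i, ] <- switch(states[i],
                        "0" = c(0, Inf),
                        "1" = c(Inf, 0),
                        "?" = c(0, 0))
  }
  # Explicit DFS from the root: order_out is a preorder, its reverse a
  # postorder (works for any node numbering and for multifurcations).
  stack <- root
  order_out <- integer(0)
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_out <- c(order_out, v)
    stack <- c(stack, children[[v]])
  }
  postorder <- rev(order_out)
  for (v in postorder) {
    if (length(children[[v]]) == 0) next # leaf, already initialised
    acc <- c(0, 0)
    for (ch in children[[v]]) {
      acc[1] <- acc[1] + min(cost[ch, 1], cost[ch, 2] + 1)
      acc[2] <- acc[2] + min(cost[ch, 1] + 1, cost[ch, 2])
    }
    cost[v, ] <- acc
  }
  min_changes <- min(cost[root, ])
  # Subtree-optimal state sets (Fitch first-pass sets under unit costs).
  state_sets <- lapply(seq_len(n_node), function(v) {
    c("0", "1")[cost[v, ] == min(cost[v, ])]
  })
  # Top-down resolution; any argmin trace is globally optimal.
  resolved <- character(n_node)
  root_set <- state_sets[[root]]
  resolved[root] <- if (length(root_set) == 1) root_set else {
    if (resolve == "deltran") "0" else "1"
  }
  preorder <- order_out
  for (v in preorder) {
    for (ch in children[[v]]) {
      p_state <- resolved[v]
      p_idx <- as.integer(p_state) + 1L
      tot <- cost[ch, ] + (c(1, 2) != p_idx)
      best <- c("0", "1")[tot == min(tot)]
      resolved[ch] <- if (length(best) == 1) best else {
        if (resolve == "deltran") p_state else setdiff(c("0", "1"), p_state)
      }
    }
  }
  names(resolved) <- as.character(seq_len(n_node))
  events <- map_events(tree, resolved)
  structure(
    list(min_changes = as.integer(min_changes), state_sets = state_sets,
         states = resolved, events = events,
         root_state = resolved[as.character(root)], root = root,
         resolve = resolve),
    class = "fitch_result")
}

#' @export
print.fitch_result <- function(x, ...) {
  cat("<fitch_result> min_changes = ", x$min_changes,
      ", root = ", x$root_state,
      ", events: ", nrow(x$events), " (", x$resolve, ")\n", sep = "")
  invisible(x)
}

# Short deterministic label for the clade below a node.
clade_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  tips <- sort(tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]])
  if (length(tips) <= 3) return(paste(tips, collapse = "+"))
  paste0(tips[1], "+", length(tips) - 1, "others")
}

#' Map gains and losses onto branches
#'
#' Given a resolved ancestral labeling, marks every branch whose parent state
#' is 0 and child state 1 as a `gain`, and 1 to 0 as a `loss`. The number of
#' events always equals the parsimony change count of the labeling.
#'
#' @param tree A rooted `phylo`.
#' @param states Named character vector (node number -> `"0"`/`"1"`), e.g.
#'   `fitch(...)$states`.
#' @return `data.frame` with columns `parent`, `child` (node numbers),
#'   `branch` (deterministic child-clade label), `type` (`"gain"`/`"loss"`)
#'   and `tips` (comma-separated sorted descendant leaves of the child).
#' @export
map_events <- function(tree, states) {
  rows <- list()
  n_tip <- length(tree$tip.label)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    sp <- states[as.character(p)]; sc <- states[as.character(ch)]
    if (sp == sc) next
    tips <- if (ch <= n_tip) tree$tip.label[ch] else
      sort(tree$tip.label[phangorn::Descendants(tree, ch, "tips")[[1]]])
    rows[[length(rows) + 1]] <- data.frame(
      parent = p, child = ch, branch = clade_label(tree, ch),
      type = if (sp == "0") "gain" else "loss",
      tips = paste(tips, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(parent = integer(), child = integer(),
                      branch = character(), type = character(),
                      tips = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarize the site-evolution scenario across domain slots
#'
#' Runs [fitch()] independently for every slot column of a site matrix
#' (`present` -> 1, `absent` -> 0, `domain_missing`/`unknown` -> `?`) and
#' assembles a per-slot table plus a text report of root states and
#' per-branch events.
#'
#' @param site_matrix A [build_site_matrix()] result (or character matrix over
#'   the four site states) whose row names cover all tree leaves.
#' @param tree A rooted `phylo`.
#' @param resolve Passed to [fitch()].
#' @return A list of class `scenario_summary`: `per_slot` (named list of
#'   `fitch_result`), `table` (`data.frame`: slot, `min_changes`,
#'   `root_state`, `n_gains`, `n_losses`), `events` (row-bound per-slot
#'   events) and `report` (character lines).
#' @export
summarize_scenario <- function(site_matrix, tree, resolve = "deltran") {
  stopifnot(is.matrix(site_matrix))
  missing <- setdiff(tree$tip.label, rownames(site_matrix))
  if (length(missing) > 0) {
    abort_egfofuc(
      paste0("site matrix lacks species: ", paste(missing, collapse = ", ")),
      "label_mismatch_error")
  }
  slots <- colnames(site_matrix)
  per_slot <- list()
  tab_rows <- list()
  ev_rows <- list()
  report <- character(0)
  for (slot in slots) {
    col <- site_matrix[tree$tip.label, slot]
    char <- ifelse(col == "present", "1", ifelse(col == "absent", "0", "?"))
    names(char) <- tree$tip.label
    fr <- fitch(tree, char, resolve = resolve)
    per_slot[[slot]] <- fr
    n_gain <- sum(fr$events$type == "gain")
    n_loss <- sum(fr$events$type == "loss")
    tab_rows[[slot]] <- data.frame(
      slot = slot, min_changes = fr$min_changes,
      root_state = unname(fr$root_state),
      n_gains = n_gain, n_losses = n_loss, stringsAsFactors = FALSE)
    if (nrow(fr$events) > 0) {
      ev_rows[[slot]] <- cbind(slot = slot, fr$events,
                               stringsAsFactors = FALSE)
    }
    report <- c(report, paste0(
      "EGF-LD ", slot, ": site ",
      if (fr$root_state == "1") "present" else "absent",
      " at the root; ", fr$min_changes, " change(s)",
      if (nrow(fr$events) > 0) paste0(" -- ", paste(
        paste0(fr$events$type, " on branch to ", fr$events$branch),
        collapse = "; "))))
  }
  structure(
    list(per_slot = per_slot,
         table = do.call(rbind, c(tab_rows, list(make.row.names = FALSE))),
         events = if (length(ev_rows) > 0)
           do.call(rbind, c(ev_rows, list(make.row.names = FALSE)))
         else NULL,
         report = report),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("<scenario_summary>\n")
  cat(paste0("  ", x$report, collapse = "\n"), "\n")
  invisible(x)
}
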
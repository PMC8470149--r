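#' @importFrom stats optim optimize rnorm runif quantile var cor sd median
#'   pnorm pt qnorm rexp setNames aggregate complete.cases
#' @importFrom utils write.csv read.csv head tail modifyList
NULL

## ---------------------------------------------------------------------------
## Trees: Newick I/O, ages, pruning, shared-time matrix, regime paintings.
## Trees are plain `ape::phylo` objects; ages are in Myr before present
## (tips at age 0), process time t = root_height - age.
## ---------------------------------------------------------------------------

#' Parse a Newick string into a phylogenetic tree
#'
#' Wraps [ape::read.tree()] with stricter syntax checking: unbalanced
#' parentheses and singleton clades (an internal node with a single child)
#' are rejected with the character offset of the offending token, and
#' missing branch lengths are an error unless `default_length` is supplied.
#'
#' @param text A Newick string (single tree, terminated by `;`).
#' @param default_length Branch length substituted where the string omits
#'   one; `NULL` (default) makes missing lengths an error.
#' @return An object of class `phylo` with `edge.length` set.
#' @export
parse_newick <- function(text, default_length = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  .newick_syntax_check(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || inherits(tr, "multiPhylo")) {
    if (inherits(tr, "multiPhylo") && length(tr) == 1L) tr <- tr[[1L]]
    else if (is.null(tr)) stop("Newick parse failure: ", substr(text, 1, 60))
  }
  if (is.null(tr$edge.length)) {
    if (is.null(default_length))
      stop("tree has no branch lengths (supply `default_length`)")
    tr$edge.length <- rep(default_length, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (is.null(default_length))
      stop("missing branch length(s) (supply `default_length`)")
    tr$edge.length[is.na(tr$edge.length)] <- default_length
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

## Character-level scan: balanced parentheses and no singleton clades.
## Reports 1-based character offsets.
.newick_syntax_check <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  commas <- integer(0)  # top-level comma count per open group
  opened <- integer(0)  # offset of each open '('
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- depth + 1L
      commas <- c(commas, 0L)
      opened <- c(opened, i)
    } else if (ch == ")") {
      if (depth == 0L)
        stop("Newick syntax error: unmatched ')' at offset ", i)
      if (commas[depth] == 0L)
        stop("Newick syntax error: singleton clade (no comma) in group opened at offset ",
             opened[depth])
      commas <- commas[-depth]
      opened <- opened[-depth]
      depth <- depth - 1L
    } else if (ch == ",") {
      if (depth == 0L)
        stop("Newick syntax error: ',' outside parentheses at offset ", i)
      commas[depth] <- commas[depth] + 1L
    }
  }
  if (depth > 0L)
    stop("Newick syntax error: unclosed '(' at offset ", opened[depth])
  invisible(TRUE)
}

#' Write a tree to a Newick string
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return Newick string.
#' @export
write_newick <- function(tree, digits = 15) {
  ape::write.tree(tree, digits = digits)
}

#' Node ages and root height
#'
#' Ages are Myr before present: tips of an ultrametric tree are at age 0 and
#' the root at `root_height(tree)`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return `node_ages()`: numeric vector over all nodes (tips then internal,
#'   ape numbering); `root_height()`: scalar, the maximum root-to-tip path.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' @rdname node_ages
#' @export
root_height <- function(tree) max(ape::node.depth.edgelength(tree))

#' Check (or assert) ultrametricity
#'
#' All root-to-tip paths must agree within `tol * root_height`.
#'
#' @param tree A `phylo`.
#' @param tol Relative tolerance (default `1e-6`).
#' @return Logical for `is_ultrametric()`; `assert_ultrametric()` errors.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(depth) - min(depth)) <= tol * max(depth)
}

#' @rdname is_ultrametric
#' @export
assert_ultrametric <- function(tree, tol = 1e-6) {
  if (!is_ultrametric(tree, tol))
    stop("tree is not ultrametric within relative tolerance ", tol)
  invisible(tree)
}

#' Prune a tree to a taxon set
#'
#' Induced subtree on `keep`; unbranched internal nodes are suppressed with
#' branch lengths summed, so retained tip depths are unchanged.
#'
#' @param tree A `phylo`.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

#' Shared-time (phylogenetic covariance structure) matrix
#'
#' Entry (i, j) is the path length from the root to the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip depths. This is
#' the matrix C used by GLS and phylogenetic PCA.
#'
#' @param tree A `phylo`.
#' @return Symmetric matrix with tip labels as dimnames, tip order of `tree`.
#' @export
shared_time_matrix <- function(tree) {
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

## ---------------------------------------------------------------------------
## Regime paintings: per-branch ordered age segments carrying discrete states.
## Stored as a data.frame (edge, parent, child, start_age, end_age, state)
## with start_age > end_age (rootward to tipward), plus a `states` attribute.
## ---------------------------------------------------------------------------

new_painting <- function(tree, segments, states) {
  segments$state <- as.character(segments$state)
  rownames(segments) <- NULL
  structure(segments,
            states = as.character(states),
            n_tips = ape::Ntip(tree),
            class = c("regime_painting", "data.frame"))
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting: ", nrow(x), " segments over ",
      length(unique(x$edge)), " branches; states: ",
      paste(attr(x, "states"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' States of a painting
#' @param painting A `regime_painting`.
#' @return Character vector of state labels.
#' @export
painting_states <- function(painting) attr(painting, "states")

#' Validate a painting against its tree
#'
#' Checks that the segments of each branch tile it exactly (no gaps or
#' overlaps, endpoints matching the branch's node ages to `tol`) and that
#' all states used are declared.
#'
#' @param tree The `phylo` the painting was built on.
#' @param painting A `regime_painting`.
#' @param tol Absolute age tolerance.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_painting <- function(tree, painting, tol = 1e-9) {
  ages <- node_ages(tree)
  E <- tree$edge
  for (e in unique(painting$edge)) {
    seg <- painting[painting$edge == e, , drop = FALSE]
    seg <- seg[order(-seg$start_age), , drop = FALSE]
    pa <- ages[E[e, 1L]]; ca <- ages[E[e, 2L]]
    if (abs(seg$start_age[1L] - pa) > tol ||
        abs(seg$end_age[nrow(seg)] - ca) > tol)
      stop("segments of edge ", e, " do not span its age interval")
    if (nrow(seg) > 1L &&
        any(abs(seg$end_age[-nrow(seg)] - seg$start_age[-1L]) > tol))
      stop("gap/overlap in segments of edge ", e)
    if (any(seg$start_age < seg$end_age - tol))
      stop("segment with start_age < end_age on edge ", e)
  }
  if (length(unique(painting$edge)) != nrow(E))
    stop("painting does not cover every branch")
  if (!all(painting$state %in% attr(painting, "states")))
    stop("painting uses undeclared states")
  invisible(TRUE)
}

.edge_frame <- function(tree) {
  ages <- node_ages(tree)
  data.frame(edge = seq_len(nrow(tree$edge)),
             parent = tree$edge[, 1L], child = tree$edge[, 2L],
             start_age = ages[tree$edge[, 1L]],
             end_age = ages[tree$edge[, 2L]])
}

#' Paint every branch with a single state
#' @param tree A `phylo`.
#' @param state State label (default `"0"`).
#' @return A `regime_painting`.
#' @export
paint_constant <- function(tree, state = "0") {
  ef <- .edge_frame(tree)
  ef$state <- state
  new_painting(tree, ef, state)
}

#' Paint a tree by a time slice
#'
#' Branch portions older than `slice_age` (Myr before present) get state
#' `"pre"`, younger portions `"post"`; a branch spanning the slice is split
#' into two segments at that age.
#'
#' @param tree A `phylo`.
#' @param slice_age Age of the slice in Myr (>= 0); the study default is
#'   2.6 Ma, the onset of the Pleistocene climatic oscillations.
#' @return A `regime_painting` with states `c("pre", "post")`.
#' @export
paint_time_slice <- function(tree, slice_age = 2.6) {
  if (!is.numeric(slice_age) || length(slice_age) != 1L || slice_age < 0)
    stop("slice_age must be a single non-negative age in Myr")
  ef <- .edge_frame(tree)
  out <- vector("list", nrow(ef))
  for (i in seq_len(nrow(ef))) {
    pa <- ef$start_age[i]; ca <- ef$end_age[i]
    if (ca >= slice_age) {
      out[[i]] <- data.frame(ef[i, 1:5], state = "pre")
    } else if (pa <= slice_age) {
      out[[i]] <- data.frame(ef[i, 1:5], state = "post")
    } else {
      out[[i]] <- data.frame(edge = ef$edge[i], parent = ef$parent[i],
                             child = ef$child[i],
                             start_age = c(pa, slice_age),
                             end_age = c(slice_age, ca),
                             state = c("pre", "post"))
    }
  }
  new_painting(tree, do.call(rbind, out), c("pre", "post"))
}

#' Paint branches from node states
#'
#' Each branch carries one full-length segment in the state of its child
#' node (stem-of-clade convention): a clade's stem branch is painted with
#' the state reconstructed for the clade's MRCA.
#'
#' @param tree A `phylo`.
#' @param tip_states Named character vector (names = tip labels), or an
#'   unnamed vector in tip order.
#' @param node_states Character vector over internal nodes, either named by
#'   ape node number or unnamed in ape internal-node order
#'   (`Ntip+1 ... Ntip+Nnode`).
#' @param states Optional explicit state set (order fixes regime order).
#' @return A `regime_painting`.
#' @export
paint_from_node_states <- function(tree, tip_states, node_states,
                                   states = NULL) {
  ntip <- ape::Ntip(tree)
  tip_states <- .as_tip_vector(tree, tip_states, "tip_states")
  node_states <- as.character(node_states)
  if (!is.null(names(node_states))) {
    idx <- as.character(ntip + seq_len(tree$Nnode))
    if (!all(idx %in% names(node_states)))
      stop("node_states missing nodes: ",
           paste(setdiff(idx, names(node_states)), collapse = ", "))
    node_states <- node_states[idx]
  } else if (length(node_states) != tree$Nnode) {
    stop("node_states must cover all ", tree$Nnode, " internal nodes")
  }
  all_states <- c(as.character(tip_states), node_states)
  if (anyNA(all_states)) stop("missing state for some node")
  full <- c(as.character(tip_states), node_states)  # indexed by node number
  ef <- .edge_frame(tree)
  ef$state <- full[ef$child]
  if (is.null(states)) states <- unique(full)
  new_painting(tree, ef, states)
}

#' Paint the stem-and-crown of a clade
#'
#' Branches descending from (and including the stem of) the MRCA of
#' `clade_tips` take the second state; all others the first.
#'
#' @param tree A `phylo`.
#' @param clade_tips Tip labels defining the clade (>= 2).
#' @param states Length-2 state labels, background first.
#' @return A `regime_painting`.
#' @export
paint_clade <- function(tree, clade_tips, states = c("out", "in")) {
  stopifnot(length(states) == 2L)
  clade_tips <- as.character(clade_tips)
  if (!all(clade_tips %in% tree$tip.label))
    stop("unknown clade tips: ",
         paste(setdiff(clade_tips, tree$tip.label), collapse = ", "))
  if (length(clade_tips) < 2L) stop("clade needs >= 2 tips")
  mrca <- ape::getMRCA(tree, clade_tips)
  desc <- .descendants(tree, mrca)
  ef <- .edge_frame(tree)
  ef$state <- ifelse(ef$child %in% c(mrca, desc), states[2L], states[1L])
  new_painting(tree, ef, states)
}

## All descendants (nodes and tips) of an internal node.
.descendants <- function(tree, node) {
  E <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    kids <- E[E[, 1L] %in% stack, 2L]
    out <- c(out, kids)
    stack <- kids[kids > ape::Ntip(tree)]
  }
  out
}

.as_tip_vector <- function(tree, x, what = "tip vector") {
  if (!is.null(names(x))) {
    missing <- setdiff(tree$tip.label, names(x))
    if (length(missing))
      stop(what, " missing tips: ", paste(missing, collapse = ", "))
    x <- x[tree$tip.label]
  } else if (length(x) != ape::Ntip(tree)) {
    stop(what, " must be named or of length Ntip")
  } else {
    names(x) <- tree$tip.label
  }
  x
}

#' Serialize a painting to JSON (and back)
#'
#' JSON maps branch id (edge row index as character) to its ordered segment
#' list; the state set is stored under `"_states"`.
#'
#' @param painting A `regime_painting`.
#' @param path Optional file to write; otherwise the JSON string is returned.
#' @export
painting_to_json <- function(painting, path = NULL) {
  segs <- split(painting[, c("start_age", "end_age", "state")], painting$edge)
  ## each edge serializes as an array of {start_age, end_age, state} objects
  obj <- c(list(`_states` = as.list(attr(painting, "states"))),
           lapply(segs, function(s) { rownames(s) <- NULL; s }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); invisible(path) } else js
}

#' @rdname painting_to_json
#' @param tree The tree the painting belongs to (for validation).
#' @param json JSON string or file path.
#' @export
painting_from_json <- function(tree, json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  states <- unlist(obj[["_states"]])
  obj[["_states"]] <- NULL
  rows <- list()
  ef <- .edge_frame(tree)
  for (e in names(obj)) {
    ei <- as.integer(e)
    for (s in obj[[e]]) {
      rows[[length(rows) + 1L]] <-
        data.frame(edge = ei, parent = ef$parent[ei], child = ef$child[ei],
                   start_age = s$start_age, end_age = s$end_age,
                   state = s$state)
    }
  }
  p <- new_painting(tree, do.call(rbind, rows), states)
  validate_painting(tree, p)
  p
}

## as.character() that preserves names (as.character drops them)
.chr_keep_names <- function(x) setNames(as.character(x), names(x))
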
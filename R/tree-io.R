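#' Read a phylogenetic tree from a Newick (or NEXUS) file
#'
#' Reads a rooted tree with branch lengths and validates it for downstream
#' comparative analyses.  Branch lengths are mandatory (they carry time in
#' Myr); ultrametricity is checked against a relative tolerance and flagged,
#' not enforced, because calibrated trees routinely carry rounding noise.
#'
#' @param path Path to a Newick file (or NEXUS when `format = "nexus"`).
#' @param format Either `"newick"` (default, read/write supported) or
#'   `"nexus"` (read-only).
#' @param tol Relative ultrametricity tolerance; a tree is flagged
#'   non-ultrametric when root-to-tip depths differ by more than
#'   `tol * root_age`.
#' @return An [ape::phylo] object with attributes `ultrametric` (logical) and
#'   `root_age` (tree height, Myr).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' attr(tr, "root_age") # 2
#' @export
read_newick <- function(path, format = c("newick", "nexus"), tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- if (format == "newick") {
    tryCatch(ape::read.tree(path),
             error = function(e) stop("malformed Newick in '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  } else {
    ape::read.nexus(path)
  }
  if (is.null(tree)) stop("malformed Newick in '", path,
                          "': parser returned no tree")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_phylogeny(tree, tol = tol)
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants assumed throughout the package: branch lengths
#' present and non-negative, a single root, and (within tolerance)
#' ultrametricity.  The result carries `root_age` and `ultrametric`
#' attributes.
#'
#' @inheritParams read_newick
#' @param tree A `phylo` object.
#' @export
validate_phylogeny <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; time-calibrated branch lengths are ",
         "required")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  attr(tree, "root_age") <- h
  ultra <- (max(depths) - min(depths)) <= tol * h
  attr(tree, "ultrametric") <- ultra
  if (!ultra)
    warning("tree is not ultrametric within tolerance (max depth spread ",
            format(max(depths) - min(depths), digits = 3),
            "); see normalize_depths()", call. = FALSE)
  tree
}

# root-to-node path lengths for all nodes (tips first, ape numbering)
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  pr <- ape::reorder.phylo(tree, "postorder")
  # preorder = reversed postorder edge list
  for (e in rev(seq_len(nrow(pr$edge)))) {
    depth[pr$edge[e, 2]] <- depth[pr$edge[e, 1]] + pr$edge.length[e]
  }
  depth
}

#' Tree height (root age) in branch-length units
#' @param tree A `phylo` object.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Rescale terminal branches so all tips are exactly contemporaneous
#'
#' Repairs small rounding noise in calibrated trees by extending/shortening
#' each terminal branch so every root-to-tip depth equals the maximum depth.
#' Refuses trees whose depth spread exceeds `max_spread` of the height, where
#' the noise is unlikely to be numerical.
#'
#' @param tree A `phylo` object.
#' @param max_spread Maximal relative depth spread considered repairable.
#' @export
normalize_depths <- function(tree, max_spread = 0.01) {
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if ((h - min(depths)) > max_spread * h)
    stop("depth spread exceeds ", max_spread,
         " of tree height; not a rounding artifact")
  term <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + (h - depths)
  validate_phylogeny(tree)
}

#' Prune tips from a phylogeny
#'
#' Removes the given tips, collapsing the resulting degree-2 nodes with their
#' branch lengths summed, so patristic distances among retained tips are
#' preserved exactly.
#'
#' @param tree A `phylo` object.
#' @param drop Character vector of tip labels to remove (may be empty).
#' @export
prune_tips <- function(tree, drop) {
  drop <- as.character(drop)
  if (length(drop) == 0) return(tree)
  missing <- setdiff(drop, tree$tip.label)
  if (length(missing) > 0)
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  if (length(unique(drop)) >= ape::Ntip(tree))
    stop("cannot drop all tips")
  out <- ape::drop.tip(tree, drop)
  validate_phylogeny(out)
}

#' Phylogenetic correlation matrix
#'
#' For an ultrametric tree, the expected correlation of a Brownian trait
#' between two tips is the shared root-to-MRCA path length divided by the
#' tree height.  Returns the tip-by-tip correlation matrix (unit diagonal,
#' positive semi-definite) used as the phylogenetic random-effect structure.
#'
#' @param tree An ultrametric `phylo` object.
#' @export
phylo_correlation <- function(tree) {
  tree <- suppressWarnings(validate_phylogeny(tree))
  if (!isTRUE(attr(tree, "ultrametric")))
    stop("tree is not ultrametric; normalize depths first ",
         "(see normalize_depths())")
  v <- ape::vcv.phylo(tree)
  v / attr(tree, "root_age")
}

#' Read a species trait table
#'
#' CSV with columns `species`, `habit` (either 0/1 or the strings
#' "evergreen"/"deciduous"; anything that is not fully deciduous counts as
#' evergreen) and optional `growth_form`.  Missing habit is kept as `NA` and
#' reported; such species are pruned before Mk/SSE fitting.
#'
#' @param path CSV path.
#' @return data.frame with `species` (character), `habit` (integer 0/1/NA),
#'   optionally `growth_form`.
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("species", "habit") %in% names(df)))
    stop("trait table needs columns 'species' and 'habit'")
  df$species <- as.character(df$species)
  if (anyDuplicated(df$species))
    stop("duplicated species identifiers in trait table")
  df$habit <- encode_habit(df$habit)
  df
}

encode_habit <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) stop("habit must be coded 0/1 (or evergreen/deciduous)")
    return(as.integer(x))
  }
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("deciduous", "1")] <- 1L
  out[x %in% c("evergreen", "semideciduous", "0")] <- 0L
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) stop("unrecognized habit value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' Match tip labels to a species table
#'
#' Exact string matching after normalizing underscores/spaces; unmatched
#' species on either side are reported, never silently dropped.
#'
#' @param tree A `phylo` object.
#' @param species Character vector of species names.
#' @return A list with `tree_index` (positions of each species among the tip
#'   labels, `NA` when unmatched), `unmatched_species`, `unmatched_tips`.
#' @export
match_species <- function(tree, species) {
  norm <- function(x) gsub("[ _]+", "_", trimws(x))
  tl <- norm(tree$tip.label)
  sp <- norm(species)
  idx <- match(sp, tl)
  res <- list(tree_index = idx,
              unmatched_species = species[is.na(idx)],
              unmatched_tips = tree$tip.label[!(tl %in% sp)])
  if (length(res$unmatched_species) > 0)
    message(length(res$unmatched_species),
            " species not found among tip labels")
  if (length(res$unmatched_tips) > 0)
    message(length(res$unmatched_tips), " tips without trait data")
  res
}

#' Named vector of binary tip states aligned to a tree
#'
#' Prunes tips without data (reported) and returns the aligned state vector
#' together with the pruned tree.
#'
#' @param tree A `phylo` object.
#' @param traits Trait table as from [read_trait_table()].
#' @export
align_tip_states <- function(tree, traits) {
  m <- match_species(tree, traits$species)
  keep <- !is.na(m$tree_index) & !is.na(traits$habit)
  states <- setNames(traits$habit[keep], tree$tip.label[m$tree_index[keep]])
  drop <- setdiff(tree$tip.label, names(states))
  tr <- if (length(drop) > 0) prune_tips(tree, drop) else tree
  list(tree = tr, states = states[tr$tip.label])
}

#' Write a tree to Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
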
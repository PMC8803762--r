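# Neighbor-joining trees with bootstrap supports and classification of
# supported duplicated clades as species-specific or lineage-specific.

as_dnabin <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) stop("sequences must be aligned (equal length)")
  m <- do.call(rbind, strsplit(tolower(aln), ""))
  rownames(m) <- names(aln)
  ape::as.DNAbin(m)
}

nj_from_alignment <- function(aln) {
  d <- ape::dist.dna(as_dnabin(aln), model = "JC69", pairwise.deletion = TRUE)
  # a JC-saturated pair (p >= 3/4) has no finite corrected distance; cap it
  # at twice the largest finite distance so NJ stays defined
  if (any(!is.finite(d))) {
    m <- as.matrix(d)
    fin <- m[is.finite(m) & m > 0]
    if (length(fin) == 0) stop("all pairwise distances are saturated")
    m[!is.finite(m)] <- 2 * max(fin)
    d <- stats::as.dist(m)
  }
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Neighbor-joining tree from aligned sequences or a distance matrix
#'
#' Distances are Jukes-Cantor-corrected p-distances with pairwise deletion
#' of gap/ambiguity sites; negative NJ branch lengths are clamped to zero.
#' Tie handling follows the deterministic pair ordering of the underlying
#' implementation, so identical input always yields the identical tree.
#'
#' @param x Named character vector of equal-length aligned nucleotide
#'   sequences (>= 4), or a `dist`/symmetric matrix of precomputed
#'   distances.
#' @return An `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(x) {
  if (inherits(x, "dist") || is.matrix(x)) {
    d <- stats::as.dist(x)
    if (attr(d, "Size") < 4) stop("need at least 4 taxa")
    tr <- ape::nj(d)
    tr$edge.length <- pmax(tr$edge.length, 0)
    return(tr)
  }
  if (length(x) < 4) stop("need at least 4 sequences")
  nj_from_alignment(x)
}

#' NJ tree with column-resampling bootstrap supports
#'
#' Builds the NJ tree, midpoint-roots it, resamples alignment columns
#' `n_reps` times under the given seed, rebuilds an NJ tree per replicate,
#' and writes the percentage of replicates containing each original
#' bipartition into the node labels. The root carries no support (`NA`).
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the supports exactly.
#' @param species_map Optional named vector gene id -> species, stored on
#'   the result; defaults to the prefix before `|` in the labels.
#' @return Object of class `supported_tree`: list with `tree` (rooted
#'   `phylo`, node labels = supports), `species`, `n_reps`.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1L, species_map = NULL) {
  stopifnot(n_reps >= 1)
  base <- phangorn::midpoint(nj_from_alignment(aln), node.labels = "delete")
  ncol_aln <- nchar(aln[[1]])
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      m <- do.call(rbind, strsplit(aln, ""))[, cols, drop = FALSE]
      resampled <- stats::setNames(apply(m, 1, paste, collapse = ""), names(aln))
      nj_from_alignment(resampled)
    })
  })
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  support[1] <- NA  # root: no bipartition
  base$node.label <- as.character(support)
  supported_tree(base, species_map %||%
                   stats::setNames(species_of(base$tip.label), base$tip.label),
                 n_reps = n_reps)
}

#' Construct a supported tree object
#'
#' @param tree An `ape::phylo` with node labels holding bootstrap supports
#'   in percent (empty or `NA` where unknown).
#' @param species_map Named vector leaf label -> species.
#' @param n_reps Bootstrap replicate count, if known.
#' @return Object of class `supported_tree`.
#' @export
supported_tree <- function(tree, species_map = NULL, n_reps = NA_integer_) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  structure(list(tree = tree,
                 species = species_map %||%
                   stats::setNames(species_of(tree$tip.label), tree$tip.label),
                 n_reps = n_reps),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  sup <- suppressWarnings(as.numeric(x$tree$node.label))
  cat(sprintf("supported_tree: %d leaves, %d species, %d supported nodes (> 50)\n",
              length(x$tree$tip.label), length(unique(x$species)),
              sum(sup > 50, na.rm = TRUE)))
  invisible(x)
}

#' Classify supported duplicated clades
#'
#' Walks the rooted tree from the root and calls a node when its bootstrap
#' support strictly exceeds `min_support` and it holds at least two genes:
#' all leaves from one species gives a species-specific duplicated clade;
#' leaves from two or more species give a lineage-specific duplicated clade
#' *provided* some species contributes at least two leaves (a mixed clade
#' without any within-species pair evidences speciation, not duplication,
#' and is not called). Calls are maximal: descendants of a called node are
#' skipped, so no gene is counted twice. The root itself is never called
#' (it has no bipartition support). Unrooted input is midpoint-rooted
#' first, with a message.
#'
#' @param st A `supported_tree`.
#' @param min_support Support threshold in percent (strict `>`; default 50).
#' @return Data frame of calls: `clade_id`, `node`, `call`, `support`,
#'   `n_genes`, `n_species`, `species`, `genes`.
#' @export
classify_clades <- function(st, min_support = 50) {
  stopifnot(inherits(st, "supported_tree"))
  tree <- st$tree
  if (!ape::is.rooted(tree)) {
    message("unrooted tree: applying midpoint rooting")
    tree <- phangorn::midpoint(tree, node.labels = "support")
  }
  if (anyNA(st$species[tree$tip.label])) {
    stop("missing species for leaf ",
         tree$tip.label[is.na(st$species[tree$tip.label])][1])
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  supports <- suppressWarnings(as.numeric(tree$node.label))
  tip_sets <- phangorn::Descendants(tree, type = "tips")
  children <- split(tree$edge[, 2], tree$edge[, 1])
  calls <- list()
  visit <- function(node) {
    if (node <= ntip) return(invisible(NULL))
    sup <- if (node == root) NA_real_ else supports[node - ntip]
    tips <- tree$tip.label[tip_sets[[node]]]
    sp <- unname(st$species[tips])
    callable <- !is.na(sup) && sup > min_support && length(tips) >= 2
    if (callable) {
      if (length(unique(sp)) == 1) {
        calls[[length(calls) + 1L]] <<- data.frame(
          node = node, call = "species_specific", support = sup,
          n_genes = length(tips), n_species = 1L,
          species = sp[1], genes = paste(sort(tips), collapse = ";"))
        return(invisible(NULL))
      }
      if (any(table(sp) >= 2)) {
        calls[[length(calls) + 1L]] <<- data.frame(
          node = node, call = "lineage_specific", support = sup,
          n_genes = length(tips), n_species = length(unique(sp)),
          species = paste(sort(unique(sp)), collapse = ";"),
          genes = paste(sort(tips), collapse = ";"))
        return(invisible(NULL))
      }
    }
    for (ch in children[[as.character(node)]]) visit(ch)
    invisible(NULL)
  }
  visit(root)
  if (length(calls) == 0) {
    return(data.frame(clade_id = character(), node = integer(),
                      call = character(), support = numeric(),
                      n_genes = integer(), n_species = integer(),
                      species = character(), genes = character()))
  }
  out <- do.call(rbind, calls)
  out <- cbind(clade_id = sprintf("clade%03d", seq_len(nrow(out))), out)
  out
}

#' Percentage of genes produced by each duplication type
#'
#' @param calls Data frame from [classify_clades()], or a named numeric
#'   vector of gene counts per call type.
#' @param total Total number of genes in the class (e.g. all TNLs).
#' @return Data frame: `call`, `n_clades`, `n_genes`, `percent` (two
#'   decimals).
#' @export
duplication_proportions <- function(calls, total) {
  stopifnot(total > 0)
  types <- c("species_specific", "lineage_specific")
  if (is.data.frame(calls)) {
    n_genes <- vapply(types, function(tp) sum(calls$n_genes[calls$call == tp]),
                      numeric(1))
    n_clades <- vapply(types, function(tp) sum(calls$call == tp), numeric(1))
  } else {
    n_genes <- vapply(types, function(tp) unname(calls[tp] %||% 0), numeric(1))
    n_genes[is.na(n_genes)] <- 0
    n_clades <- rep(NA_integer_, 2)
  }
  data.frame(call = types, n_clades = n_clades, n_genes = n_genes,
             percent = vapply(n_genes, pct, numeric(1), total = total),
             row.names = NULL)
}

#' Read a Newick tree with bootstrap supports
#'
#' Internal node labels are read as supports. Labels that all lie in
#' `[0, 1]` are taken to be fractions and rescaled to percent with a
#' warning. Unbalanced parentheses abort with the offending character
#' position.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @param species_map Optional named vector leaf -> species.
#' @return A `supported_tree`.
#' @export
read_newick <- function(x, species_map = NULL) {
  txt <- if (file.exists(x)) paste(readLines(x), collapse = "") else x
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("Newick parse error: unbalanced ')' at position ", i)
  }
  if (depth != 0L) stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not read tree")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  nonempty <- !is.na(sup)
  if (any(nonempty) && all(sup[nonempty] >= 0 & sup[nonempty] <= 1)) {
    warning("node supports look like fractions; rescaling to percent")
    sup[nonempty] <- 100 * sup[nonempty]
    tree$node.label <- ifelse(is.na(sup), "", as.character(sup))
  }
  supported_tree(tree, species_map)
}

#' Write a supported tree to Newick
#'
#' Round-trips topology, branch lengths and node supports with
#' [read_newick()].
#'
#' @param st A `supported_tree` (or `phylo`).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_newick <- function(st, path) {
  tree <- if (inherits(st, "supported_tree")) st$tree else st
  ape::write.tree(tree, file = path)
  invisible(path)
}
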
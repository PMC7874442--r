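#' Read a rooted phylogenetic tree from Newick text
#'
#' Thin validating wrapper around \code{ape}: accepts a Newick string or a
#' file path, requires branch lengths on every edge, unique leaf names, and
#' rejects quoted labels and comment blocks so that read/write round trips
#' are byte-deterministic.
#'
#' @param source Newick text (containing a semicolon) or path to a file.
#' @return An \code{ape::phylo} tree.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)  # 5
#' @export
read_tree <- function(source) {
  txt <- if (grepl(";", source, fixed = TRUE)) source else {
    if (!file.exists(source)) stop("tree file not found: ", source)
    paste(readLines(source, warn = FALSE), collapse = "")
  }
  if (grepl("'", txt, fixed = TRUE) || grepl("[", txt, fixed = TRUE))
    stop("quoted labels and [comments] are not supported; ",
         "use plain Newick labels")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: could not parse tree")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (is.null(tree$tip.label) || length(tree$tip.label) < 2L)
    stop("tree must have at least 2 named leaves")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf name(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      any(is.na(tree$edge.length)))
    stop("every branch must carry a length")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) present")
  tree
}

#' Write a tree to Newick
#'
#' @param tree A \code{phylo} tree.
#' @param path Optional file path; if omitted the Newick string is returned.
#' @return Newick string (invisibly when written to a file).
#' @export
write_tree <- function(tree, path = NULL) {
  txt <- ape::write.tree(validate_tree(tree))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Rescale all branch lengths by a constant factor
#'
#' Branch lengths estimated from alignments of closely related genomes are
#' systematically underestimated where homologous recombination is
#' frequent; a user-supplied multiplicative correction compensates.
#' Spanning-subtree distances scale linearly with the factor.
#'
#' @param tree A \code{phylo} tree.
#' @param factor Positive multiplier.
#' @return The rescaled tree (topology unchanged).
#' @export
rescale_tree <- function(tree, factor) {
  validate_tree(tree)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("'factor' must be a single positive number")
  tree$edge.length <- tree$edge.length * factor
  tree
}

# Per-edge bitmask of the leaves below each edge; leaves are numbered by
# tip order (1..N <= 30 so masks fit a double-precision integer exactly).
edge_leaf_masks <- function(tree) {
  N <- length(tree$tip.label)
  if (N > 30L) stop("bitmask machinery supports at most 30 leaves")
  nnode <- tree$Nnode
  below <- numeric(N + nnode)
  below[seq_len(N)] <- 2^(seq_len(N) - 1)
  for (i in ape::postorder(tree)) {  # child edges visited before parents
    parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    below[parent] <- below[parent] + below[child]
  }
  list(mask = below[tree$edge[, 2]], length = tree$edge.length,
       full = 2^N - 1, N = N)
}

spanning_from_masks <- function(masks, subset_mask) {
  # an edge contributes iff the subset both intersects and is not fully
  # contained in the clade below the edge (stem above the MRCA excluded)
  m <- masks$mask
  contrib <- bit_and(subset_mask, m) != 0 &
    bit_and(subset_mask, masks$full - m) != 0
  sum(masks$length[contrib])
}

# bitwAnd for doubles holding exact integers < 2^31 (vectorised)
bit_and <- function(a, b) bitwAnd(as.integer(a), as.integer(b))

#' Total spanning-subtree distance of a genome subset
#'
#' The total evolutionary distance D spanned by a set of leaves: the sum of
#' branch lengths of the tree pruned to that subset, with the stem branch
#' above the subset's most recent common ancestor removed. A single leaf
#' spans distance 0, so the k = 1 mean intersection equals the mean genome
#' size.
#'
#' @param tree A \code{phylo} tree.
#' @param subset Character vector of leaf names (non-empty).
#' @return Total branch length D (single number).
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' spanning_length(tr, c("A", "C"))  # 4
#' @export
spanning_length <- function(tree, subset) {
  validate_tree(tree)
  idx <- match(subset, tree$tip.label)
  if (length(idx) == 0L) stop("'subset' must be non-empty")
  if (anyNA(idx))
    stop("unknown leaf name(s): ",
         paste(subset[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(0)
  masks <- edge_leaf_masks(tree)
  spanning_from_masks(masks, sum(2^(unique(idx) - 1)))
}

#' Spanning-distance distributions for all subset sizes
#'
#' For each k = 1..N, the distribution P(D_k) of the total spanning
#' distance over k-genome subsets. \code{mode = "exact"} enumerates all
#' \eqn{C(N,k)} subsets (a full 2^N sweep using per-edge leaf bitsets,
#' capped by default at N = 20, about 10^6 subsets); \code{mode = "sample"}
#' draws \code{sample_size} uniform k-subsets with replacement per k.
#'
#' @param tree A \code{phylo} tree.
#' @param mode "exact" or "sample".
#' @param sample_size Subsets per k in sample mode (default 10000).
#' @param seed Integer seed for sample mode.
#' @param max_exact_n Cap on N for exact enumeration (default 20).
#' @return Object of class \code{"distance_distribution"}: a list with
#'   \code{n_genomes} and \code{levels}, where \code{levels[[k]]} is a list
#'   with numeric \code{D} and \code{weight} (weights sum to 1).
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' dd <- distance_distributions(tr)
#' dd$levels[[2]]$D  # the three pairwise spanning distances 2, 4, 4
#' @export
distance_distributions <- function(tree, mode = c("exact", "sample"),
                                   sample_size = 10000L, seed = 1L,
                                   max_exact_n = 20L) {
  mode <- match.arg(mode)
  validate_tree(tree)
  N <- length(tree$tip.label)
  masks <- edge_leaf_masks(tree)
  levels <- vector("list", N)
  if (mode == "exact") {
    if (N > max_exact_n)
      stop("exact enumeration capped at N = ", max_exact_n,
           " (2^N subsets); use mode = \"sample\" for larger trees")
    n_subsets <- 2^N - 1
    s <- seq_len(n_subsets)
    D <- numeric(n_subsets)
    full <- masks$full
    for (i in seq_along(masks$mask)) {
      m <- masks$mask[i]
      hit <- bitwAnd(s, m) != 0L & bitwAnd(s, full - m) != 0L
      D[hit] <- D[hit] + masks$length[i]
    }
    pc <- popcount_table(N)[s + 1L]
    for (k in seq_len(N)) {
      Dk <- D[pc == k]
      levels[[k]] <- list(D = Dk, weight = rep(1 / length(Dk), length(Dk)))
    }
    prov <- "exact"
  } else {
    withr::with_seed(seed, {
      for (k in seq_len(N)) {
        if (k == 1L) {
          levels[[k]] <- list(D = 0, weight = 1)
          next
        }
        Dk <- numeric(sample_size)
        for (j in seq_len(sample_size)) {
          sub <- sample.int(N, k)
          Dk[j] <- spanning_from_masks(masks, sum(2^(sub - 1)))
        }
        levels[[k]] <- list(D = Dk,
                            weight = rep(1 / sample_size, sample_size))
      }
    })
    prov <- sprintf("sample(size=%d, seed=%d)", sample_size, seed)
  }
  structure(list(n_genomes = N, levels = levels, provenance = prov),
            class = "distance_distribution")
}

# number of set bits for 0..2^N-1, built by doubling
popcount_table <- function(N) {
  pc <- 0L
  for (i in seq_len(N)) pc <- c(pc, pc + 1L)
  pc
}

#' @export
print.distance_distribution <- function(x, ...) {
  mean_k <- vapply(x$levels, function(l) sum(l$D * l$weight), numeric(1))
  cat("Spanning-distance distributions (", x$provenance, "), N = ",
      x$n_genomes, "\n", sep = "")
  print(stats::setNames(mean_k, paste0("k=", seq_len(x$n_genomes))))
  invisible(x)
}

#' Serialise a distance distribution to a TSV table
#'
#' @param dists A \code{distance_distribution}.
#' @param path File path to write (columns k, D, weight).
#' @export
write_distance_distribution <- function(dists, path) {
  stopifnot(inherits(dists, "distance_distribution"))
  tab <- do.call(rbind, lapply(seq_len(dists$n_genomes), function(k) {
    l <- dists$levels[[k]]
    data.frame(k = k, D = l$D, weight = l$weight)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Tree-averaged model intersection curve
#'
#' The model mean intersection for each subset size k is the exponential
#' decay averaged over the spanning-distance distribution,
#' \eqn{\langle I \rangle_k = \sum_j w_{k,j} \sum_i x_i
#' e^{-\lambda_i D_{k,j}}}, i.e. the discrete weighted form of the
#' integral over P(D_k). Since single genomes span distance 0,
#' \eqn{\langle I \rangle_1 = \sum_i x_i} is the mean genome size.
#'
#' @param classes A \code{\link{gene_classes}} object.
#' @param dists A \code{\link{distance_distributions}} result.
#' @return An \code{\link{intersection_profile}}.
#' @export
mean_intersection_curve <- function(classes, dists) {
  classes <- as_gene_classes(classes)
  if (!inherits(dists, "distance_distribution"))
    stop("'dists' must be a distance_distribution")
  if (any(vapply(dists$levels, is.null, logical(1))))
    stop("distance distribution is missing k levels")
  vals <- vapply(dists$levels, function(l) {
    sum(l$weight * expected_intersection(classes, l$D))
  }, numeric(1))
  intersection_profile(vals)
}

#' Generate a random Yule (pure-birth) tree
#'
#' Seeded pure-birth tree with exponential waiting times between
#' speciations; a synthetic stand-in for the phylogenies of closely
#' related genome clusters. Mean pairwise distance scales as
#' 1/\code{branching_rate}.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param branching_rate Speciation rate (per unit branch length).
#' @param seed Integer seed; same seed gives the identical tree.
#' @return A \code{phylo} tree with leaves t1..tn.
#' @export
generate_random_tree <- function(n_leaves, branching_rate = 1, seed = 1L) {
  if (n_leaves < 2L) stop("'n_leaves' must be >= 2")
  if (branching_rate <= 0) stop("'branching_rate' must be positive")
  tree <- withr::with_seed(seed,
    ape::rphylo(n_leaves, birth = branching_rate, death = 0))
  validate_tree(tree)
}

#' Subsample leaves to a maximum count
#'
#' Clusters larger than a practical cap are represented by a uniform random
#' subset of their genomes; the tree is pruned to the retained leaves
#' (suppressing unifurcations) so spanning distances among retained leaves
#' are unchanged.
#'
#' @param tree A \code{phylo} tree.
#' @param max_n Maximum number of leaves to keep (default 20).
#' @param seed Integer seed for the uniform draw.
#' @return The pruned tree (unchanged if it already has <= max_n leaves).
#' @export
subsample_leaves <- function(tree, max_n = 20L, seed = 1L) {
  validate_tree(tree)
  if (max_n < 2L) stop("'max_n' must be >= 2")
  N <- length(tree$tip.label)
  if (N <= max_n) return(tree)
  keep <- withr::with_seed(seed, sample(tree$tip.label, max_n))
  ape::keep.tip(tree, keep)
}

#' Check a genome cluster's tree against the dataset-selection criteria
#'
#' A cluster is informative for turnover-rate inference when its genomes
#' are sufficiently diverged: the maximum pairwise leaf-to-leaf path
#' distance must reach at least \code{min_depth} substitutions per site.
#' The number of distinct modes in the pairwise-distance distribution is
#' reported as an advisory (clusters whose distances concentrate around
#' only one or two values carry little information about the decay curve),
#' not as a hard filter.
#'
#' @param tree A \code{phylo} tree.
#' @param min_depth Minimum acceptable maximum pairwise distance
#'   (default 0.1).
#' @return A list with \code{pass}, \code{max_pairwise_distance},
#'   \code{min_depth}, and advisory \code{n_distance_modes}.
#' @export
check_cluster_criteria <- function(tree, min_depth = 0.1) {
  validate_tree(tree)
  dmat <- ape::cophenetic.phylo(tree)
  dvec <- dmat[upper.tri(dmat)]
  maxd <- max(dvec)
  # advisory: count modes of the pairwise-distance density
  nmodes <- if (length(dvec) >= 3L && stats::sd(dvec) > 0) {
    dens <- stats::density(dvec)
    y <- dens$y
    sum(diff(sign(diff(y))) == -2L)
  } else 1L
  list(pass = maxd >= min_depth,
       max_pairwise_distance = maxd,
       min_depth = min_depth,
       n_distance_modes = nmodes)
}
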
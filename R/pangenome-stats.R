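#' Construct a gene presence/absence matrix
#'
#' Rows are gene families (orthologous groups, copy number collapsed to
#' presence), columns are genomes. Every family must be present in at
#' least one genome and genome names must be unique.
#'
#' @param incidence Binary matrix (0/1 or logical), rows = families,
#'   columns = genomes; dimnames used as identifiers (generated when
#'   absent).
#' @param classes Optional per-family class labels (character/factor,
#'   length = number of rows), e.g. slow/fast for simulated data.
#' @return Object of class \code{"pangenome_matrix"}.
#' @export
pangenome_matrix <- function(incidence, classes = NULL) {
  m <- as.matrix(incidence)
  if (is.logical(m)) m[] <- as.numeric(m)
  if (!is.numeric(m) || !all(m %in% c(0, 1)))
    stop("incidence entries must all be 0 or 1")
  if (nrow(m) < 1L || ncol(m) < 1L) stop("matrix must be non-empty")
  if (is.null(rownames(m))) rownames(m) <- paste0("fam", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m)))
    stop("duplicate genome names: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  zero <- rowSums(m) == 0
  if (any(zero))
    stop(sum(zero), " gene families present in no genome (first: ",
         rownames(m)[which(zero)[1]], ")")
  if (!is.null(classes)) {
    if (length(classes) != nrow(m))
      stop("'classes' must have one label per gene family")
    classes <- as.character(classes)
  }
  structure(list(incidence = m, classes = classes),
            class = "pangenome_matrix")
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat("Pangenome matrix: ", nrow(x$incidence), " gene families x ",
      ncol(x$incidence), " genomes\n", sep = "")
  if (!is.null(x$classes)) {
    cat("Class composition:\n")
    print(table(x$classes))
  }
  invisible(x)
}

#' Gene commonality counts of a pangenome matrix
#'
#' Tallies, for each k = 1..N, the number of gene families present in
#' exactly k genomes — the empirical U-shaped commonality distribution.
#'
#' @param matrix A \code{\link{pangenome_matrix}}.
#' @return A \code{\link{commonality}} object with integer counts summing
#'   to the pangenome size (number of rows).
#' @export
commonality_counts <- function(matrix) {
  stopifnot(inherits(matrix, "pangenome_matrix"))
  N <- ncol(matrix$incidence)
  commonality(tabulate(rowSums(matrix$incidence), nbins = N))
}

#' Number of genes common to a genome subset
#'
#' The genome intersection I for one chosen subset: the count of gene
#' families present in every genome of the subset.
#'
#' @param matrix A \code{\link{pangenome_matrix}}.
#' @param subset Character vector of genome names (non-empty).
#' @return Integer count.
#' @export
subset_intersection <- function(matrix, subset) {
  stopifnot(inherits(matrix, "pangenome_matrix"))
  idx <- match(subset, colnames(matrix$incidence))
  if (length(idx) == 0L) stop("'subset' must be non-empty")
  if (anyNA(idx))
    stop("unknown genome name(s): ",
         paste(subset[is.na(idx)], collapse = ", "))
  sum(rowSums(matrix$incidence[, unique(idx), drop = FALSE]) ==
        length(unique(idx)))
}

#' Mean genome intersections of a pangenome matrix
#'
#' The uniform mean \eqn{\langle I \rangle_k} of the intersection over all
#' \eqn{C(N,k)} k-genome subsets. The default \code{"transform"} mode uses
#' the exact combinatorial identity \eqn{\langle I \rangle_n = \sum_m g_m
#' C(m,n) / C(N,n)} (a family in exactly m genomes lies in C(m,n) of the
#' subsets), keeping integer numerators so the result is exact and costs
#' O(N * families). \code{"enumerate"} evaluates every subset directly and
#' is retained as an oracle and for per-subset output; both modes agree
#' exactly.
#'
#' @param matrix A \code{\link{pangenome_matrix}}.
#' @param mode "transform" (default) or "enumerate".
#' @param max_enumerate_n Cap on N for enumerate mode (default 20).
#' @return An \code{\link{intersection_profile}} with exact numerators.
#' @export
mean_intersection_profile <- function(matrix,
                                      mode = c("transform", "enumerate"),
                                      max_enumerate_n = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "pangenome_matrix"))
  N <- ncol(matrix$incidence)
  if (mode == "transform") {
    g <- commonality_counts(matrix)$counts
    S <- vapply(seq_len(N), function(n) sum(g[n:N] * choose(n:N, n)),
                numeric(1))
  } else {
    if (N > max_enumerate_n)
      stop("enumerate mode capped at N = ", max_enumerate_n,
           "; use transform mode")
    per <- per_subset_intersections(matrix)
    S <- vapply(seq_len(N), function(k) sum(per$I[per$k == k]), numeric(1))
  }
  intersection_profile(S / choose(N, seq_len(N)), numerators = S)
}

#' Intersections of every genome subset
#'
#' Enumerates all 2^N - 1 non-empty subsets, returning the subset size k,
#' its spanning bitmask, and the intersection count — the raw material for
#' intersection-vs-distance plots.
#'
#' @param matrix A \code{\link{pangenome_matrix}}.
#' @param tree Optional \code{phylo} tree with matching leaf names; when
#'   supplied a column \code{D} of spanning distances is included.
#' @return data.frame with columns k, I (and D when a tree is given).
#' @export
per_subset_intersections <- function(matrix, tree = NULL) {
  stopifnot(inherits(matrix, "pangenome_matrix"))
  m <- matrix$incidence
  N <- ncol(m)
  if (N > 20L) stop("subset enumeration capped at N = 20")
  s <- seq_len(2^N - 1)
  pc <- popcount_table(N)[s + 1L]
  # row bitmask of each family's phyletic pattern
  pat <- as.integer(m %*% 2^(seq_len(N) - 1))
  pat_count <- table(pat)
  pat_vals <- as.integer(names(pat_count))
  I <- integer(length(s))
  for (j in seq_along(pat_vals)) {
    p <- pat_vals[j]
    hit <- bitwAnd(s, p) == s  # subset contained in the pattern
    I[hit] <- I[hit] + as.integer(pat_count[j])
  }
  out <- data.frame(k = pc, I = I)
  if (!is.null(tree)) {
    validate_tree(tree)
    if (!setequal(tree$tip.label, colnames(m)))
      stop("tree leaves and genome names differ: ",
           paste(c(setdiff(tree$tip.label, colnames(m)),
                   setdiff(colnames(m), tree$tip.label)), collapse = ", "))
    # reorder masks to the matrix's genome order
    perm <- match(colnames(m), tree$tip.label)
    masks <- edge_leaf_masks(tree)
    D <- numeric(length(s))
    # remap each edge mask from tip order to matrix column order
    remap <- function(mask) {
      bits <- which(bitwAnd(mask, 2^(seq_len(N) - 1)) != 0)
      sum(2^(match(bits, perm) - 1))
    }
    masks$mask <- vapply(masks$mask, remap, numeric(1))
    full <- masks$full
    for (i in seq_along(masks$mask)) {
      mm <- masks$mask[i]
      hit <- bitwAnd(s, as.integer(mm)) != 0L &
        bitwAnd(s, as.integer(full - mm)) != 0L
      D[hit] <- D[hit] + masks$length[i]
    }
    out$D <- D
  }
  out
}

#' Core and singleton errors of a model fit
#'
#' The two diagnostic statistics of fit quality at the ends of the
#' U-shaped distribution: signed relative errors
#' \eqn{(g^{model} - g^{data}) / g^{data}} for the core genome size
#' \eqn{g_N} and the number of singletons \eqn{g_1}, plus the pangenome
#' totals.
#'
#' @param model_g,data_g \code{\link{commonality}} objects with equal N;
#'   data must have positive g_1 and g_N.
#' @return List with \code{core_error}, \code{singleton_error},
#'   \code{pangenome_model}, \code{pangenome_data}.
#' @export
fit_errors <- function(model_g, data_g) {
  stopifnot(inherits(model_g, "commonality"),
            inherits(data_g, "commonality"))
  if (model_g$n_genomes != data_g$n_genomes)
    stop("model and data have different N")
  N <- data_g$n_genomes
  if (data_g$counts[1] <= 0 || data_g$counts[N] <= 0)
    stop("data g_1 and g_N must be positive for relative errors")
  list(core_error = (model_g$counts[N] - data_g$counts[N]) /
         data_g$counts[N],
       singleton_error = (model_g$counts[1] - data_g$counts[1]) /
         data_g$counts[1],
       pangenome_model = sum(model_g$counts),
       pangenome_data = sum(data_g$counts))
}
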
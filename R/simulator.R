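#' Simulation parameters for gene content evolution
#'
#' Defines a 1-3 class Gillespie simulation of gene gain and loss along a
#' tree. Each class i has an initial genome size \code{x} (genes) and a
#' total per-genome loss rate \code{loss} (events per unit branch length).
#' The regime selects which model assumptions hold:
#' \describe{
#'   \item{igp-cgs}{infinite gene pool, constant genome size: every gain
#'     introduces a brand-new gene and gain rate equals loss rate
#'     (\eqn{P^+_i = P^-_i}).}
#'   \item{fgp-cgs}{finite gene pool: gains draw from a fixed pool of
#'     \code{pool} genes per class, so families can be regained;
#'     \eqn{P^+_i = P^-_i}.}
#'   \item{igp-vgs}{infinite pool, varying genome size: gain rates
#'     \code{gain} may differ from loss rates, letting genomes grow or
#'     shrink.}
#' }
#'
#' @param x Integer vector of initial class sizes.
#' @param loss Numeric vector of total per-genome loss rates P- per class.
#' @param regime One of "igp-cgs", "fgp-cgs", "igp-vgs".
#' @param pool (fgp-cgs) integer pool sizes L_i >= x_i per class.
#' @param gain (igp-vgs) gain rates P+ per class; defaults to \code{loss}.
#' @param labels Optional class labels (default slow/.../fast by loss/x).
#' @param fgp_gain_mode (fgp-cgs) "absent" (default): a gain draws
#'   uniformly from pool members currently absent from the genome, so each
#'   gain adds exactly one gene; "any": draws from the whole pool and is a
#'   no-op if the gene is already present.
#' @return Object of class \code{"sim_params"}.
#' @examples
#' sim_params(x = c(3730, 749), loss = c(3730 * 0.04, 749 * 1.98))
#' @export
sim_params <- function(x, loss,
                       regime = c("igp-cgs", "fgp-cgs", "igp-vgs"),
                       pool = NULL, gain = NULL, labels = NULL,
                       fgp_gain_mode = c("absent", "any")) {
  regime <- match.arg(regime)
  fgp_gain_mode <- match.arg(fgp_gain_mode)
  k <- length(x)
  if (k < 1L || k > 3L) stop("1 to 3 gene classes supported")
  if (length(loss) != k) stop("'loss' must match 'x' in length")
  if (any(x < 0) || any(x %% 1 != 0)) stop("'x' must be non-negative integers")
  if (any(!is.finite(loss)) || any(loss < 0))
    stop("'loss' rates must be finite and >= 0")
  if (regime == "fgp-cgs") {
    if (is.null(pool) || length(pool) != k)
      stop("fgp-cgs requires one pool size per class")
    if (any(pool < x)) stop("pool sizes L_i must be >= initial sizes x_i")
  } else if (!is.null(pool)) {
    stop("'pool' only applies to the fgp-cgs regime")
  }
  if (regime == "igp-vgs") {
    if (is.null(gain)) gain <- loss
    if (length(gain) != k || any(!is.finite(gain)) || any(gain < 0))
      stop("igp-vgs gain rates must be finite, >= 0, one per class")
  } else {
    if (!is.null(gain)) stop("'gain' only applies to the igp-vgs regime")
    gain <- loss  # CGS: P+ = P-
  }
  if (is.null(labels)) {
    # per-gene decay lambda = P-/x orders classes slow -> fast
    lam <- ifelse(x > 0, loss / x, Inf)
    base <- switch(as.character(k), "1" = "all",
                   "2" = c("slow", "fast"),
                   "3" = c("slow", "intermediate", "fast"))
    labels <- base[order(order(lam))]
  }
  structure(list(x = as.integer(x), loss = loss, gain = gain,
                 regime = regime, pool = if (is.null(pool)) NULL else
                   as.integer(pool),
                 labels = labels, fgp_gain_mode = fgp_gain_mode),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Gillespie simulation parameters [", x$regime, "]\n", sep = "")
  df <- data.frame(class = x$labels, x = x$x, loss = x$loss,
                   gain = x$gain)
  if (!is.null(x$pool)) df$pool <- x$pool
  print(df, row.names = FALSE)
  invisible(x)
}

#' Exponential waiting time between gene turnover events
#'
#' Draws the Gillespie waiting time \eqn{\tau = -\ln(r) / a_0} where r is
#' uniform on (0, 1] and \eqn{a_0 = P^+ + P^-} is the total event rate.
#' A non-positive total rate means no event can occur: \code{Inf} is
#' returned so the caller's branch clock simply runs out.
#'
#' @param a0 Total event rate (sum of all gain and loss rates).
#' @param r Optional uniform(0,1] variate (drawn internally when NULL;
#'   exposed for testing).
#' @return Waiting time (Inf when a0 <= 0).
#' @export
draw_waiting_time <- function(a0, r = NULL) {
  if (a0 <= 0) return(Inf)
  if (is.null(r)) r <- stats::runif(1)
  -log(r) / a0
}

# Internal genome state: per class a vector of gene ids with an active
# length (swap-delete / amortised append keeps events O(1)).
new_state <- function(params) {
  k <- length(params$x)
  genes <- vector("list", k)
  for (i in seq_len(k)) {
    n <- params$x[i]
    genes[[i]] <- if (params$regime == "fgp-cgs")
      seq_len(max(n, 1L))[seq_len(n)] else seq_len(n)
    length(genes[[i]]) <- max(n, 1L)  # capacity >= 1
  }
  # the id counter is an environment: a reference shared by every copy of
  # the state, so gene ids stay globally unique across sibling lineages
  counter <- new.env(parent = emptyenv())
  counter$id <- max(params$x, 0L) + 1L
  list(genes = genes, n = params$x, counter = counter)
}

state_gene_sets <- function(state, params) {
  lapply(seq_along(state$n), function(i)
    state$genes[[i]][seq_len(state$n[i])])
}

#' Evolve a genome along one branch
#'
#' Runs the Gillespie scheme for a single branch: waiting times are drawn
#' with total rate \eqn{a_0 = \sum_i (P^+_i + P^-_i)} until the branch
#' length is exhausted; each event selects a class and gain-vs-loss with
#' probability proportional to its rate. A loss removes a uniformly chosen
#' present gene of that class (no-op when the class is empty). A gain adds
#' a never-seen gene id (infinite pool) or a uniformly drawn absent pool
#' member (finite pool). Under the constant-genome-size regimes the total
#' per-genome rates are constants along the branch (the literal scheme);
#' under varying genome size the gain rate is constant (acquisition from
#' outside does not depend on current content) while the loss rate tracks
#' the class size, \eqn{P^-_i(t) = \lambda_i n_i(t)} with
#' \eqn{\lambda_i = P^-_i(0)/x_i}, since deletion attempts scale with the
#' number of resident genes.
#'
#' @param state Genome state as produced by \code{simulate_pangenome}'s
#'   internals (list with per-class gene id vectors).
#' @param length Branch length (>= 0).
#' @param params A \code{\link{sim_params}} object.
#' @return The evolved state.
#' @export
evolve_branch <- function(state, length, params) {
  if (length < 0) stop("branch length must be >= 0")
  k <- length(params$x)
  vgs <- params$regime == "igp-vgs"
  # per-gene loss rates: under varying genome size the deletion attempt
  # rate scales with current gene content, so the class loss rate is
  # lambda_i * n_i(t); under constant genome size n_i stays at x_i and
  # the total rates are constants
  lambda <- ifelse(params$x > 0, params$loss / params$x, 0)
  current_rates <- function() {
    if (vgs) c(params$gain, lambda * state$n)
    else c(params$gain, params$loss)  # per-class gain then loss
  }
  rates <- current_rates()
  a0 <- sum(rates)
  if (a0 <= 0 || length == 0) return(state)
  t <- draw_waiting_time(a0)
  while (t <= length) {
    ev <- findInterval(stats::runif(1), cumsum(rates) / a0) + 1L
    if (ev <= k) {                      # gain in class ev
      i <- ev
      if (params$regime == "fgp-cgs") {
        present <- state$genes[[i]][seq_len(state$n[i])]
        if (params$fgp_gain_mode == "absent") {
          absent <- setdiff(seq_len(params$pool[i]), present)
          if (length(absent) > 0L) {
            gid <- if (length(absent) == 1L) absent else
              absent[sample.int(length(absent), 1L)]
            state <- push_gene(state, i, gid)
          }
        } else {
          gid <- sample.int(params$pool[i], 1L)
          if (!(gid %in% present)) state <- push_gene(state, i, gid)
        }
      } else {                          # infinite pool: brand-new id
        gid <- state$counter$id
        state$counter$id <- gid + 1L
        state <- push_gene(state, i, gid)
      }
    } else {                            # loss in class ev - k
      i <- ev - k
      if (state$n[i] > 0L) {
        j <- sample.int(state$n[i], 1L)
        state$genes[[i]][j] <- state$genes[[i]][state$n[i]]
        state$n[i] <- state$n[i] - 1L
      }
    }
    if (vgs) {
      rates <- current_rates()
      a0 <- sum(rates)
      if (a0 <= 0) break
    }
    t <- t + draw_waiting_time(a0)
  }
  state
}

push_gene <- function(state, i, gid) {
  n <- state$n[i] + 1L
  if (n > length(state$genes[[i]]))     # grow capacity geometrically
    length(state$genes[[i]]) <- 2L * length(state$genes[[i]])
  state$genes[[i]][n] <- gid
  state$n[i] <- n
  state
}

#' Simulate a pangenome along a phylogeny
#'
#' Gillespie simulation of gene content evolution: the root genome starts
#' with x_i genes per class (the first x_i pool members under a finite
#' pool); the state is copied to each child and evolved along the
#' connecting branch; the leaf gene sets are assembled into a binary gene
#' family x genome matrix over all families observed in at least one
#' leaf. Branches are visited in a fixed preorder and all randomness comes
#' from one stream seeded with \code{seed}, so results are fully
#' reproducible.
#'
#' @param tree A \code{phylo} tree with named leaves.
#' @param params A \code{\link{sim_params}} object.
#' @param seed Integer seed.
#' @return A \code{\link{pangenome_matrix}} with per-family class labels.
#' @examples
#' tr <- generate_random_tree(6, seed = 1)
#' pm <- simulate_pangenome(tr, sim_params(x = 200, loss = 20), seed = 1)
#' commonality_counts(pm)
#' @export
simulate_pangenome <- function(tree, params, seed = 1L) {
  validate_tree(tree)
  stopifnot(inherits(params, "sim_params"))
  N <- length(tree$tip.label)
  n_class <- length(params$x)
  root <- N + 1L
  # children of each internal node, in stored edge order (deterministic)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  leaf_sets <- vector("list", N)
  withr::with_seed(as.integer(seed), {
    recurse <- function(node, state) {
      for (e in kids[[as.character(node)]]) {
        child <- tree$edge[e, 2]
        st <- evolve_branch(state, tree$edge.length[e], params)
        if (child <= N) leaf_sets[[child]] <<- state_gene_sets(st, params)
        else recurse(child, st)
      }
    }
    recurse(root, new_state(params))
  })
  # assemble union of families per class
  inc_list <- list(); class_vec <- character(0); fam_names <- character(0)
  for (i in seq_len(n_class)) {
    ids <- sort(unique(unlist(lapply(leaf_sets, `[[`, i))))
    if (length(ids) == 0L) next
    inc <- vapply(leaf_sets, function(ls) as.numeric(ids %in% ls[[i]]),
                  numeric(length(ids)))
    inc <- matrix(inc, nrow = length(ids))
    inc_list[[length(inc_list) + 1L]] <- inc
    class_vec <- c(class_vec, rep(params$labels[i], length(ids)))
    fam_names <- c(fam_names,
                   paste0(params$labels[i], "_", ids))
  }
  m <- do.call(rbind, inc_list)
  colnames(m) <- tree$tip.label
  rownames(m) <- fam_names
  pangenome_matrix(m, classes = class_vec)
}

#' Random presence/absence matrix fixture
#'
#' Tree-free fixture for exercising the combinatorial transforms: each
#' gene family draws an occupancy k from \code{occupancy_law} and is then
#' placed in a uniform random k-subset of genomes.
#'
#' @param n_genomes,n_families Positive integers.
#' @param occupancy_law Either "uniform" (k uniform on 1..N), a numeric
#'   vector of length N of probabilities for k = 1..N, or a single integer
#'   giving a point mass.
#' @param seed Integer seed.
#' @return A \code{\link{pangenome_matrix}}.
#' @export
random_matrix_fixture <- function(n_genomes, n_families,
                                  occupancy_law = "uniform", seed = 1L) {
  if (n_genomes < 1L || n_families < 1L) stop("sizes must be >= 1")
  N <- as.integer(n_genomes)
  probs <- if (identical(occupancy_law, "uniform")) rep(1 / N, N)
  else if (is.numeric(occupancy_law) && length(occupancy_law) == 1L) {
    k0 <- as.integer(occupancy_law)
    if (k0 < 1L || k0 > N) stop("point-mass occupancy outside 1..N")
    replace(numeric(N), k0, 1)
  } else if (is.numeric(occupancy_law) && length(occupancy_law) == N) {
    if (any(occupancy_law < 0) || sum(occupancy_law) <= 0)
      stop("invalid occupancy law")
    occupancy_law / sum(occupancy_law)
  } else stop("invalid occupancy law specification")
  withr::with_seed(as.integer(seed), {
    ks <- sample.int(N, n_families, replace = TRUE, prob = probs)
    m <- matrix(0, n_families, N)
    for (f in seq_len(n_families)) m[f, sample.int(N, ks[f])] <- 1
  })
  colnames(m) <- paste0("g", seq_len(N))
  rownames(m) <- paste0("fam", seq_len(n_families))
  pangenome_matrix(m)
}
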
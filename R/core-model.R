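#' Fixation probability of a gene gain or loss
#'
#' Kimura-form probability that a mutation of selective effect \code{S}
#' reaches fixation, \eqn{F(S) = S / (1 - e^{-S})}. The singularity at
#' \eqn{S = 0} is removable with limit 1; near zero the function is
#' evaluated by its series expansion to avoid 0/0.
#'
#' @param S Selection coefficient (finite real, signed); vectorised.
#' @return Numeric vector of fixation probabilities (relative to neutral).
#' @examples
#' fixation_probability(0)    # 1
#' fixation_probability(1)    # 1.581977
#' @export
fixation_probability <- function(S) {
  if (!is.numeric(S) || any(!is.finite(S)))
    stop("'S' must be finite numeric")
  out <- numeric(length(S))
  small <- abs(S) < 1e-5
  # series: S/(1 - e^-S) = 1 + S/2 + S^2/12 - S^4/720 + ...
  s <- S[small]
  out[small] <- 1 + s / 2 + s^2 / 12
  s <- S[!small]
  out[!small] <- s / (1 - exp(-s))
  out
}

#' Gene gain and loss rates in the weak-mutation limit
#'
#' In the weak-mutation (sequential-fixation) limit the genome-wide gain and
#' loss rates factor into mutational input times fixation probability:
#' \eqn{P^+ = \alpha F(S)} and \eqn{P^- = \beta F(-S)}, where \eqn{\alpha}
#' and \eqn{\beta} are the raw acquisition and deletion rates and \eqn{S}
#' the selective benefit of carrying one extra gene. Note the identity
#' \eqn{F(S) - F(-S) = S}, so \eqn{P^+ - P^-} carries the sign of selection
#' when \eqn{\alpha = \beta}.
#'
#' @param alpha Acquisition (attempt) rate, non-negative.
#' @param beta Deletion (attempt) rate, non-negative.
#' @param S Selection coefficient for a single gene acquisition.
#' @return Named list with elements \code{gain} (\eqn{P^+}) and
#'   \code{loss} (\eqn{P^-}).
#' @export
weak_mutation_rates <- function(alpha, beta, S) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha < 0 || beta < 0)
    stop("'alpha' and 'beta' must be non-negative rates")
  list(gain = alpha * fixation_probability(S),
       loss = beta * fixation_probability(-S))
}

#' Define gene turnover classes
#'
#' A pangenome model is a mixture of gene classes, each with an expected
#' gene count \code{size} (x_i) and a per-gene loss rate \code{decay}
#' (lambda_i, per unit branch length). Classes are canonicalised in
#' ascending order of decay rate (slow genes first) so that fitted
#' parameters are identifiable up to label switching.
#'
#' @param size Numeric vector of expected gene counts, one per class.
#' @param decay Numeric vector of per-gene loss rates, same length.
#' @param labels Optional character labels; defaults to slow/intermediate/
#'   fast naming for up to three classes, otherwise class1..classK.
#' @return An object of class \code{"gene_classes"}: a data.frame with
#'   columns \code{label}, \code{size}, \code{decay}, rows sorted by decay.
#' @examples
#' gene_classes(size = c(749, 3730), decay = c(1.98, 0.04))
#' @export
gene_classes <- function(size, decay, labels = NULL) {
  if (length(size) != length(decay) || length(size) < 1L)
    stop("'size' and 'decay' must be equal-length, non-empty")
  if (any(!is.finite(size)) || any(size < 0))
    stop("class sizes must be finite and >= 0")
  if (any(!is.finite(decay)) || any(decay < 0))
    stop("decay rates must be finite and >= 0")
  k <- length(size)
  if (is.null(labels)) {
    labels <- switch(as.character(k),
      "1" = "all",
      "2" = c("slow", "fast"),
      "3" = c("slow", "intermediate", "fast"),
      paste0("class", seq_len(k)))
    labels <- labels[order(order(decay))]  # label by rank of decay
  }
  if (anyDuplicated(labels))
    stop("class labels must be distinct")
  ord <- order(decay)
  out <- data.frame(label = labels[ord], size = size[ord],
                    decay = decay[ord], stringsAsFactors = FALSE)
  class(out) <- c("gene_classes", "data.frame")
  out
}

#' @export
print.gene_classes <- function(x, ...) {
  cat("Gene turnover classes (", nrow(x), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Expected genome intersection at a given evolutionary distance
#'
#' Under the infinite-gene-pool, constant-genome-size model the number of
#' genes shared by a set of genomes spanning total tree distance D decays
#' exponentially in each class: \eqn{I(D) = \sum_i x_i e^{-\lambda_i D}}.
#'
#' @param classes A \code{\link{gene_classes}} object.
#' @param D Total spanning-subtree distance(s), non-negative; vectorised.
#' @return Expected number of shared genes for each D.
#' @examples
#' cls <- gene_classes(100, 0.1)
#' expected_intersection(cls, 2)  # 100 * exp(-0.2) = 81.873
#' @export
expected_intersection <- function(classes, D) {
  classes <- as_gene_classes(classes)
  if (any(!is.finite(D)) || any(D < 0))
    stop("'D' must be finite and >= 0")
  vapply(D, function(d) sum(classes$size * exp(-classes$decay * d)),
         numeric(1))
}

as_gene_classes <- function(x) {
  if (inherits(x, "gene_classes")) return(x)
  if (is.list(x) && !is.null(x$size) && !is.null(x$decay))
    return(gene_classes(x$size, x$decay))
  stop("expected a 'gene_classes' object")
}

#' Construct an intersection profile
#'
#' The mean genome intersection \eqn{\langle I \rangle_k} for
#' k = 1..N is the average, over all \eqn{C(N,k)} k-genome subsets, of the
#' number of genes common to all members of the subset. When the profile is
#' derived from data the exact integer subset-sum numerators S_k (with
#' \eqn{\langle I \rangle_k = S_k / C(N,k)}) can be carried so that
#' downstream inclusion-exclusion stays in exact integer arithmetic.
#'
#' @param values Numeric vector \eqn{\langle I \rangle_1 ...
#'   \langle I \rangle_N}, non-increasing in k.
#' @param numerators Optional integer-valued vector S_k with
#'   values = numerators / choose(N, k).
#' @return Object of class \code{"intersection_profile"}.
#' @export
intersection_profile <- function(values, numerators = NULL) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector")
  if (any(!is.finite(values)) || any(values < -1e-9))
    stop("intersection values must be finite and non-negative")
  N <- length(values)
  if (!is.null(numerators)) {
    if (length(numerators) != N)
      stop("'numerators' must have length N")
    if (max(abs(numerators - values * choose(N, seq_len(N)))) > 1e-6)
      stop("'numerators' inconsistent with 'values'")
  }
  structure(list(n_genomes = N, values = as.numeric(values),
                 numerators = numerators),
            class = "intersection_profile")
}

#' @export
print.intersection_profile <- function(x, ...) {
  cat("Mean genome intersections <I>_k, N =", x$n_genomes, "\n")
  print(stats::setNames(x$values, paste0("k=", seq_len(x$n_genomes))))
  invisible(x)
}

#' Construct a gene commonality distribution
#'
#' Gene commonality \eqn{g_k} is the number of gene families present in
#' exactly k of the N genomes; it is the familiar U-shaped gene frequency
#' spectrum of prokaryotic pangenomes. The cumulative commonality
#' \eqn{J_k = \sum_{n \le k} g_n} is carried alongside; \eqn{J_N} is the
#' pangenome size.
#'
#' @param counts Numeric vector g_1..g_N (integers when empirical).
#' @return Object of class \code{"commonality"} with fields
#'   \code{n_genomes}, \code{counts}, \code{cumulative}.
#' @export
commonality <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 1L)
    stop("'counts' must be a non-empty numeric vector")
  if (any(!is.finite(counts)))
    stop("commonality counts must be finite")
  structure(list(n_genomes = length(counts), counts = as.numeric(counts),
                 cumulative = cumsum(as.numeric(counts))),
            class = "commonality")
}

#' @export
print.commonality <- function(x, ...) {
  cat("Gene commonality g_k, N =", x$n_genomes,
      "; pangenome =", x$cumulative[x$n_genomes], "\n")
  print(stats::setNames(x$counts, paste0("k=", seq_len(x$n_genomes))))
  invisible(x)
}

#' Inclusion-exclusion coefficient q_n^(k)
#'
#' The exact integer coefficient \eqn{q_n^{(k)} = C(n,k) C(N,n)} appearing
#' in the transform from mean intersections to gene commonality.
#' Out-of-range arguments raise an error (rather than returning 0) to
#' surface index bugs early.
#'
#' @param n,k,N Integers with 1 <= k <= n <= N.
#' @return The exact integer \eqn{C(n,k) C(N,n)} (as a double; exact below
#'   2^53).
#' @export
q_coefficient <- function(n, k, N) {
  if (any(c(n, k, N) %% 1 != 0)) stop("'n', 'k', 'N' must be integers")
  if (k < 1 || k > n || n > N)
    stop("require 1 <= k <= n <= N (got k=", k, ", n=", n, ", N=", N, ")")
  choose(n, k) * choose(N, n)
}

#' Gene commonality from mean genome intersections
#'
#' The exact inclusion-exclusion transform
#' \deqn{g_k = \sum_{n=k}^{N} (-1)^{n-k} C(n,k) C(N,n) \langle I \rangle_n.}
#' This relation holds for any gene presence/absence data, with no model
#' assumption. When the profile carries exact integer numerators S_n
#' (\eqn{\langle I \rangle_n = S_n / C(N,n)}) the sum collapses to
#' \eqn{g_k = \sum_n (-1)^{n-k} C(n,k) S_n} and is evaluated in exact
#' integer arithmetic, immune to the catastrophic cancellation that the
#' alternating series (coefficients up to ~3e9 at N = 20) otherwise causes.
#' Float profiles (model predictions) use Kahan-compensated summation.
#'
#' @param profile An \code{\link{intersection_profile}}.
#' @param negative_tol Absolute tolerance below zero before a float-path
#'   result triggers an inconsistency warning (default 1e-6 of the largest
#'   term).
#' @return A \code{\link{commonality}} object.
#' @examples
#' # three toy genomes {a,b,c}, {b,c,d}, {c,d,e}
#' p <- intersection_profile(c(3, 5/3, 1), numerators = c(9, 5, 1))
#' commonality_from_intersections(p)$counts  # 2 2 1
#' @export
commonality_from_intersections <- function(profile, negative_tol = NULL) {
  if (!inherits(profile, "intersection_profile"))
    stop("'profile' must be an intersection_profile")
  N <- profile$n_genomes
  g <- numeric(N)
  if (!is.null(profile$numerators)) {
    S <- profile$numerators
    for (k in seq_len(N)) {
      n <- k:N
      g[k] <- sum((-1)^(n - k) * choose(n, k) * S[n])
    }
    if (any(g < 0))
      warning("negative commonality from exact transform: ",
              "input is not a consistent uniform-subset mean")
  } else {
    I <- profile$values
    maxterm <- 0
    for (k in seq_len(N)) {
      # Kahan summation over the alternating series
      s <- 0; c0 <- 0
      for (n in k:N) {
        term <- (-1)^(n - k) * choose(n, k) * choose(N, n) * I[n]
        maxterm <- max(maxterm, abs(term))
        y <- term - c0
        t <- s + y
        c0 <- (t - s) - y
        s <- t
      }
      g[k] <- s
    }
    if (is.null(negative_tol)) negative_tol <- 1e-6 * max(maxterm, 1)
    if (any(g < -negative_tol))
      warning("materially negative commonality values (min ",
              format(min(g)), "); intersection profile is inconsistent ",
              "with any gene presence/absence matrix")
  }
  commonality(g)
}

#' Mean genome intersections from gene commonality
#'
#' Exact inverse of \code{\link{commonality_from_intersections}}: a family
#' present in exactly m genomes lies in \eqn{C(m,n)} of the \eqn{C(N,n)}
#' n-subsets, so \eqn{\langle I \rangle_n = \sum_{m \ge n} g_m C(m,n) /
#' C(N,n)}. Numerators are integer-exact, making the round trip with the
#' forward transform an identity.
#'
#' @param dist A \code{\link{commonality}} object.
#' @return An \code{\link{intersection_profile}} carrying exact numerators
#'   when the counts are integers.
#' @export
intersections_from_commonality <- function(dist) {
  if (!inherits(dist, "commonality"))
    stop("'dist' must be a commonality object")
  N <- dist$n_genomes
  g <- dist$counts
  S <- vapply(seq_len(N), function(n) sum(g[n:N] * choose(n:N, n)),
              numeric(1))
  vals <- S / choose(N, seq_len(N))
  integral <- max(abs(g - round(g))) < 1e-9
  intersection_profile(vals, numerators = if (integral) S else NULL)
}

#' Cumulative gene commonality
#'
#' \eqn{J_k = \sum_{n=1}^k g_n}: the number of gene families present in at
#' most k genomes. \eqn{J_N} equals the pangenome size.
#'
#' @param dist A \code{\link{commonality}} object.
#' @return Numeric vector J_1..J_N.
#' @export
cumulative_commonality <- function(dist) {
  if (!inherits(dist, "commonality"))
    stop("'dist' must be a commonality object")
  dist$cumulative
}
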
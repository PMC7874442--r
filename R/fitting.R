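#' Fit configuration
#'
#' Controls which statistic is fitted, the number of gene classes, the
#' objective scale, and the multistart search. The model curves are linear
#' in the class sizes x_i for all three statistics, so the linear-scale
#' fit profiles them out with non-negative least squares and searches only
#' over the decay rates (variable projection); the log-scale objective
#' refines the full parameter vector from the linear solution.
#'
#' @param statistic "meanI" (mean genome intersections), "commonality"
#'   (g_k) or "cumulative" (J_k).
#' @param n_classes 1, 2 or 3 gene classes.
#' @param scale "linear" (default) or "log" residuals.
#' @param n_starts Multistart count (Latin hypercube over log decay,
#'   default 32).
#' @param lambda_bounds Decay-rate search range (default 1e-4..1e2).
#' @param seed Seed for the start draw.
#' @param reltol Optimiser convergence tolerance.
#' @return Object of class \code{"fit_config"}.
#' @export
fit_config <- function(statistic = c("meanI", "commonality", "cumulative"),
                       n_classes = 2L, scale = c("linear", "log"),
                       n_starts = 32L, lambda_bounds = c(1e-4, 1e2),
                       seed = 1L, reltol = 1e-10) {
  statistic <- match.arg(statistic)
  scale <- match.arg(scale)
  if (!n_classes %in% 1:3) stop("'n_classes' must be 1, 2 or 3")
  if (length(lambda_bounds) != 2L || any(lambda_bounds <= 0) ||
      diff(lambda_bounds) <= 0)
    stop("'lambda_bounds' must be increasing positive limits")
  structure(list(statistic = statistic, n_classes = as.integer(n_classes),
                 scale = scale, n_starts = as.integer(n_starts),
                 lambda_bounds = lambda_bounds, seed = as.integer(seed),
                 reltol = reltol),
            class = "fit_config")
}

# Moment-matched compression of a distance distribution: bins the D values
# of each k level onto at most n_bins bins, replacing each bin by its
# weight and weighted mean D. Exact for the mean; the error on
# <e^{-lambda D}> is second order, ~(lambda * binwidth)^2 / 8 per bin.
compress_distribution <- function(dists, n_bins = 256L) {
  stopifnot(inherits(dists, "distance_distribution"))
  levels <- lapply(dists$levels, function(l) {
    if (length(l$D) <= n_bins) return(l)
    rng <- range(l$D)
    cut_idx <- findInterval(l$D, seq(rng[1], rng[2], length.out = n_bins + 1L),
                            rightmost.closed = TRUE)
    w <- as.numeric(tapply(l$weight, cut_idx, sum))
    d <- as.numeric(tapply(l$weight * l$D, cut_idx, sum)) / w
    list(D = d, weight = w)
  })
  structure(list(n_genomes = dists$n_genomes, levels = levels,
                 provenance = paste0(dists$provenance, "+binned")),
            class = "distance_distribution")
}

#' Model curves for all three pangenome statistics
#'
#' Chains the closed-form machinery: the tree-averaged mean intersections
#' \eqn{\langle I \rangle_k}, the commonality g_k obtained from them by
#' the exact inclusion-exclusion transform, and the cumulative
#' commonality J_k.
#'
#' @param classes A \code{\link{gene_classes}} object.
#' @param dists A \code{\link{distance_distributions}} result.
#' @return List with \code{meanI} (intersection_profile), \code{g}
#'   (commonality), \code{J} (numeric vector).
#' @export
predict_statistics <- function(classes, dists) {
  prof <- mean_intersection_curve(classes, dists)
  g <- suppressWarnings(commonality_from_intersections(prof))
  list(meanI = prof, g = g, J = cumulative_commonality(g))
}

# basis curve of the chosen statistic for a unit class (x = 1) at decay
# lambda; model curve is then A %*% x
statistic_basis <- function(lambda, dists, statistic) {
  N <- dists$n_genomes
  A <- vapply(lambda, function(l) {
    mi <- vapply(dists$levels, function(lv) sum(lv$weight * exp(-l * lv$D)),
                 numeric(1))
    switch(statistic,
           meanI = mi,
           commonality = suppressWarnings(
             commonality_from_intersections(
               intersection_profile(mi))$counts),
           cumulative = cumsum(suppressWarnings(
             commonality_from_intersections(
               intersection_profile(mi))$counts)))
  }, numeric(N))
  matrix(A, nrow = N)
}

#' Goodness of fit
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} about the observed mean, and the
#' adjusted \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @param n_params Number of fitted parameters p.
#' @return List with \code{r_squared} and \code{adj_r_squared} (NA when
#'   n <= p + 1).
#' @export
goodness_of_fit <- function(pred, obs, n_params) {
  if (length(pred) != length(obs)) stop("length mismatch")
  n <- length(obs)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("zero variance in observations; R^2 undefined")
  r2 <- 1 - sum((obs - pred)^2) / ss_tot
  adj <- if (n > n_params + 1) 1 - (1 - r2) * (n - 1) / (n - n_params - 1)
  else NA_real_
  list(r_squared = r2, adj_r_squared = adj)
}

#' Fit a multi-class gene turnover model
#'
#' Least-squares inference of the class sizes x_i and decay rates
#' lambda_i from one of the three statistics. The observed input may be a
#' \code{pangenome_matrix}, an \code{intersection_profile} or a
#' \code{commonality} object: the statistic selected in \code{config} is
#' derived from it (they are exact transforms of one another). The search
#' runs a seeded Latin-hypercube multistart of Nelder-Mead over log decay
#' rates, solving non-negative least squares for the sizes at each
#' candidate (variable projection). Additional warm starts (e.g. the
#' optimum of a smaller model) can be supplied.
#'
#' @param observed A \code{pangenome_matrix}, \code{intersection_profile}
#'   or \code{commonality}.
#' @param dists Distance distributions of the matching tree.
#' @param config A \code{\link{fit_config}}.
#' @param warm_starts Optional list of numeric decay-rate vectors (length
#'   n_classes) added to the start set.
#' @param compress_bins Bin count for internal distance-distribution
#'   compression (default 256; set NULL to disable).
#' @return Object of class \code{"fit_result"}: fields \code{classes}
#'   (\code{gene_classes}), \code{predicted} (meanI/g/J curves),
#'   \code{r_squared}, \code{adj_r_squared}, \code{errors} (core /
#'   singleton diagnostics), \code{rss}, \code{converged},
#'   \code{degenerate} flags, \code{config}.
#' @export
fit_model <- function(observed, dists, config = fit_config(),
                      warm_starts = NULL, compress_bins = 256L) {
  stopifnot(inherits(dists, "distance_distribution"),
            inherits(config, "fit_config"))
  obs <- observed_statistics(observed, dists$n_genomes)
  target <- switch(config$statistic,
                   meanI = obs$meanI, commonality = obs$g,
                   cumulative = obs$J)
  if (any(target < 0)) stop("negative observed values")
  N <- dists$n_genomes
  fit_dists <- if (!is.null(compress_bins))
    compress_distribution(dists, compress_bins) else dists
  p <- config$n_classes
  lb <- log(config$lambda_bounds)

  objective <- function(loglam) {
    lam <- exp(pmin(pmax(loglam, lb[1]), lb[2]))
    A <- statistic_basis(lam, fit_dists, config$statistic)
    # near-identical decay candidates make A rank-deficient; treat as a
    # poor candidate rather than aborting the search
    sol <- tryCatch(pracma::lsqnonneg(A, target), error = function(e) NULL)
    if (is.null(sol))
      return(list(rss = sum(target^2) + 1e6, x = rep(0, length(lam)),
                  lambda = lam))
    list(rss = sum((A %*% sol$x - target)^2), x = sol$x, lambda = lam)
  }

  starts <- multistart_points(p, lb, config$n_starts, config$seed)
  if (!is.null(warm_starts))
    starts <- c(lapply(warm_starts, function(w) log(pmax(w, exp(lb[1])))),
                starts)
  best <- NULL
  for (s0 in starts) {
    res <- if (p == 1L) {
      opt <- stats::optimize(function(z) objective(z)$rss,
                             interval = lb, tol = 1e-10)
      list(par = opt$minimum, value = opt$objective, convergence = 0L)
    } else {
      stats::optim(s0, function(z) objective(z)$rss,
                   method = "Nelder-Mead",
                   control = list(reltol = config$reltol, maxit = 2000L))
    }
    if (is.null(best) || res$value < best$value) best <- res
    if (p == 1L) break  # 1-D golden search is global over the bounds
  }
  sol <- objective(best$par)
  classes <- gene_classes(as.numeric(sol$x), sol$lambda)

  if (config$scale == "log") {
    # refine on log residuals from the linear-scale solution
    pos <- target > 0
    par0 <- log(pmax(c(classes$size, classes$decay), 1e-8))
    logobj <- function(par) {
      xs <- exp(par[seq_len(p)]); ls <- exp(par[p + seq_len(p)])
      A <- statistic_basis(ls, fit_dists, config$statistic)
      pred <- as.numeric(A %*% xs)
      if (any(pred[pos] <= 0)) return(1e12)
      sum((log(pred[pos]) - log(target[pos]))^2)
    }
    ref <- stats::optim(par0, logobj, method = "Nelder-Mead",
                        control = list(reltol = config$reltol,
                                       maxit = 5000L))
    classes <- gene_classes(exp(ref$par[seq_len(p)]),
                            exp(ref$par[p + seq_len(p)]))
    best$value <- ref$value
    best$convergence <- ref$convergence
  }

  predicted <- predict_statistics(classes, dists)
  pred_target <- switch(config$statistic,
                        meanI = predicted$meanI$values,
                        commonality = predicted$g$counts,
                        cumulative = predicted$J)
  gof <- goodness_of_fit(pred_target, target, 2L * p)
  errors <- tryCatch(
    fit_errors(predicted$g, obs$g_obj),
    error = function(e) NULL)
  structure(list(classes = classes, predicted = predicted,
                 observed = obs,
                 r_squared = gof$r_squared,
                 adj_r_squared = gof$adj_r_squared,
                 errors = errors, rss = best$value,
                 converged = identical(best$convergence, 0L),
                 degenerate = degeneracy_flags(classes),
                 config = config),
            class = "fit_result")
}

# derive all three observed statistics (they are exact transforms)
observed_statistics <- function(observed, N) {
  if (inherits(observed, "pangenome_matrix")) {
    prof <- mean_intersection_profile(observed)
    g <- commonality_counts(observed)
  } else if (inherits(observed, "intersection_profile")) {
    prof <- observed
    g <- suppressWarnings(commonality_from_intersections(observed))
  } else if (inherits(observed, "commonality")) {
    g <- observed
    prof <- intersections_from_commonality(observed)
  } else stop("'observed' must be a pangenome_matrix, ",
              "intersection_profile or commonality object")
  if (prof$n_genomes != N)
    stop("observed N (", prof$n_genomes,
         ") does not match distance distributions (", N, ")")
  list(meanI = prof$values, g = g$counts, J = cumulative_commonality(g),
       g_obj = g, profile = prof)
}

multistart_points <- function(p, log_bounds, n_starts, seed) {
  if (p == 1L) return(list(mean(log_bounds)))
  grid <- withr::with_seed(seed, lhs::randomLHS(n_starts, p))
  lapply(seq_len(n_starts), function(i)
    sort(log_bounds[1] + grid[i, ] * diff(log_bounds)))
}

degeneracy_flags <- function(classes, frac_threshold = 0.01,
                             ratio_window = c(0.9, 1.1)) {
  total <- sum(classes$size)
  tiny <- total > 0 & (classes$size / max(total, 1e-300)) < frac_threshold
  near <- FALSE
  if (nrow(classes) > 1L) {
    lam <- classes$decay
    for (i in seq_len(nrow(classes) - 1L)) {
      r <- lam[i] / lam[i + 1L]
      if (!is.nan(r) && r >= ratio_window[1] && r <= ratio_window[2])
        near <- TRUE
    }
  }
  list(tiny_class = any(tiny), near_equal_decay = near,
       degenerate = any(tiny) || near)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Gene turnover model fit [", x$config$statistic, ", ",
      x$config$n_classes, " class(es)]\n", sep = "")
  print(x$classes)
  cat(sprintf("R^2 = %.6f  adj R^2 = %s\n", x$r_squared,
              ifelse(is.na(x$adj_r_squared), "NA",
                     sprintf("%.6f", x$adj_r_squared))))
  if (!is.null(x$errors))
    cat(sprintf("core error = %+.3f  singleton error = %+.3f\n",
                x$errors$core_error, x$errors$singleton_error))
  if (x$degenerate$degenerate) cat("NOTE: degenerate solution flagged\n")
  invisible(x)
}

#' Compare a 2-class and a 3-class fit
#'
#' Model selection by adjusted R-squared with a fewer-parameters
#' tie-break, plus degeneracy detection: a 3-class solution whose smallest
#' class holds under 1% of the genes, or with two near-identical decay
#' rates (ratio within 0.9..1.1), has effectively collapsed to two
#' classes. The singleton-error comparison is reported alongside.
#'
#' @param fit2,fit3 \code{fit_result} objects fitted to the same observed
#'   statistic.
#' @param frac_threshold,ratio_window Degeneracy thresholds.
#' @return List with \code{selected} ("2-class"/"3-class"),
#'   \code{adj_r_squared} pair, \code{fit3_degenerate}, and the two
#'   singleton errors.
#' @export
select_model <- function(fit2, fit3, frac_threshold = 0.01,
                         ratio_window = c(0.9, 1.1)) {
  stopifnot(inherits(fit2, "fit_result"), inherits(fit3, "fit_result"))
  if (fit2$config$statistic != fit3$config$statistic ||
      !isTRUE(all.equal(fit2$observed$meanI, fit3$observed$meanI)))
    stop("fits must target the same observed data and statistic")
  deg <- degeneracy_flags(fit3$classes, frac_threshold, ratio_window)
  prefer3 <- !deg$degenerate &&
    isTRUE(fit3$adj_r_squared > fit2$adj_r_squared)
  list(selected = if (prefer3) "3-class" else "2-class",
       adj_r_squared = c(`2-class` = fit2$adj_r_squared,
                         `3-class` = fit3$adj_r_squared),
       fit3_degenerate = deg,
       singleton_error = c(
         `2-class` = if (!is.null(fit2$errors))
           fit2$errors$singleton_error else NA_real_,
         `3-class` = if (!is.null(fit3$errors))
           fit3$errors$singleton_error else NA_real_))
}

#' Fit 2- and 3-class models and select between them
#'
#' Convenience wrapper: fits the 2-class model, warm-starts the 3-class
#' model from its optimum (so the larger model can never fit worse), and
#' applies \code{\link{select_model}}.
#'
#' @inheritParams fit_model
#' @return List with \code{fit2}, \code{fit3}, \code{selection}.
#' @export
compare_class_counts <- function(observed, dists,
                                 config = fit_config(),
                                 compress_bins = 256L) {
  cfg2 <- config; cfg2$n_classes <- 2L
  cfg3 <- config; cfg3$n_classes <- 3L
  fit2 <- fit_model(observed, dists, cfg2, compress_bins = compress_bins)
  warm <- list(sort(c(fit2$classes$decay,
                      exp(mean(log(config$lambda_bounds))))))
  fit3 <- fit_model(observed, dists, cfg3, warm_starts = warm,
                    compress_bins = compress_bins)
  list(fit2 = fit2, fit3 = fit3, selection = select_model(fit2, fit3))
}
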
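#' Read a gene presence/absence table
#'
#' Plain dialect: first column gene family ID, remaining columns one per
#' genome with 0/1 entries; an optional \code{class} column carries
#' per-family class labels (as written for simulated data). Roary dialect:
#' a \code{gene_presence_absence.csv}-style table whose standard
#' annotation columns are dropped and where any non-empty cell denotes
#' presence.
#'
#' @param path TSV (tab) or CSV (comma) file; delimiter chosen by
#'   extension (".csv" = comma).
#' @param dialect "plain" (default) or "roary".
#' @return A \code{\link{pangenome_matrix}}.
#' @export
load_presence_absence <- function(path, dialect = c("plain", "roary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) < 1L || ncol(df) < 2L) stop("empty or header-only matrix")
  fam <- as.character(df[[1]])
  header <- names(df)[-1]
  df <- df[, -1, drop = FALSE]
  names(df) <- header  # data.frame subsetting repairs duplicates; undo
  classes <- NULL
  if (dialect == "plain") {
    if ("class" %in% names(df)) {
      classes <- as.character(df[["class"]])
      df <- df[, names(df) != "class", drop = FALSE]
    }
    m <- as.matrix(df)
    bad <- which(matrix(!(trimws(m) %in% c("0", "1", 0, 1)), nrow(m)),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-binary cell at row ", bad[1, 1], " (family ",
           fam[bad[1, 1]], "), column '", colnames(df)[bad[1, 2]], "': ",
           m[bad[1, , drop = FALSE]])
    storage.mode(m) <- "numeric"
  } else {
    roary_meta <- c("Non-unique Gene name", "Annotation", "No. isolates",
                    "No. sequences", "Avg sequences per isolate",
                    "Genome Fragment", "Order within Fragment",
                    "Accessory Fragment", "Accessory Order with Fragment",
                    "QC", "Min group size nuc", "Max group size nuc",
                    "Avg group size nuc")
    df <- df[, !(names(df) %in% roary_meta), drop = FALSE]
    if (ncol(df) < 1L) stop("no genome columns after removing metadata")
    m <- vapply(df, function(col) {
      as.numeric(!is.na(col) & trimws(as.character(col)) != "")
    }, numeric(nrow(df)))
    m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, names(df)))
  }
  rownames(m) <- fam
  pangenome_matrix(m, classes = classes)
}

#' Write a gene presence/absence table
#'
#' Plain-dialect TSV (family ID first, one 0/1 column per genome, optional
#' trailing \code{class} column); round-trips through
#' \code{\link{load_presence_absence}}.
#'
#' @param matrix A \code{\link{pangenome_matrix}}.
#' @param path Output file path.
#' @export
write_presence_absence <- function(matrix, path) {
  stopifnot(inherits(matrix, "pangenome_matrix"))
  df <- data.frame(family = rownames(matrix$incidence),
                   matrix$incidence, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(matrix$classes)) df$class <- matrix$classes
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Glues the stages together: obtain a presence/absence matrix (from a
#' file or by simulation along the tree), compute the empirical
#' statistics, build the tree's spanning-distance distributions, run the
#' requested fits, and return (optionally write) a machine-readable
#' report. Deterministic for a fixed config and seed.
#'
#' @param config A named list (or path to a YAML/JSON file) with fields:
#'   \describe{
#'     \item{tree}{Newick string or file path (required).}
#'     \item{matrix}{path to a presence/absence table, or}
#'     \item{simulation}{list(x, loss, regime, pool, gain) passed to
#'       \code{\link{sim_params}} — exactly one of matrix/simulation.}
#'     \item{rescale}{branch-length rescale factor (default 1).}
#'     \item{fits}{list of lists passed to \code{\link{fit_config}}
#'       (default: one 2-class fit to meanI).}
#'     \item{seed}{master seed (default 1).}
#'     \item{out_dir}{optional output directory for JSON/TSV artifacts.}
#'   }
#' @return List (class \code{"pangloss_pipeline"}) with the matrix,
#'   distance distributions, observed statistics, fit results, and the
#'   config echo.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config$tree)) stop("pipeline config requires a 'tree'")
  has_matrix <- !is.null(config$matrix)
  has_sim <- !is.null(config$simulation)
  if (has_matrix == has_sim)
    stop("config must contain exactly one of 'matrix' or 'simulation'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  tree <- read_tree(config$tree)
  if (!is.null(config$rescale) && config$rescale != 1)
    tree <- rescale_tree(tree, config$rescale)

  if (has_matrix) {
    dialect <- if (is.null(config$dialect)) "plain" else config$dialect
    pm <- load_presence_absence(config$matrix, dialect)
  } else {
    sp <- do.call(sim_params, config$simulation)
    pm <- simulate_pangenome(tree, sp, seed = seed)
  }
  if (!setequal(colnames(pm$incidence), tree$tip.label))
    stop("genome names and tree leaves differ: ",
         paste(c(setdiff(colnames(pm$incidence), tree$tip.label),
                 setdiff(tree$tip.label, colnames(pm$incidence))),
               collapse = ", "))

  N <- length(tree$tip.label)
  mode <- if (N <= 20L) "exact" else "sample"
  dists <- distance_distributions(tree, mode = mode, seed = seed)

  g <- commonality_counts(pm)
  prof <- mean_intersection_profile(pm)
  # transform cross-check: Eq. closure between the two statistics
  closure_ok <- isTRUE(all.equal(
    suppressWarnings(commonality_from_intersections(prof))$counts,
    g$counts, tolerance = 1e-9))

  fit_specs <- config$fits
  if (is.null(fit_specs))
    fit_specs <- list(list(statistic = "meanI", n_classes = 2L))
  fits <- lapply(fit_specs, function(fs) {
    fs$seed <- if (is.null(fs$seed)) seed else fs$seed
    fit_model(pm, dists, do.call(fit_config, fs))
  })
  names(fits) <- vapply(fits, function(f)
    paste0(f$config$statistic, "_", f$config$n_classes, "class"),
    character(1))

  result <- structure(
    list(matrix = pm, tree = tree, dists = dists,
         observed = list(commonality = g, meanI = prof,
                         J = cumulative_commonality(g)),
         transform_closure_ok = closure_ok,
         fits = fits, seed = seed, config = config),
    class = "pangloss_pipeline")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_presence_absence(pm, file.path(config$out_dir, "matrix.tsv"))
    write_distance_distribution(
      dists, file.path(config$out_dir, "distance_distributions.tsv"))
    jsonlite::write_json(pipeline_report(result),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

# flat serialisable summary of a pipeline run
pipeline_report <- function(result) {
  list(seed = result$seed,
       n_genomes = result$observed$commonality$n_genomes,
       pangenome_size = sum(result$observed$commonality$counts),
       commonality = result$observed$commonality$counts,
       mean_intersections = result$observed$meanI$values,
       cumulative_commonality = result$observed$J,
       transform_closure_ok = result$transform_closure_ok,
       fits = lapply(result$fits, function(f) list(
         statistic = f$config$statistic,
         n_classes = f$config$n_classes,
         size = f$classes$size, decay = f$classes$decay,
         r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
         core_error = if (!is.null(f$errors)) f$errors$core_error else NA,
         singleton_error = if (!is.null(f$errors))
           f$errors$singleton_error else NA)))
}

#' @export
print.pangloss_pipeline <- function(x, ...) {
  cat("pangloss pipeline run (seed ", x$seed, ")\n", sep = "")
  print(x$matrix)
  cat("Transform closure exact:", x$transform_closure_ok, "\n")
  for (nm in names(x$fits)) {
    cat("--- fit:", nm, "---\n")
    print(x$fits[[nm]])
  }
  invisible(x)
}
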
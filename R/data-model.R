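#' Read a diagnostic meta-analysis of 2x2 tables from CSV
#'
#' Each row is one study's 2x2 contingency table: TP (true positives), FP
#' (false positives), FN (false negatives), TN (true negatives). Column names
#' are matched case-insensitively; an optional label/author column is carried
#' through, and any other columns (e.g. a cut-off column) are kept but ignored
#' by the models -- cut-off heterogeneity is absorbed by the study-level
#' location random effect.
#'
#' @param path Path to a CSV file with a header row.
#' @param name Optional dataset name; defaults to the file name.
#' @return A tibble of class `srocpb_meta` with columns `label`, `tp`, `fp`,
#'   `fn`, `tn` (plus any extra columns), one row per study in file order.
#' @examples
#' cd64 <- read_meta_csv(srocpb_example("cd64.csv"))
#' nrow(cd64)
#' @export
read_meta_csv <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) abort("Empty dataset: the CSV contains no study rows.")
  as_meta(raw, name = name %||% basename(path))
}

#' Validate a data frame of 2x2 diagnostic study tables
#'
#' @param x A data frame with columns `tp`, `fp`, `fn`, `tn` (case-insensitive;
#'   an optional `label`/`author`/`study` column provides study labels).
#' @param name Optional dataset name stored as an attribute.
#' @return A validated `srocpb_meta` tibble with canonical lower-case count
#'   columns, row order preserved.
#' @export
as_meta <- function(x, name = NULL) {
  x <- as_tibble(x)
  if (nrow(x) == 0L) abort("Empty dataset: no study rows.")
  nm <- tolower(names(x))
  pick <- function(col) {
    hit <- which(nm == col)
    if (length(hit) == 0L) abort(paste0("Missing required column: ", toupper(col)))
    x[[hit[1L]]]
  }
  counts <- list(tp = pick("tp"), fp = pick("fp"), fn = pick("fn"), tn = pick("tn"))
  for (cn in names(counts)) {
    v <- counts[[cn]]
    if (!is.numeric(v)) abort(paste0("Column ", toupper(cn), " is not numeric."))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L) {
      abort(paste0("Column ", toupper(cn), ": row ", bad[1L],
                   " is not a non-negative integer count."))
    }
    counts[[cn]] <- as.integer(v)
  }
  label_col <- which(nm %in% c("label", "author", "study_label"))
  label <- if (length(label_col) > 0L) as.character(x[[label_col[1L]]]) else
    paste0("study_", seq_len(nrow(x)))
  n1 <- counts$tp + counts$fn
  n0 <- counts$tn + counts$fp
  if (any(n1 < 1L)) {
    abort(paste0("Row ", which(n1 < 1L)[1L],
                 " has no diseased subjects (TP + FN = 0); the model conditions on n1 >= 1."))
  }
  if (any(n0 < 1L)) {
    abort(paste0("Row ", which(n0 < 1L)[1L],
                 " has no non-diseased subjects (TN + FP = 0); the model conditions on n0 >= 1."))
  }
  extra <- x[, !(nm %in% c("tp", "fp", "fn", "tn", "label", "author", "study_label")),
             drop = FALSE]
  out <- tibble(label = label, tp = counts$tp, fp = counts$fp,
                fn = counts$fn, tn = counts$tn)
  out <- dplyr::bind_cols(out, extra)
  class(out) <- c("srocpb_meta", class(out))
  attr(out, "name") <- name %||% "meta"
  out
}

# internal: counts + margins as plain vectors
.meta_counts <- function(data) {
  data <- if (inherits(data, "srocpb_meta")) data else as_meta(data)
  list(tp = data$tp, fp = data$fp, fn = data$fn, tn = data$tn,
       n1 = data$tp + data$fn, n0 = data$tn + data$fp, S = nrow(data))
}

#' Write / read a fitted result as JSON
#'
#' Serialises a fit (from [fit_unadjusted()], [fit_sensitivity()]) to a
#' machine-readable JSON record at full double precision: parameter estimates,
#' selection parameters, log-likelihood, flattened covariance matrix, summary
#' operating point, SAUC with its confidence interval, and convergence
#' diagnostics. `read_result()` reconstructs the fit object (without the data).
#'
#' @param result A `srocpb_fit` object.
#' @param path Output (input) file path.
#' @return `write_result()` returns `path` invisibly; `read_result()` returns
#'   a `srocpb_fit`.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "srocpb_fit"))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort(paste0("Cannot write result: directory does not exist: ", dirname(path)))
  rec <- list(
    params = as.list(result$params),
    gamma0 = result$gamma0, gamma1 = result$gamma1,
    p = result$p, c0 = result$c0, c1 = result$c1,
    loglik = result$loglik,
    vcov = as.numeric(result$vcov),
    vcov_dim = dim(result$vcov),
    vcov_names = rownames(result$vcov),
    sop = as.list(result$sop),
    sauc = result$sauc, sauc_se = result$sauc_se,
    sauc_ci = as.numeric(result$sauc_ci),
    converged = result$converged,
    diagnostics = result$diagnostics,
    n_studies = result$n_studies,
    nodes = result$nodes
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  vc <- matrix(rec$vcov, nrow = rec$vcov_dim[1], ncol = rec$vcov_dim[2])
  dimnames(vc) <- list(rec$vcov_names, rec$vcov_names)
  new_srocpb_fit(
    params = unlist(rec$params),
    gamma0 = rec$gamma0, gamma1 = rec$gamma1,
    p = rec$p, c0 = rec$c0, c1 = rec$c1,
    loglik = rec$loglik, vcov = vc,
    sop = unlist(rec$sop),
    sauc = rec$sauc, sauc_se = rec$sauc_se,
    sauc_ci = rec$sauc_ci,
    converged = rec$converged,
    diagnostics = rec$diagnostics,
    n_studies = rec$n_studies, nodes = rec$nodes
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
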
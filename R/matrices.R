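# Category matrices and Euclidean dissimilarity.  A category matrix holds the
# measured variables of one data category (RES, BCC, SCC, PS or BCM) with
# site-date samples as rows; it moves through the stages
# raw -> normalized -> standardized before the dissimilarity step.

#' Construct a category matrix
#'
#' @param values Numeric matrix or data frame; rownames are site-date ids,
#'   colnames are variable names.
#' @param category Category label, one of RES, BCC, SCC, PS, BA, BCM.
#' @param stage Processing stage: `"raw"`, `"normalized"` or
#'   `"standardized"`.
#' @return Object of class `category_matrix` (a numeric matrix with
#'   attributes `category` and `stage`).
#' @export
category_matrix <- function(values, category, stage = "raw") {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) {
    stop("category matrix needs site-date rownames", call. = FALSE)
  }
  stage <- match.arg(stage, c("raw", "normalized", "standardized"))
  structure(x, category = category, stage = stage, class = "category_matrix")
}

#' @export
print.category_matrix <- function(x, ...) {
  cat(sprintf("category_matrix [%s, %s]: %d samples x %d variables\n",
              attr(x, "category"), attr(x, "stage"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}

cm_stage <- function(x) attr(x, "stage")
cm_category <- function(x) attr(x, "category")

#' Normalize selected columns of a raw category matrix
#'
#' Applies per-variable normalizing transforms before standardization.
#' Supported transforms: `"identity"` (no change) and `"log10_shift"`
#' (`log10(x + shift)`), the usual treatment for right-skewed concentrations
#' and rates.  Variables absent from `transform_map` are left unchanged.
#'
#' @param matrix A raw [category_matrix()].
#' @param transform_map Named list/vector mapping variable names to
#'   `"identity"` or `"log10_shift"`; may carry an attribute-free `shift`
#'   via entries of the form `list(transform = "log10_shift", shift = 1)`.
#' @param shift Default shift added inside the log for `"log10_shift"`
#'   entries given as plain strings (default 0).
#' @return The matrix at stage `"normalized"`.
#' @export
normalize_columns <- function(matrix, transform_map = list(), shift = 0) {
  stopifnot(inherits(matrix, "category_matrix"))
  if (cm_stage(matrix) != "raw") {
    stop("normalize_columns expects a raw matrix (got stage '",
         cm_stage(matrix), "')", call. = FALSE)
  }
  x <- unclass(matrix)
  unknown <- setdiff(names(transform_map), colnames(x))
  if (length(unknown)) {
    stop("transform_map names unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (v in names(transform_map)) {
    spec <- transform_map[[v]]
    if (is.list(spec)) {
      tr <- spec$transform
      sh <- spec$shift %||% shift
    } else {
      tr <- spec
      sh <- shift
    }
    tr <- match.arg(tr, c("identity", "log10_shift"))
    if (tr == "log10_shift") {
      vals <- x[, v] + sh
      if (any(vals <= 0, na.rm = TRUE)) {
        stop("log10_shift of variable '", v,
             "' hits a non-positive argument; increase the shift",
             call. = FALSE)
      }
      x[, v] <- log10(vals)
    }
  }
  category_matrix(x, cm_category(matrix), stage = "normalized")
}

#' Standardize all columns to z-scores
#'
#' Centres each variable and scales it to unit sample standard deviation
#' (n - 1 denominator), putting all variables of a category on a common
#' dimensionless scale before the Euclidean dissimilarity step.
#'
#' @param matrix A normalized [category_matrix()] (a raw matrix is accepted
#'   when no normalizing transform is wanted).
#' @return The matrix at stage `"standardized"`.
#' @export
standardize_columns <- function(matrix) {
  stopifnot(inherits(matrix, "category_matrix"))
  if (cm_stage(matrix) == "standardized") {
    stop("matrix is already standardized", call. = FALSE)
  }
  x <- unclass(matrix)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds == 0 | !is.finite(sds)]
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  category_matrix(z, cm_category(matrix), stage = "standardized")
}

#' Euclidean site-dissimilarity matrix
#'
#' Pairwise Euclidean distances between the (standardized) sample rows of a
#' category matrix, the between-site dissimilarity measure underlying all
#' rate-of-change statistics.
#'
#' @param matrix A standardized [category_matrix()].
#' @param require_standardized Set `FALSE` to allow other stages (used e.g.
#'   for single-variable distances where standardization happened upstream).
#' @return Square symmetric numeric matrix with zero diagonal and the
#'   site-date ids as dimnames.
#' @export
euclidean_distance_matrix <- function(matrix, require_standardized = TRUE) {
  stopifnot(inherits(matrix, "category_matrix"))
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("empty category matrix", call. = FALSE)
  }
  if (require_standardized && cm_stage(matrix) != "standardized") {
    stop("dissimilarities are computed on the standardized stage (got '",
         cm_stage(matrix), "')", call. = FALSE)
  }
  if (anyNA(matrix)) {
    keep <- stats::complete.cases(unclass(matrix))
    warning(sum(!keep), " row(s) with missing values dropped from category ",
            cm_category(matrix), call. = FALSE)
    matrix <- category_matrix(unclass(matrix)[keep, , drop = FALSE],
                              cm_category(matrix), stage = cm_stage(matrix))
  }
  as.matrix(stats::dist(unclass(matrix), method = "euclidean"))
}
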
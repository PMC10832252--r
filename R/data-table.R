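#' Construct a data table for pattern analysis
#'
#' A \code{data_table} is a named numeric matrix (rows = subjects, columns =
#' variables) that carries per-column preprocessing provenance: the ordered
#' list of transforms applied (log, centring, scaling) with their fitted
#' parameters, and the per-column variance recorded before any adjustment.
#' The provenance makes every preprocessing step replayable on the raw data
#' and applicable to new subjects.
#'
#' @param values numeric matrix or data.frame with unique column names.
#' @param roles optional named character vector mapping columns to one of
#'   \code{"outcome"}, \code{"explanatory"}, \code{"covariate"},
#'   \code{"excluded"}; unset columns default to \code{"explanatory"}.
#' @return object of class \code{"data_table"}.
#' @export
data_table <- function(values, roles = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cn <- colnames(values)
  if (is.null(cn) || anyDuplicated(cn))
    stop("values must have unique column names")
  role <- rep("explanatory", ncol(values)); names(role) <- cn
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), cn)
    if (length(bad)) stop("unknown columns in roles: ", paste(bad, collapse = ", "))
    ok <- c("outcome", "explanatory", "covariate", "excluded")
    if (!all(roles %in% ok)) stop("roles must be one of ", paste(ok, collapse = ", "))
    role[names(roles)] <- roles
  }
  structure(list(values = values,
                 column_roles = role,
                 preprocessing_log = stats::setNames(
                   rep(list(list()), ncol(values)), cn),
                 original_variance = apply(values, 2, stats::var)),
            class = "data_table")
}

boolean_tokens <- c("yes" = 1, "no" = 0, "true" = 1, "false" = 0, "1" = 1, "0" = 0)

#' Read a tabular dataset from CSV or XLSX
#'
#' Reads a file with a header row of column names into a
#' \code{\link{data_table}}. Boolean tokens (yes/no, true/false, 1/0,
#' case-insensitive) are recoded to 0/1 when \code{booleans = TRUE}; any
#' other non-numeric cell is an error. Columns containing missing values or
#' with zero variance are flagged in the attached validation report, not
#' dropped: modelling functions refuse incomplete columns, so the report
#' tells the user what to fix or exclude.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"xlsx"}; guessed from the extension
#'   by default. XLSX import requires the readxl package.
#' @param id_column if TRUE, the first column holds subject identifiers and
#'   is dropped from the numeric matrix.
#' @param sheet sheet name or index for XLSX input.
#' @param booleans recode boolean tokens to 0/1 (default TRUE).
#' @return a \code{data_table}; its \code{attr(, "validation")} is a list
#'   with \code{missing} and \code{zero_variance} column-name vectors.
#' @export
read_table <- function(path, format = c("auto", "csv", "xlsx"),
                       id_column = FALSE, sheet = 1, booleans = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("xlsx import requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                           .name_repair = "minimal"),
                        check.names = FALSE)
  }
  if (anyDuplicated(colnames(df)))
    stop("duplicate column names: ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  if (id_column) df <- df[, -1, drop = FALSE]
  num <- lapply(stats::setNames(seq_along(df), colnames(df)), function(j) {
    col <- df[[j]]
    if (is.numeric(col)) return(as.numeric(col))
    if (is.logical(col)) return(as.numeric(col))
    s <- trimws(as.character(col))
    s[s == ""] <- NA
    low <- tolower(s)
    if (booleans && all(is.na(low) | low %in% names(boolean_tokens)))
      return(unname(boolean_tokens[low]))
    suppressWarnings(x <- as.numeric(s))
    bad <- !is.na(s) & is.na(x)
    if (any(bad))
      stop("column '", colnames(df)[j], "' contains non-numeric value(s): ",
           paste(utils::head(unique(s[bad]), 3), collapse = ", "))
    x
  })
  values <- do.call(cbind, num)
  rownames(values) <- NULL
  tab <- data_table(values)
  v <- apply(values, 2, function(x) stats::var(x[!is.na(x)]))
  attr(tab, "validation") <- list(
    missing = colnames(values)[colSums(is.na(values)) > 0],
    zero_variance = colnames(values)[!is.na(v) & v < .Machine$double.eps])
  tab
}

#' Preprocess a data table: log transform, centre, standardise
#'
#' Applies, in order: natural log to the requested columns (values must be
#' strictly positive), mean-centring of every column, and (optionally) unit
#' sample-variance scaling. The variance of each column is recorded
#' immediately before scaling so that later variance partitions can report
#' fractions of the original variance. Every fitted parameter (column means,
#' scale factors) is appended to the preprocessing log, which replays
#' bit-identically via \code{\link{replay_preprocessing}}.
#'
#' @param table a \code{\link{data_table}}.
#' @param log_columns character vector of columns to log-transform.
#' @param standardize scale all columns to unit sample variance (default TRUE).
#' @return the preprocessed \code{data_table}.
#' @export
preprocess <- function(table, log_columns = character(), standardize = TRUE) {
  stopifnot(inherits(table, "data_table"))
  X <- table$values
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing values in column(s): ", paste(bad, collapse = ", "))
  }
  log_columns <- as.character(log_columns)
  bad <- setdiff(log_columns, colnames(X))
  if (length(bad)) stop("unknown log columns: ", paste(bad, collapse = ", "))
  for (cl in log_columns) {
    if (any(X[, cl] <= 0))
      stop("column '", cl, "' has non-positive values; cannot log-transform")
    X[, cl] <- log(X[, cl])
    table$preprocessing_log[[cl]] <- c(table$preprocessing_log[[cl]],
                                       list(list(op = "log")))
  }
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  v_before_scale <- apply(X, 2, stats::var)
  table$original_variance <- v_before_scale
  for (cl in colnames(X))
    table$preprocessing_log[[cl]] <- c(table$preprocessing_log[[cl]],
                                       list(list(op = "center", mean = mu[[cl]])))
  if (standardize) {
    s <- sqrt(v_before_scale)
    if (any(s < .Machine$double.eps))
      stop("zero-variance column(s): ",
           paste(colnames(X)[s < .Machine$double.eps], collapse = ", "))
    X <- sweep(X, 2, s, "/")
    for (cl in colnames(X))
      table$preprocessing_log[[cl]] <- c(table$preprocessing_log[[cl]],
                                         list(list(op = "scale", sd = s[[cl]])))
  }
  table$values <- X
  table
}

#' Replay a preprocessing log on raw data
#'
#' Applies the recorded transforms of a preprocessed table to a raw numeric
#' matrix with the same columns, using the stored parameters (not statistics
#' of the new data). Replaying on the original raw input reproduces the
#' preprocessed matrix exactly; applying to new subjects puts them on the
#' training scale.
#'
#' @param table a preprocessed \code{\link{data_table}} (the provenance source).
#' @param raw numeric matrix or data.frame with (at least) the same columns.
#' @return numeric matrix on the preprocessed scale, columns ordered as in
#'   \code{table}.
#' @export
replay_preprocessing <- function(table, raw) {
  stopifnot(inherits(table, "data_table"))
  raw <- as.matrix(raw)
  cn <- colnames(table$values)
  if (!all(cn %in% colnames(raw)))
    stop("raw data lacks column(s): ",
         paste(setdiff(cn, colnames(raw)), collapse = ", "))
  out <- raw[, cn, drop = FALSE]
  storage.mode(out) <- "double"
  for (cl in cn) {
    for (step in table$preprocessing_log[[cl]]) {
      out[, cl] <- switch(step$op,
        log    = log(out[, cl]),
        center = out[, cl] - step$mean,
        scale  = out[, cl] / step$sd,
        stop("unknown preprocessing op: ", step$op))
    }
  }
  out
}

#' Pearson correlation matrix of selected columns
#'
#' @param table a \code{\link{data_table}}.
#' @param columns columns to include (default: all).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, columns = colnames(table$values)) {
  stopifnot(inherits(table, "data_table"))
  X <- table$values[, columns, drop = FALSE]
  if (nrow(X) < 2) stop("at least 2 observations required")
  v <- apply(X, 2, stats::var)
  if (any(v < .Machine$double.eps))
    stop("zero-variance column(s): ",
         paste(colnames(X)[v < .Machine$double.eps], collapse = ", "))
  stats::cor(X)
}

#' Assign analysis roles to columns
#'
#' @param table a \code{\link{data_table}}.
#' @param outcome single column name.
#' @param explanatory character vector of explanatory columns; default: all
#'   columns not otherwise assigned.
#' @param covariates character vector of covariate columns.
#' @return the table with updated \code{column_roles}.
#' @export
set_roles <- function(table, outcome, explanatory = NULL, covariates = character()) {
  stopifnot(inherits(table, "data_table"))
  cn <- colnames(table$values)
  stopifnot(length(outcome) == 1, outcome %in% cn, all(covariates %in% cn))
  if (is.null(explanatory))
    explanatory <- setdiff(cn, c(outcome, covariates))
  stopifnot(all(explanatory %in% cn))
  role <- rep("excluded", length(cn)); names(role) <- cn
  role[explanatory] <- "explanatory"
  role[covariates] <- "covariate"
  role[outcome] <- "outcome"
  table$column_roles <- role
  table
}

#' @export
print.data_table <- function(x, ...) {
  cat(sprintf("data_table: %d subjects x %d variables\n",
              nrow(x$values), ncol(x$values)))
  tr <- table(x$column_roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tr), tr), collapse = ", "), "\n")
  val <- attr(x, "validation")
  if (!is.null(val)) {
    if (length(val$missing))
      cat("  columns with missing values:", paste(val$missing, collapse = ", "), "\n")
    if (length(val$zero_variance))
      cat("  zero-variance columns:", paste(val$zero_variance, collapse = ", "), "\n")
  }
  invisible(x)
}
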
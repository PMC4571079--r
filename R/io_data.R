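#' Construct a cohort table
#'
#' The central container of the package: one row per patient, one column per
#' gated flow-cytometry population expression, plus a binary phenotype
#' (1 = case, e.g. interstitial lung disease; 0 = control). All downstream
#' code assumes this coding.
#'
#' @param X numeric matrix, rows = patients, columns = variables. Must have
#'   unique column names (assigned `fc001`, `fc002`, ... when absent).
#' @param phenotype integer vector of 0/1 labels, one per row of `X`.
#' @param patient_ids optional character vector of unique patient
#'   identifiers; defaults to `P0001`, `P0002`, ...
#' @return an object of class `cohort_table` with fields `patient_ids`,
#'   `variables`, `X` and `phenotype`.
#' @export
cohort_table <- function(X, phenotype, patient_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("fc%03d", seq_len(ncol(X)))
  }
  if (anyDuplicated(colnames(X))) {
    stop("variable names must be unique", call. = FALSE)
  }
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(X)) {
    stop("phenotype length must equal the number of rows of X", call. = FALSE)
  }
  if (anyNA(phenotype) || !all(phenotype %in% c(0L, 1L))) {
    stop("phenotype must be coded 0/1", call. = FALSE)
  }
  if (is.null(patient_ids)) {
    patient_ids <- sprintf("P%04d", seq_len(nrow(X)))
  }
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != nrow(X)) {
    stop("patient_ids length must equal the number of rows of X", call. = FALSE)
  }
  if (anyDuplicated(patient_ids)) {
    stop("duplicate patient IDs", call. = FALSE)
  }
  rownames(X) <- patient_ids
  structure(
    list(patient_ids = patient_ids, variables = colnames(X),
         X = X, phenotype = phenotype),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d patients x %d variables; prevalence %.3f\n",
    length(x$patient_ids), length(x$variables), mean(x$phenotype)
  ))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$X)

#' Subset a cohort by patient rows
#'
#' @param cohort a [cohort_table()].
#' @param rows integer or logical row index.
#' @return a `cohort_table` restricted to the selected patients.
#' @export
subset_cohort <- function(cohort, rows) {
  cohort_table(cohort$X[rows, , drop = FALSE],
               cohort$phenotype[rows],
               cohort$patient_ids[rows])
}

#' Read a cohort table from delimited text
#'
#' Reads a CSV with a header row, one row per patient. Rows with any missing
#' value are dropped (patients lacking a full complement of measurements are
#' excluded, never imputed) and the number dropped is reported.
#'
#' @param path path to a CSV file.
#' @param phenotype_column name of the binary phenotype column.
#' @param id_column optional name of a patient-identifier column; when `NULL`
#'   sequential IDs are assigned.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, phenotype_column = "ild", id_column = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!phenotype_column %in% names(df)) {
    stop(sprintf("phenotype column '%s' not found", phenotype_column),
         call. = FALSE)
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop(sprintf("id column '%s' not found", id_column), call. = FALSE)
    }
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  keep <- stats::complete.cases(df)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("read_cohort: %d row(s) with missing values dropped", n_drop))
  }
  df <- df[keep, , drop = FALSE]
  if (!is.null(ids)) ids <- ids[keep]
  if (nrow(df) == 0) stop("no usable rows after dropping missing data", call. = FALSE)
  y <- df[[phenotype_column]]
  if (!is.numeric(y) || !all(y %in% c(0, 1))) {
    stop("phenotype column must contain only 0 and 1", call. = FALSE)
  }
  df[[phenotype_column]] <- NULL
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop(sprintf("non-numeric variable column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cohort_table(as.matrix(df), as.integer(y), ids)
}

#' Write a cohort table as CSV
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @param phenotype_column name for the phenotype column.
#' @param include_ids write the patient IDs as an `id` column.
#' @export
write_cohort <- function(cohort, path, phenotype_column = "ild",
                         include_ids = FALSE) {
  df <- as.data.frame(cohort$X)
  df[[phenotype_column]] <- cohort$phenotype
  if (include_ids) df <- cbind(id = cohort$patient_ids, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Randomly split a cohort into training and validation sets
#'
#' Simple random (optionally phenotype-stratified) partition, reproducible
#' for a fixed seed. The study design this mirrors assigns 79 of 119
#' patients to training and 40 to validation.
#'
#' @param cohort a [cohort_table()].
#' @param n_train number of training patients; must leave at least one
#'   validation patient.
#' @param seed integer seed.
#' @param stratify if `TRUE`, sample proportionally within each phenotype
#'   class.
#' @return a list with elements `train` and `valid`, both `cohort_table`s.
#' @export
split_cohort <- function(cohort, n_train, seed = 1L, stratify = FALSE) {
  n <- length(cohort$patient_ids)
  if (n_train <= 0 || n_train >= n) {
    stop("n_train must satisfy 0 < n_train < number of patients", call. = FALSE)
  }
  set.seed(seed)
  if (stratify) {
    idx1 <- which(cohort$phenotype == 1L)
    idx0 <- which(cohort$phenotype == 0L)
    k1 <- round(n_train * length(idx1) / n)
    k1 <- min(max(k1, n_train - length(idx0)), length(idx1))
    take <- c(sample(idx1, k1), sample(idx0, n_train - k1))
  } else {
    take <- sample(n, n_train)
  }
  take <- sort(take)
  list(train = subset_cohort(cohort, take),
       valid = subset_cohort(cohort, setdiff(seq_len(n), take)))
}

#' Fit per-variable standardization parameters on training data
#'
#' Stores mean, standard deviation (n - 1 denominator) and the observed
#' range of every variable, computed on training data only. Validation data
#' are always standardized against these training statistics so that the
#' screening-tool threshold frame never leaks information.
#'
#' @param train a [cohort_table()] with at least two patients.
#' @return an object of class `standardization_params`: a data frame with
#'   columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
fit_standardization <- function(train) {
  X <- train$X
  if (nrow(X) < 2) stop("need at least 2 patients", call. = FALSE)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  if (any(s <= 0)) {
    stop(sprintf("constant variable(s): %s",
                 paste(colnames(X)[s <= 0], collapse = ", ")), call. = FALSE)
  }
  structure(
    data.frame(variable = colnames(X), mean = mu, sd = s,
               min = apply(X, 2, min), max = apply(X, 2, max),
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("standardization_params", "data.frame")
  )
}

#' Standardize a cohort with training-derived parameters
#'
#' Each expression value becomes `(value - mean) / sd` with mean and sd taken
#' from `params` (i.e. from the training set), not from the cohort itself.
#'
#' @param cohort a [cohort_table()].
#' @param params a [fit_standardization()] result whose variable list matches
#'   the cohort's.
#' @return a `cohort_table` of z-scores, with `params` attached as an
#'   attribute.
#' @export
standardize <- function(cohort, params) {
  if (!identical(cohort$variables, params$variable)) {
    stop("variable lists of cohort and params do not match", call. = FALSE)
  }
  Z <- sweep(sweep(cohort$X, 2, params$mean, "-"), 2, params$sd, "/")
  out <- cohort_table(Z, cohort$phenotype, cohort$patient_ids)
  attr(out, "standardization") <- params
  out
}

#' Invert a standardization
#'
#' @param cohort a standardized [cohort_table()].
#' @param params the parameters used to standardize it.
#' @return a `cohort_table` on the original measurement scale.
#' @export
unstandardize <- function(cohort, params) {
  if (!identical(cohort$variables, params$variable)) {
    stop("variable lists of cohort and params do not match", call. = FALSE)
  }
  X <- sweep(sweep(cohort$X, 2, params$sd, "*"), 2, params$mean, "+")
  cohort_table(X, cohort$phenotype, cohort$patient_ids)
}
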
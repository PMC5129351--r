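#' Read and write descriptor tables
#'
#' A descriptor table is delimited text (comma- or tab-separated,
#' autodetected from the extension: \code{.csv} is comma, anything else
#' tab) with a header row: a compound identifier column, numeric descriptor
#' columns, and a binary 0/1 carcinogenicity label column (1 = carcinogen).
#' Ingestion is schema-validated; malformed cells are reported with their
#' row and column.
#'
#' @param path file path.
#' @param id_col,label_col column names for identifier and label.
#' @return Validated data frame (identifier, descriptors, label).
#' @export
read_descriptor_table <- function(path, id_col = "id", label_col = "label") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!(id_col %in% names(df)))
    stop("missing identifier column '", id_col, "'")
  if (!(label_col %in% names(df)))
    stop("missing label column '", label_col, "'")
  if (anyDuplicated(names(df))) stop("duplicate column names")
  desc_cols <- setdiff(names(df), c(id_col, label_col, "name"))
  for (cn in desc_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric descriptor cell at row %d, column '%s'",
                     bad[1], cn))
      df[[cn]] <- vn
    }
    if (anyNA(df[[cn]]))
      stop(sprintf("missing value at row %d, column '%s'",
                   which(is.na(df[[cn]]))[1], cn))
  }
  lab <- df[[label_col]]
  bad <- which(!(lab %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("non-binary label at row %d (value '%s')",
                 bad[1], as.character(lab[bad[1]])))
  df[[label_col]] <- as.integer(lab)
  df
}

#' @rdname read_descriptor_table
#' @param t descriptor table (data frame).
#' @export
write_descriptor_table <- function(t, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(t, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pearson correlation matrix of the descriptor columns
#'
#' @param t descriptor table; \code{id}, \code{name} and label columns are
#'   excluded.
#' @param label_col label column name.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(t, label_col = "label") {
  X <- t[setdiff(names(t), c("id", "name", label_col))]
  X <- X[vapply(X, is.numeric, logical(1))]
  if (nrow(X) < 3) stop("need at least 3 compounds")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant descriptor column: ",
         paste(names(X)[sds == 0], collapse = ", "))
  stats::cor(as.matrix(X))
}

#' Greedy collinearity filter
#'
#' Removes descriptors until every off-diagonal |r| is below the threshold
#' (the classic "drop one of any pair with |r| >= 0.8" preprocessing rule).
#' Deterministic removal order: take the offending pair with the largest
#' |r|; drop the member with the larger mean absolute correlation to all
#' remaining descriptors (ties break toward the later column).
#'
#' @param m correlation matrix (symmetric, unit diagonal).
#' @param threshold collinearity threshold on |r| (default 0.8).
#' @return Character vector of retained column names.
#' @examples
#' collinearity_filter(aa_correlations())  # retains all eight
#' @export
collinearity_filter <- function(m, threshold = 0.8) {
  m <- as.matrix(m)
  if (is.null(colnames(m)))
    colnames(m) <- rownames(m) <- as.character(seq_len(ncol(m)))
  keep <- colnames(m)
  repeat {
    sub <- abs(m[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (all(sub < threshold)) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- vapply(pair, function(cn) {
      others <- setdiff(keep, cn)
      mean(abs(m[cn, others]))
    }, numeric(1))
    drop <- if (mean_abs[2] >= mean_abs[1]) pair[2] else pair[1]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Descriptor prefilter (coverage and variability rules)
#'
#' Operationalizes the usual descriptor-selection preprocessing: a
#' descriptor must be defined (non-missing) for at least
#' \code{min_coverage} of the compounds and take at least
#' \code{min_distinct} distinct values; the rest are dropped.
#'
#' @param t descriptor table.
#' @param min_coverage minimum fraction of compounds with a defined value
#'   (default 0.9).
#' @param min_distinct minimum number of distinct values (default 2; drops
#'   constant columns).
#' @param label_col label column name.
#' @return The table with failing descriptor columns removed.
#' @export
prefilter <- function(t, min_coverage = 0.9, min_distinct = 2,
                      label_col = "label") {
  desc <- setdiff(names(t), c("id", "name", label_col))
  drop <- character(0)
  for (cn in desc) {
    v <- t[[cn]]
    if (mean(!is.na(v)) < min_coverage ||
        length(unique(v[!is.na(v)])) < min_distinct)
      drop <- c(drop, cn)
  }
  t[setdiff(names(t), drop)]
}

#' Random train/test allocation by compound encoding
#'
#' Encodes the compounds 1..n_total, draws \code{n_test} distinct uniform
#' random encodings, and assigns the matching compounds to the test set;
#' the remainder form the training set. Reproducible given \code{seed}.
#'
#' @param n_total total number of compounds (e.g. 128).
#' @param n_test number of test compounds (e.g. 35).
#' @param seed optional integer seed.
#' @return List with sorted integer vectors \code{train} and \code{test}.
#' @examples
#' s <- random_split(128, 35, seed = 1)
#' lengths(s)  # 93 and 35
#' @export
random_split <- function(n_total, n_test, seed = NULL) {
  if (n_test < 1 || n_test >= n_total)
    stop("n_test must satisfy 1 <= n_test < n_total")
  if (!is.null(seed)) set.seed(seed)
  test <- sort(sample.int(n_total, n_test))
  list(train = setdiff(seq_len(n_total), test), test = test)
}
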
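#' Specification of a synthetic descriptor study
#'
#' Bundles everything needed to emulate the benchmark's statistical
#' structure without its (unpublished) descriptor values: the number of
#' compounds, a target correlation matrix for the eight Gaussian
#' descriptors (default: the packaged benchmark correlation matrix), a
#' planted decision rule whose sign defines the carcinogenicity label, a
#' label-noise flip probability, and a seed.
#'
#' @param n_compounds number of compounds (default 128).
#' @param correlation target correlation matrix; column names become the
#'   descriptor names.
#' @param rule planted expression tree over the descriptor names; default
#'   is the balanced linear rule \code{NCOS + NNOS > 0}.
#' @param flip label flip probability in [0, 0.5).
#' @param n_test test-set size for [make_study()] (default 35).
#' @param seed integer seed.
#' @return List of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_compounds = 128, correlation = aa_correlations(),
                           rule = NULL, flip = 0, n_test = 35, seed = 1) {
  if (flip < 0 || flip >= 0.5) stop("flip must lie in [0, 0.5)")
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)))
    stop("correlation target must be symmetric")
  if (is.null(rule)) {
    nm <- tolower(colnames(correlation))
    rule <- structure(list(op = "+", arity = 2L,
                           args = list(nm[1], nm[2])),
                      class = "expression_tree")
  }
  structure(list(n_compounds = n_compounds, correlation = correlation,
                 rule = rule, flip = flip, n_test = n_test, seed = seed),
            class = "synthetic_spec")
}

# Clip negative eigenvalues at zero and rescale to unit diagonal; identity
# when the matrix is already positive semi-definite.
repair_correlation <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values > -tol)) return(list(matrix = m, repaired = FALSE))
  vals <- pmax(e$values, 0)
  r <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  dimnames(r) <- dimnames(m)
  list(matrix = r, repaired = TRUE)
}

#' Generate correlated Gaussian descriptors
#'
#' Draws \code{n} compounds of standard-Gaussian descriptors whose
#' population correlation equals the (PSD-repaired, if necessary) target
#' matrix, via its Cholesky factor. Column names come from the target.
#'
#' @param spec a [synthetic_spec()], or a correlation matrix.
#' @param n number of compounds (defaults to \code{spec$n_compounds}).
#' @param seed optional seed override.
#' @return Data frame with an \code{id} column and one numeric column per
#'   descriptor. The attribute \code{"repaired"} records whether the
#'   target needed eigenvalue clipping.
#' @export
gen_descriptors <- function(spec, n = NULL, seed = NULL) {
  if (is.matrix(spec)) spec <- synthetic_spec(correlation = spec)
  if (is.null(n)) n <- spec$n_compounds
  if (n < 3) stop("need at least 3 compounds")
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  rep <- repair_correlation(spec$correlation)
  L <- chol(rep$matrix + diag(1e-12, ncol(rep$matrix)))
  p <- ncol(rep$matrix)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% L
  colnames(X) <- colnames(spec$correlation)
  out <- data.frame(id = seq_len(n), X, check.names = FALSE)
  attr(out, "repaired") <- rep$repaired
  out
}

#' Plant labels from a decision rule
#'
#' Sets \code{label = 1} exactly where the rule value is strictly
#' positive, then flips each label independently with probability
#' \code{flip}.
#'
#' @param t descriptor table (data frame).
#' @param rule expression tree evaluable on the descriptor columns.
#' @param flip flip probability in [0, 0.5).
#' @param seed optional seed.
#' @return The table with a \code{label} column appended.
#' @export
plant_labels <- function(t, rule, flip = 0, seed = NULL) {
  if (flip < 0 || flip >= 0.5) stop("flip must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  X <- t[setdiff(names(t), c("id", "name", "label"))]
  v <- evaluate(rule, X)
  lab <- as.integer(v > 0)
  if (flip > 0) {
    fl <- stats::runif(length(lab)) < flip
    lab[fl] <- 1L - lab[fl]
  }
  t$label <- lab
  t
}

#' Generate a complete synthetic study (train + test)
#'
#' Emulates the benchmark design end to end: generates
#' \code{spec$n_compounds} correlated descriptor rows, plants labels from
#' the planted rule with its flip probability, and allocates compounds to
#' training and test sets with [random_split()] (default 128 compounds
#' split 93 / 35).
#'
#' @param spec a [synthetic_spec()].
#' @return List with data frames \code{train} and \code{test}, each with
#'   \code{id}, descriptors, and \code{label}.
#' @examples
#' study <- make_study(synthetic_spec(seed = 11))
#' c(nrow(study$train), nrow(study$test))
#' @export
make_study <- function(spec = synthetic_spec()) {
  tab <- gen_descriptors(spec)
  tab <- plant_labels(tab, spec$rule, flip = spec$flip)
  sp <- random_split(spec$n_compounds, spec$n_test)
  list(train = tab[sp$train, , drop = FALSE],
       test = tab[sp$test, , drop = FALSE])
}
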
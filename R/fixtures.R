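#' Packaged aromatic-amine benchmark data
#'
#' The package ships three small plain-text fixtures from the published
#' 128-compound aromatic-amine rat-liver carcinogenicity benchmark:
#' the Pearson correlation matrix of the eight retained molecular
#' descriptors (NCOS, NNOS, KFBI, BBI, SICI, TEIA, PLPT, LUMO), the
#' per-compound experimental labels with the reported GEP and MLP
#' predictions for the 93-compound training and 35-compound test splits,
#' and the reported headline metrics (accuracy, sensitivity, specificity,
#' Youden's index) per model and split.
#'
#' Note: the per-compound prediction columns are arithmetically
#' inconsistent with the reported headline metrics (recomputing GEP test
#' accuracy from the prediction columns gives about 0.686, not the
#' reported 0.829). Both are shipped verbatim; the headline metrics table
#' is the metric ground truth. See the methods vignette.
#'
#' @return \code{aa_correlations()}: 8x8 symmetric numeric matrix with unit
#'   diagonal (the raw file keeps the source's asymmetric precision, e.g.
#'   \code{-0.18}; values are normalized numerically on load).
#' @examples
#' round(aa_correlations()["NCOS", "KFBI"], 3)
#' @export
aa_correlations <- function() {
  path <- system.file("extdata", "aa_descriptor_correlation.tsv",
                      package = "gepqsar")
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           fill = TRUE, check.names = FALSE)
  m <- as.matrix(raw)
  m[is.na(m)] <- 0
  m <- m + t(m) - diag(diag(m))
  storage.mode(m) <- "double"
  m
}

#' @rdname aa_correlations
#' @param split \code{"train"} (93 compounds) or \code{"test"} (35).
#' @return \code{aa_predictions()}: data frame with columns \code{no},
#'   \code{name}, \code{exp} (experimental label), \code{gep}, \code{mlp}
#'   (reported model predictions).
#' @export
aa_predictions <- function(split = c("train", "test")) {
  split <- match.arg(split)
  path <- system.file("extdata",
                      sprintf("aa_%s_predictions.tsv", split),
                      package = "gepqsar")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' @rdname aa_correlations
#' @return \code{aa_reported_metrics()}: data frame with columns
#'   \code{model}, \code{split}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{youden}.
#' @export
aa_reported_metrics <- function() {
  path <- system.file("extdata", "aa_reported_metrics.tsv",
                      package = "gepqsar")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Canonical descriptor schema of the benchmark
#'
#' Maps the generic rule variables x1..x8 to the eight descriptor names:
#' number of C atoms (NCOS), number of N atoms (NNOS), Kier flexibility
#' index (KFBI), Balaban index (BBI), structural information content index
#' order 0 (SICI), topographic electronic index (TEIA), polarity parameter
#' (PLPT) and LUMO energy (LUMO).
#'
#' @return Named character vector \code{c(x1 = "NCOS", ...)}.
#' @export
aa_descriptor_names <- function() {
  c(x1 = "NCOS", x2 = "NNOS", x3 = "KFBI", x4 = "BBI",
    x5 = "SICI", x6 = "TEIA", x7 = "PLPT", x8 = "LUMO")
}

# tree-building helpers for the frozen reference rule
.et <- function(op, ...) {
  args <- list(...)
  structure(list(op = op, arity = length(args), args = args),
            class = "expression_tree")
}

#' The published evolved classification rule
#'
#' The reference study's final GEP model is printed as a single nonlinear
#' arithmetic expression over x1..x8. Its typography is ambiguous in two
#' places (an operand juxtaposed against a two-argument \code{mod}, and a
#' collapsed fraction); the rule is therefore shipped as a frozen
#' expression tree under a documented interpretation, not re-parsed from
#' text:
#' \describe{
#'   \item{\code{"product"} (default)}{juxtaposition is multiplication:
#'     \code{tan(x5+x3) * mod(log(x6*x2), log(x8))} and
#'     \code{log(x5 * mod(x3, x1))}; the collapsed fraction reads
#'     \code{(x1*x6)/(x3+x2)}.}
#'   \item{\code{"bare"}}{the juxtaposed left operand is dropped:
#'     \code{mod(log(x6*x2), log(x8))} and \code{log(mod(x3, x1))}.}
#' }
#' Both interpretations evaluate finitely everywhere under the protected
#' arithmetic policy. Neither is a claim about the original software's
#' internal genome: no descriptor values are published for the 128
#' compounds, so the printed per-compound predictions cannot be
#' regenerated from either reading.
#'
#' @param interpretation \code{"product"} or \code{"bare"}.
#' @return An \code{"expression_tree"} over terminals x1..x8, usable with
#'   [evaluate()] and [to_infix()].
#' @examples
#' v <- reference_rule_value(stats::setNames(rep(1, 8), paste0("x", 1:8)))
#' is.finite(v)
#' @export
aromatic_amine_rule <- function(interpretation = c("product", "bare")) {
  interpretation <- match.arg(interpretation)
  term2 <- .et("tan",
               .et("-", .et("log", .et("+", "x8", "x5")),
                   .et("/", .et("*", "x1", "x6"), .et("+", "x3", "x2"))))
  mod_term <- .et("mod", .et("log", .et("*", "x6", "x2")), .et("log", "x8"))
  term3 <- if (interpretation == "product")
    .et("*", .et("tan", .et("+", "x5", "x3")), mod_term) else mod_term
  inner_mod <- .et("mod", "x3", "x1")
  inner <- if (interpretation == "product")
    .et("log", .et("*", "x5", inner_mod)) else .et("log", inner_mod)
  term7 <- .et("tan", .et("exp", .et("+", inner, "x5")))
  .et("+",
      .et("+",
          .et("+",
              .et("+",
                  .et("+", .et("+", "x1", term2), term3),
                  "x5"),
              .et("tan",
                  .et("-", .et("+", .et("+", "x2", "x3"), "x7"), "x1"))),
          .et("tan", .et("-", .et("+", "x4", "x8"), "x1"))),
      term7)
}

#' Evaluate the published rule on descriptor data
#'
#' Accepts descriptors named either x1..x8 or by their canonical names
#' (NCOS...LUMO, case-insensitive) and returns the rule value(s); the
#' associated carcinogenicity call is 1 iff the value is strictly
#' positive.
#'
#' @param x named numeric vector or data frame of the eight descriptors.
#' @param interpretation passed to [aromatic_amine_rule()].
#' @return Numeric vector of finite rule values.
#' @export
reference_rule_value <- function(x, interpretation = c("product", "bare")) {
  schema <- aa_descriptor_names()
  if (is.null(dim(x))) {
    nm <- tolower(names(x))
    hit <- match(nm, tolower(schema))
    names(x)[!is.na(hit)] <- names(schema)[hit[!is.na(hit)]]
  } else {
    nm <- tolower(colnames(x))
    hit <- match(nm, tolower(schema))
    colnames(x)[!is.na(hit)] <- names(schema)[hit[!is.na(hit)]]
  }
  evaluate(aromatic_amine_rule(interpretation), x)
}
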
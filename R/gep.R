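#' Fit a GEP symbolic classification rule
#'
#' Evolves a Karva-notation arithmetic rule over the descriptor columns and
#' turns it into a binary classifier: a compound is called a carcinogen
#' (class 1) exactly when the rule value is strictly positive; a value of 0
#' is class 0 (conservative for a carcinogen screen).
#'
#' @param formula model formula, e.g. \code{label ~ .} (binary 0/1 response
#'   on the left, numeric descriptors on the right).
#' @param data data frame holding the response and descriptors.
#' @param control a [gep_control()] with population size, operator rates,
#'   fitness mode and seed.
#' @param function_set optional [function_set()]; defaults to the extended
#'   arithmetic alphabet \{+, -, *, /, mod, exp, log, sin, tan\} over the
#'   model's descriptor columns.
#' @return An object of class \code{"gep"} with components
#'   \code{chromosome}, \code{tree}, \code{rule} (infix string),
#'   \code{fitness}, \code{history}, \code{schema} (descriptor names),
#'   \code{control}, \code{train_accuracy} and \code{call}.
#' @examples
#' \donttest{
#' study <- make_study(synthetic_spec(seed = 7))
#' fit <- gep(label ~ . - id, study$train,
#'            control = gep_control(population = 50, generations = 50, seed = 7))
#' mean(predict(fit, study$test) == study$test$label)
#' }
#' @seealso [predict.gep()], [screening_metrics()], [gep_control()]
#' @export
gep <- function(formula, data, control = gep_control(), function_set = NULL) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes must be represented")
  X <- mf[-1]
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all descriptors must be numeric")
  train <- cbind(X, label = as.numeric(y))
  res <- gep_evolve(train, control = control, function_set = function_set,
                    label = "label")
  tree <- decode(res$best)
  pred <- as.integer(evaluate(tree, X) > 0)
  structure(
    list(chromosome = res$best, tree = tree, rule = to_infix(tree),
         fitness = res$fitness, history = res$history,
         schema = names(X), control = control,
         terms = stats::terms(mf),
         train_accuracy = mean(pred == y), call = cl),
    class = "gep")
}

#' Predict carcinogenicity from a fitted GEP rule
#'
#' @param object a fitted [gep()] model.
#' @param newdata data frame containing the model's descriptor columns.
#' @param type \code{"class"} for 0/1 labels (1 iff rule value > 0) or
#'   \code{"value"} for the raw rule values.
#' @param ... unused.
#' @return Numeric vector, one element per row of \code{newdata}.
#' @export
predict.gep <- function(object, newdata, type = c("class", "value"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(tolower(object$schema),
                          tolower(names(newdata)))
  if (length(missing_cols))
    stop("newdata is missing descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  v <- evaluate(object$tree, newdata)
  if (type == "value") v else as.integer(v > 0)
}

#' @export
print.gep <- function(x, ...) {
  cat("GEP classification rule\n")
  cat("  rule:      ", x$rule, "\n")
  cat("  decision:   class 1 (carcinogen) iff rule value > 0\n")
  cat(sprintf("  fitness:    %g (%s mode)\n", x$fitness, x$control$fitness))
  cat(sprintf("  train acc:  %.3f over %d generations\n",
              x$train_accuracy, max(x$history$generation)))
  invisible(x)
}

#' @export
summary.gep <- function(object, ...) {
  structure(list(model = object), class = "summary.gep")
}

#' @export
print.summary.gep <- function(x, ...) {
  m <- x$model
  print(m)
  cat("  chromosome:", format(m$chromosome), "\n")
  cat("  descriptors:", paste(m$schema, collapse = ", "), "\n")
  h <- m$history
  cat(sprintf("  fitness history: start best %g -> final best %g (%d generations logged)\n",
              h$best[1], h$best[nrow(h)], nrow(h)))
  invisible(x)
}

#' @export
coef.gep <- function(object, ...) object$rule

#' Plot the evolution history of a GEP fit
#'
#' Best and mean population fitness per generation.
#'
#' @param x a fitted [gep()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gep <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$best, type = "l", lwd = 2,
                 xlab = "generation", ylab = "fitness",
                 main = "GEP evolution", ...)
  graphics::lines(h$generation, h$mean, lty = 2)
  graphics::legend("bottomright", legend = c("best", "mean"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}

#' Serialize a fitted GEP model to JSON
#'
#' The file stores the chromosome (head, tokens, alphabet), descriptor
#' schema, control parameters, seed and package version, and restores to a
#' model whose predictions are identical.
#'
#' @param object a fitted [gep()] model.
#' @param path output path; when NULL the JSON string is returned.
#' @export
gep_to_json <- function(object, path = NULL) {
  fs <- object$chromosome$function_set
  ctl <- object$control
  ctl$fitness <- as.character(ctl$fitness)
  obj <- list(
    type = "gep_model",
    version = as.character(utils::packageVersion("gepqsar")),
    chromosome = list(head_length = object$chromosome$head_length,
                      symbols = object$chromosome$symbols),
    function_set = list(functions = as.list(fs$functions),
                        terminals = fs$terminals, constants = fs$constants),
    schema = object$schema,
    control = ctl[!vapply(ctl, is.null, logical(1))],
    train_accuracy = object$train_accuracy)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname gep_to_json
#' @param json JSON string or path written by [gep_to_json()].
#' @export
gep_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  const <- as.numeric(obj$function_set$constants)
  base_terms <- setdiff(obj$function_set$terminals,
                        if (length(const)) format(const, trim = TRUE) else character(0))
  fs <- function_set(unlist(obj$function_set$functions), base_terms,
                     constants = const)
  chrom <- chromosome(obj$chromosome$symbols, obj$chromosome$head_length, fs)
  tree <- decode(chrom)
  ctl <- do.call(gep_control, obj$control[names(obj$control) %in%
                                            names(formals(gep_control))])
  structure(
    list(chromosome = chrom, tree = tree, rule = to_infix(tree),
         fitness = NA_real_, history = NULL, schema = obj$schema,
         control = ctl, terms = NULL,
         train_accuracy = obj$train_accuracy, call = NULL),
    class = "gep")
}
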
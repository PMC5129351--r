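#' Function sets for Karva-notation chromosomes
#'
#' A function set bundles the operator alphabet (tokens with arities) and the
#' terminal alphabet (descriptor variable names, plus optional numeric
#' constants) from which chromosomes are built. Tokens are case-insensitive
#' and stored in lowercase.
#'
#' Two stock alphabets are provided: [fset_basic()] is the classic
#' \{+, -, *, /, Q\} set, where \code{Q} is the (protected) square root;
#' [fset_extended()] is the richer \{+, -, *, /, mod, exp, log, sin, tan\}
#' set used to evolve arithmetic classification rules over the eight
#' aromatic-amine descriptors.
#'
#' @param functions named integer vector: names are operator tokens, values
#'   their arities (all >= 1).
#' @param terminals character vector of terminal tokens (variable names).
#' @param constants optional numeric vector of constant terminals (disabled
#'   by default); each constant becomes a terminal token equal to its
#'   decimal rendering.
#' @return An object of class \code{"function_set"} with elements
#'   \code{functions}, \code{terminals}, \code{constants} and
#'   \code{max_arity}.
#' @examples
#' fs <- function_set(c("+" = 2, "Q" = 1), c("a", "b"))
#' fs$max_arity
#' @export
function_set <- function(functions, terminals, constants = numeric(0)) {
  if (length(functions) == 0 || is.null(names(functions)))
    stop("`functions` must be a named integer vector of arities")
  arity <- as.integer(functions)
  names(arity) <- tolower(names(functions))
  if (any(arity < 1L)) stop("arities must be >= 1")
  if (anyDuplicated(names(arity))) stop("duplicate function tokens")
  terminals <- tolower(as.character(terminals))
  const_tok <- if (length(constants)) format(constants, trim = TRUE) else character(0)
  terminals <- c(terminals, const_tok)
  if (length(terminals) == 0) stop("terminal set must be nonempty")
  if (anyDuplicated(terminals)) stop("duplicate terminal tokens")
  if (any(terminals %in% names(arity)))
    stop("function and terminal tokens must be disjoint")
  structure(
    list(functions = arity, terminals = terminals,
         constants = as.numeric(constants), max_arity = max(arity)),
    class = "function_set")
}

#' @rdname function_set
#' @export
fset_basic <- function(terminals = paste0("x", 1:8), constants = numeric(0)) {
  function_set(c("+" = 2, "-" = 2, "*" = 2, "/" = 2, "q" = 1),
               terminals, constants)
}

#' @rdname function_set
#' @export
fset_extended <- function(terminals = paste0("x", 1:8), constants = numeric(0)) {
  function_set(c("+" = 2, "-" = 2, "*" = 2, "/" = 2, "mod" = 2,
                 "exp" = 1, "log" = 1, "sin" = 1, "tan" = 1),
               terminals, constants)
}

#' @export
print.function_set <- function(x, ...) {
  cat("Function set:",
      paste(sprintf("%s/%d", names(x$functions), x$functions), collapse = " "),
      "\n")
  cat("Terminals:", paste(x$terminals, collapse = " "), "\n")
  invisible(x)
}

#' Tail length of a Karva chromosome
#'
#' For head length \code{h} and maximum operator arity \code{n}, the tail
#' must hold \code{t = h (n - 1) + 1} terminals so that every genotype
#' decodes to a complete expression tree.
#'
#' @param head_length positive integer head length \code{h}.
#' @param max_arity positive integer maximum arity \code{n}.
#' @return Integer tail length.
#' @examples
#' tail_length(7, 2)  # 8
#' @export
tail_length <- function(head_length, max_arity) {
  if (!is.numeric(head_length) || length(head_length) != 1 || head_length < 1 ||
      head_length != floor(head_length))
    stop("`head_length` must be a positive integer")
  if (!is.numeric(max_arity) || length(max_arity) != 1 || max_arity < 1 ||
      max_arity != floor(max_arity))
    stop("`max_arity` must be a positive integer")
  as.integer(head_length * (max_arity - 1) + 1)
}

#' Construct a Karva chromosome
#'
#' A chromosome is a fixed-length token string: the first \code{h} positions
#' (the head) may hold operator or terminal tokens; the remaining
#' \code{t = h(n-1)+1} positions (the tail) hold terminals only.
#'
#' @param symbols character vector of tokens, length \code{h + t}, or a
#'   single space-separated string.
#' @param head_length head length \code{h}.
#' @param function_set a [function_set()].
#' @param validate check invariants (default TRUE).
#' @return An object of class \code{"chromosome"}.
#' @examples
#' fs <- fset_basic(letters[1:4])
#' chromosome("* b + a - c d", 3, fs)
#' @export
chromosome <- function(symbols, head_length, function_set, validate = TRUE) {
  if (length(symbols) == 1 && grepl(" ", symbols))
    symbols <- strsplit(trimws(symbols), "\\s+")[[1]]
  obj <- structure(
    list(symbols = tolower(as.character(symbols)),
         head_length = as.integer(head_length),
         function_set = function_set),
    class = "chromosome")
  if (validate) {
    rep <- validate_chromosome(obj)
    if (length(rep)) stop("invalid chromosome: ", paste(rep, collapse = "; "))
  }
  obj
}

#' Validate a chromosome against the head/tail invariants
#'
#' @param c a [chromosome()] (possibly built with \code{validate = FALSE}).
#' @return Character vector of violations; empty when valid.
#' @export
validate_chromosome <- function(c) {
  fs <- c$function_set
  h <- c$head_length
  t <- tail_length(h, fs$max_arity)
  s <- c$symbols
  out <- character(0)
  if (length(s) != h + t)
    out <- c(out, sprintf("length mismatch: expected %d (h=%d + t=%d), got %d",
                          h + t, h, t, length(s)))
  known <- c(names(fs$functions), fs$terminals)
  bad <- setdiff(unique(s), known)
  if (length(bad))
    out <- c(out, paste("unknown token:", paste(bad, collapse = ", ")))
  tail_part <- s[seq_len(length(s)) > h]
  if (any(tail_part %in% names(fs$functions)))
    out <- c(out, "function in tail")
  out
}

is_function_token <- function(tok, fs) tok %in% names(fs$functions)

#' Random valid chromosome
#'
#' Head positions draw uniformly from operators and terminals; tail positions
#' from terminals only. Uses the current RNG stream.
#'
#' @inheritParams chromosome
#' @export
random_chromosome <- function(head_length, function_set) {
  fs <- function_set
  t <- tail_length(head_length, fs$max_arity)
  head_pool <- c(names(fs$functions), fs$terminals)
  chromosome(
    c(sample(head_pool, head_length, replace = TRUE),
      sample(fs$terminals, t, replace = TRUE)),
    head_length, fs, validate = FALSE)
}

#' @export
print.chromosome <- function(x, ...) {
  h <- x$head_length
  cat("Karva chromosome (h =", h, "):",
      paste(x$symbols[1:h], collapse = " "), "|",
      paste(x$symbols[-(1:h)], collapse = " "), "\n")
  invisible(x)
}

#' @export
format.chromosome <- function(x, ...) paste(x$symbols, collapse = " ")

# --- decoding -----------------------------------------------------------

#' Decode a chromosome into an expression tree
#'
#' Karva decoding is breadth-first: the first symbol is the root; each
#' subsequent tree level is filled left to right, consuming one token per
#' open child slot. Decoding stops when no slots remain open; trailing
#' unused tokens are ignored. The tail-length invariant guarantees that
#' every valid chromosome decodes completely.
#'
#' Internally the child positions of node \code{i} are precomputed as a
#' contiguous block starting right after all previously allocated children,
#' then the tree is assembled recursively from those offsets.
#'
#' @param c a valid [chromosome()].
#' @return An \code{"expression_tree"}: leaves are terminal tokens
#'   (character scalars), internal nodes are lists with elements \code{op},
#'   \code{arity} and \code{args}.
#' @examples
#' fs <- fset_basic(letters[1:4])
#' to_infix(decode(chromosome("* b + a - c d a", 3, fs)))
#' @export
decode <- function(c) {
  rep <- validate_chromosome(c)
  if (length(rep)) stop("invalid chromosome: ", paste(rep, collapse = "; "))
  decode_symbols(c$symbols, c$function_set)
}

#' @rdname decode
#' @param symbols token sequence (character vector or space-separated
#'   string): a full chromosome or any Karva prefix long enough to close
#'   every open child slot.
#' @param function_set a [function_set()].
#' @export
decode_symbols <- function(symbols, function_set) {
  if (length(symbols) == 1 && grepl(" ", symbols))
    symbols <- strsplit(trimws(symbols), "\\s+")[[1]]
  fs <- function_set
  s <- tolower(symbols)
  known <- c(names(fs$functions), fs$terminals)
  bad <- setdiff(unique(s), known)
  if (length(bad)) {
    num <- !is.na(suppressWarnings(as.numeric(bad)))
    if (any(!num)) stop("unknown token: ", paste(bad[!num], collapse = ", "))
  }
  ar <- function(tok) if (is_function_token(tok, fs)) fs$functions[[tok]] else 0L
  # allocate child index blocks in level order
  kids <- vector("list", length(s))
  next_free <- 2L
  i <- 1L
  while (i < next_free && i <= length(s)) {
    a <- ar(s[i])
    if (a > 0L) {
      kids[[i]] <- seq.int(next_free, next_free + a - 1L)
      next_free <- next_free + a
    }
    i <- i + 1L
  }
  if (next_free - 1L > length(s))
    stop("incomplete expression: symbol sequence exhausted with open slots")
  build <- function(j) {
    if (is.null(kids[[j]])) return(s[j])
    structure(list(op = s[j], arity = length(kids[[j]]),
                   args = lapply(kids[[j]], build)),
              class = "expression_tree")
  }
  root <- build(1L)
  if (!inherits(root, "expression_tree"))
    root <- structure(list(op = NULL, arity = 0L, leaf = root),
                      class = "expression_tree")
  attr(root, "used") <- next_free - 1L
  root
}

is_leaf_node <- function(node) !is.list(node)

#' Render an expression tree as a fully parenthesized infix string
#'
#' Deterministic: equal trees yield equal strings. Binary operators render as
#' \code{(lhs op rhs)}; unary and n-ary operators as \code{op(args)}; the
#' binary \code{mod} as \code{mod(a,b)}.
#'
#' @param t an expression tree from [decode()], or a bare leaf token.
#' @return A character scalar.
#' @export
to_infix <- function(t) {
  render <- function(node) {
    if (is_leaf_node(node)) return(as.character(node))
    if (!is.null(node$leaf)) return(as.character(node$leaf))
    op <- node$op
    args <- vapply(node$args, render, character(1))
    if (node$arity == 2 && op %in% c("+", "-", "*", "/"))
      paste0("(", args[1], op, args[2], ")")
    else
      paste0(op, "(", paste(args, collapse = ","), ")")
  }
  render(t)
}

# --- protected arithmetic ------------------------------------------------

# Each operator is total on finite inputs: division by zero yields 1, log of
# a non-positive yields 0, square root acts on |x|, exp is clamped at
# exponent +/-700, mod(a,0) is 0, tan is clamped at +/-1e6. A final clamp
# keeps every node value inside [-1e300, 1e300] and maps NaN to 0, so rule
# values are always finite.
.finitize <- function(x) {
  x[is.nan(x)] <- 0
  pmin(pmax(x, -1e300), 1e300)
}

protected_ops <- list(
  "+"   = function(a, b) a + b,
  "-"   = function(a, b) a - b,
  "*"   = function(a, b) a * b,
  "/"   = function(a, b) { r <- a / b; r[b == 0] <- 1; r },
  "q"   = function(a) sqrt(abs(a)),
  "mod" = function(a, b) { r <- a - b * trunc(a / b); r[b == 0] <- 0; r },
  "exp" = function(a) exp(pmin(pmax(a, -700), 700)),
  "log" = function(a) { r <- suppressWarnings(log(a)); r[a <= 0] <- 0; r },
  "sin" = function(a) sin(a),
  "tan" = function(a) pmin(pmax(tan(a), -1e6), 1e6)
)

#' Evaluate an expression tree on descriptor data
#'
#' Recursive, vectorized evaluation: \code{x} may be a single named
#' descriptor vector or a data frame / matrix of compounds (one row each).
#' All arithmetic is protected (see Details), so the result is finite for
#' every finite input.
#'
#' @param t an expression tree ([decode()]) or bare terminal token.
#' @param x named numeric vector, or data frame / matrix with descriptor
#'   columns; names are matched case-insensitively.
#' @return Numeric vector with one value per compound.
#' @details Protected arithmetic policy: \code{a/0 = 1}; \code{log(a) = 0}
#'   for \code{a <= 0}; \code{Q(a) = sqrt(|a|)}; \code{exp} clamped at
#'   exponent \eqn{\pm 700}; \code{mod(a,b)} is the floating remainder with
#'   \code{mod(a,0) = 0}; \code{tan} clamped at \eqn{\pm 10^6}; any NaN
#'   becomes 0 and magnitudes are capped at 1e300.
#' @examples
#' fs <- fset_basic(letters[1:4])
#' tree <- decode(chromosome("* b + a - c d a", 3, fs))
#' evaluate(tree, c(a = 2, b = 3, c = 5, d = 1))  # 3 * (2 + (5 - 1)) = 18
#' @export
evaluate <- function(t, x) {
  if (is.null(dim(x))) {
    nm <- tolower(names(x))
    vals <- as.numeric(x)
  } else {
    x <- as.data.frame(x)
    nm <- tolower(colnames(x))
    vals <- x
  }
  get_leaf <- function(tok) {
    i <- match(tok, nm)
    if (!is.na(i)) {
      if (is.null(dim(x))) return(vals[i]) else return(as.numeric(vals[[i]]))
    }
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) stop("unknown variable: ", tok)
    if (is.null(dim(x))) v else rep(v, nrow(x))
  }
  rec <- function(node) {
    if (is_leaf_node(node)) return(get_leaf(as.character(node)))
    if (!is.null(node$leaf)) return(get_leaf(as.character(node$leaf)))
    f <- protected_ops[[node$op]]
    if (is.null(f)) stop("unknown operator: ", node$op)
    .finitize(do.call(f, lapply(node$args, rec)))
  }
  rec(t)
}

# --- serialization -------------------------------------------------------

#' Serialize / restore a chromosome as JSON
#'
#' The JSON object stores the head length, the token list, the operator
#' arities and the terminal alphabet, so a model file is self-contained.
#'
#' @param c a [chromosome()].
#' @param path file path; when NULL, the JSON string is returned.
#' @export
chromosome_to_json <- function(c, path = NULL) {
  obj <- list(head_length = c$head_length,
              symbols = c$symbols,
              functions = as.list(c$function_set$functions),
              terminals = c$function_set$terminals,
              constants = c$function_set$constants)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname chromosome_to_json
#' @param json JSON string or file path produced by [chromosome_to_json()].
#' @export
chromosome_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  fs <- function_set(unlist(obj$functions),
                     setdiff(obj$terminals,
                             if (length(obj$constants)) format(obj$constants, trim = TRUE) else character(0)),
                     constants = obj$constants)
  chromosome(obj$symbols, obj$head_length, fs)
}
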
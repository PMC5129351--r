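# Independent oracles and fixture builders used across the suite.

# Queue-based level-order Karva decoder, written independently of the
# package's index-offset implementation; renders straight to the same
# fully parenthesized infix dialect for string comparison.
oracle_decode_infix <- function(symbols, fs) {
  s <- tolower(symbols)
  arity <- function(tok) {
    if (tok %in% names(fs$functions)) fs$functions[[tok]] else 0L
  }
  nodes <- list(list(tok = s[1], kids = integer(0)))
  queue <- if (arity(s[1]) > 0) 1L else integer(0)
  ptr <- 2L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    a <- arity(nodes[[cur]]$tok)
    for (k in seq_len(a)) {
      nodes[[length(nodes) + 1L]] <- list(tok = s[ptr], kids = integer(0))
      nodes[[cur]]$kids <- c(nodes[[cur]]$kids, length(nodes))
      if (arity(s[ptr]) > 0) queue <- c(queue, length(nodes))
      ptr <- ptr + 1L
    }
  }
  render <- function(i) {
    nd <- nodes[[i]]
    if (length(nd$kids) == 0) return(nd$tok)
    args <- vapply(nd$kids, render, character(1))
    if (length(args) == 2 && nd$tok %in% c("+", "-", "*", "/"))
      paste0("(", args[1], nd$tok, args[2], ")")
    else
      paste0(nd$tok, "(", paste(args, collapse = ","), ")")
  }
  render(1L)
}

# Direct-formula Pearson correlation for two vectors.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Jittered XOR pattern set: the classic nonlinear sanity check.
xor_data <- function(seed, reps = 50, jitter = 0.1) {
  set.seed(seed)
  base <- expand.grid(x1 = c(0, 1), x2 = c(0, 1))
  d <- base[rep(1:4, reps), ]
  n <- nrow(d)
  truth <- as.integer(xor(d$x1 == 1, d$x2 == 1))
  d$x1 <- d$x1 + rnorm(n, 0, jitter)
  d$x2 <- d$x2 + rnorm(n, 0, jitter)
  d$label <- truth
  rownames(d) <- NULL
  d
}

# Separable two-descriptor table labelled by a planted linear rule.
separable_data <- function(n = 100, seed = 1) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n, 5, 2), x2 = rnorm(n, 5, 2))
  d$label <- as.integer(d$x1 + d$x2 - 10 > 0)
  if (length(unique(d$label)) < 2) stop("degenerate draw")
  d
}
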
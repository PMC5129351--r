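test_that("tail length follows t = h(n-1)+1 and rejects bad input", {
  expect_identical(tail_length(7, 2), 8L)
  expect_identical(tail_length(1, 1), 1L)
  expect_identical(tail_length(10, 3), 21L)
  expect_error(tail_length(0, 2), "positive")
  expect_error(tail_length(3, -1), "positive")
})

test_that("chromosome validation reports head/tail violations", {
  fs <- fset_basic(letters[1:4])
  ok <- chromosome("* b + a - c d a b c d", 5, fs)
  expect_length(validate_chromosome(ok), 0)

  bad_tail <- chromosome(c("*", "b", "+", "a", "-",
                           "c", "*", "a", "b", "c", "d"), 5, fs,
                         validate = FALSE)
  expect_match(validate_chromosome(bad_tail), "function in tail", all = FALSE)

  short <- chromosome(c("*", "a", "b"), 5, fs, validate = FALSE)
  expect_match(validate_chromosome(short), "length mismatch", all = FALSE)

  alien <- chromosome(c("*", "z", "+", "a", "-",
                        "c", "d", "a", "b", "c", "d"), 5, fs,
                      validate = FALSE)
  expect_match(validate_chromosome(alien), "unknown token", all = FALSE)
})

test_that("level-order decoding reproduces the worked multiplication example", {
  fs <- fset_basic(letters[1:4])
  tree <- decode_symbols("* b + a - c d", fs)
  expect_identical(to_infix(tree), "(b*(a+(c-d)))")
  # same prefix embedded in a full-length chromosome, trailing tokens unused
  full <- chromosome("* b + a - c d a b c d", 5, fs)
  expect_identical(to_infix(decode(full)), "(b*(a+(c-d)))")
  # terminal at the root closes decoding immediately
  leaf <- chromosome(c("a", "b"), 1,
                     function_set(c("q" = 1), c("a", "b")))
  expect_identical(to_infix(decode(leaf)), "a")
})

test_that("decoding agrees with an independent queue-based oracle", {
  fs <- fset_extended(paste0("x", 1:8))
  set.seed(42)
  for (i in 1:1000) {
    h <- sample(3:10, 1)
    ch <- random_chromosome(h, fs)
    expect_identical(to_infix(decode(ch)),
                     oracle_decode_infix(ch$symbols, fs))
  }
})

test_that("decoding never reads beyond the chromosome and is deterministic", {
  fs <- fset_basic(letters[1:4])
  set.seed(7)
  for (i in 1:200) {
    h <- sample(2:8, 1)
    ch <- random_chromosome(h, fs)
    tree <- decode(ch)
    expect_lte(attr(tree, "used"), length(ch$symbols))
    expect_identical(to_infix(tree), to_infix(decode(ch)))
  }
})

test_that("infix rendering handles unary operators", {
  fs <- fset_basic(letters[1:2])
  expect_identical(to_infix(decode_symbols("q + a b", fs)), "q((a+b))")
})

test_that("evaluation matches hand arithmetic and honours Q as root", {
  fs <- fset_basic(letters[1:4])
  tree <- decode_symbols("* b + a - c d", fs)
  expect_equal(evaluate(tree, c(a = 2, b = 3, c = 5, d = 1)), 18)
  expect_equal(evaluate(decode_symbols("q a", fs), c(a = 4)), 2)
  # vectorized over a table
  X <- data.frame(a = c(2, 0), b = c(3, 1), c = c(5, 2), d = c(1, 2))
  expect_equal(evaluate(tree, X), c(18, 0))
  expect_error(evaluate(tree, c(a = 1, b = 2, c = 3)), "unknown variable")
})

test_that("protected arithmetic keeps every operation finite", {
  fse <- fset_extended(c("a", "b"))
  expect_equal(evaluate(decode_symbols("log a", fse), c(a = 0, b = 1)), 0)
  expect_equal(evaluate(decode_symbols("log a", fse), c(a = -3, b = 1)), 0)
  expect_equal(evaluate(decode_symbols("/ a b", fse), c(a = 5, b = 0)), 1)
  expect_equal(evaluate(decode_symbols("mod a b", fse), c(a = 5, b = 0)), 0)
  expect_equal(evaluate(decode_symbols("mod a b", fse), c(a = 7.5, b = 2)), 1.5)
  expect_true(is.finite(evaluate(decode_symbols("exp a", fse),
                                 c(a = 1e4, b = 1))))
  fsb <- fset_basic(c("a", "b"))
  expect_equal(evaluate(decode_symbols("q a", fsb), c(a = -9, b = 1)), 3)
})

test_that("every random rule evaluates finitely on extreme inputs", {
  fs <- fset_extended(paste0("x", 1:8))
  set.seed(11)
  X <- matrix(c(rnorm(400), runif(200, -1e8, 1e8), rep(0, 100),
                rep(c(-700, 700), 50)), ncol = 8)
  colnames(X) <- paste0("x", 1:8)
  for (i in 1:300) {
    ch <- random_chromosome(sample(3:9, 1), fs)
    v <- evaluate(decode(ch), as.data.frame(X))
    expect_true(all(is.finite(v)))
  }
})

test_that("tokens are case-insensitive with canonical lowercase storage", {
  fs <- fset_basic(c("A", "b"))
  ch <- chromosome("Q A b", 2, function_set(c("Q" = 1), c("A", "b")))
  expect_identical(ch$symbols[1], "q")
  expect_equal(evaluate(decode(ch), c(A = 16, b = 2)), 4)
})

test_that("numeric constant terminals are supported but off by default", {
  fs_off <- fset_basic(c("a", "b"))
  expect_false(any(c("1", "2") %in% fs_off$terminals))
  fs_on <- fset_basic(c("a", "b"), constants = c(1, 2))
  expect_true(all(c("1", "2") %in% fs_on$terminals))
  tree <- decode_symbols("+ a 2", fs_on)
  expect_equal(evaluate(tree, c(a = 3, b = 0)), 5)
})

test_that("chromosome JSON serialization round-trips", {
  fs <- fset_extended(paste0("x", 1:8))
  set.seed(5)
  ch <- random_chromosome(7, fs)
  js <- chromosome_to_json(ch)
  back <- chromosome_from_json(js)
  expect_identical(back$symbols, ch$symbols)
  expect_identical(back$head_length, ch$head_length)
  expect_identical(to_infix(decode(back)), to_infix(decode(ch)))
})
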
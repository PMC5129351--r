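test_that("gep() learns a separable synthetic study end to end", {
  study <- make_study(synthetic_spec(seed = 7))
  fit <- gep(label ~ . - id, study$train,
             control = gep_control(population = 60, generations = 120,
                                   seed = 7))
  expect_s3_class(fit, "gep")
  expect_gte(fit$train_accuracy, 0.95)
  pred <- predict(fit, study$test)
  expect_true(all(pred %in% c(0L, 1L)))
  expect_length(pred, nrow(study$test))
  expect_gte(mean(pred == study$test$label), 0.9)
})

test_that("prediction follows the strict rule-positive convention", {
  fs <- fset_basic(c("x1", "x2"))
  fit <- structure(
    list(chromosome = NULL, tree = decode_symbols("- x1 x2", fs),
         rule = "(x1-x2)", schema = c("x1", "x2"),
         control = gep_control(), train_accuracy = NA),
    class = "gep")
  nd <- data.frame(x1 = c(5, 3, 3), x2 = c(1.8, 3, 7))
  # value 3.2 -> 1; value exactly 0 -> 0 (ties go to the negative class)
  expect_identical(predict(fit, nd), c(1L, 0L, 0L))
  expect_equal(predict(fit, nd, type = "value"), c(3.2, 0, -4))
  expect_error(predict(fit, data.frame(x1 = 1)), "missing descriptor")
})

test_that("fitting is reproducible and serialization preserves predictions", {
  d <- separable_data(80, seed = 31)
  ctl <- gep_control(population = 40, generations = 40, seed = 12)
  f1 <- gep(label ~ ., d, control = ctl)
  f2 <- gep(label ~ ., d, control = ctl)
  expect_identical(f1$chromosome$symbols, f2$chromosome$symbols)
  expect_identical(f1$history, f2$history)

  path <- withr::local_tempfile(fileext = ".json")
  gep_to_json(f1, path)
  back <- gep_from_json(path)
  expect_identical(back$rule, f1$rule)
  nd <- separable_data(50, seed = 99)
  expect_identical(predict(back, nd), predict(f1, nd))
})

test_that("single-class training data is rejected", {
  d <- data.frame(x1 = rnorm(10), label = rep(1, 10))
  expect_error(gep(label ~ x1, d), "both classes")
})

test_that("print, summary, coef and plot methods work", {
  d <- separable_data(60, seed = 3)
  fit <- gep(label ~ ., d,
             control = gep_control(population = 30, generations = 20, seed = 2))
  expect_output(print(fit), "GEP classification rule")
  expect_output(print(summary(fit)), "chromosome:")
  expect_type(coef(fit), "character")
  tf <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  expect_invisible(plot(fit))
  grDevices::dev.off()
})

test_that("the published rule evaluates finitely under both interpretations", {
  x1 <- stats::setNames(rep(1, 8), paste0("x", 1:8))
  v_prod <- reference_rule_value(x1, "product")
  v_bare <- reference_rule_value(x1, "bare")
  expect_true(is.finite(v_prod))
  expect_true(is.finite(v_bare))

  # independent term-by-term hand evaluation at x = (1, ..., 1), product
  # interpretation, protected ops applied manually:
  #   x1 ............................................. 1
  #   tan(log(x8+x5) - (x1*x6)/(x3+x2)) .............. tan(log 2 - 0.5)
  #   tan(x5+x3) * mod(log(x6*x2), log x8) ........... tan(2) * mod(0, 0) = 0
  #   x5 ............................................. 1
  #   tan(x2+x3+x7-x1) ............................... tan(2)
  #   tan(x4+x8-x1) .................................. tan(1)
  #   tan(exp(log(x5 * mod(x3,x1)) + x5)) ............ tan(exp(0 + 1))
  oracle <- 1 + tan(log(2) - 0.5) + 0 + 1 + tan(2) + tan(1) + tan(exp(1))
  expect_equal(v_prod, oracle, tolerance = 1e-12)

  # descriptor-named input is equivalent to x1..x8 input
  xn <- stats::setNames(rep(1, 8), aa_descriptor_names())
  expect_equal(reference_rule_value(xn), v_prod)

  # batch evaluation stays finite on random descriptor tables
  tab <- gen_descriptors(synthetic_spec(seed = 3), n = 100)
  v <- reference_rule_value(tab[-1])
  expect_true(all(is.finite(v)))
  expect_length(v, 100)

  # threshold behaviour: positive value -> carcinogen call
  expect_identical(as.integer(v_prod > 0), 1L)
})
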
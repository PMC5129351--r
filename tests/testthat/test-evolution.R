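fs2 <- fset_basic(c("x1", "x2"))

test_that("coverage counts tally strictly positive rule values per class", {
  d <- data.frame(x1 = c(6, 7, 1, 9), label = c(1, 1, 0, 0))
  rule <- decode_symbols("- x1 5", fset_basic("x1", constants = 5))
  f <- coverage_counts(rule, d)
  expect_equal(f, list(p_cov = 2, n_cov = 1, P_tot = 2, N_tot = 2))
  expect_error(coverage_counts(rule, data.frame(x1 = 1:3, label = c(1, 1, 1))),
               "both classes")
})

test_that("consig measures precision gain over the base rate", {
  expect_equal(consig(list(p_cov = 10, n_cov = 0, P_tot = 10, N_tot = 10)),
               0.25)
  # precision equal to base rate: first factor vanishes
  expect_equal(consig(list(p_cov = 5, n_cov = 5, P_tot = 10, N_tot = 10)), 0)
  expect_equal(consig(list(p_cov = 0, n_cov = 5, P_tot = 10, N_tot = 10)),
               -0.25)
  # rule that fires on nothing: defined as 0
  expect_equal(consig(list(p_cov = 0, n_cov = 0, P_tot = 10, N_tot = 10)), 0)
})

test_that("compl is the positive-coverage fraction", {
  expect_equal(compl(list(p_cov = 4, n_cov = 0, P_tot = 4, N_tot = 2)), 1)
  expect_equal(compl(list(p_cov = 0, n_cov = 0, P_tot = 4, N_tot = 2)), 0)
  expect_equal(compl(list(p_cov = 3, n_cov = 0, P_tot = 4, N_tot = 2)), 0.75)
})

test_that("consig is bounded by base(1-base), equality iff pure positive coverage", {
  # brute force over all coverage grids with class totals up to 12
  ok_bound <- TRUE; ok_equality <- TRUE
  for (P in 1:12) for (N in 1:12) {
    base <- P / (P + N)
    bound <- base * (1 - base)
    for (p in 0:P) for (n in 0:N) {
      cs <- consig(list(p_cov = p, n_cov = n, P_tot = P, N_tot = N))
      ok_bound <- ok_bound && cs <= bound + 1e-12
      at_bound <- abs(cs - bound) < 1e-12
      ok_equality <- ok_equality && (at_bound == (n == 0 && p > 0))
    }
  }
  expect_true(ok_bound)
  expect_true(ok_equality)
})

test_that("printed fitness mode is degenerate exactly as published", {
  d <- separable_data(40, seed = 2)
  perfect <- decode_symbols("- + 10 x1 x2",
                            fset_basic(c("x1", "x2"), constants = 10))
  # perfect rule: compl = 1, so ln(compl - 1) hits the protected log -> 0
  expect_equal(rule_fitness(perfect, d, mode = "printed"), 0)
  # anti-rule with consig < 0 -> zero branch
  anti <- decode_symbols("- 10 + x1 x2",
                         fset_basic(c("x1", "x2"), constants = 10))
  f <- coverage_counts(anti, d)
  expect_lt(consig(f), 0)
  expect_equal(rule_fitness(anti, d, mode = "printed"), 0)
})

test_that("hits fitness counts correct classifications of both classes", {
  d <- separable_data(40, seed = 2)
  perfect <- decode_symbols("- + 10 x1 x2",
                            fset_basic(c("x1", "x2"), constants = 10))
  expect_equal(rule_fitness(perfect, d, mode = "hits"), 40)
  # the sign-flipped rule misclassifies every compound
  anti <- decode_symbols("- 10 + x1 x2",
                         fset_basic(c("x1", "x2"), constants = 10))
  expect_equal(rule_fitness(anti, d, mode = "hits"), 0)
})

test_that("roulette selection is fitness-proportionate", {
  set.seed(99)
  draws <- replicate(1e5, roulette_select(c(3, 1)))
  p1 <- mean(draws == 1)
  sigma <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(p1 - 0.75), 3 * sigma + 1e-9)
  # all-zero fitness falls back to uniform
  draws0 <- replicate(2000, roulette_select(c(0, 0)))
  expect_gt(mean(draws0 == 1), 0.4)
  expect_lt(mean(draws0 == 1), 0.6)
  expect_equal(roulette_select(5), 1L)
  expect_error(roulette_select(numeric(0)), "empty")
})

test_that("genetic operators map valid chromosomes to valid chromosomes", {
  fs <- fset_extended(paste0("x", 1:8))
  set.seed(13)
  ch <- random_chromosome(7, fs)
  expect_identical(mutate(ch, 0)$symbols, ch$symbols)
  m1 <- mutate(ch, 1)
  expect_length(validate_chromosome(m1), 0)
  violations <- 0L
  for (i in 1:1000) {
    a <- random_chromosome(7, fs)
    b <- random_chromosome(7, fs)
    kids <- recombine(a, b, sample(c("one_point", "two_point"), 1))
    violations <- violations +
      length(validate_chromosome(mutate(a, 0.1))) +
      length(validate_chromosome(transpose(a, "IS"))) +
      length(validate_chromosome(transpose(a, "RIS"))) +
      length(validate_chromosome(kids[[1]])) +
      length(validate_chromosome(kids[[2]]))
  }
  expect_identical(violations, 0L)
})

test_that("transposition edge cases are handled", {
  fs <- fset_basic(c("a", "b"))
  # all-terminal chromosome: RIS has no eligible operator segment
  flat <- chromosome(c("a", "b", "a", "b", "a", "b", "a"), 3, fs)
  expect_identical(transpose(flat, "RIS")$symbols, flat$symbols)
  set.seed(1)
  expect_length(validate_chromosome(transpose(flat, "IS")), 0)
  expect_identical(transpose(flat, "gene")$symbols, flat$symbols)
})

test_that("recombination respects shapes and boundary behaviour", {
  fs <- fset_basic(c("a", "b"))
  set.seed(3)
  a <- random_chromosome(5, fs)
  kids <- recombine(a, a, "one_point")
  expect_identical(kids[[1]]$symbols, a$symbols)
  expect_identical(kids[[2]]$symbols, a$symbols)
  b <- random_chromosome(5, fs)
  swapped <- recombine(a, b, "gene")
  expect_identical(swapped[[1]]$symbols, b$symbols)
  expect_identical(swapped[[2]]$symbols, a$symbols)
  c8 <- random_chromosome(8, fs)
  expect_error(recombine(a, c8, "one_point"), "share")
})

test_that("evolution recovers a planted separable rule", {
  d <- separable_data(200, seed = 21)
  res <- gep_evolve(d, gep_control(population = 100, generations = 200,
                                   seed = 21),
                    function_set = fset_extended(c("x1", "x2"),
                                                 constants = c(1, 10)))
  acc <- res$fitness / nrow(d)
  expect_gte(acc, 0.95)
})

test_that("evolution is reproducible and respects the generation budget", {
  d <- separable_data(60, seed = 5)
  ctl <- gep_control(population = 30, generations = 15, seed = 8,
                     stop_when_perfect = FALSE)
  r1 <- gep_evolve(d, ctl)
  r2 <- gep_evolve(d, ctl)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best$symbols, r2$best$symbols)
  # zero generations: best of the random initial population
  r0 <- gep_evolve(d, gep_control(population = 30, generations = 0, seed = 8))
  expect_equal(nrow(r0$history), 1)
  expect_equal(r0$fitness, r0$history$best[1])
})

test_that("best population fitness is non-decreasing under elitism", {
  d <- separable_data(80, seed = 9)
  res <- gep_evolve(d, gep_control(population = 40, generations = 30,
                                   elitism = 1, seed = 4,
                                   stop_when_perfect = FALSE))
  expect_true(all(diff(res$history$best) >= 0))
})
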
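test_that("Clarke regions match the published boundary cases", {
  expect_equal(as.character(clarke_region(100, 100)), "A")
  expect_equal(as.character(clarke_region(100, 119)), "A")   # within 20%
  expect_equal(as.character(clarke_region(65, 65)), "A")     # hypo corner
  expect_equal(as.character(clarke_region(400, 120)), "D")
  expect_equal(as.character(clarke_region(50, 250)), "E")
  expect_equal(as.character(clarke_region(200, 60)), "E")
  expect_equal(as.character(clarke_region(150, 270)), "C")   # y >= x + 110
  expect_equal(as.character(clarke_region(160, 40)), "C")    # lower-right C
  expect_equal(as.character(clarke_region(300, 150)), "D")
  expect_equal(as.character(clarke_region(100, 150)), "B")
  expect_error(clarke_region(0, 100), "positive")
})

test_that("the prediction diagonal is always region A and assignment is exhaustive", {
  g <- seq(10, 600, by = 10)
  expect_true(all(clarke_region(g, g) == "A"))
  grid <- expand.grid(ref = seq(10, 600, by = 5), pred = seq(10, 600, by = 5))
  r <- clarke_region(grid$ref, grid$pred)
  expect_false(any(is.na(r)))          # exhaustive and exclusive
  expect_setequal(levels(r), c("A", "B", "C", "D", "E"))
})

test_that("range fractions sum to one, count boundaries as in range, and are permutation-invariant", {
  expect_equal(unname(range_fractions(rep(120, 5))), c(1, 0, 0))
  expect_equal(unname(range_fractions(c(70, 120, 200, 150))),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(range_fractions(c(80, 180))), c(1, 0, 0))
  g <- runif(100, 40, 300)
  expect_equal(range_fractions(g), range_fractions(sample(g)))
  expect_equal(sum(range_fractions(g)), 1)
  expect_error(range_fractions(numeric(0)), "empty")
})

test_that("return comparison behaves at the extremes", {
  set.seed(1)
  a <- rnorm(10, 0, 0.1)
  expect_equal(compare_returns(a, a)$p_value, 1, tolerance = 0.05)
  res <- compare_returns(1:10 + 100, 1:10)   # fully separated
  expect_lt(res$p_value, 0.01)
  expect_warning(res2 <- compare_returns(rep(1, 5), rep(1, 5)),
                 "degenerate")
  expect_equal(res2$p_value, 1)
  expect_error(compare_returns(1, 1:5), "at least 2")
})

test_that("glycemic reports have consistent counts and fractions", {
  set.seed(2)
  ref <- runif(200, 50, 300)
  pred <- ref * runif(200, 0.85, 1.15)
  rep_ <- glycemic_report(ref, pred, returns = c(-3, -5, -4))
  expect_equal(sum(rep_$clarke_counts), rep_$n_points)
  expect_equal(rep_$tir + rep_$tar + rep_$tbr, 1)
  expect_equal(rep_$mean_return, -4)
  expect_output(print(rep_), "glycemic_report")
})
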
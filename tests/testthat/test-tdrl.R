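# Single-TDRL forward model, inference, oracle equivalence, bounds.

test_that("apply_tdrl implements the concatenation forward model", {
  ev <- tdrl_event(c(3, 9), copy1_survivors = c(4, 9))
  expect_equal(apply_tdrl(13, ev),
               c(1L, 2L, 4L, 9L, 3L, 5L, 6L, 7L, 8L, 10L, 11L, 12L, 13L))
  # full copy-1 survival leaves the identity
  expect_equal(apply_tdrl(13, tdrl_event(c(3, 9), 3:9)), 1:13)
  expect_equal(apply_tdrl(3, tdrl_event(c(1, 2), 2L)), c(2L, 1L, 3L))
  # survivor sets must partition the interval
  expect_error(tdrl_event(c(3, 9), c(4, 9), c(3, 4, 5, 6, 7, 8)), "overlap")
  expect_error(tdrl_event(c(3, 9), c(4, 9), c(3, 5, 6, 7)), "partition")
})

test_that("run decomposition counts descents and clusters", {
  d <- run_decomposition(c(1, 2, 4, 9, 3, 5, 6, 7, 8, 10, 11, 12, 13))
  expect_length(d$runs, 2)
  expect_equal(d$runs[[1]], c(1L, 2L, 4L, 9L))
  expect_equal(d$runs[[2]], c(3L, 5L, 6L, 7L, 8L, 10L, 11L, 12L, 13L))
  expect_equal(length(d$runs), length(d$descent_positions) + 1L)
  expect_length(run_decomposition(1:5)$runs, 1)
  expect_length(run_decomposition(c(4, 3, 2, 1))$runs, 4)
})

test_that("inference localizes the minimal interval and forced bipartition", {
  inf <- infer_single_tdrl(c(1, 2, 4, 9, 3, 5, 6, 7, 8, 10, 11, 12, 13))
  expect_equal(inf$status, "event")
  expect_equal(inf$interval, c(3L, 9L))
  expect_equal(inf$event$copy1, c(4L, 9L))
  expect_equal(inf$event$copy2, c(3L, 5L, 6L, 7L, 8L))
  # the bipartition is forced: no other split of 3..9 reproduces the window
  target <- c(1L, 2L, 4L, 9L, 3L, 5L, 6L, 7L, 8L, 10L, 11L, 12L, 13L)
  reproducing <- 0L
  for (mask in 0:(2^7 - 1L)) {
    c1 <- (3:9)[as.logical(bitwAnd(mask, 2^(0:6)))]
    if (identical(apply_tdrl(13, tdrl_event(c(3, 9), c1)), target)) {
      reproducing <- reproducing + 1L
    }
  }
  expect_equal(reproducing, 1L)

  expect_equal(infer_single_tdrl(1:13)$status, "identity")
  expect_equal(infer_single_tdrl(c(3, 2, 1))$status, "not_explainable")
})

test_that("inference inverts the forward model (inverse consistency)", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    sim <- simulate_tdrl(simulation_config(window_size = n))
    inf <- infer_single_tdrl(sim$window)
    expect_true(inf$status %in% c("event", "identity"))
    if (inf$status == "event") {
      expect_equal(apply_tdrl(n, inf$event), sim$window$values)
    }
  }
})

test_that("enumeration oracle: n=3 outcomes and n=1 degenerate case", {
  out3 <- enumerate_single_tdrl_outcomes(3)
  keys <- vapply(out3, paste, "", collapse = ",")
  expect_true(all(c("1,2,3", "2,1,3", "1,3,2", "2,3,1", "3,1,2") %in% keys))
  expect_false("3,2,1" %in% keys)
  expect_equal(enumerate_single_tdrl_outcomes(1), list(1L))
  expect_error(enumerate_single_tdrl_outcomes(9), "guard")
  # the rank-7 analogue of the Symphurus pattern is reachable
  keys7 <- vapply(enumerate_single_tdrl_outcomes(7), paste, "",
                  collapse = ",")
  expect_true("2,7,1,3,4,5,6" %in% keys7)
})

test_that("analytic single-TDRL test equals exhaustive enumeration, n <= 6", {
  for (n in 2:6) {
    reachable <- vapply(enumerate_single_tdrl_outcomes(n), paste, "",
                        collapse = ",")
    for (p in all_perms(n)) {
      inf <- infer_single_tdrl(p)
      expect_equal(inf$status %in% c("event", "identity"),
                   paste(p, collapse = ",") %in% reachable,
                   info = paste(p, collapse = ","))
    }
  }
})

test_that("step lower bound: 0 iff identity, 1 for single events, log2 cap", {
  expect_equal(min_tdrl_steps_lower_bound(1:13), 0L)
  expect_equal(min_tdrl_steps_lower_bound(
    c(1, 2, 4, 9, 3, 5, 6, 7, 8, 10, 11, 12, 13)), 1L)
  expect_equal(min_tdrl_steps_lower_bound(c(4, 3, 2, 1)), 2L)
  set.seed(3)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    p <- sample(n)
    b <- min_tdrl_steps_lower_bound(p)
    expect_equal(b == 0L, identical(as.integer(p), seq_len(n)))
    expect_lte(b, ceiling(log2(n)))
    if (infer_single_tdrl(p)$status == "event") expect_equal(b, 1L)
  }
})
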
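test_that("replication cost follows 2 L (e_d + e_p) and is linear in L", {
  expect_identical(replicationCost(1), 26)
  expect_identical(replicationCost(1, eD = 0, eP = 0), 0)
  expect_identical(replicationCost(194000), 2 * 194000 * 13)
  # linearity
  L <- c(1, 10, 1e3, 2e5)
  expect_equal(replicationCost(L), L * replicationCost(1))
  expect_error(replicationCost(0))
  expect_error(replicationCost(100, eD = -1))
})

test_that("cost difference depends only on the length difference", {
  expect_identical(costDifference(12000 + 1, 1), 312000)
  expect_identical(costDifference(194000, 182000), 312000)
  expect_identical(costDifference(200000, 188000), 312000)
  expect_identical(costDifference(5e4, 5e4), 0)
  # symmetric
  expect_identical(costDifference(182000, 194000), 312000)
  # exact integer arithmetic
  expect_true(costDifference(194000, 182000) %% 1 == 0)
})
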
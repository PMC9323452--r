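mock_set <- function(species, means, sds = 0, n = 500, pair = "phi_j,phi_ad",
                     ctype = 1, gt = NA_real_, seed = 1) {
  set.seed(seed)
  purrr::map2_dfr(species, means, function(sp, m) {
    tibble::tibble(
      species = sp, correlation_type = ctype, pair = pair,
      draw = seq_len(n), value = rnorm(n, m, sds),
      generation_time = gt[match(sp, species)]
    )
  })
}

test_that("correlations derive from variances and covariances draw-wise", {
  expect_equal(correlations_from_sigma(0.3, 0.2, 0.03), 0.5)
  expect_equal(correlations_from_sigma(c(0.3, 0.4), c(0.2, 0.4), c(0, 0)), c(0, 0))
  expect_warning(
    r <- correlations_from_sigma(c(0.3, 0), c(0.2, 0.2), c(0.03, 0.01)),
    "degenerate"
  )
  expect_equal(r, 0.5)
  expect_error(
    correlations_from_sigma(0.1, 0.1, 0.5),
    "outside"
  )
  # elementwise oracle on draws from a mock posterior
  set.seed(61)
  sx <- runif(200, 0.2, 0.5)
  sy <- runif(200, 0.2, 0.5)
  cv <- runif(200, -1, 1) * sx * sy
  expect_equal(correlations_from_sigma(sx, sy, cv), cv / (sx * sy))
})

test_that("grand means average species draws at equal indices", {
  sets <- dplyr::bind_rows(
    mock_set("A", 0.2, sds = 0, n = 100),
    mock_set("B", 0.4, sds = 0, n = 100)
  )
  gm <- grand_mean(sets, n_draws = 100)
  expect_equal(gm$summary$mean, 0.3)
  expect_equal(gm$summary$sd, 0)
  expect_equal(gm$summary$n_species, 2)
  # single species: identity
  one <- mock_set("A", 0.25, sds = 0.1, n = 3000, seed = 3)
  gm1 <- grand_mean(one, n_draws = 3000)
  expect_equal(sort(gm1$draws$value), sort(one$value))
  # error when no species contributes
  expect_error(grand_mean(sets, pair = "psi,pi"), "no contributing")
})

test_that("grand-mean posterior mean equals the average of species means", {
  sets <- dplyr::bind_rows(
    mock_set("A", 0.1, sds = 0.2, n = 3000, seed = 4),
    mock_set("B", 0.3, sds = 0.1, n = 3000, seed = 5),
    mock_set("C", -0.2, sds = 0.15, n = 3000, seed = 6)
  )
  gm <- grand_mean(sets, n_draws = 3000)
  by_sp <- tapply(sets$value, sets$species, mean)
  expect_equal(gm$summary$mean, mean(by_sp), tolerance = 1e-10)
  # linearity holds exactly because draws enter at equal counts
  expect_equal(mean(gm$draws$value), mean(by_sp), tolerance = 1e-10)
})

test_that("resampling to a common draw count is deterministic", {
  x <- rnorm(5000)
  expect_identical(resample_draws(x, 3000, seed = 2), resample_draws(x, 3000, seed = 2))
  expect_length(resample_draws(x, 3000), 3000)
  expect_length(resample_draws(x[1:10], 3000), 3000)
  expect_identical(resample_draws(x[1:3000], 3000), x[1:3000])
})

test_that("direction tallies count signs, CRI overlap and type flips", {
  sets <- dplyr::bind_rows(
    mock_set("A", 0.1, sds = 0.01, n = 200, seed = 7),
    mock_set("B", -0.2, sds = 0.01, n = 200, seed = 8),
    mock_set("C", 0.3, sds = 0.01, n = 200, seed = 9),
    # wide posterior straddling zero
    mock_set("D", 0.05, sds = 0.2, n = 200, seed = 10)
  )
  tal <- direction_tally(sets)
  expect_equal(tal$overall$n, 4)
  expect_equal(tal$overall$n_positive, 3)
  expect_equal(tal$overall$n_negative, 1)
  expect_equal(tal$by_pair$n, 4)
  expect_equal(tal$overall$frac_cri_overlap_zero, 1 / 4)
  # one sign flip between the two correlation types
  both <- dplyr::bind_rows(
    mock_set("A", 0.37, sds = 0.01, n = 200, ctype = 2, seed = 11),
    mock_set("A", -0.29, sds = 0.01, n = 200, ctype = 1, seed = 12),
    mock_set("B", 0.2, sds = 0.01, n = 200, ctype = 2, seed = 13),
    mock_set("B", 0.1, sds = 0.01, n = 200, ctype = 1, seed = 14)
  )
  tal2 <- direction_tally(both)
  expect_equal(sum(tal2$sign_flips$sign_flip), 1)
  expect_equal(nrow(tal2$sign_flips), 2)
})

test_that("type contrasts form draw-wise differences with a P value", {
  same <- mock_set("A", 0.2, sds = 0.1, n = 3000, seed = 15)
  cmp <- compare_types(same, same, pair = "phi_j,phi_ad")
  expect_equal(cmp$summary$mean, 0)
  expect_equal(cmp$summary$P, 0.5)
  t1 <- mock_set("A", 0.5, sds = 0.001, n = 3000, seed = 16)
  t2 <- mock_set("A", -0.5, sds = 0.001, n = 3000, seed = 17)
  cmp2 <- compare_types(t2, t1, pair = "phi_j,phi_ad")
  expect_equal(cmp2$summary$mean, 1, tolerance = 0.01)
  expect_equal(cmp2$summary$P, 1)
  expect_error(compare_types(t1, t2, pair = "psi,pi"), "absent")
})

test_that("tallies are internally consistent on random suites", {
  set.seed(18)
  sets <- purrr::map_dfr(1:6, function(i) {
    mock_set(LETTERS[i], rnorm(1, 0, 0.3), sds = runif(1, 0.05, 0.3),
      n = 400, seed = 20 + i
    )
  })
  tal <- direction_tally(sets)
  expect_equal(tal$overall$n_positive + tal$overall$n_negative, tal$overall$n)
  expect_true(all(tal$by_pair$frac_cri_overlap_zero >= 0 &
    tal$by_pair$frac_cri_overlap_zero <= 1))
  gm <- grand_mean(sets, n_draws = 400)
  expect_true(all(abs(gm$draws$value) <= 1 + 1e-12 |
    abs(gm$draws$value) <= max(abs(sets$value))))
})
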
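mk_series <- function(...) {
  specs <- list(...)
  structure(lapply(specs, function(s)
    list(peaks = s$peaks, mean_dmz = s$dmz, mean_drt = s$drt, r2 = 1)),
    class = "homol_series_list")
}

test_that("peak-sharing pairs are extracted exactly once, dmz-ordered", {
  s <- mk_series(list(peaks = 1:5, dmz = 14, drt = 20),
                 list(peaks = 6:10, dmz = 44, drt = 30),
                 list(peaks = 11:15, dmz = 58, drt = 40))
  expect_equal(nrow(find_pairs(s)), 0L)   # disjoint
  s2 <- mk_series(list(peaks = c(1, 2, 3), dmz = 14, drt = 20),
                  list(peaks = c(3, 4, 5), dmz = 44, drt = 30),
                  list(peaks = c(3, 6, 7), dmz = 58, drt = 40))
  pr <- find_pairs(s2)
  expect_equal(nrow(pr), 3L)              # C(3,2) around the shared peak
  expect_true(all(pr$mean_dmz_x >= pr$mean_dmz_y))
  # an identical duplicated series forms one pair sharing all peaks
  s3 <- mk_series(list(peaks = 1:4, dmz = 14, drt = 20),
                  list(peaks = 1:4, dmz = 14, drt = 20))
  pr3 <- find_pairs(s3)
  expect_equal(nrow(pr3), 1L)
  expect_equal(pr3$n_shared, 4L)
})

test_that("intersection angles: parallel, orthogonal, symmetric, clamped", {
  expect_equal(intersection_angle(2, 28, 1, 14, c_drt = 1, c_dmz = 1), 0)
  expect_equal(intersection_angle(1, 0, 0, 1, c_drt = 1, c_dmz = 1), pi / 2)
  th1 <- intersection_angle(3, 14, -2, 44, 10, 50)
  th2 <- intersection_angle(-2, 44, 3, 14, 10, 50)
  expect_equal(th1, th2)
  # common rescaling of RT means and their scale leaves theta unchanged
  th3 <- intersection_angle(3 * 7, 14, -2 * 7, 44, 10 * 7, 50)
  expect_equal(th1, th3)
  # numerically parallel vectors survive the acos clamp
  expect_equal(intersection_angle(0.1 * 3, 0.1 * 7, 3, 7, 1, 1), 0)
  expect_error(intersection_angle(1, 1, 1, 1, 0, 1), "c_drt > 0")
})

test_that("pair angles match a direct high-precision computation", {
  set.seed(51)
  for (i in 1:50) {
    ux <- c(runif(1, -5, 5), runif(1, 0.1, 5))
    uy <- c(runif(1, -5, 5), runif(1, 0.1, 5))
    th <- intersection_angle(ux[1], ux[2], uy[1], uy[2], 1, 1)
    ref <- acos(sum(ux * uy) / sqrt(sum(ux^2) * sum(uy^2)))
    expect_equal(th, ref, tolerance = 1e-12)
    expect_true(th >= 0 && th <= pi)
  }
})

test_that("superjacency classification and SOM vectors", {
  s <- mk_series(list(peaks = c(1, 2, 3), dmz = 14.016, drt = 20),
                 list(peaks = c(2, 4, 5), dmz = 28.031, drt = 40),
                 list(peaks = c(2, 6, 7), dmz = 44.026, drt = -30))
  pr <- pair_angles(s)
  expect_equal(pr$superjacent, pr$theta < 0.08 * pi)
  # the parallel pair (series 1 and 2) is superjacent
  par_row <- pr[pr$series_x == 2 & pr$series_y == 1, ]
  expect_true(par_row$superjacent)
  # a zero threshold labels nothing superjacent
  expect_false(any(pair_angles(s, theta_threshold = 0)$superjacent))
  v <- pair_vectors(pr, c_hat_drt = 1, c_hat_dmz = 1)
  expect_equal(v[, "dmz_x"], pr$mean_dmz_x)
  expect_equal(pair_vectors(pr, 2, 2), v / 2)
  # x/y ordering normalizes the vector regardless of input order
  expect_true(all(v[, "dmz_x"] >= v[, "dmz_y"]))
})

test_that("cross-sample prevalence counts samples within the window", {
  one <- delta_mz_prevalence(list(a = c(14.016, 44.026)))
  expect_equal(one$n_samples, c(1L, 1L))
  three <- delta_mz_prevalence(list(a = c(14.016, 30.011),
                                    b = 14.0157, c = c(14.0163, 58.042)))
  expect_equal(three$n_samples[abs(three$dmz - 14.016) < 1e-3][1], 3L)
  expect_true(all(three$n_samples <= 3L))
  # units 1 Th apart with a +/-0.005 window count independently
  two <- delta_mz_prevalence(list(a = 14, b = 15))
  expect_equal(two$n_samples, c(1L, 1L))
})
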
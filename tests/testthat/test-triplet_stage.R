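test_that("subspace boxes implement the interval arithmetic", {
  g <- gamma_bounds(c("C", "H", "N", "O", "S", "Cl", "Br"))
  p <- default_test_params(dmz_min = 14, dmz_max = 60, drt_min = 10,
                           drt_max = 120)
  pk <- as_peaklist(data.frame(mz = 300, rt = 300, intensity = 1))
  vec <- embed_peaks(pk, g)[1, ]
  boxes <- subspace_boxes(vec, mass_defect(300), p, g)
  H <- boxes$H[[1]]
  expect_equal(H$lo[1], 314, tolerance = 1e-6)
  expect_equal(H$hi[1], 360, tolerance = 1e-6)
  expect_equal(H$lo[4], 310, tolerance = 1e-6)
  expect_equal(H$hi[4], 420, tolerance = 1e-6)
  # L mirrors H through the center in dims 1 and 4
  L <- boxes$L[[1]]
  expect_equal(vec[1] - L$hi[1], H$lo[1] - vec[1], tolerance = 1e-6)
  expect_equal(vec[4] - L$lo[4], H$hi[4] - vec[4], tolerance = 1e-6)
  # degenerate RT window collapses to the center RT
  p0 <- default_test_params(drt_min = 0, drt_max = 0)
  H0 <- subspace_boxes(vec, mass_defect(300), p0, g)$H[[1]]
  expect_equal(H0$lo[4], H0$hi[4], tolerance = 1e-6)
})

test_that("a single planted CH2 chain yields exactly one triplet", {
  pk <- ch2_series_peaks(3)
  trip <- find_triplets(pk, default_test_params())
  expect_equal(unname(trip), matrix(1:3, nrow = 1))
})

test_that("spacings below the m/z window yield nothing", {
  pk <- as_peaklist(data.frame(mz = c(200, 210, 220), rt = c(10, 20, 30),
                               intensity = 1))
  p <- default_test_params(dmz_min = 14)
  expect_equal(nrow(find_triplets(pk, p)), 0L)
  expect_equal(nrow(find_triplets(pk[0, ], p)), 0L)
})

test_that("triplet search equals the brute-force predicate oracle", {
  set.seed(202)
  gam <- gamma_bounds(c("C", "H", "N", "O", "S", "Cl", "Br"))
  for (rep in 1:12) {
    pk <- random_peaklist(sample(30:150, 1))
    p <- detection_params(dmz_min = runif(1, 5, 15),
                          dmz_max = runif(1, 40, 80),
                          drt_min = runif(1, -60, 0),
                          drt_max = runif(1, 50, 200),
                          ddrt_max = runif(1, 10, 60), n_min = 3,
                          epsilon = epsilon_model(runif(1, 1e-3, 2e-2)))
    expect_identical(unname(find_triplets(pk, p, gam)),
                     unname(brute_triplets(pk, p, gam)))
  }
})

test_that("mass-defect wraps across +/-0.5 are handled", {
  # a CH2 chain whose member defects cross the 0.5 boundary
  dmz <- unit_mass("CH2")
  mz <- 492.49 + (0:4) * dmz   # defects: 0.490, .505 -> -0.494, ...
  expect_gt(max(abs(diff(mass_defect(mz)))), 0.9)  # raw wrap present
  pk <- as_peaklist(data.frame(mz = mz, rt = 100 + (0:4) * 30,
                               intensity = 1))
  # dmz_max below 2 units so only consecutive-member triplets qualify
  trip <- find_triplets(pk, default_test_params(dmz_max = 20))
  expect_equal(nrow(trip), 3L)
  res <- detect_series(pk, default_test_params(n_min = 5))
  expect_length(res, 1L)
  expect_equal(res[[1]]$peaks, 1:5)
})

test_that("triplets respect bounds and are monotone in epsilon", {
  set.seed(303)
  pk <- random_peaklist(120)
  p_small <- default_test_params(epsilon = epsilon_model(1e-3))
  p_large <- default_test_params(epsilon = epsilon_model(2e-2))
  t_small <- find_triplets(pk, p_small)
  t_large <- find_triplets(pk, p_large)
  key <- function(m) apply(m, 1, paste, collapse = "-")
  expect_true(all(key(t_small) %in% key(t_large)))
  if (nrow(t_large) > 0) {
    d12 <- pk$mz[t_large[, 2]] - pk$mz[t_large[, 1]]
    d23 <- pk$mz[t_large[, 3]] - pk$mz[t_large[, 2]]
    expect_true(all(d12 >= p_large$dmz_min & d12 <= p_large$dmz_max))
    expect_true(all(d23 >= p_large$dmz_min & d23 <= p_large$dmz_max))
    r12 <- pk$rt[t_large[, 2]] - pk$rt[t_large[, 1]]
    expect_true(all(r12 >= p_large$drt_min & r12 <= p_large$drt_max))
  }
})
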
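test_that("overlapping tuples merge; disjoint ones are retained", {
  pk <- ch2_series_peaks(4)
  p <- default_test_params()
  st <- merge_step(list(c(1L, 2L, 3L), c(2L, 3L, 4L)), pk, p)
  expect_equal(st$extended, list(c(1L, 2L, 3L, 4L)))
  expect_length(st$retained, 0L)
  # two disjoint chains: nothing merges
  pk2 <- as_peaklist(rbind(
    data.frame(mz = 200 + (0:2) * unit_mass("CH2"), rt = 100 + (0:2) * 20,
               intensity = 1),
    data.frame(mz = 600 + (0:2) * unit_mass("CH2"), rt = 500 + (0:2) * 20,
               intensity = 1)))
  st2 <- merge_step(list(1:3, 4:6), pk2, p)
  expect_length(st2$extended, 0L)
  expect_length(st2$retained, 2L)
})

test_that("a triplet can branch into two 4-tuples via an isobaric twin", {
  dmz <- unit_mass("CH2")
  # members 1,2,3 then two isobaric variants of member 4
  pk <- as_peaklist(data.frame(
    mz = c(200, 200 + dmz, 200 + 2 * dmz, 200 + 3 * dmz,
           200 + 3 * dmz + 5e-4),
    rt = c(100, 120, 140, 160, 162), intensity = 1))
  p <- default_test_params()
  st <- merge_step(list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(2L, 3L, 5L)),
                   pk, p)
  expect_length(st$extended, 2L)
  expect_length(st$retained, 0L)   # the branching triplet is removed once
})

test_that("the spline RT model check behaves at its limits", {
  mz <- 200 + (0:5) * 14
  rt_lin <- 100 + (0:5) * 25
  expect_true(spline_check(mz, rt_lin, lambda = 0, r2_min = 0.99)$pass)
  expect_equal(spline_check(mz, rt_lin, lambda = 0, r2_min = 0.99)$r2, 1)
  # constant RT: SS_tot = 0 passes by convention
  expect_true(spline_check(mz, rep(5, 6), lambda = 10, r2_min = 0.9)$pass)
  # a smooth monotone trend passes under smoothing
  expect_true(spline_check(mz, rt_lin, lambda = 1e-3, r2_min = 0.9)$pass)
  # one gross RT outlier under strong smoothing fails
  rt_out <- rt_lin; rt_out[3] <- rt_out[3] + 400
  sc <- spline_check(mz, rt_out, lambda = 1, r2_min = 0.9)
  expect_false(sc$pass)
  expect_lt(sc$r2, 0.9)
  # short tuples are not checked
  expect_true(spline_check(mz[1:3], rt_out[1:3], lambda = 1,
                           r2_min = 0.9)$pass)
})

test_that("regular-omission sub-tuples are filtered, irregular ones kept", {
  parents <- list(c(1L, 2L, 3L, 4L, 5L))
  kept <- filter_subtuples(list(c(1L, 3L, 5L), c(1L, 2L, 4L)), parents)
  expect_equal(kept, list(c(1L, 2L, 4L)))
  # no parent present: nothing is removed
  expect_length(filter_subtuples(list(c(1L, 3L, 5L)), list()), 1L)
  # offsets and longer steps
  parents7 <- list(1:7)
  expect_length(filter_subtuples(list(c(2L, 4L, 6L), c(1L, 4L, 7L),
                                      c(1L, 3L, 5L, 7L)), parents7), 0L)
})

test_that("planted series are recovered exactly over background", {
  sim <- simulate_peaklist(list(planted_series(length = 8)),
                           n_background = 500, seed = 21)
  res <- detect_series(sim$peaks, detection_params(n_min = 5))
  planted <- sim$truth$peak_id[!is.na(sim$truth$series)]
  hit <- vapply(res, function(s) all(planted %in% s$peaks), logical(1))
  expect_true(any(hit))
  # every reported series satisfies the full series definition
  p <- detection_params(n_min = 5)
  gam <- gamma_bounds(p$elements)
  expect_true(all(vapply(res, function(s)
    validate_tuple(s$peaks, sim$peaks, p, gam), logical(1))))
})

test_that("n_min cuts short series and two series may share a peak", {
  pk <- ch2_series_peaks(4)
  expect_length(detect_series(pk, default_test_params(n_min = 5)), 0L)
  expect_length(detect_series(pk, default_test_params(n_min = 4)), 1L)
  # crossing series: one CH2 chain, one C2H4O chain sharing one member
  d1 <- unit_mass("CH2"); d2 <- unit_mass("C2H4O")
  a <- data.frame(mz = 300 + (0:4) * d1, rt = 200 + (0:4) * 25)
  b <- data.frame(mz = 300 + 2 * d1 - (2:0) * d2,
                  rt = 200 + 2 * 25 - (2:0) * 40)
  pk2 <- as_peaklist(data.frame(mz = c(a$mz, b$mz[-3]),
                                rt = c(a$rt, b$rt[-3]), intensity = 1))
  res <- detect_series(pk2, default_test_params(n_min = 3))
  shared <- pk2$peak_id[abs(pk2$mz - (300 + 2 * d1)) < 1e-9]
  n_with_shared <- sum(vapply(res, function(s) shared %in% s$peaks,
                              logical(1)))
  expect_gte(n_with_shared, 2L)
})

test_that("a series gap splits recovery into flanking fragments", {
  # 9 members with member 5 missing; fragments of length 4 reach n_min = 4
  sim <- simulate_peaklist(list(planted_series(length = 9, gaps = 5L,
                                               rt_model = "constant")),
                           seed = 31)
  res <- detect_series(sim$peaks, detection_params(n_min = 4,
                                                   dmz_max = 20))
  lens <- sort(vapply(res, function(s) length(s$peaks), integer(1)))
  expect_equal(lens, c(4L, 4L))
  # with dmz_max admitting a double-spacing bridge, a bridging series
  # across the gap can also appear
  res2 <- detect_series(sim$peaks, detection_params(n_min = 4))
  expect_gte(length(res2), 2L)
})
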
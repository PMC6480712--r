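# chi1 traces, cis/trans classification, occupancy, stability windows.

test_that("chi1_trace reads constructed sidechain torsions exactly", {
  for (x1 in c(300, 180, 57.3)) {
    p <- build_toy_protomer(chi1 = c("199" = x1, "390" = x1))
    tr <- traj_from_frames(p$structure, list(coords_matrix(p$structure)))
    expect_equal(chi1_trace(tr, "A", 199)$chi1, x1, tolerance = 1e-6)
    expect_equal(chi1_trace(tr, "A", 390)$chi1, x1, tolerance = 1e-6)
    expect_equal(chi1_trace(tr, bw = p$bw, bw_id = "5.48")$chi1, x1,
                 tolerance = 1e-6)
  }
  p <- build_toy_protomer()
  tr <- traj_from_frames(p$structure, list(coords_matrix(p$structure)))
  expect_error(chi1_trace(tr, "A", 195), "lacks atom CB")  # glycine filler
})

test_that("rotamer classification follows the strict >240 cis convention", {
  expect_equal(classify_rotamer(300), "cis")
  expect_equal(classify_rotamer(180), "trans")
  expect_equal(classify_rotamer(240), "trans")     # tie goes to trans
  expect_equal(classify_rotamer(240 + 1e-9), "cis")
  expect_error(classify_rotamer(-10), "wrap")
  expect_error(classify_rotamer(360), "wrap")
  expect_equal(classify_rotamer(wrap_angle(-60)), "cis")
  # wrap is idempotent under classification
  a <- seq(0, 359.9, by = 7.7)
  expect_identical(classify_rotamer(a), classify_rotamer(wrap_angle(a)))
  # raising the threshold never increases the cis fraction
  f_cis <- function(th) mean(classify_rotamer(a, threshold = th) == "cis")
  ths <- c(120, 180, 240, 300)
  expect_true(all(diff(vapply(ths, f_cis, 0)) <= 0))
})

test_that("occupancies count frames and are window-additive", {
  tr <- tibble::tibble(frame = 1:1000, time = (0:999) * 0.1,
                       chi1 = rep(c(180, 300), 500))
  class(tr) <- c("chi1_trace", class(tr))
  st <- rotamer_states(tr)
  occ <- state_occupancy(st)
  expect_equal(occ$fraction_cis, 0.5)
  expect_equal(occ$fraction_trans, 0.5)
  expect_equal(occ$fraction_cis + occ$fraction_trans, 1)

  all_trans <- tr; all_trans$chi1 <- 180
  expect_equal(state_occupancy(rotamer_states(all_trans))$fraction_trans, 1.0)

  # counts over a partition of the window sum to the window's counts
  o1 <- state_occupancy(st, c(-0.05, 49.95))
  o2 <- state_occupancy(st, c(49.95, 99.95))
  expect_equal(o1$n_cis + o2$n_cis, occ$n_cis)
  expect_equal(o1$n_frames + o2$n_frames, occ$n_frames)
  expect_error(state_occupancy(st, c(200, 300)), "no frames")
})

test_that("markov occupancy is recovered within the autocorrelation-aware band", {
  spec <- synthetic_spec(n_frames = 10000, seed = 42,
                         rotamers = list(rotamer_plan("A", 199, 0.75, p_stay = 0.9)))
  s <- generate_rotamer_sequence(spec, 1)
  est <- mean(classify_rotamer(s$angles) == "trans")
  se <- rotamer_recovery_se(0.75, 0.9, 10000)
  expect_lt(abs(est - 0.75), 3 * se)
})

test_that("stability onset finds the earliest all-below-threshold suffix", {
  mk <- function(v) {
    tr <- tibble::tibble(frame = seq_along(v), time = seq_along(v) - 1, rmsd = v)
    class(tr) <- c("rmsd_trace", class(tr))
    tr
  }
  expect_equal(stability_onset(mk(c(1, 2, 1)), 3)$onset, 0)  # all below: first frame
  w <- stability_onset(mk(c(5, 4, 2, 2, 3.5, 1, 1)), 3)
  expect_equal(w$onset, 5)                  # last violation at index 5 (time 4)
  expect_equal(w$onset_frame, 6L)
  # worst case: everything at/above threshold except the final frame
  expect_equal(stability_onset(mk(c(5, 5, 0)), 3)$onset, 2)
  # monotone in threshold: larger threshold, onset never later
  v <- c(4, 1, 3.2, 2.9, 1, 0.5)
  on <- vapply(c(1, 2, 3, 3.5, 5), function(th) stability_onset(mk(v), th)$onset, 0)
  expect_true(all(diff(on) <= 0))
})

test_that("trace summaries use population SD and circular statistics for angles", {
  expect_equal(summarize_trace(c(2, 2, 2)), tibble::tibble(mean = 2, sd = 0, n = 3))
  expect_equal(summarize_trace(c(1, 3))$sd, 1)
  expect_equal(summarize_trace(c(1, 3))$mean, 2)
  expect_error(summarize_trace(5), "at least 2")

  # circular mean across the 0/360 seam
  s <- summarize_trace(c(350, 10), circular = TRUE)
  expect_lt(min(s$mean, 360 - s$mean), 1e-9)  # circularly at the seam
  expect_lt(s$sd, 15)
  set.seed(7)
  g <- wrap_angle(300 + rnorm(4000, sd = 12))
  sg <- summarize_trace(g, circular = TRUE)
  expect_equal(sg$mean, 300, tolerance = 1)
  expect_equal(sg$sd, 12, tolerance = 0.7)

  # gaussian recovery on a plain trace
  set.seed(8)
  v <- rnorm(5000, mean = 1.5, sd = 0.5)
  sv <- summarize_trace(v)
  expect_lt(abs(sv$mean - 1.5), 3 * 0.5 / sqrt(5000))
})
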
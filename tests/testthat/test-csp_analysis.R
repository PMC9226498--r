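make_peaks <- function(residue, h, n) {
  pk <- data.frame(residue = residue, h_ppm = h, n_ppm = n)
  class(pk) <- c("peak_list", "data.frame")
  pk
}

test_that("combined CSP evaluates the weighted amide formula", {
  ref <- make_peaks(1:3, c(8.0, 8.2, 7.9), c(120, 118, 125))
  expect_true(all(combined_csp(ref, ref)$csp_ppm == 0))

  # pure 1H change: CSP collapses to |ddelta_H| for any alpha
  end <- make_peaks(1:3, c(8.1, 8.2, 7.9), c(120, 118, 125))
  expect_equal(combined_csp(ref, end, alpha_n = 0.3)$csp_ppm[1], 0.1)

  # hand evaluation: dH = 0.03, dN = 0.5, alpha = 0.14
  end2 <- make_peaks(1, 8.03, 120.5)
  got <- combined_csp(make_peaks(1, 8.0, 120.0), end2, alpha_n = 0.14)
  expect_equal(got$csp_ppm, sqrt(0.03^2 + (0.14 * 0.5)^2), tolerance = 1e-12)
  expect_equal(got$csp_ppm, 0.07616, tolerance = 1e-4)

  # residues in only one list are omitted and reported; disjoint errors
  end3 <- make_peaks(2:4, c(8.2, 7.9, 8.5), c(118, 125, 122))
  got <- combined_csp(ref, end3)
  expect_equal(got$residue, 2:3)
  expect_equal(attr(got, "omitted"), c(1L, 4L))
  expect_error(combined_csp(ref, make_peaks(9, 8, 120)), "no residues")
})

test_that("CSP is symmetric in its inputs and scales linearly", {
  ref <- make_peaks(1:5, 8 + (1:5) / 10, 115 + 1:5)
  end <- make_peaks(1:5, 8 + (1:5) / 10 + c(0.1, 0, -0.05, 0.02, 0),
                    115 + 1:5 + c(0.5, -1, 0, 0.2, 0))
  expect_equal(combined_csp(ref, end)$csp_ppm,
               combined_csp(end, ref)$csp_ppm)

  # scaling all shift differences by c scales all CSPs by c
  cfac <- 3.7
  end_sc <- make_peaks(1:5,
                       ref$h_ppm + cfac * (end$h_ppm - ref$h_ppm),
                       ref$n_ppm + cfac * (end$n_ppm - ref$n_ppm))
  expect_equal(combined_csp(ref, end_sc)$csp_ppm,
               cfac * combined_csp(ref, end)$csp_ppm, tolerance = 1e-12)
})

test_that("trajectory collinearity statistic matches brute force", {
  sp <- small_titration_spec(seed = 17, noise_sd_h = 0, noise_sd_n = 0)
  ser <- simulate_titration(sp)

  # displace one interior point of one residue perpendicular to its track
  r <- sp$interface[1]
  i <- match(r, sp$residues$residue)
  dh <- sp$offsets$ddelta_h[match(r, sp$offsets$residue)]
  dn <- 0.14 * sp$offsets$ddelta_n[match(r, sp$offsets$residue)]
  u <- c(-dn, dh) / sqrt(dh^2 + dn^2)  # unit perpendicular, (h, alpha*n)
  k <- match(r, ser[[4]]$peaks$residue)
  ser[[4]]$peaks$h_ppm[k] <- ser[[4]]$peaks$h_ppm[k] + 0.05 * u[1]
  ser[[4]]$peaks$n_ppm[k] <- ser[[4]]$peaks$n_ppm[k] + 0.05 * u[2] / 0.14

  traj <- peak_trajectories(ser, alpha_n = 0.14)
  got <- traj$max_perp_ppm[traj$residue == r]
  tr <- attr(traj, "trajectories")[[as.character(r)]]
  ref <- max_perp_bruteforce(tr$h_ppm, tr$n_ppm, 0.14)
  expect_equal(got, ref, tolerance = 1e-6)
  expect_gt(got, 0.03)                       # displacement is recovered
  expect_true(traj$flagged[traj$residue == r])
  expect_true(all(traj$max_perp_ppm[traj$residue != r] < 1e-9))

  # two-point trajectories are exactly collinear
  two <- ser[c(1, 7)]
  class(two) <- "titration_series"
  t2 <- peak_trajectories(two)
  expect_true(all(t2$max_perp_ppm == 0))
})

test_that("residues with fewer than two points are excluded and reported", {
  sp <- small_titration_spec(seed = 17, noise_sd_h = 0, noise_sd_n = 0)
  ser <- simulate_titration(sp)
  r_drop <- sp$residues$residue[1]
  for (t in 2:length(ser)) {
    ser[[t]]$peaks <- ser[[t]]$peaks[ser[[t]]$peaks$residue != r_drop, ]
  }
  traj <- peak_trajectories(ser)
  expect_false(r_drop %in% traj$residue)
  expect_equal(attr(traj, "excluded"), r_drop)
})

test_that("hotspot calling thresholds the profile as specified", {
  flat <- structure(data.frame(residue = 1:10, csp_ppm = rep(0.2, 10),
                               relative_csp = 1),
                    class = c("csp_profile", "data.frame"))
  expect_length(call_hotspots(flat, "ksd")$hotspots, 0L)

  prof <- flat
  prof$csp_ppm <- c(1, rep(0, 9))
  call <- call_hotspots(prof, "ksd", k = 1)
  expect_equal(call$hotspots, 1L)
  expect_equal(call$threshold_value, mean(prof$csp_ppm) + sd(prof$csp_ppm))

  qcall <- call_hotspots(prof, "quantile", q = 0.85)
  expect_equal(qcall$hotspots, 1L)

  single <- flat[1, ]
  class(single) <- class(flat)
  expect_error(call_hotspots(single, "ksd"), "SD undefined")
})

test_that("synthetic interfaces are recovered with perfect precision/recall", {
  hits <- vapply(1:20, function(seed) {
    sp <- clamp_like_titration_spec(seed = seed)
    ser <- simulate_titration(sp)
    call <- call_hotspots(csp_from_series(ser), "ksd", k = 1)
    setequal(call$hotspots, sp$interface)
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("non-interface CSP scales with the noise level only", {
  base <- clamp_like_titration_spec(seed = 50, n_residues = 30L,
                                    first_residue = 131L)
  noisy <- clamp_like_titration_spec(seed = 50, n_residues = 30L,
                                     first_residue = 131L,
                                     noise_sd_h = 0.012, noise_sd_n = 0.06)
  bg <- function(sp) {
    prof <- csp_from_series(simulate_titration(sp))
    median(prof$csp_ppm[!prof$residue %in% sp$interface])
  }
  m1 <- bg(base)
  m3 <- bg(noisy)
  # tripling the noise roughly triples the background CSP
  expect_gt(m3 / m1, 1.5)
  expect_lt(m1, 3 * base$noise_sd_h)
})
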
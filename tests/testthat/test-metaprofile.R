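test_that("profiles are transcript-oriented and normalized", {
  ev <- make_event(1000, 1011)
  # all coverage at one base at r = -25
  tr <- make_track(7, start = 975L)
  p <- extract_profile(tr, ev[1, ], "distal")
  expect_equal(sum(p$density), 1, tolerance = 1e-9)
  expect_equal(p$density[p$rel == -25], 1)
  expect_equal(sum(p$density != 0), 1L)

  # uniform coverage: every density 1/400
  tru <- make_track(rep(3, 400), start = 800L)
  pu <- extract_profile(tru, ev[1, ], "distal")
  expect_true(all(abs(pu$density - 1 / 400) < 1e-12))

  # zero coverage is flagged, not divided
  pz <- extract_profile(make_track(0, start = 10L), ev[1, ], "distal")
  expect_true(pz$zero_coverage)
  expect_null(pz$density)
})

test_that("minus-strand profiles mirror genomic coordinates", {
  # genomic peak downstream of the donor coordinate of a minus-strand event
  ev <- make_event(2000, 1989, strand = "-")
  tr <- make_track(5, start = 2030L)  # genomic 2030 = donor + 30
  p <- extract_profile(tr, ev[1, ], "distal")
  expect_equal(p$rel[p$raw > 0], -30L)  # upstream in transcript orientation

  # full strand equivariance: mirror all coordinates, flip strand
  set.seed(61)
  vals <- rpois(400, 3) + c(rep(0, 160), rep(10, 30), rep(0, 210))
  plus_ev <- make_event(1000, 1011, strand = "+")
  plus_tr <- make_track(vals, start = 800L)  # window [800, 1200)
  p_plus <- extract_profile(plus_tr, plus_ev[1, ], "distal")

  L <- 5000L
  mirror_ev <- make_event(L - 1000L, L - 1011L, strand = "-")
  mirror_tr <- make_track(rev(vals), start = L - 1199L)
  p_minus <- extract_profile(mirror_tr, mirror_ev[1, ], "distal")
  expect_equal(p_minus$raw, p_plus$raw)
  expect_equal(p_minus$density, p_plus$density)
})

test_that("window past the chromosome start names the event", {
  ev <- make_event(100, 111, id = "near_edge")
  expect_error(extract_profile(make_track(1), ev[1, ], "distal"),
               "near_edge")
})

test_that("aggregation computes mean and sample-SD standard errors", {
  ev <- make_event(1000, 1011)
  one <- extract_profile(make_track(4, start = 990L), ev[1, ], "distal")
  m1 <- aggregate_profiles(list(one))
  expect_equal(m1$mean, one$density)
  expect_true(all(m1$se == 0))

  # two delta profiles at disjoint positions: mean 0.5, SE 0.5 at each
  two <- extract_profile(make_track(4, start = 1050L), ev[1, ], "distal")
  m2 <- aggregate_profiles(list(one, two))
  expect_equal(sum(m2$mean), 1, tolerance = 1e-6)
  at <- which(m2$mean > 0)
  expect_equal(unname(m2$mean[at]), c(0.5, 0.5))
  expect_equal(unname(m2$se[at]), c(0.5, 0.5))  # sd(c(1,0))/sqrt(2)

  # zero-coverage profiles are excluded and accounted for
  zero <- extract_profile(make_track(0, start = 10L), ev[1, ], "distal")
  m3 <- aggregate_profiles(list(one, two, zero))
  expect_equal(m3$n_used, 2L)
  expect_equal(m3$n_zero, 1L)
  expect_error(aggregate_profiles(list(zero)), "nonzero")
})

test_that("section argmax matches brute-force section sums", {
  ev <- make_event(1000, 1011)
  # rectangular peak centered at r = -25, width 30: wholly inside section 4
  p4 <- extract_profile(make_track(rep(10, 30), start = 960L), ev[1, ],
                        "distal")
  expect_equal(section_argmax(list(p4))$per_event$argmax_section, 4L)

  # peak centered at r = +75 lands in section 6; cross-check brute force
  p6 <- extract_profile(make_track(rep(10, 30), start = 1060L), ev[1, ],
                        "distal")
  rep6 <- section_argmax(list(p6))
  brute <- vapply(1:8, function(k) {
    lo <- -200 + 50 * (k - 1)
    sum(p6$raw[p6$rel >= lo & p6$rel < lo + 50])
  }, numeric(1))
  expect_equal(rep6$per_event$argmax_section, which.max(brute))
  expect_equal(rep6$per_event$argmax_section, 6L)

  # uniform coverage ties across all sections: lowest index, flagged
  pu <- extract_profile(make_track(rep(2, 400), start = 800L), ev[1, ],
                        "distal")
  repu <- section_argmax(list(pu))
  expect_equal(repu$per_event$argmax_section, 1L)
  expect_true(repu$per_event$tie)

  # all-zero event excluded from the histogram
  pz <- extract_profile(make_track(0, start = 10L), ev[1, ], "distal")
  repz <- section_argmax(list(p4, pz))
  expect_equal(sum(repz$histogram), 1L)
  expect_equal(repz$n_zero, 1L)
  expect_equal(repz$section4, 1L)
})

test_that("metaprofile report builds the class-by-anchor grid", {
  cfg <- simulation_config(n_events = 60, depth = 200, background_rate = 0,
                           peak_fraction = 1, seed = 77)
  sim <- simulate_events(cfg)
  cts <- simulate_counts(sim$events, sim$truth, cfg)
  clip <- simulate_clip(sim$events, sim$truth, cfg)
  cl <- classify_events(analyze_counts(cts, "ctrl", "kd"))
  rep <- metaprofile_report(sim$events, cl, clip)

  da <- rep$panels[["distal_activated.distal"]]
  expect_false(is.null(da))
  # peaks are planted upstream of the distal donor of distal-activated
  # events: the mean density maximum falls in r in [-50, 0)
  rmax <- da$meta$rel[which.max(da$meta$mean)]
  expect_true(rmax >= -50 && rmax < 0)
  expect_equal(sum(da$meta$mean), 1, tolerance = 1e-6)
  # proximal anchor sees the same peak displaced upstream by the offset
  dp <- rep$panels[["distal_activated.proximal"]]
  rmax_p <- dp$meta$rel[which.max(dp$meta$mean)]
  expect_equal(rmax_p, rmax - 11L)

  # zero-background: no peaks on proximal-activated events, whole class has
  # zero coverage, so that panel is absent rather than an error
  expect_null(rep$panels[["proximal_activated.distal"]])
})

test_that("no-peak cohorts give approximately flat metaprofiles", {
  cfg <- simulation_config(n_events = 500, background_rate = 5,
                           peak_fraction = 0, strand_mix = 0.5, seed = 13)
  sim <- simulate_events(cfg)
  clip <- simulate_clip(sim$events, sim$truth, cfg)
  profs <- lapply(seq_len(nrow(sim$events)), function(i)
    extract_profile(clip, sim$events[i, ], "distal"))
  meta <- aggregate_profiles(profs)
  expect_lt(max(meta$mean) / min(meta$mean), 2)
})
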
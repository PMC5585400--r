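test_that("event simulation is deterministic and respects strand_mix", {
  cfg <- simulation_config(n_events = 30, seed = 99)
  a <- simulate_events(cfg)
  b <- simulate_events(cfg)
  expect_identical(a, b)

  expect_equal(nrow(simulate_events(simulation_config(n_events = 0))$events),
               0L)

  minus <- simulate_events(simulation_config(n_events = 20, strand_mix = 1,
                                             seed = 3))
  expect_true(all(minus$events$strand == "-"))
  expect_true(all(minus$events$distal_donor > minus$events$proximal_donor))
  expect_true(all(minus$events$offset == 11L))

  # truth direction is consistent with delta psi and the 0.2 threshold
  tr <- a$truth
  expect_true(all((tr$delta_psi <= -0.2) ==
                    (tr$direction == "distal_activated")))
  expect_true(all((tr$delta_psi >= 0.2) ==
                    (tr$direction == "proximal_activated")))
})

test_that("window placement failures are reported", {
  expect_error(simulate_events(simulation_config(n_events = 2, spacing = 200,
                                                 seed = 1)),
               "overlap")
  expect_error(simulate_events(simulation_config(n_events = 50,
                                                 chrom_length = 2000,
                                                 seed = 1)),
               "too short")
})

test_that("count simulation follows the binomial sampling model", {
  cfg <- simulation_config(n_events = 40, psi_control = 1, psi_knockdown = 1,
                           depth = 50, seed = 21)
  sim <- simulate_events(cfg)
  cts <- simulate_counts(sim$events, sim$truth, cfg)
  expect_true(all(cts$n_distal == 0))  # psi = 1: only inclusion reads

  cfg0 <- simulation_config(n_events = 20, depth = 0, seed = 21)
  sim0 <- simulate_events(cfg0)
  cts0 <- simulate_counts(sim0$events, sim0$truth, cfg0)
  expect_true(all(cts0$n_distal + cts0$n_proximal == 0))

  # psi = 0.5 at high depth concentrates near 0.5
  cfg5 <- simulation_config(n_events = 5, psi_control = 0.5,
                            psi_knockdown = 0.5, depth = 10000, seed = 8)
  sim5 <- simulate_events(cfg5)
  cts5 <- simulate_counts(sim5$events, sim5$truth, cfg5)
  frac <- cts5$n_proximal / (cts5$n_proximal + cts5$n_distal)
  expect_true(all(abs(frac - 0.5) < 0.02))
})

test_that("empirical psi-hat concentrates around true psi across a cohort", {
  cfg <- simulation_config(n_events = 200, depth = 200, seed = 17)
  sim <- simulate_events(cfg)
  cts <- simulate_counts(sim$events, sim$truth, cfg)
  ctrl <- cts[cts$sample_id == "ctrl", ]
  ctrl <- ctrl[match(sim$truth$event_id, ctrl$event_id), ]
  n <- ctrl$n_distal + ctrl$n_proximal
  ok <- n > 0
  psi_hat <- ctrl$n_proximal[ok] / n[ok]
  psi <- sim$truth$psi_control[ok]
  band <- 3 * sqrt(psi * (1 - psi) / n[ok])
  expect_gte(mean(abs(psi_hat - psi) < band + 1e-9), 0.99)
})

test_that("planted peaks land on the stated genomic bases, both strands", {
  base <- function(strand) {
    cfg <- simulation_config(n_events = 1, strand_mix = strand,
                             background_rate = 0, peak_fraction = 1,
                             peak_class = "all", peak_center_offset = -25,
                             peak_width = 30, peak_height = 10, seed = 4)
    sim <- simulate_events(cfg)
    clip <- simulate_clip(sim$events, sim$truth, cfg)
    list(d = sim$events$distal_donor,
         nz = which(coverage_at(clip, cfg$chrom, 0:3000) > 0) - 1L)
  }
  plus <- base(0)  # all plus strand
  expect_equal(plus$nz, (plus$d - 40):(plus$d - 11))  # [d-40, d-10)
  minus <- base(1)
  expect_equal(minus$nz, (minus$d + 11):(minus$d + 40))  # mirrored
})

test_that("zero background and zero peaks give an all-zero track", {
  cfg <- simulation_config(n_events = 3, background_rate = 0,
                           peak_fraction = 0, seed = 2)
  sim <- simulate_events(cfg)
  clip <- simulate_clip(sim$events, sim$truth, cfg)
  expect_true(all(coverage_at(clip, cfg$chrom, 0:4000) == 0))
})

test_that("a fixed seed gives byte-identical dataset files", {
  cfg <- simulation_config(n_events = 15, seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("events.tsv", "counts.tsv", "clip.bedgraph", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
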
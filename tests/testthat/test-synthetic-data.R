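test_that("site layout is log-spaced between forced endpoints", {
  two <- simulate_sites(2, 0.19, 34.8)
  expect_identical(two$distance_km, c(0.19, 34.8))

  three <- simulate_sites(3, 0.19, 34.8)
  # independent arithmetic: middle site is the geometric mean of the ends
  expect_equal(three$distance_km[2], sqrt(0.19 * 34.8), tolerance = 1e-12)
  expect_equal(three$distance_km[2], 2.571381, tolerance = 1e-6)

  many <- simulate_sites(17, 0.19, 34.8)
  expect_true(all(diff(many$distance_km) > 0))
  expect_true(all(diff(log10(many$distance_km)) -
                    diff(log10(many$distance_km))[1] < 1e-12))
  expect_false(anyDuplicated(many$site_id) > 0)

  expect_error(simulate_sites(1, 0.19, 34.8), "at least 2")
  expect_error(simulate_sites(5, -1, 34.8), "positive")
  expect_error(simulate_sites(5, 10, 5), "smaller")
})

test_that("noise-free water quality reproduces the back-transformed mean curve", {
  sites <- data.frame(site_id = c("A", "B"), distance_km = c(1, 10),
                      stringsAsFactors = FALSE)
  cfg <- sim_config(n_sites = 2, n_days = 28, baseline_days = 0,
                    metrics = noise_free_metrics(ntu_intercept = 1.0,
                                                 ntu_slope = -0.5))
  wq <- simulate_water_quality(cfg, sites, seed = 5)
  # log10(NTU) = 1.0 - 0.5 * log10(d): NTU = 10 at 1 km, 10^0.5 at 10 km
  expect_equal(unique(wq$ntu[wq$site_id == "A"]), 10, tolerance = 1e-12)
  expect_equal(unique(wq$ntu[wq$site_id == "B"]), 10^0.5, tolerance = 1e-12)
  # sqrt(DLI) = 1.5 + 1.0 * log10(d)
  expect_equal(unique(wq$dli[wq$site_id == "B"]), 2.5^2, tolerance = 1e-12)

  flat <- noise_free_metrics()
  for (m in names(flat)) flat[[m]]$slope <- 0
  cfg0 <- sim_config(n_sites = 2, n_days = 14, baseline_days = 14,
                     metrics = flat)
  wq0 <- simulate_water_quality(cfg0, sites, seed = 5)
  expect_equal(unique(wq0$ntu), 10^1.0, tolerance = 1e-12)   # all site-days
  expect_equal(unique(wq0$dli), 1.5^2, tolerance = 1e-12)
})

test_that("noise-free generator round-trips through preprocessing and back-transform", {
  cfg <- sim_config(n_sites = 5, n_days = 70, baseline_days = 28,
                    metrics = noise_free_metrics())
  sites <- simulate_sites(5, cfg$d_near_km, cfg$d_far_km)
  wq <- simulate_water_quality(cfg, sites, seed = 2)
  fs <- preprocess_water_quality(wq)
  # fortnights >= 1 have running-mean windows wholly inside the dredge phase
  ssc <- fs[fs$metric == "ssc" & fs$fortnight >= 1, ]
  expected <- 1.8 * 10^(1.0 - 0.5 *
    log10(sites$distance_km[match(ssc$site_id, sites$site_id)]))
  expect_equal(ssc$value, expected, tolerance = 1e-10)
  dli <- fs[fs$metric == "dli" & fs$fortnight >= 1, ]
  expected_dli <- (1.5 + 1.0 *
    log10(sites$distance_km[match(dli$site_id, sites$site_id)]))^2
  expect_equal(dli$value, expected_dli, tolerance = 1e-10)
})

test_that("identical seeds give identical tables, different seeds differ", {
  cfg <- small_sim()
  sites <- simulate_sites(cfg$n_sites, cfg$d_near_km, cfg$d_far_km)
  a <- simulate_water_quality(cfg, sites, seed = 42)
  b <- simulate_water_quality(cfg, sites, seed = 42)
  c <- simulate_water_quality(cfg, sites, seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ntu, c$ntu)))

  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$water_quality, d2$water_quality)
  expect_identical(d1$colonies, d2$colonies)
  expect_identical(d1$psd, d2$psd)
  expect_identical(d1$truth, cfg)   # truth echoes the config exactly
})

test_that("branching and corymbose colonies never show smothering scores", {
  mix <- c(encrusting = 0, foliose = 0, corymbose = 0.5, branching = 0.5,
           massive = 0)
  cfg <- sim_config(n_sites = 4, n_days = 112, colonies_per_site = 20,
                    porites_topup = 0, morphology_mix = mix,
                    smother_logit_intercept = 5,   # extreme deposition
                    smother_logit_slope = 0, dislodged_fraction = 0)
  sites <- simulate_sites(4, 0.19, 34.8)
  obs <- simulate_colony_panel(cfg, sites, seed = 9)
  expect_true(all(obs$sediment_score == 1))
  expect_true(all(is.na(obs$mucus_score)))   # no massive Porites tagged
})

test_that("flat smothering model gives ~50% exceedance and n_days = 0 gives no surveys", {
  cfg <- sim_config(n_sites = 6, n_days = 530, colonies_per_site = 40,
                    porites_topup = 0, dislodged_fraction = 0,
                    morphology_mix = c(encrusting = 0, foliose = 0,
                                       corymbose = 0, branching = 0,
                                       massive = 1),
                    smother_logit_intercept = 0,   # logit(0.5)
                    smother_logit_slope = 0)
  sites <- simulate_sites(6, 0.19, 34.8)
  obs <- simulate_colony_panel(cfg, sites, seed = 11)
  p <- mean(obs$sediment_score >= 3)
  n <- nrow(obs)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))   # binomial error band

  empty <- simulate_colony_panel(sim_config(n_days = 0), sites, seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("colony surveys run at a 14-day cadence with fixed morphology", {
  cfg <- small_sim()
  sites <- simulate_sites(cfg$n_sites, cfg$d_near_km, cfg$d_far_km)
  obs <- simulate_colony_panel(cfg, sites, seed = 3)
  expect_setequal(unique(obs$day), seq(0, cfg$n_days - 1, by = 14))
  morphs <- tapply(obs$morphology, obs$colony_id,
                   function(m) length(unique(m)))
  expect_true(all(morphs == 1))
  expect_true(all(obs$site_id %in% sites$site_id))
})

test_that("psd compositions close to 100 and obey the configured enrichment", {
  cfg <- small_sim()
  sites <- simulate_sites(cfg$n_sites, cfg$d_near_km, cfg$d_far_km)
  psd <- simulate_psd(cfg, sites, seed = 4)
  expect_equal(rowSums(psd[c("gravel", "sand", "silt", "clay")]),
               rep(100, nrow(psd)), tolerance = 1e-9)

  # noise-free mode: after/before silt+clay ratio at the nearest site is
  # exactly the configured near-field enrichment
  nf <- sim_config(n_sites = 5, psd_enrichment_near = 5,
                   psd_concentration = Inf)
  s5 <- simulate_sites(5, nf$d_near_km, nf$d_far_km)
  p5 <- simulate_psd(nf, s5, seed = 1)
  near <- p5[p5$site_id == "S01", ]
  r <- enrichment_ratio(near[near$phase == "after_1", ],
                        near[near$phase == "before", ])
  expect_equal(r, 5.0, tolerance = 1e-12)
  # and exactly 1 at the far endpoint
  far <- p5[p5$site_id == "S05", ]
  expect_equal(enrichment_ratio(far[far$phase == "after_1", ],
                                far[far$phase == "before", ]),
               1.0, tolerance = 1e-12)

  none <- sim_config(n_sites = 5, psd_enrichment_near = 1,
                     psd_concentration = Inf)
  p1 <- simulate_psd(none, s5, seed = 1)
  for (sid in unique(p1$site_id)) {
    b <- p1[p1$site_id == sid & p1$phase == "before", ]
    a <- p1[p1$site_id == sid & p1$phase == "after_1", ]
    expect_equal(silt_clay_fraction(a), silt_clay_fraction(b),
                 tolerance = 1e-12)
  }
})

test_that("panel variance decomposition approaches the generating SDs", {
  sites <- simulate_sites(150, 0.19, 34.8)
  pan <- simulate_decay_panel(sites, 150, beta0 = 1, beta1 = -0.8,
                              sd_site = 0.3, sd_fortnight = 0.2,
                              sd_resid = 0.2, seed = 77)
  centred <- pan$y - (1 - 0.8 * log10(pan$distance_km))
  site_means <- tapply(centred, pan$site_id, mean)
  fort_means <- tapply(centred, pan$fortnight, mean)
  resid <- centred - site_means[pan$site_id] -
    fort_means[as.character(pan$fortnight)]
  expect_equal(sd(site_means), 0.3, tolerance = 0.1)
  expect_equal(sd(fort_means), 0.2, tolerance = 0.1)
  expect_equal(sd(resid), 0.2, tolerance = 0.1)
})

test_that("dataset child tables reference the site table and csv writer emits four files", {
  cfg <- small_sim()
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$water_quality$site_id %in% ds$sites$site_id))
  expect_true(all(ds$colonies$site_id %in% ds$sites$site_id))
  expect_true(all(ds$psd$site_id %in% ds$sites$site_id))
  expect_true(all(ds$sites$distance_km > 0))
  td <- withr::local_tempdir()
  paths <- write_dataset_csv(ds, td)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(td, "sites.csv"))
  expect_equal(back$distance_km, ds$sites$distance_km, tolerance = 1e-12)
})
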
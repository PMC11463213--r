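# a tiny hand-built world: one pixel per site, integer resource dates
toy_stack <- function(greenup = 100, d25 = 70, d50 = 80, d75 = 90,
                      d100 = 100, n = 3) {
  m <- function(v) matrix(v, n, n)
  resource_stack(m(greenup),
                 list(d25 = m(d25), d50 = m(d50), d75 = m(d75),
                      d100 = m(d100)),
                 lat = 40 + seq_len(n) * 0.5, lon = 117 + seq_len(n) * 0.5)
}

toy_sites <- function(arrivals, lat = 40.5, lon = 117.5) {
  data.frame(track_id = sprintf("tr%02d", seq_along(arrivals)),
             site_id = sprintf("tr%02d_s", seq_along(arrivals)),
             role = "stopover", lat = lat, lon = lon,
             arrival_day = arrivals,
             departure_day = arrivals + 5, stay_days = 6)
}

test_that("design construction draws seeded absences off the arrival day", {
  sites <- toy_sites(c(92, 95, 88, 91, 90))
  des <- build_design(sites, toy_stack(), n_absence_per_site = 10, seed = 5)
  expect_equal(sum(des$response == 0), 50)
  expect_equal(sum(des$response == 1), 5)
  # absences never fall on the site's arrival day
  for (sid in unique(des$site_id)) {
    d <- des[des$site_id == sid, ]
    expect_false(any(d$candidate_day[d$response == 0] %in%
                       d$candidate_day[d$response == 1]))
  }
  # mismatch definition: candidate day on the pixel's d75 gives zero
  row90 <- des[des$candidate_day == 90, ][1, ]
  expect_equal(row90$m_melt75, 0)
  expect_equal(row90$m_greenup, -10)
  # seeded reproducibility
  des2 <- build_design(sites, toy_stack(), n_absence_per_site = 10, seed = 5)
  expect_identical(des, des2)
  des3 <- build_design(sites, toy_stack(), n_absence_per_site = 10, seed = 6)
  expect_false(identical(des, des3))
})

test_that("the RSF reduces to the fixed-effects fit when grouping is degenerate", {
  set.seed(91)
  sites <- toy_sites(round(stats::rnorm(12, 92, 2)))
  sites$track_id <- "one_track"
  sites$site_id <- sprintf("s%02d", seq_len(nrow(sites)))
  des <- build_design(sites, toy_stack(), seed = 7)
  f <- fit_rsf(des, "melt75", 2)
  delta2 <- (des$m_melt75 - 2)^2
  ref <- suppressWarnings(
    stats::glm(des$response ~ delta2, family = stats::binomial()))
  expect_identical(f$model, "fixed")
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_lt(abs(f$coefficients[["b2"]] - stats::coef(ref)[[2]]), 1e-6)
})

test_that("shuffled mismatches carry no information beyond the intercept", {
  set.seed(92)
  sites <- toy_sites(round(stats::rnorm(30, 92, 2)))
  des <- build_design(sites, toy_stack(), seed = 8)
  des$m_melt75 <- sample(des$m_melt75)
  f <- fit_rsf(des, "melt75", 2)
  null_ll <- as.numeric(stats::logLik(
    stats::glm(des$response ~ 1, family = stats::binomial())))
  expect_lt(f$loglik - null_ll, 3)    # ~ chi-square(1) improvement at most
  expect_gte(f$loglik, null_ll - 1e-6)
})

test_that("a separable design drives the log-likelihood towards zero", {
  # presences exactly at the melt75 date, absences far away
  sites <- toy_sites(rep(90, 10))
  des <- build_design(sites, toy_stack(), n_absence_per_site = 0, seed = 1)
  absn <- des[rep(1, 20), ]
  absn$response <- 0L
  absn$candidate_day <- rep(c(30, 150), 10)
  for (cue in c("greenup", "melt25", "melt50", "melt75", "melt100"))
    absn[[paste0("m_", cue)]] <- absn$candidate_day -
      c(greenup = 100, melt25 = 70, melt50 = 80, melt75 = 90,
        melt100 = 100)[[cue]]
  des <- rbind(des, absn)
  f <- fit_rsf(des, "melt75", 0)
  expect_gt(f$loglik, -0.1)
})

test_that("the lag scan pins the lag of noiseless arrivals", {
  sites <- toy_sites(rep(90, 20))        # arrivals exactly on the cue date
  des <- build_design(sites, toy_stack(), seed = 9)
  sc <- suppressWarnings(scan_lags(des, "melt75", k = 0))
  expect_s3_class(sc, "lag_scan")
  expect_equal(sc$optimal_lag, 0)
  expect_equal(sc$lag_paper, 0)
  expect_equal(sc$aic[which.min(sc$aic)], min(sc$aic))
  expect_true(sc$range_lo <= sc$optimal_lag &&
                sc$optimal_lag <= sc$range_hi)
})

test_that("shifting every resource date shifts the optimal lag oppositely", {
  set.seed(93)
  arrivals <- round(stats::rnorm(25, 92, 1.5))
  sites <- toy_sites(arrivals)
  base <- suppressWarnings(scan_lags(
    build_design(sites, toy_stack(), seed = 10), "melt75", k = 0))
  shifted <- suppressWarnings(scan_lags(
    build_design(sites, toy_stack(d75 = 90 + 4), seed = 10), "melt75",
    k = 0))
  expect_equal(shifted$optimal_lag, base$optimal_lag - 4)
})

test_that("duplicating every design row preserves the optimal lag", {
  set.seed(94)
  sites <- toy_sites(round(stats::rnorm(20, 93, 2)))
  des <- build_design(sites, toy_stack(), seed = 11)
  sc1 <- suppressWarnings(scan_lags(des, "melt75", k = 0))
  sc2 <- suppressWarnings(scan_lags(rbind(des, des), "melt75", k = 0))
  expect_equal(sc2$optimal_lag, sc1$optimal_lag)
})

test_that("interpolated likelihood crossings match a quadratic profile", {
  grid <- -10:10
  for (curv in c(0.25, 1)) {
    ll <- -5 - curv * grid^2
    cr <- wavetrack:::profile_crossings(grid, ll, max(ll) - 1,
                                        which.max(ll))
    expect_equal(cr[2] - cr[1], 2 * sqrt(1 / curv), tolerance = 0.2)
    expect_equal(mean(cr), 0, tolerance = 1e-9)
  }
})

test_that("k-fold splits by track and scores monotone bins at 1", {
  set.seed(95)
  sites <- toy_sites(round(stats::rnorm(25, 92, 1.5)))
  des <- build_design(sites, toy_stack(), seed = 12)
  rs <- kfold_rs(des, "melt75", 2, k = 5, seed = 3, reps = 1)
  expect_length(rs$rs_folds, 5)
  expect_true(all(rs$rs_folds >= -1 & rs$rs_folds <= 1))
  # repeated splits concatenate k scores per split
  rs3 <- kfold_rs(des, "melt75", 2, k = 5, seed = 3, reps = 3)
  expect_length(rs3$rs_folds, 15)
  expect_error(kfold_rs(des[des$track_id %in% unique(des$track_id)[1:3], ],
                        "melt75", 2, k = 5),
               "at least k")
  # a perfectly monotone bin-frequency sequence has Spearman rs = 1
  expect_equal(stats::cor(1:10, seq(0.05, 0.5, length.out = 10),
                          method = "spearman"), 1)
})

test_that("cue choice follows the rs comparison and the minimal-lag rule", {
  mk <- function(cue, rs, lag, uninformative = FALSE)
    structure(list(cue = cue, rs_mean = rs, optimal_lag = lag,
                   abs_lag = abs(lag), uninformative = uninformative),
              class = "lag_scan")
  res <- list(greenup = mk("greenup", 0.95, 14),
              melt25 = mk("melt25", 0.5, 9), melt50 = mk("melt50", 0.6, 5),
              melt75 = mk("melt75", 0.7, 2), melt100 = mk("melt100", 0.6, 6))
  ca <- choose_cue(res)
  expect_identical(ca$winner, "plant")
  expect_identical(ca$specific_cue, "greenup")

  res2 <- res
  res2$greenup <- mk("greenup", 0.4, 14)
  res2$melt25$rs_mean <- 0.8; res2$melt50$rs_mean <- 0.8
  res2$melt75$rs_mean <- 0.8; res2$melt100$rs_mean <- 0.8
  ca2 <- choose_cue(res2)
  expect_identical(ca2$winner, "snowmelt")
  expect_identical(ca2$specific_cue, "melt75")   # |lags| = 9, 5, 2, 6

  # ties break towards the earlier phase
  res3 <- res2
  res3$melt50$abs_lag <- 2
  expect_identical(choose_cue(res3)$specific_cue, "melt50")

  # uninformative snow profiles are excluded from the snow mean
  res4 <- res2
  res4$melt25 <- mk("melt25", -0.9, 1, uninformative = TRUE)
  ca4 <- choose_cue(res4)
  expect_identical(ca4$winner, "snowmelt")
  expect_identical(ca4$specific_cue, "melt75")
  expect_equal(ca4$rs_snow_mean, 0.8)
})

test_that("summary and table methods expose the headline columns", {
  sites <- toy_sites(rep(92, 15))
  des <- build_design(sites, toy_stack(), seed = 13)
  sc <- suppressWarnings(scan_lags(des, "melt75", k = 5, seed = 2))
  s <- summary(sc)
  expect_true(all(c("optimal_lag", "lag_paper", "difference", "loglik",
                    "rs_mean") %in% names(s)))
  expect_equal(s$lag_paper, -s$optimal_lag)
  tab <- lagscan_table(list(melt75 = sc), region = "NCP", species = "toy")
  expect_equal(tab$difference, sc$difference)
  expect_equal(tab$lag, sc$lag_paper)
  expect_type(coef(sc), "double")
})
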
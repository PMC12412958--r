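test_that("track metrics are exact on constructed tracks", {
  # constant-velocity 0.9 um/min
  tr <- straightTrack(0.9, frameInterval = 5, duration = 100)
  expect_identical(meanSpeed(tr), 0.9)
  expect_identical(persistence(tr), 1)
  # stationary track: zero speed, undefined persistence
  still <- Track("s", seq(0, 50, 5), rep(0, 11))
  expect_identical(meanSpeed(still), 0)
  expect_warning(p <- persistence(still), "undefined")
  expect_true(is.na(p))
  # out-and-back ends at the origin: persistence 0
  oab <- Track("o", seq(0, 50, 5), c(0:5, 4:0))
  expect_identical(persistence(oab), 0)
  # 87 um forward, 13 um back: (87 - 13) / (87 + 13) = 0.740
  expect_equal(persistence(twoLegTrack(87, 13)), 0.740, tolerance = 1e-12)
})

test_that("persistence and speed are invariant to time reversal and subsampling", {
  tr <- genTracks(1, 0.9, 0.7, spec = GeneratorSpec(seed = 3))$tracks[[1]]
  rev_tr <- Track("rev", tr@times,
                  tr@positions[rev(seq_len(nrow(tr@positions))), , drop = FALSE])
  expect_equal(meanSpeed(rev_tr), meanSpeed(tr))
  expect_equal(persistence(rev_tr), persistence(tr))
  # subsampling a straight track keeps persistence at 1
  st <- straightTrack(1.2, frameInterval = 5, duration = 200)
  sub <- Track("sub", st@times[seq(1, 41, by = 4)],
               st@positions[seq(1, 41, by = 4), , drop = FALSE])
  expect_identical(persistence(sub), 1)
})

test_that("persistence lies in [0, 1] under randomized fuzzing", {
  withr::with_seed(77, {
    for (i in 1:200) {
      nd <- sample(1:2, 1)
      n <- sample(3:40, 1)
      pos <- matrix(cumsum(rnorm(n * nd)), ncol = nd)
      tr <- Track("f", seq(0, by = 5, length.out = n), pos)
      p <- suppressWarnings(persistence(tr))
      if (!is.na(p)) {
        expect_gte(p, 0)
        expect_lte(p, 1)
      }
      expect_lte(netDisplacement(tr), pathLength(tr) + 1e-12)
    }
  })
})

test_that("speed-persistence correlation behaves at both extremes", {
  # persistence strictly increasing in speed -> r > 0
  tracks <- lapply(1:10, function(i) {
    fw <- 10 + 8 * i
    twoLegTrack(fw, 10, trackId = paste0("t", i))
  })
  r <- speedPersistenceCorrelation(tracks)
  expect_gt(as.numeric(r), 0)
  # permutation-shuffled pairing: |r| small at n = 100 (seeded null)
  gt <- genTracks(100, 0.9, 0.6, spec = GeneratorSpec(seed = 8))
  st <- trackStats(gt$tracks)
  withr::with_seed(9, {
    rs <- cor(st$persistence, sample(st$persistence))
  })
  expect_lt(abs(rs), 0.3)
  # duplicated identical tracks: zero variance -> NA with warning
  same <- lapply(1:5, function(i) straightTrack(1, trackId = paste0("d", i)))
  expect_warning(rr <- speedPersistenceCorrelation(same), "zero variance")
  expect_true(is.na(as.numeric(rr)))
})

test_that("telegraph cohorts match requested persistence and speed", {
  gt <- genTracks(200, 0.918, 0.740, spec = GeneratorSpec(seed = 4))
  st <- trackStats(gt$tracks)
  # constant step magnitude: every track's speed is exact
  expect_equal(st$mean_speed_um_min, rep(0.918, 200), tolerance = 1e-12)
  expect_equal(mean(st$persistence), 0.740, tolerance = 0.05 / 0.740)
  # target 1: no flips, persistence exactly 1
  g1 <- genTracks(10, 1, 1, spec = GeneratorSpec(seed = 5))
  expect_true(all(vapply(g1$tracks, persistence, numeric(1)) == 1))
  expect_error(genTracks(5, 1, 1.2, spec = GeneratorSpec(seed = 1)),
               "persistenceTarget")
})

test_that("nucleus tracking links single and gated trajectories", {
  ps <- 0.65
  # one nucleus moving steadily: a single fully linked track
  tr <- straightTrack(0.9, frameInterval = 5, duration = 75)
  mv <- genChannelMovie(list(tr), spec = GeneratorSpec(seed = 2,
                                                       pixelSize = ps))
  tk <- trackNuclei(mv$frames, ps, frameInterval = 5, maxStep = 15)
  expect_equal(length(tk), 1)
  expect_equal(length(tk[[1]]@times), length(tr@times))
  # two nuclei always farther apart than maxStep: two tracks, never merged
  trA <- straightTrack(0.9, duration = 75, trackId = "A")
  trB <- Track("B", trA@times, trA@positions + 60)
  mv2 <- genChannelMovie(list(trA, trB),
                         spec = GeneratorSpec(seed = 3, pixelSize = ps))
  tk2 <- trackNuclei(mv2$frames, ps, frameInterval = 5, maxStep = 15)
  expect_equal(length(tk2), 2)
  # all-empty movie: no tracks
  blank <- genChannelMovie(list(), spec = GeneratorSpec(seed = 4,
                                                        pixelSize = ps))
  expect_equal(length(trackNuclei(blank$frames, ps, maxStep = 10)), 0)
})

test_that("tracking round trip localizes nuclei within a pixel", {
  ps <- 0.65
  gt <- genTracks(4, 0.9, 0.8, duration = 100, spec = GeneratorSpec(seed = 6))
  mv <- genChannelMovie(gt$tracks, spec = GeneratorSpec(seed = 7,
                                                        pixelSize = ps))
  tk <- trackNuclei(mv$frames, ps, frameInterval = 5, maxStep = 15)
  expect_equal(length(tk), 4)
  errs <- c()
  for (t in tk) {
    im <- which.min(vapply(mv$truth, function(g)
      sum((g@positions[1, ] - t@positions[1, ])^2), numeric(1)))
    g <- mv$truth[[im]]
    expect_equal(length(t@times), length(g@times))
    errs <- c(errs, sqrt(rowSums((t@positions - g@positions)^2)))
  }
  expect_lt(mean(errs) / ps, 1)
  # statistics from tracked movies match ground-truth statistics within 3%
  stT <- trackStats(tk)
  stG <- trackStats(mv$truth)
  expect_equal(mean(stT$mean_speed_um_min), mean(stG$mean_speed_um_min),
               tolerance = 0.03)
  expect_equal(mean(stT$persistence), mean(stG$persistence),
               tolerance = 0.03)
})

test_that("track tables round trip through CSV", {
  dir <- withr::local_tempdir()
  gt <- genTracks(3, 1.1, 0.6, duration = 60, spec = GeneratorSpec(seed = 8))
  path <- file.path(dir, "tracks.csv")
  writeTracks(gt$tracks, path)
  back <- readTracks(path)
  expect_equal(length(back), 3)
  expect_equal(trackStats(back)$persistence,
               trackStats(gt$tracks)$persistence)
  # tracks shorter than 3 samples are dropped on read
  tab <- utils::read.csv(path)
  tab <- rbind(tab, data.frame(track_id = "tiny", frame = 1:2,
                               time_min = c(0, 5), x_um = c(0, 1)))
  expect_equal(length(readTracks(tab)), 3)
})
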
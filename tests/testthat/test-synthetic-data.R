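test_that("dwell-time samples follow the shifted exponential", {
  d <- genDwellTimes(57, 5000, tMin = 5, seed = 1)
  expect_length(d, 5000)
  expect_true(all(d > 5))
  expect_lt(abs(mean(d) - 62), 2.5)        # 3 SE, SE = 57/sqrt(5000)
  expect_gt(genDwellTimes(1, 1, tMin = 0.5, seed = 99), 0.5)
  d2 <- genDwellTimes(81, 1e5, tMin = 0, seed = 7)
  expect_lt(abs(mean(d2) - 81), 0.8)
  expect_error(genDwellTimes(-1, 10), "tau")
  expect_error(genDwellTimes(5, 0), "n")
})

test_that("all generators are deterministic under a fixed seed", {
  expect_identical(genDwellTimes(10, 50, seed = 3),
                   genDwellTimes(10, 50, seed = 3))
  sch <- telegraphScheme()
  expect_identical(stateLabels(genStateSeries(sch, 1000, seed = 4)),
                   stateLabels(genStateSeries(sch, 1000, seed = 4)))
  expect_identical(genHeightSamples(c(0, 4), c(0.5, 0.5), 2, 100, seed = 5),
                   genHeightSamples(c(0, 4), c(0.5, 0.5), 2, 100, seed = 5))
  tmpl <- buildTemplateProtein()
  cfg <- hingeConfig(nFrames = 20, seed = 6, atomNoiseSigma = 0.1)
  expect_identical(genHingeTrajectory(cfg, tmpl)@coords,
                   genHingeTrajectory(cfg, tmpl)@coords)
})

test_that("state-series dwell means converge to the scheme taus", {
  sch <- telegraphScheme(57, 81)
  ss <- genStateSeries(sch, 1e6, dt = 1, seed = 8)
  # oracle: dwell means straight from the exact event log
  ev <- metadata(ss)$events
  dwell <- diff(ev$time)
  st <- ev$state[-nrow(ev)]
  expect_lt(abs(mean(dwell[st == "A"]) - 57) / 57, 0.03)
  expect_lt(abs(mean(dwell[st == "B"]) - 81) / 81, 0.03)
  # grid-sampled runs agree with the event-driven oracle
  r <- rle(stateLabels(ss))
  gridMeanA <- mean(r$lengths[r$values == "A"])
  expect_lt(abs(gridMeanA - mean(dwell[st == "A"])) / 57, 0.03)
})

test_that("degenerate schemes behave: single state constant, symmetry", {
  one <- kineticScheme("A", data.frame(from = character(),
                                       to = character(), tau = numeric()))
  ss <- genStateSeries(one, 100, seed = 1)
  expect_true(all(stateLabels(ss) == "A"))
  sym <- telegraphScheme(40, 40)
  ss2 <- genStateSeries(sym, 2e5, seed = 2)
  occA <- mean(stateLabels(ss2) == "A")
  expect_lt(abs(occA - 0.5), 0.05)
  expect_error(genStateSeries(sym, 1000, init = "Z"), "initial state")
  expect_error(genStateSeries(sym, 0.5, dt = 1), "duration")
})

test_that("hinge trajectories are exact rigid rotations of the template", {
  tmpl <- buildTemplateProtein()
  cfg <- hingeConfig(nFrames = 30, angleOpen = 0, angleClosed = 20,
                     dwellTauOpen = 10, dwellTauClosed = 10, seed = 9)
  tr <- genHingeTrajectory(cfg, tmpl)
  mob <- indices(selectAtoms(tmpl, chain = "N"))
  fixed <- indices(selectAtoms(tmpl, chain = "C"))
  ref <- coords(tmpl)
  refDist <- dist(ref[mob, ])
  for (k in c(1, 10, 30)) {
    fc <- frameCoords(tr, k)
    # fixed domain untouched, mobile domain internally rigid
    expect_equal(fc[fixed, ], ref[fixed, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(as.vector(dist(fc[mob, ])), as.vector(refDist),
                 tolerance = 1e-9)
    # and the frame is exactly the template rotated by the logged angle
    R <- rotationAboutAxis(cfg@hingeAxis, metadata(tr)$angles[k])
    expect_equal(fc[mob, ], tcrossprod(ref[mob, ], R), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("hinge chord displacement follows 2 r sin(theta/2)", {
  # one atom 45 A from a z hinge axis, rotated by 20 degrees
  sys <- makeSystem(elety = c("CA", "CA", "CA", "CA"),
                    resid = "ALA", resno = 1:4,
                    chain = c("C", "C", "C", "N"),
                    coords = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(45, 0, 0)),
                    elesy = "C")
  cfg <- hingeConfig(nFrames = 40, angleOpen = 0, angleClosed = 20,
                     dwellTauOpen = 5, dwellTauClosed = 5, seed = 10)
  tr <- genHingeTrajectory(cfg, sys)
  ang <- metadata(tr)$angles
  io <- which(ang == 0)[1]; ic <- which(ang == 20)[1]
  disp <- sqrt(sum((frameCoords(tr, ic)[4, ] - frameCoords(tr, io)[4, ])^2))
  expect_equal(disp, 2 * 45 * sin(10 * pi / 180), tolerance = 1e-9)
  expect_equal(round(disp, 1), 15.6)
})

test_that("water scenes hold the prescribed pocket occupancy every frame", {
  tmpl <- buildTemplateProtein()
  prot <- staticTrajectory(tmpl, 40)
  shift <- c(15, 15, 15) - colMeans(coords(tmpl))
  prot@coords <- prot@coords + array(rep(shift, each = nAtoms(prot)),
                                     dim(prot@coords))
  sch <- kineticScheme("w4", data.frame(from = character(),
                                        to = character(), tau = numeric()))
  cfg <- waterSceneConfig(box = c(30, 30, 30), bulkDensity = 0.02,
                          pocketCenter = c(15, 15, 15), pocketRadius = 3.5,
                          pocketWatersPerState = c(w4 = 4L), scheme = sch,
                          seed = 12)
  sc <- genWaterScene(cfg, prot)
  a <- atoms(sc)
  isO <- a$class == "water" & a$elesy == "O"
  nBulk <- metadata(sc)$nBulk
  for (k in c(1, 20, 40)) {
    fc <- frameCoords(sc, k)
    d <- sqrt(rowSums(sweep(fc[isO, ], 2, c(15, 15, 15))^2))
    expect_equal(sum(d <= 3.5), 4)
    inBox <- rowSums(fc[isO, ] >= 0 & sweep(fc[isO, ], 2, cfg@box, "<=")) == 3
    expect_equal(sum(inBox), nBulk + 4)    # water count conservation
  }
  # reproducibility is byte-identical
  expect_identical(sc@coords, genWaterScene(cfg, prot)@coords)
})

test_that("pocket occupancy tracks the hydration state series", {
  tmpl <- buildTemplateProtein()
  prot <- staticTrajectory(tmpl, 60)
  shift <- c(15, 15, 15) - colMeans(coords(tmpl))
  prot@coords <- prot@coords + array(rep(shift, each = nAtoms(prot)),
                                     dim(prot@coords))
  sch <- kineticScheme(c("dry", "wet"),
                       c("dry->wet" = 15, "wet->dry" = 15))
  cfg <- waterSceneConfig(box = c(30, 30, 30), bulkDensity = 0,
                          pocketCenter = c(15, 15, 15), pocketRadius = 3.5,
                          pocketWatersPerState = c(dry = 0L, wet = 2L),
                          scheme = sch, seed = 13)
  sc <- genWaterScene(cfg, prot)
  lab <- stateLabels(metadata(sc)$states)[seq_len(60)]
  a <- atoms(sc)
  isO <- a$class == "water" & a$elesy == "O"
  nIn <- vapply(seq_len(60), function(k) {
    d <- sqrt(rowSums(sweep(frameCoords(sc, k)[isO, , drop = FALSE], 2,
                            c(15, 15, 15))^2))
    sum(d <= 3.5)
  }, numeric(1))
  expect_equal(nIn, ifelse(lab == "wet", 2, 0), ignore_attr = TRUE)
})

test_that("height samples realise the requested mixture", {
  h <- genHeightSamples(0, 1, sigma = 3.4, n = 1e4, seed = 14)
  expect_lt(abs(sd(h) - 3.4), 0.05)
  expect_length(genHeightSamples(c(0, 5), c(0.5, 0.5), 1, 0), 0)
  expect_error(genHeightSamples(0, 1, sigma = -1, n = 10), "sigma")
  expect_error(genHeightSamples(c(0, 1), c(0.9, 0.9), 1, 10), "weights")
})

test_that("the Ornstein-Uhlenbeck angle process is stationary and seeded", {
  tmpl <- buildTemplateProtein(nRes = 6)
  cfg <- hingeConfig(nFrames = 4000, angleProcess = "ou_process",
                     angleOpen = 10, angleClosed = 2, dwellTauOpen = 20,
                     dwellTauClosed = 20, seed = 15)
  tr <- genHingeTrajectory(cfg, tmpl)
  ang <- metadata(tr)$angles
  # mean = angleOpen, stationary SD = |angleOpen - angleClosed| / 2
  expect_lt(abs(mean(ang) - 10), 1)
  expect_lt(abs(sd(ang) - 4) / 4, 0.25)
  # one-lag autocorrelation ~ exp(-dt/tau)
  expect_lt(abs(cor(ang[-1], ang[-4000]) - exp(-1 / 20)), 0.05)
  expect_identical(metadata(genHingeTrajectory(cfg, tmpl))$angles, ang)
})

test_that("Brownian bulk mode keeps waters in the box and off the pocket", {
  tmpl <- buildTemplateProtein(nRes = 4)
  prot <- staticTrajectory(tmpl, 30)
  shift <- c(10, 10, 10) - colMeans(coords(tmpl))
  prot@coords <- prot@coords + array(rep(shift, each = nAtoms(prot)),
                                     dim(prot@coords))
  sch <- kineticScheme("w1", data.frame(from = character(),
                                        to = character(), tau = numeric()))
  cfg <- waterSceneConfig(box = c(20, 20, 20), bulkDensity = 0.01,
                          pocketCenter = c(10, 10, 10), pocketRadius = 3,
                          pocketWatersPerState = c(w1 = 1L), scheme = sch,
                          seed = 16)
  sc <- genWaterScene(cfg, prot, brownian = TRUE, D = 0.2)
  a <- atoms(sc)
  isO <- a$class == "water" & a$elesy == "O"
  for (k in c(1, 15, 30)) {
    ox <- frameCoords(sc, k)[isO, ]
    inBox <- rowSums(ox >= 0 & sweep(ox, 2, cfg@box, "<=")) == 3
    d <- sqrt(rowSums(sweep(ox, 2, c(10, 10, 10))^2))
    expect_equal(sum(inBox), metadata(sc)$nBulk + 1)
    expect_equal(sum(d <= 3), 1)          # exactly the pocket water
  }
  # bulk waters actually move between frames in this mode
  o1 <- frameCoords(sc, 1)[isO, ]; o2 <- frameCoords(sc, 2)[isO, ]
  expect_gt(median(sqrt(rowSums((o2 - o1)^2))), 0.1)
})
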
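singleAtomSystem <- function(elesy = "C", elety = "CB") {
  makeSystem(elety = elety, resid = "ALA", resno = 1, chain = "A",
             coords = matrix(c(0, 0, 0), 1, 3), elesy = elesy)
}

test_that("an isolated atom has the full probe-expanded sphere area", {
  asa <- computeASA(singleAtomSystem(), per = "atom")
  expect_equal(asa[1], 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  expect_equal(round(asa[1], 1), 120.8)
})

test_that("an atom enclosed by a shell of atoms has zero ASA", {
  # 60 carbon occluders on a 2-A shell fully cover the central atom
  i <- seq_len(60) - 0.5
  z <- 1 - 2 * i / 60
  r <- sqrt(1 - z^2); th <- pi * (3 - sqrt(5)) * i
  shell <- 2 * cbind(r * cos(th), r * sin(th), z)
  sys <- makeSystem(elety = c("CB", rep("CD", 60)), resid = "ALA",
                    resno = c(1, rep(2, 60)), chain = "A",
                    coords = rbind(c(0, 0, 0), shell), elesy = "C")
  expect_equal(computeASA(sys, per = "atom")[1], 0)
})

test_that("two-atom ASA matches the closed-form spherical cap", {
  for (d in c(2.0, 3.5, 5.0)) {
    sys <- makeSystem(elety = c("CB", "OG"), resid = "SER", resno = 1,
                      chain = "A", coords = rbind(c(0, 0, 0), c(d, 0, 0)),
                      elesy = c("C", "O"))
    R1 <- 1.7 + 1.4; R2 <- 1.52 + 1.4
    exact <- twoSphereASA(R1, R2, d)
    got <- computeASA(sys, per = "atom")[1]
    expect_lt(abs(got - exact) / exact, 0.01)
    # high-resolution run converges to the same closed form
    hi <- computeASA(sys, nPoints = 10000, per = "atom")[1]
    expect_lt(abs(hi - exact) / exact, 0.002)
  }
})

test_that("ASA is rigid-transform invariant and per-residue side-chain only", {
  tmpl <- buildTemplateProtein(nRes = 6)
  base <- computeASA(tmpl)
  set.seed(71)
  moved <- makeSystem(elety = atoms(tmpl)$elety, resid = atoms(tmpl)$resid,
                      resno = atoms(tmpl)$resno, chain = atoms(tmpl)$chain,
                      coords = sweep(tcrossprod(coords(tmpl),
                                                randomRotation()),
                                     2, c(12, -7, 3), "+"),
                      elesy = atoms(tmpl)$elesy)
  # rotation invariance holds to the sphere-point discretisation error
  expect_lt(max(abs(computeASA(moved)$asa - base$asa)), 1)
  expect_lt(mean(abs(computeASA(moved)$asa - base$asa)), 0.5)
  expect_true(all(c("chain", "resno", "asa") %in% names(base)))
  expect_equal(nrow(base), 12)
  # unknown element is a named error
  bad <- singleAtomSystem(elesy = "XX")
  expect_error(computeASA(bad), "radius")
})

test_that("approach of a second atom monotonically reduces ASA", {
  areas <- vapply(c(6, 5, 4, 3, 2.5), function(d) {
    sys <- makeSystem(elety = c("CB", "CG"), resid = "ALA", resno = 1,
                      chain = "A", coords = rbind(c(0, 0, 0), c(d, 0, 0)),
                      elesy = "C")
    computeASA(sys, per = "atom")[1]
  }, numeric(1))
  expect_true(all(diff(areas) < 1e-9))
})

test_that("hydration waters count distinct molecules within the cutoff", {
  res <- makeSystem(elety = c("CA", "CB", "CG"), resid = "LEU", resno = 1,
                    chain = "A",
                    coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)),
                    elesy = "C")
  at34 <- bindSystems(res, makeWaters(c(1.5, 3.4, 0)))
  expect_equal(countHydrationWaters(at34, 1), 1L)
  at36 <- bindSystems(res, makeWaters(c(1.5, 3.6, 0)))
  expect_equal(countHydrationWaters(at36, 1), 0L)
  # three waters each near two side-chain atoms count once each
  multi <- bindSystems(res, makeWaters(rbind(c(2.2, 1, 0), c(2.2, -1, 0),
                                             c(2.2, 0, 1))))
  expect_equal(countHydrationWaters(multi, 1), 3L)
  # glycine-like residue: backbone only
  gly <- makeSystem(elety = c("N", "CA", "C", "O"), resid = "GLY",
                    resno = 2, chain = "A",
                    coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0),
                                   c(4, 0, 0)), elesy = c("N", "C", "C", "O"))
  glyW <- bindSystems(gly, makeWaters(c(1.5, 2, 0)))
  expect_warning(n <- countHydrationWaters(glyW, 2), "side-chain")
  expect_equal(n, 0L)
})

test_that("hydration counts equal a brute-force all-pairs scan", {
  set.seed(81)
  for (rep in 1:5) {
    res <- makeSystem(elety = c("CA", "CB", "CG", "CD"), resid = "LYS",
                      resno = 1, chain = "A",
                      coords = matrix(rnorm(12, sd = 2), 4, 3), elesy = "C")
    wat <- makeWaters(matrix(rnorm(45, sd = 4), 15, 3))
    sys <- bindSystems(res, wat)
    got <- countHydrationWaters(sys, 1, cutoff = 3.5)
    # oracle: explicit double loop over side-chain atoms and water oxygens
    sc <- coords(res)[-1, ]               # CB, CG, CD (CA is backbone)
    ow <- coords(wat)[seq(1, 45, by = 3), ]
    cnt <- 0L
    for (w in seq_len(nrow(ow))) {
      near <- FALSE
      for (s in seq_len(nrow(sc)))
        if (sqrt(sum((ow[w, ] - sc[s, ])^2)) <= 3.5) near <- TRUE
      cnt <- cnt + near
    }
    expect_equal(got, cnt)
  }
})

changeTableFixture <- function() {
  # residue 1: CB exposed in open frames, buried under a cage in closed
  # frames; residue 2: unchanged; waters hydrate residue 1 only when open
  resA <- c(0, 0, 0)
  base <- makeSystem(elety = c("CB", "CB"), resid = "ALA", resno = 1:2,
                     chain = "A", coords = rbind(resA, c(20, 0, 0)),
                     elesy = "C")
  i <- seq_len(40) - 0.5
  z <- 1 - 2 * i / 40
  r <- sqrt(1 - z^2); th <- pi * (3 - sqrt(5)) * i
  cage <- 2.2 * cbind(r * cos(th), r * sin(th), z)
  cageSys <- makeSystem(elety = rep("CD", 40), resid = "CAGE", resno = 3,
                        chain = "A", coords = cage, elesy = "C")
  wOpen <- makeWaters(rbind(c(3, 0, 0), c(0, 3, 0)))
  wClosed <- makeWaters(rbind(c(50, 0, 0), c(0, 50, 0)))
  openSys <- bindSystems(bindSystems(base, cageSys), wOpen)
  closedSys <- bindSystems(bindSystems(base, cageSys), wClosed)
  cOpen <- coords(openSys)
  cClosed <- cOpen
  # closed frames: move the cage from far away onto residue 1, swap waters
  cOpen[3:42, ] <- cage + 100
  cClosed[43:48, ] <- coords(wClosed)
  traj <- trajFromCoords(openSys, list(cOpen, cOpen, cClosed, cClosed))
  list(traj = traj,
       classes = c("open", "open", "closed", "closed"))
}

test_that("residue change tables follow the sign and burial conventions", {
  fx <- changeTableFixture()
  tab <- residueChangeTable(fx$traj, fx$classes, nPoints = 480)
  r1 <- tab[tab$resno == 1, ]
  r2 <- tab[tab$resno == 2, ]
  # pocket-lining residue: packing and dehydration upon closing
  expect_false(r1$excluded)
  expect_lt(r1$rAsa, 0)
  expect_lt(r1$rWat, 0)
  expect_equal(r1$watOpen, 2); expect_equal(r1$watClosed, 0)
  expect_equal(r1$rWat, -1)                 # (0 - 2)/2
  # untouched residue: no change
  expect_equal(r2$rAsa, 0, tolerance = 1e-9)
  expect_equal(r2$rWat, 0)
  # the cage pseudo-residue is buried in neither ensemble mean > 10 A^2?
  # closed-buried residue 1 still uses the OPEN mean for exclusion
  expect_gt(r1$asaOpen, 10)
})

test_that("relative-change arithmetic and burial exclusion are exact", {
  fx <- changeTableFixture()
  tab <- residueChangeTable(fx$traj, fx$classes, nPoints = 480)
  r1 <- tab[tab$resno == 1, ]
  expect_equal(r1$rAsa, (r1$asaClosed - r1$asaOpen) / r1$asaOpen)
  tabAbs <- residueChangeTable(fx$traj, fx$classes, nPoints = 480,
                               mode = "absolute")
  expect_equal(tabAbs[tabAbs$resno == 1, "rAsa"],
               r1$asaClosed - r1$asaOpen)
  # reversing the ensembles flags residue 1 as buried (open mean ~ 0)
  rev <- residueChangeTable(fx$traj, rev(fx$classes), nPoints = 480)
  expect_true(rev[rev$resno == 1, "excluded"])
  expect_true(is.na(rev[rev$resno == 1, "rAsa"]))
  expect_error(residueChangeTable(fx$traj, rep("open", 4)), "closed")
})

test_that("change tables are independent of frame order", {
  fx <- changeTableFixture()
  tab <- residueChangeTable(fx$traj, fx$classes, nPoints = 480)
  perm <- c(3, 1, 4, 2)
  shuffled <- trajFromCoords(fx$traj@topology,
                             lapply(perm, function(k)
                               frameCoords(fx$traj, k)))
  tab2 <- residueChangeTable(shuffled, fx$classes[perm], nPoints = 480)
  expect_equal(tab2, tab)
})

test_that("the jaw-separation gauge takes the nearer ring hydrogen", {
  sys <- makeJawSystem(hd1 = c(0, 0, 6), he1 = c(0, 0, 9),
                       cd1 = c(0, 0, 0), cg = c(0, 0, 0))
  expect_equal(gaugeDHS1(sys), 6)
  # coincident jaws: zero with a degeneracy warning
  sys0 <- makeJawSystem(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_warning(d0 <- gaugeDHS1(sys0), "degenerate")
  expect_equal(d0, 0)
  # constructed jaw separation is returned exactly
  for (a in c(4.8, 6.2, 7.5)) {
    s <- makeJawSystem(hd1 = c(0, a, 0), he1 = c(0, a + 2, 0),
                       cd1 = c(-1, 0, 0), cg = c(1, 0, 0))
    expect_equal(gaugeDHS1(s), a, tolerance = 1e-9)
  }
  # hydrogen-less input is an explicit error
  noH <- makeSystem(elety = c("CD1", "CG"), resid = "TRP", resno = c(89, 92),
                    chain = "A", coords = rbind(c(0, 0, 0), c(1, 0, 0)),
                    elesy = "C")
  expect_error(gaugeDHS1(noH), "HD1/HE1")
})

test_that("the crevice-stretch gauge is the plain atom distance", {
  expect_equal(gaugeDHS2(makeCreviceSystem(c(0, 0, 0), c(0, 0, 10.5))), 10.5)
  expect_equal(gaugeDHS2(makeCreviceSystem(c(1, 2, 3), c(1, 2, 3))), 0)
  stretch <- seq(9.5, 11.5, by = 0.5)
  series <- vapply(stretch, function(d)
    gaugeDHS2(makeCreviceSystem(c(0, 0, 0), c(d, 0, 0))), numeric(1))
  expect_equal(series, stretch, tolerance = 1e-12)
  noAtom <- makeSystem(elety = "CA", resid = "ALA", resno = 190,
                       chain = "A", coords = matrix(0, 1, 3), elesy = "C")
  expect_error(gaugeDHS2(noAtom), "354")
})

test_that("gauge series align with trajectory timestamps", {
  frames <- lapply(seq(9.5, 11.5, by = 0.5), function(d)
    coords(makeCreviceSystem(c(0, 0, 0), c(d, 0, 0))))
  tr <- trajFromCoords(makeCreviceSystem(c(0, 0, 0), c(9.5, 0, 0)), frames)
  gs <- gaugeSeries(tr, which = "dHS2")
  expect_equal(gs$time, 0:4)
  expect_equal(gs$dHS2, seq(9.5, 11.5, by = 0.5), tolerance = 1e-12)
})
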
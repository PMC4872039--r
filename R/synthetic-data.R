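#' @include AllClasses.R AllGenerics.R molecular-io.R
NULL

# Evaluate expr under a local RNG seeded with `seed`, restoring global state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a kinetic scheme
#'
#' @param states ordered character state labels.
#' @param tau either a data.frame with columns from/to/tau, or a named
#'   numeric vector like `c("A->B" = 57, "B->A" = 81)` (ps).
#' @return a [KineticScheme-class].
#' @export
kineticScheme <- function(states, tau) {
  if (!is.data.frame(tau)) {
    parts <- strsplit(names(tau), "->", fixed = TRUE)
    tau <- data.frame(from = trimws(vapply(parts, `[`, "", 1)),
                      to = trimws(vapply(parts, `[`, "", 2)),
                      tau = unname(as.numeric(tau)),
                      stringsAsFactors = FALSE)
  }
  new("KineticScheme", states = states, tau = tau)
}

#' Sample shifted-exponential dwell times
#'
#' Draws `n` samples of `tMin + Exp(tau)`; the sample mean converges to
#' `tMin + tau`.
#'
#' @param tau mean of the exponential part (ps), > 0.
#' @param n number of samples, >= 1.
#' @param tMin shift (ps), >= 0.
#' @param seed optional integer seed (restores the global RNG state).
#' @return numeric vector of `n` dwell times (ps).
#' @export
genDwellTimes <- function(tau, n, tMin = 0, seed = NULL) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (tMin < 0) stop("tMin must be >= 0")
  withSeed(seed, tMin + stats::rexp(n, rate = 1 / tau))
}

# Event-driven continuous-time Markov path. Competing exponential clocks:
# from state s, each allowed transition s->b fires after Exp(tau_sb); the
# earliest wins. Returns data.frame(time, state) of entry events.
simulateMarkovPath <- function(scheme, duration, init) {
  edges <- scheme@tau
  t <- 0
  s <- init
  ev_t <- 0
  ev_s <- s
  repeat {
    out <- edges[edges$from == s, , drop = FALSE]
    if (nrow(out) == 0) break               # absorbing state
    waits <- stats::rexp(nrow(out), rate = 1 / out$tau)
    k <- which.min(waits)
    t <- t + waits[k]
    if (t >= duration) break
    s <- out$to[k]
    ev_t <- c(ev_t, t)
    ev_s <- c(ev_s, s)
  }
  data.frame(time = ev_t, state = ev_s, stringsAsFactors = FALSE)
}

#' Generate a Markovian state series on a uniform time grid
#'
#' Simulates the continuous-time Markov process defined by `scheme`
#' (competing exponential transitions with the given mean dwell times) and
#' samples the state at every grid time. The exact event log is stored in
#' `metadata(series)$events`.
#'
#' @param scheme a [KineticScheme-class].
#' @param duration total time (ps), >= dt.
#' @param dt grid spacing (ps).
#' @param seed optional integer seed.
#' @param init initial state (default: first declared state).
#' @return a [StateSeries-class] with times 0, dt, ..., <= duration.
#' @export
genStateSeries <- function(scheme, duration, dt = 1, seed = NULL,
                           init = NULL) {
  if (duration < dt) stop("duration must be >= dt")
  if (is.null(init)) init <- scheme@states[1]
  if (!init %in% scheme@states)
    stop("initial state '", init, "' is not in the scheme")
  events <- withSeed(seed, simulateMarkovPath(scheme, duration, init))
  times <- seq(0, duration, by = dt)
  idx <- findInterval(times, events$time)
  labels <- events$state[idx]
  new("StateSeries", times = times, labels = labels,
      metadata = list(events = events, scheme = scheme))
}

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#'
#' @param axis 3-vector (normalised internally).
#' @param angleDeg rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  n <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Build the default two-domain template protein
#'
#' A programmatically built dummy: two ideal alpha-helical segments
#' (backbone N, CA, C, O plus a CB pseudo-side-chain per residue), chain "C"
#' (the fixed core domain) running along -x and chain "N" (the mobile
#' domain) along +x, meeting near the origin where a hinge axis along z is
#' natural. Purely geometric -- no force field, no chemistry.
#'
#' @param nRes residues per domain (default 16).
#' @param gap half-gap (A) between the two domains along x (default 4).
#' @return a [MolecularSystem-class] with chains "C" (residues 1..nRes) and
#'   "N" (residues nRes+1..2*nRes).
#' @export
buildTemplateProtein <- function(nRes = 16, gap = 4) {
  helix <- function(n, x0, dir, resnoStart, chain) {
    i <- seq_len(n) - 1
    phase <- i * 100 * pi / 180
    ca <- cbind(x0 + dir * 1.5 * i, 2.3 * cos(phase), 2.3 * sin(phase))
    # offsets approximate backbone geometry; CB points radially outward
    rad <- cbind(0, cos(phase), sin(phase))
    ax <- c(dir, 0, 0)
    nt <- ca + 1.2 * rad - 0.8 * matrix(ax, n, 3, byrow = TRUE)
    cc <- ca + 1.2 * rad + 0.8 * matrix(ax, n, 3, byrow = TRUE)
    oo <- cc + 1.23 * rad
    cb <- ca + 1.53 * rad
    crd <- do.call(rbind, lapply(seq_len(n), function(k)
      rbind(nt[k, ], ca[k, ], cc[k, ], oo[k, ], cb[k, ])))
    list(
      elety = rep(c("N", "CA", "C", "O", "CB"), n),
      resno = rep(resnoStart + i, each = 5),
      chain = rep(chain, 5 * n),
      coords = crd)
  }
  hC <- helix(nRes, -gap - 1.5 * (nRes - 1), +1, 1, "C")
  hN <- helix(nRes, gap, +1, nRes + 1, "N")
  makeSystem(
    elety = c(hC$elety, hN$elety),
    resid = "ALA",
    resno = c(hC$resno, hN$resno),
    chain = c(hC$chain, hN$chain),
    coords = rbind(hC$coords, hN$coords),
    elesy = rep(c("N", "C", "C", "O", "C"), 2 * nRes))
}

#' Hinge-motion generator configuration
#'
#' @param nFrames,dt,hingeAxis,hingePoint,angleProcess,angleOpen,angleClosed,dwellTauOpen,dwellTauClosed,atomNoiseSigma,seed
#'   see [HingeConfig-class].
#' @return a [HingeConfig-class].
#' @export
hingeConfig <- function(nFrames, dt = 1, hingeAxis = c(0, 0, 1),
                        hingePoint = c(0, 0, 0),
                        angleProcess = "two_state",
                        angleOpen = 0, angleClosed = 20,
                        dwellTauOpen = 50, dwellTauClosed = 50,
                        atomNoiseSigma = 0, seed = 1L) {
  new("HingeConfig", nFrames = as.integer(nFrames), dt = dt,
      hingeAxis = hingeAxis / sqrt(sum(hingeAxis^2)),
      hingePoint = hingePoint, angleProcess = angleProcess,
      angleOpen = angleOpen, angleClosed = angleClosed,
      dwellTauOpen = dwellTauOpen, dwellTauClosed = dwellTauClosed,
      atomNoiseSigma = atomNoiseSigma, seed = as.integer(seed))
}

#' Generate a rigid two-domain hinge trajectory
#'
#' Chain `mobileChain` of the template is rotated about
#' (hingePoint, hingeAxis) by a stochastic angle process; all other atoms
#' stay fixed. Optional isotropic Gaussian noise is added to every atom.
#' Ground-truth angles and (for two_state) the underlying state series are
#' stored in the trajectory metadata.
#'
#' The two RNG streams (angle process, atom noise) are seeded independently
#' from `cfg@seed` by fixed offsets, so the angle path is unchanged when
#' noise is switched on.
#'
#' @param cfg a [HingeConfig-class].
#' @param template a two-domain [MolecularSystem-class] (see
#'   [buildTemplateProtein()]).
#' @param mobileChain chain id of the mobile domain (default "N").
#' @return a [Trajectory-class].
#' @export
genHingeTrajectory <- function(cfg, template, mobileChain = "N") {
  a <- atoms(template)
  mob <- which(a$chain == mobileChain)
  if (length(mob) == 0)
    stop("template has no atoms in mobile chain '", mobileChain, "'")
  if (length(mob) == nrow(a))
    stop("template has no fixed domain (all atoms are in '",
         mobileChain, "')")
  nf <- cfg@nFrames
  times <- (seq_len(nf) - 1) * cfg@dt
  if (cfg@angleProcess == "two_state") {
    # dwellTauOpen = mean dwell in open => open's exit clock is tau open
    sch <- kineticScheme(c("open", "closed"),
                         c("open->closed" = cfg@dwellTauOpen,
                           "closed->open" = cfg@dwellTauClosed))
    ss <- genStateSeries(sch, duration = times[nf], dt = cfg@dt,
                         seed = cfg@seed + 1L, init = "open")
    angles <- ifelse(stateLabels(ss) == "open", cfg@angleOpen,
                     cfg@angleClosed)
    meta <- list(config = cfg, angles = angles, states = ss)
  } else {
    tau <- cfg@dwellTauOpen
    mu <- cfg@angleOpen
    sdS <- abs(cfg@angleOpen - cfg@angleClosed) / 2
    phi <- exp(-cfg@dt / tau)
    eps <- withSeed(cfg@seed + 1L,
                    stats::rnorm(nf, 0, sdS * sqrt(1 - phi^2)))
    angles <- numeric(nf)
    angles[1] <- mu
    for (k in seq_len(nf - 1))
      angles[k + 1] <- mu + phi * (angles[k] - mu) + eps[k + 1]
    meta <- list(config = cfg, angles = angles)
  }
  base <- coords(template)
  arr <- array(rep(base, nf), c(nrow(base), 3, nf))
  mobRel <- sweep(base[mob, , drop = FALSE], 2, cfg@hingePoint)
  for (k in seq_len(nf)) {
    R <- rotationAboutAxis(cfg@hingeAxis, angles[k])
    arr[mob, , k] <- sweep(tcrossprod(mobRel, R), 2, cfg@hingePoint, "+")
  }
  if (cfg@atomNoiseSigma > 0) {
    noise <- withSeed(cfg@seed + 2L,
                      stats::rnorm(length(arr), 0, cfg@atomNoiseSigma))
    arr <- arr + array(noise, dim(arr))
  }
  new("Trajectory", topology = template, coords = arr, times = times,
      metadata = meta)
}

#' Water-scene generator configuration
#'
#' @param box,bulkDensity,pocketCenter,pocketRadius,pocketWatersPerState,scheme,seed
#'   see [WaterSceneConfig-class].
#' @return a [WaterSceneConfig-class].
#' @export
waterSceneConfig <- function(box, bulkDensity = 0.0334,
                             pocketCenter, pocketRadius,
                             pocketWatersPerState, scheme, seed = 1L) {
  pw <- pocketWatersPerState
  stopifnot(!is.null(names(pw)))
  storage.mode(pw) <- "integer"
  new("WaterSceneConfig", box = box, bulkDensity = bulkDensity,
      pocketCenter = pocketCenter, pocketRadius = pocketRadius,
      pocketWatersPerState = pw, scheme = scheme, seed = as.integer(seed))
}

# deterministic well-spread points inside a sphere (golden-spiral shells)
pocketSites <- function(center, radius, k) {
  if (k == 0) return(matrix(numeric(0), 0, 3))
  i <- seq_len(k)
  golden <- pi * (3 - sqrt(5))
  z <- if (k == 1) 0 else (2 * (i - 1) / (k - 1) - 1) * 0.6
  r <- sqrt(pmax(0, 0.6^2 - z^2))
  th <- golden * i
  sweep(radius * cbind(r * cos(th), r * sin(th), z), 2, center, "+")
}

waterTriplet <- function(o) {
  # rigid 3-site water: O-H 0.9572 A, H-O-H 104.52 deg, in the xy plane
  h1 <- o + c(0.9572, 0, 0)
  ang <- 104.52 * pi / 180
  h2 <- o + 0.9572 * c(cos(ang), sin(ang), 0)
  rbind(o, h1, h2)
}

#' Generate a solvated scene around a protein trajectory
#'
#' Merges the protein with (i) bulk waters placed uniformly in the box and
#' independently resampled every frame (correct stationary voxel density,
#' no residence-time structure) and (ii) pocket waters at fixed sites inside
#' a spherical pocket region, present only in frames whose Markov hydration
#' state demands them. Absent pocket waters are parked far outside the box
#' so every frame has the same atom count. Bulk placement rejects the
#' pocket region so the in-pocket oxygen count is exactly the
#' state-prescribed count in every frame.
#'
#' @param cfg a [WaterSceneConfig-class].
#' @param protein a [Trajectory-class] (may have zero frames' worth of
#'   motion; its frame grid defines the output grid).
#' @param brownian if TRUE bulk waters follow reflected Brownian motion
#'   (diffusion constant `D`, A^2/ps) instead of independent resampling.
#' @param D bulk diffusion constant used when `brownian = TRUE`.
#' @return a merged [Trajectory-class]; metadata holds the hydration
#'   [StateSeries-class], pocket site coordinates and bulk water count.
#' @export
genWaterScene <- function(cfg, protein, brownian = FALSE, D = 0.2) {
  times <- frameTimes(protein)
  nf <- length(times)
  dt <- if (nf > 1) times[2] - times[1] else 1
  ss <- genStateSeries(cfg@scheme, duration = max(times[nf], dt), dt = dt,
                       seed = cfg@seed + 11L)
  stLab <- stateLabels(ss)[seq_len(nf)]
  kPerFrame <- cfg@pocketWatersPerState[stLab]
  maxK <- max(cfg@pocketWatersPerState)
  sites <- pocketSites(cfg@pocketCenter, cfg@pocketRadius, maxK)
  park <- cfg@box + 100                      # parking spot outside the box
  vol <- prod(cfg@box)
  nBulk <- round(cfg@bulkDensity * vol)

  sampleBulk <- function(n) {
    # uniform in box, rejecting the pocket sphere
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      cand <- cbind(stats::runif(2 * n, 0, cfg@box[1]),
                    stats::runif(2 * n, 0, cfg@box[2]),
                    stats::runif(2 * n, 0, cfg@box[3]))
      d2 <- rowSums(sweep(cand, 2, cfg@pocketCenter)^2)
      out <- rbind(out, cand[d2 > cfg@pocketRadius^2, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }

  nW <- nBulk + maxK
  protAtoms <- atoms(protein)
  allAtoms <- if (nW > 0) rbind(protAtoms, data.frame(
    eleno = max(protAtoms$eleno, 0) + seq_len(3 * nW),
    elety = rep(c("OH2", "H1", "H2"), nW),
    resid = "HOH",
    resno = max(protAtoms$resno, 0) + rep(seq_len(nW), each = 3),
    chain = "W",
    elesy = rep(c("O", "H", "H"), nW),
    class = "water", stringsAsFactors = FALSE)) else protAtoms
  nP <- nrow(protAtoms)
  arr <- array(NA_real_, c(nP + 3 * nW, 3, nf))

  fillWaters <- function(oPos) do.call(rbind, lapply(
    seq_len(nrow(oPos)), function(i) waterTriplet(oPos[i, ])))

  withSeed(cfg@seed + 12L, {
    bulkO <- if (nBulk > 0) sampleBulk(nBulk) else matrix(numeric(0), 0, 3)
    for (k in seq_len(nf)) {
      if (nBulk > 0) {
        if (brownian) {
          step <- matrix(stats::rnorm(3 * nBulk, 0, sqrt(2 * D * dt)),
                         nBulk, 3)
          bulkO <- bulkO + step
          for (j in 1:3) {               # reflect at the walls
            bulkO[, j] <- abs(bulkO[, j])
            over <- bulkO[, j] > cfg@box[j]
            bulkO[over, j] <- 2 * cfg@box[j] - bulkO[over, j]
          }
          d2 <- rowSums(sweep(bulkO, 2, cfg@pocketCenter)^2)
          kick <- d2 <= cfg@pocketRadius^2
          if (any(kick)) bulkO[kick, ] <- sampleBulk(sum(kick))
        } else {
          bulkO <- sampleBulk(nBulk)
        }
      }
      kk <- kPerFrame[k]
      pockO <- matrix(rep(park, maxK), maxK, 3, byrow = TRUE)
      if (kk > 0) pockO[seq_len(kk), ] <- sites[seq_len(kk), , drop = FALSE]
      oPos <- rbind(bulkO, pockO)
      arr[, , k] <- rbind(frameCoords(protein, k),
                          if (nW > 0) fillWaters(oPos))
    }
  })
  topo <- newMolecularSystem(allAtoms, arr[, , 1])
  new("Trajectory", topology = topo, coords = arr, times = times,
      metadata = list(states = ss, nBulk = nBulk, pocketSites = sites,
                      config = cfg))
}

#' Sample heights from a Gaussian mixture
#'
#' @param means component means (A).
#' @param weights simplex weights (same length as `means`, sum to 1).
#' @param sigma common standard deviation (A), > 0.
#' @param n number of samples (0 allowed).
#' @param seed optional integer seed.
#' @return numeric vector of `n` heights (A).
#' @export
genHeightSamples <- function(means, weights = rep(1 / length(means),
                                                  length(means)),
                             sigma, n, seed = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (length(weights) != length(means))
    stop("means and weights differ in length")
  if (n == 0) return(numeric(0))
  withSeed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    stats::rnorm(n, mean = means[comp], sd = sigma)
  })
}
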
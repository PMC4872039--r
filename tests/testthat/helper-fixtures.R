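# Programmatic fixtures shared across the suite; nothing is read from disk.

# a system of bare water molecules with oxygens at the given positions;
# hydrogens (if wanted) at fixed small offsets chosen to stay close to O
makeWaters <- function(oPos, withH = TRUE, hOffsets = NULL) {
  oPos <- matrix(oPos, ncol = 3)
  n <- nrow(oPos)
  if (withH) {
    if (is.null(hOffsets))
      hOffsets <- list(c(0.25, 0, 0), c(0, 0.25, 0))
    crd <- do.call(rbind, lapply(seq_len(n), function(i)
      rbind(oPos[i, ], oPos[i, ] + hOffsets[[1]], oPos[i, ] + hOffsets[[2]])))
    makeSystem(elety = rep(c("OH2", "H1", "H2"), n), resid = "HOH",
               resno = rep(seq_len(n), each = 3), chain = "W",
               coords = crd, elesy = rep(c("O", "H", "H"), n))
  } else {
    makeSystem(elety = rep("OH2", n), resid = "HOH", resno = seq_len(n),
               chain = "W", coords = oPos, elesy = rep("O", n))
  }
}

# combine two systems (same frame) into one
bindSystems <- function(a, b) {
  at <- rbind(atoms(a), atoms(b))
  at$eleno <- seq_len(nrow(at))
  makeSystem(elety = at$elety, resid = at$resid, resno = at$resno,
             chain = at$chain, coords = rbind(coords(a), coords(b)),
             elesy = at$elesy)
}

# trajectory holding the given list of coordinate matrices over one topology
trajFromCoords <- function(system, coordList, dt = 1) {
  arr <- array(NA_real_, c(nrow(coords(system)), 3, length(coordList)))
  for (k in seq_along(coordList)) arr[, , k] <- coordList[[k]]
  new("Trajectory", topology = system, coords = arr,
      times = (seq_along(coordList) - 1) * dt)
}

staticTrajectory <- function(system, nFrames, dt = 1) {
  trajFromCoords(system, rep(list(coords(system)), nFrames), dt = dt)
}

# hydrophobic-pocket jaw fixture: upper-jaw residue with HD1/HE1, lower jaw
# with CD1 (res 89) and CG (res 92), at prescribed positions
makeJawSystem <- function(hd1, he1, cd1, cg) {
  makeSystem(elety = c("HD1", "HE1", "CD1", "CG"),
             resid = c("PHE", "PHE", "TRP", "TRP"),
             resno = c(340, 340, 89, 92), chain = "A",
             coords = rbind(hd1, he1, cd1, cg),
             elesy = c("H", "H", "C", "C"))
}

# crevice fixture for the d_HS2 gauge
makeCreviceSystem <- function(caPos, oe1Pos) {
  makeSystem(elety = c("CA", "OE1"), resid = c("ALA", "GLU"),
             resno = c(190, 354), chain = "A",
             coords = rbind(caPos, oe1Pos), elesy = c("C", "O"))
}

# random rotation matrix from a random unit quaternion
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# independent oracle: minimum RMSD over rotations via axis-angle search
# (coarse random sampling refined by Nelder-Mead); no SVD anywhere
bruteForceMinRMSD <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rotOf <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    rotationAboutAxis(v / th, th * 180 / pi)
  }
  obj <- function(v) {
    R <- rotOf(v)
    sqrt(mean(rowSums((tcrossprod(P, R) - Q)^2)))
  }
  best <- c(0, 0, 0); bestVal <- obj(best)
  for (i in 1:500) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    v <- ax * stats::runif(1, 0, pi)
    if (obj(v) < bestVal) { best <- v; bestVal <- obj(v) }
  }
  opt <- stats::optim(best, obj, control = list(maxit = 5000,
                                                reltol = 1e-14))
  opt$value
}

# brute-force density oracle: per-frame triple loop over water atoms,
# integer electron counts, then frame-average (independent of the package
# accumulation path)
bruteForceDensity <- function(traj, origin, dims, spacing = 1) {
  a <- atoms(traj)
  watIdx <- which(a$class == "water")
  els <- c(O = 8L, H = 1L)
  counts <- array(0L, dims)
  nf <- nFrames(traj)
  for (k in seq_len(nf)) {
    fc <- frameCoords(traj, k)
    for (i in watIdx) {
      ijk <- floor((fc[i, ] - origin) / spacing) + 1
      if (all(ijk >= 1) && all(ijk <= dims))
        counts[ijk[1], ijk[2], ijk[3]] <-
          counts[ijk[1], ijk[2], ijk[3]] + els[[toupper(a$elesy[i])]]
    }
  }
  counts / nf
}

# closed-form accessible area of sphere 1 (radius R1) occluded by a single
# sphere of radius R2 at centre distance d (spherical-cap formula)
twoSphereASA <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  cosAlpha <- (d^2 + R1^2 - R2^2) / (2 * d * R1)
  h <- R1 * (1 - cosAlpha)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# two-state telegraph scheme used in several kinetics tests
telegraphScheme <- function(tauAB = 57, tauBA = 81)
  kineticScheme(c("A", "B"), c("A->B" = tauAB, "B->A" = tauBA))
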
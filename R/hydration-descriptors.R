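#' @include AllClasses.R AllGenerics.R molecular-io.R
NULL

# Bondi van-der-Waals radii (A); single hard-coded table used everywhere
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
               S = 1.80, CL = 1.75, BR = 1.85, NA. = 2.27, K = 2.75,
               MG = 1.73, CA = 2.31, ZN = 1.39)

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                    "HA", "HA2", "HA3")

vdwRadiusOf <- function(elesy, elety = NULL) {
  el <- toupper(elesy)
  el[el == "NA"] <- "NA."
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    bad <- which(is.na(r))
    lab <- if (!is.null(elety)) paste0(elety[bad], " (", elesy[bad], ")")
           else elesy[bad]
    stop("no van-der-Waals radius for atom(s): ",
         paste(unique(lab), collapse = ", "))
  }
  unname(r)
}

# deterministic near-uniform points on the unit sphere (golden spiral)
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom is covered with `nPoints` near-uniform sphere
#' points at radius r_vdw + probe; a point is accessible when it lies
#' outside every other atom's probe-expanded sphere. Only protein atoms are
#' considered (waters and ions are solvent, not occluders).
#'
#' @param system a [MolecularSystem-class] (or a coordinate matrix together
#'   with `elesy`).
#' @param probeRadius probe radius in Angstrom (default 1.4, a water).
#' @param nPoints sphere points per atom (default 960).
#' @param per "sidechain" (default): per-residue side-chain ASA, backbone
#'   N/CA/C/O excluded; "atom": per-atom ASA.
#' @return for `per = "atom"` a numeric vector of per-atom areas (A^2); for
#'   `per = "sidechain"` a data.frame with chain, resno, resid and `asa`.
#' @export
computeASA <- function(system, probeRadius = 1.4, nPoints = 960,
                       per = c("sidechain", "atom")) {
  per <- match.arg(per)
  a <- atoms(system)
  keep <- which(a$class == "protein")
  xyz <- coords(system)[keep, , drop = FALSE]
  ap <- a[keep, , drop = FALSE]
  n <- nrow(xyz)
  radii <- vdwRadiusOf(ap$elesy, ap$elety) + probeRadius
  pts <- spherePoints(nPoints)
  area <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(di < radii[i] + radii & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      acc <- acc & d2 > radii[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * radii[i]^2 * mean(acc)
  }
  if (per == "atom") {
    out <- numeric(nrow(a))
    out[keep] <- area
    return(out)
  }
  side <- !(ap$elety %in% BACKBONE_NAMES)
  key <- paste(ap$chain, ap$resno)
  res <- unique(data.frame(chain = ap$chain, resno = ap$resno,
                           resid = ap$resid, key = key,
                           stringsAsFactors = FALSE))
  sums <- tapply(area[side], key[side], sum)
  res$asa <- as.numeric(sums[res$key])
  res$asa[is.na(res$asa)] <- 0
  res$key <- NULL
  rownames(res) <- NULL
  res
}

#' Count hydration waters around a residue's side chain
#'
#' Counts distinct water molecules whose oxygen lies within `cutoff` of any
#' side-chain atom of the residue. The oxygen is the molecule's counted
#' atom (robust to hydrogen-less inputs); a water touching several
#' side-chain atoms is counted once.
#'
#' @param frame a [MolecularSystem-class] containing protein and waters.
#' @param resno residue number.
#' @param chain optional chain id (required if `resno` is ambiguous).
#' @param cutoff distance cutoff in Angstrom (default 3.5).
#' @return integer count; 0 with a warning for residues without side-chain
#'   atoms (glycine).
#' @export
countHydrationWaters <- function(frame, resno, chain = NULL, cutoff = 3.5) {
  a <- atoms(frame)
  sel <- a$class == "protein" & a$resno == resno &
         !(a$elety %in% BACKBONE_NAMES)
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) {
    warning("residue ", resno, " has no side-chain atoms; count is 0")
    return(0L)
  }
  wO <- a$class == "water" & toupper(a$elesy) == "O"
  if (!any(wO)) return(0L)
  sc <- coords(frame)[sel, , drop = FALSE]
  wx <- coords(frame)[wO, , drop = FALSE]
  wid <- paste(a$chain[wO], a$resno[wO])
  hit <- logical(nrow(wx))
  for (k in seq_len(nrow(sc))) {
    d2 <- rowSums(sweep(wx, 2, sc[k, ])^2)
    hit <- hit | d2 <= cutoff^2
  }
  length(unique(wid[hit]))
}

#' Per-residue packing and hydration change table
#'
#' For every protein residue, the mean side-chain ASA and the mean
#' hydration-water count are taken over the open-classified and
#' closed-classified frames, and combined into relative change statistics
#'
#'   R = (<X>_closed - <X>_open) / <X>_open
#'
#' (negative R: the quantity decreases upon closing). Residues whose
#' open-ensemble mean side-chain ASA is below `burialThreshold` are buried
#' and carry no R values (`excluded = TRUE`). `mode = "absolute"` reports
#' plain differences instead of relative changes.
#'
#' @param trajectory a [Trajectory-class] with protein (and, for the
#'   hydration counts, water) atoms.
#' @param classifications per-frame labels, "open"/"closed"/"intermediate"
#'   (see [classifyConformation()]); intermediate frames are ignored.
#' @param cutoff hydration cutoff (A, default 3.5).
#' @param probeRadius,nPoints ASA settings (see [computeASA()]).
#' @param burialThreshold burial exclusion on <ASA>_open (A^2, default 10).
#' @param mode "relative" (default) or "absolute".
#' @return data.frame with one row per residue: chain, resno, resid,
#'   asaOpen, asaClosed, watOpen, watClosed, rAsa, rWat, excluded.
#' @export
residueChangeTable <- function(trajectory, classifications, cutoff = 3.5,
                               probeRadius = 1.4, nPoints = 960,
                               burialThreshold = 10,
                               mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  nf <- nFrames(trajectory)
  if (length(classifications) != nf)
    stop("classifications must have one label per frame")
  iOpen <- which(classifications == "open")
  iClosed <- which(classifications == "closed")
  if (length(iOpen) == 0) stop("no open frames")
  if (length(iClosed) == 0) stop("no closed frames")

  a <- atoms(trajectory)
  resKey <- unique(a[a$class == "protein", c("chain", "resno", "resid")])
  rownames(resKey) <- NULL
  nR <- nrow(resKey)
  hasWater <- any(a$class == "water")

  frameStats <- function(k) {
    fr <- getFrame(trajectory, k)
    asa <- computeASA(fr, probeRadius = probeRadius, nPoints = nPoints)
    stopifnot(nrow(asa) == nR)
    wat <- if (hasWater)
      vapply(seq_len(nR), function(r) suppressWarnings(
        countHydrationWaters(fr, resKey$resno[r], resKey$chain[r],
                             cutoff = cutoff)), integer(1))
      else rep(0L, nR)
    cbind(asa = asa$asa, wat = wat)
  }
  meanOver <- function(idx) {
    acc <- matrix(0, nR, 2)
    for (k in idx) acc <- acc + frameStats(k)
    acc / length(idx)
  }
  mo <- meanOver(iOpen)
  mc <- meanOver(iClosed)

  rel <- function(cl, op) {
    if (mode == "absolute") return(cl - op)
    ifelse(op > 0, (cl - op) / op, ifelse(cl == 0, 0, NA_real_))
  }
  out <- data.frame(resKey,
                    asaOpen = mo[, 1], asaClosed = mc[, 1],
                    watOpen = mo[, 2], watClosed = mc[, 2],
                    rAsa = rel(mc[, 1], mo[, 1]),
                    rWat = rel(mc[, 2], mo[, 2]),
                    excluded = mo[, 1] < burialThreshold,
                    stringsAsFactors = FALSE)
  out$rAsa[out$excluded] <- NA_real_
  out$rWat[out$excluded] <- NA_real_
  out
}

findAtom <- function(a, xyz, resno, elety, what, chain = NULL) {
  sel <- a$resno == resno & a$elety %in% elety
  if (!is.null(chain)) sel <- sel & a$chain == chain
  idx <- which(sel)
  if (length(idx) == 0)
    stop("missing atom for ", what, ": residue ", resno, " atom ",
         paste(elety, collapse = "/"))
  xyz[idx, , drop = FALSE]
}

#' Hydrophobic-pocket jaw separation gauge
#'
#' Distance from the nearer of the HD1/HE1 ring hydrogens of the upper-jaw
#' phenylalanine to the midpoint of the lower jaw (CD1 of the first
#' tryptophan, CG of the second). The two ring hydrogens are chemically
#' equivalent positions, hence the per-frame minimum. Requires hydrogens in
#' the input.
#'
#' @param frame a [MolecularSystem-class].
#' @param resF upper-jaw residue number (default 340).
#' @param resW1,resW2 lower-jaw residue numbers (defaults 89, 92).
#' @param chain optional chain id.
#' @return distance in Angstrom.
#' @export
gaugeDHS1 <- function(frame, resF = 340, resW1 = 89, resW2 = 92,
                      chain = NULL) {
  a <- atoms(frame)
  xyz <- coords(frame)
  hs <- tryCatch(
    findAtom(a, xyz, resF, c("HD1", "HE1"), "d_HS1 jaw hydrogens", chain),
    error = function(e) stop(
      "d_HS1 requires the HD1/HE1 hydrogens of residue ", resF,
      "; none present (hydrogen-less input?)"))
  m1 <- findAtom(a, xyz, resW1, "CD1", "d_HS1 lower jaw", chain)[1, ]
  m2 <- findAtom(a, xyz, resW2, "CG", "d_HS1 lower jaw", chain)[1, ]
  mid <- (m1 + m2) / 2
  d <- min(sqrt(rowSums(sweep(hs, 2, mid)^2)))
  if (d < 1e-9) warning("degenerate geometry: jaw atom groups coincide")
  d
}

#' Hydrophilic-crevice stretch gauge
#'
#' Euclidean distance between the CA atom of the alanine side of the
#' crevice and the OE1 atom of the glutamate side.
#'
#' @param frame a [MolecularSystem-class].
#' @param resA CA-side residue number (default 190).
#' @param resE OE1-side residue number (default 354).
#' @param chain optional chain id.
#' @return distance in Angstrom.
#' @export
gaugeDHS2 <- function(frame, resA = 190, resE = 354, chain = NULL) {
  a <- atoms(frame)
  xyz <- coords(frame)
  p1 <- findAtom(a, xyz, resA, "CA", "d_HS2", chain)[1, ]
  p2 <- findAtom(a, xyz, resE, "OE1", "d_HS2", chain)[1, ]
  sqrt(sum((p1 - p2)^2))
}

#' Gauge time series over a trajectory
#'
#' @param trajectory a [Trajectory-class].
#' @param ... residue ids passed to [gaugeDHS1()] / [gaugeDHS2()].
#' @param which character subset of c("dHS1", "dHS2").
#' @return data.frame with time (ps) and the requested gauges (A).
#' @export
gaugeSeries <- function(trajectory, which = c("dHS1", "dHS2"), ...) {
  nf <- nFrames(trajectory)
  out <- data.frame(time = frameTimes(trajectory))
  args <- list(...)
  pick <- function(nm) args[intersect(names(args), nm)]
  if ("dHS1" %in% which)
    out$dHS1 <- vapply(seq_len(nf), function(k) do.call(
      gaugeDHS1, c(list(getFrame(trajectory, k)),
                   pick(c("resF", "resW1", "resW2", "chain")))), numeric(1))
  if ("dHS2" %in% which)
    out$dHS2 <- vapply(seq_len(nf), function(k) do.call(
      gaugeDHS2, c(list(getFrame(trajectory, k)),
                   pick(c("resA", "resE", "chain")))), numeric(1))
  out
}
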
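#' @include AllClasses.R AllGenerics.R molecular-io.R
NULL

#' Construct a voxel grid
#'
#' @param origin lower corner (A).
#' @param dim integer (nx, ny, nz).
#' @param spacing voxel edge (A, default 1).
#' @return a [VoxelGrid-class].
#' @export
voxelGrid <- function(origin, dim, spacing = 1) {
  new("VoxelGrid", origin = origin, dim = as.integer(dim),
      spacing = spacing)
}

#' @rdname voxelGrid
#' @param lower,upper box corners (A); the grid covers the box.
#' @export
gridFromBox <- function(lower, upper, spacing = 1) {
  voxelGrid(lower, ceiling((upper - lower) / spacing - 1e-9), spacing)
}

# 1-based voxel (i,j,k) per row of coords; NA where outside. Half-open
# voxels: a coordinate exactly on a boundary belongs to the lower voxel.
voxelIndexOf <- function(grid, coords) {
  ijk <- floor(sweep(coords, 2, grid@origin) / grid@spacing) + 1
  bad <- ijk < 1 | sweep(ijk, 2, grid@dim, ">")
  ijk[rowSums(bad) > 0, ] <- NA
  ijk
}

voxelCenters <- function(grid) {
  gx <- grid@origin[1] + (seq_len(grid@dim[1]) - 0.5) * grid@spacing
  gy <- grid@origin[2] + (seq_len(grid@dim[2]) - 0.5) * grid@spacing
  gz <- grid@origin[3] + (seq_len(grid@dim[3]) - 0.5) * grid@spacing
  as.matrix(expand.grid(x = gx, y = gy, z = gz))
}

sameGrid <- function(a, b) {
  identical(a@dim, b@dim) && isTRUE(all.equal(a@origin, b@origin)) &&
    isTRUE(all.equal(a@spacing, b@spacing))
}

#' Locally superpose a trajectory window on an anchor selection
#'
#' Every frame of the window is rigid-transformed so that the anchor atoms
#' best fit the window's first frame; the transform is applied to all atoms
#' including waters. This removes the anchor group's translation/rotation
#' so that time-averaged solvent density around it is not smeared.
#'
#' @param trajectory a [Trajectory-class].
#' @param frames integer frame indices of the window (contiguous).
#' @param anchorSelection [AtomSelection-class] or indices, >= 3 atoms.
#' @return list with `window` (aligned [Trajectory-class]) and
#'   `avgProtein` (window-average protein structure,
#'   [MolecularSystem-class]).
#' @export
localSuperposeWindow <- function(trajectory, frames, anchorSelection) {
  if (length(frames) == 0) stop("empty window")
  anchor <- asIndices(anchorSelection)
  if (length(anchor) < 3) stop("anchor selection needs >= 3 atoms")
  ref <- frameCoords(trajectory, frames[1])
  n <- nAtoms(trajectory)
  arr <- array(NA_real_, c(n, 3, length(frames)))
  for (k in seq_along(frames)) {
    m <- frameCoords(trajectory, frames[k])
    tf <- kabschSuperpose(m, ref, anchor)
    arr[, , k] <- applyTransform(tf, m)
  }
  prot <- which(atoms(trajectory)$class == "protein")
  avg <- apply(arr[prot, , , drop = FALSE], c(1, 2), mean)
  avgSys <- newMolecularSystem(atoms(trajectory)[prot, , drop = FALSE], avg)
  win <- new("Trajectory", topology = trajectory@topology, coords = arr,
             times = frameTimes(trajectory)[frames])
  list(window = win, avgProtein = avgSys)
}

#' Accumulate a solvent electron-density map over an aligned window
#'
#' Every water atom contributes its electron count (O = 8, H = 1) to the
#' voxel containing its centre; per-voxel totals are summed over frames as
#' integers and divided by the frame count, giving time-averaged electrons
#' per voxel. A water resident in a voxel for the whole window therefore
#' contributes 10 e regardless of window length.
#'
#' @param window an aligned [Trajectory-class] (see
#'   [localSuperposeWindow()]), or any Trajectory.
#' @param grid a [VoxelGrid-class].
#' @param avgProtein optional window-average protein structure stored in
#'   the map (computed from the window when omitted).
#' @return a [DensityMap-class].
#' @export
accumulateDensity <- function(window, grid, avgProtein = NULL) {
  nf <- nFrames(window)
  if (nf == 0) stop("window has zero frames")
  a <- atoms(window)
  wat <- which(a$class == "water")
  el <- if (length(wat)) electronsOf(a$elesy[wat]) else numeric(0)
  counts <- array(0L, grid@dim)
  nvox <- prod(grid@dim)
  for (k in seq_len(nf)) {
    if (!length(wat)) break
    fc <- window@coords[, , k, drop = FALSE]
    dim(fc) <- dim(fc)[1:2]
    ijk <- voxelIndexOf(grid, fc[wat, , drop = FALSE])
    ok <- !is.na(ijk[, 1])
    if (!any(ok)) next
    lin <- (ijk[ok, 3] - 1) * grid@dim[1] * grid@dim[2] +
           (ijk[ok, 2] - 1) * grid@dim[1] + ijk[ok, 1]
    acc <- vapply(split(el[ok], lin), sum, numeric(1))
    idx <- as.integer(names(acc))
    counts[idx] <- counts[idx] + as.integer(acc)
  }
  if (is.null(avgProtein)) {
    prot <- which(a$class == "protein")
    if (length(prot)) {
      avg <- apply(window@coords[prot, , , drop = FALSE], c(1, 2), mean)
      avgProtein <- newMolecularSystem(a[prot, , drop = FALSE], avg)
    } else {
      avgProtein <- newMolecularSystem(
        a[integer(0), , drop = FALSE], matrix(numeric(0), 0, 3))
    }
  }
  t <- frameTimes(window)
  win <- if (nf > 1) c(t[1], t[nf]) else c(t[1], t[1] + 1)
  new("DensityMap", grid = grid, density = counts / nf,
      window = win, avgProtein = avgProtein)
}

#' Sliding-window solvent density series
#'
#' Computes one locally superposed, time-averaged density map per window
#' position. With frame spacing dt, a window holds round(windowLength/dt)
#' consecutive frames and advances by round(stride/dt) frames; the number
#' of maps is floor((nFrames - nWin)/strideF) + 1.
#'
#' @param trajectory a [Trajectory-class] (uniform frame spacing).
#' @param windowLength window length in ps (default 50).
#' @param stride window step in ps (default 1).
#' @param anchorSelection anchor atoms for the local superposition.
#' @param grid a [VoxelGrid-class].
#' @return list of [DensityMap-class], one per window position.
#' @export
slidingDensitySeries <- function(trajectory, windowLength = 50, stride = 1,
                                 anchorSelection, grid) {
  t <- frameTimes(trajectory)
  nf <- length(t)
  dt <- if (nf > 1) t[2] - t[1] else 1
  nWin <- max(1L, as.integer(round(windowLength / dt)))
  strideF <- max(1L, as.integer(round(stride / dt)))
  if (nf < nWin)
    stop(sprintf("trajectory (%d frames) shorter than window (%d frames)",
                 nf, nWin))
  starts <- seq.int(1L, nf - nWin + 1L, by = strideF)
  lapply(starts, function(s) {
    w <- localSuperposeWindow(trajectory, s:(s + nWin - 1L),
                              anchorSelection)
    accumulateDensity(w$window, grid, avgProtein = w$avgProtein)
  })
}

#' Mean bulk solvent density per voxel
#'
#' Averages the map over voxels whose centre is farther than
#' `exclusionDistance` from every protein atom of the map's window-average
#' structure; used to express contour levels in units of the bulk density.
#'
#' @param map a [DensityMap-class].
#' @param exclusionDistance protein exclusion distance (A, default 4).
#' @return mean electrons per voxel in the bulk region.
#' @export
bulkDensity <- function(map, exclusionDistance = 4) {
  centers <- voxelCenters(map@grid)
  px <- coords(map@avgProtein)
  if (nrow(px) == 0) {
    bulk <- rep(TRUE, nrow(centers))
  } else {
    mind2 <- rep(Inf, nrow(centers))
    for (i in seq_len(nrow(px)))
      mind2 <- pmin(mind2, rowSums(sweep(centers, 2, px[i, ])^2))
    bulk <- mind2 > exclusionDistance^2
  }
  if (!any(bulk)) stop("no bulk voxels beyond the exclusion distance")
  mean(map@density[bulk])
}

#' Region masks on a voxel grid
#'
#' Membership is evaluated at voxel centres. Masks combine with `|` / `&`.
#'
#' @param grid a [VoxelGrid-class].
#' @param center sphere centre (A).
#' @param radius sphere/cylinder radius (A).
#' @return a [RegionMask-class].
#' @export
maskSphere <- function(grid, center, radius) {
  c2 <- rowSums(sweep(voxelCenters(grid), 2, center)^2)
  new("RegionMask", grid = grid,
      mask = array(c2 <= radius^2, grid@dim))
}

#' @rdname maskSphere
#' @param lower,upper box corners (A).
#' @export
maskBox <- function(grid, lower, upper) {
  v <- voxelCenters(grid)
  inb <- v[, 1] >= lower[1] & v[, 1] <= upper[1] &
         v[, 2] >= lower[2] & v[, 2] <= upper[2] &
         v[, 3] >= lower[3] & v[, 3] <= upper[3]
  new("RegionMask", grid = grid, mask = array(inb, grid@dim))
}

#' @rdname maskSphere
#' @param point cylinder base centre (A).
#' @param axis cylinder axis direction.
#' @param length cylinder length (A), extending from `point` along `axis`.
#' @export
maskCylinder <- function(grid, point, axis, length, radius) {
  u <- axis / sqrt(sum(axis^2))
  v <- sweep(voxelCenters(grid), 2, point)
  along <- drop(v %*% u)
  perp2 <- rowSums(v^2) - along^2
  inb <- along >= 0 & along <= length & perp2 <= radius^2
  new("RegionMask", grid = grid, mask = array(inb, grid@dim))
}

#' @export
setMethod("|", signature("RegionMask", "RegionMask"), function(e1, e2) {
  stopifnot(sameGrid(e1@grid, e2@grid))
  new("RegionMask", grid = e1@grid, mask = e1@mask | e2@mask)
})

#' @export
setMethod("&", signature("RegionMask", "RegionMask"), function(e1, e2) {
  stopifnot(sameGrid(e1@grid, e2@grid))
  new("RegionMask", grid = e1@grid, mask = e1@mask & e2@mask)
})

#' Region-integrated hydration charge Q
#'
#' Sum of the time-averaged solvent electron density over the voxels of the
#' mask; ~10 e per fully resident water.
#'
#' @param map a [DensityMap-class].
#' @param mask a [RegionMask-class] on the same grid.
#' @return Q in electrons.
#' @export
integrateQ <- function(map, mask) {
  if (!sameGrid(map@grid, mask@grid))
    stop("mask and map are on different grids")
  if (!any(mask@mask)) stop("empty mask")
  sum(map@density[mask@mask])
}

#' @rdname integrateQ
#' @param maps list of [DensityMap-class] (see [slidingDensitySeries()]).
#' @return for `integrateQSeries`: data.frame with window start/end times
#'   (ps) and Q (e); `mask` may be a function(map) -> RegionMask for masks
#'   anchored to each window-average structure.
#' @export
integrateQSeries <- function(maps, mask) {
  q <- vapply(maps, function(m) {
    mk <- if (is.function(mask)) mask(m) else mask
    integrateQ(m, mk)
  }, numeric(1))
  data.frame(tStart = vapply(maps, function(m) m@window[1], numeric(1)),
             tEnd = vapply(maps, function(m) m@window[2], numeric(1)),
             Q = q)
}

#' Write a density map as a plain-text voxel table
#'
#' Tab-separated columns i, j, k, x, y, z (voxel centre, A) and density
#' (e); zero-density voxels are omitted.
#'
#' @param map a [DensityMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDensityTable <- function(map, path) {
  nz <- which(map@density > 0, arr.ind = TRUE)
  ctr <- sweep((nz - 0.5) * map@grid@spacing, 2, map@grid@origin, "+")
  df <- data.frame(i = nz[, 1], j = nz[, 2], k = nz[, 3],
                   x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                   density = map@density[nz])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
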
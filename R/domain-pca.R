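#' @include AllClasses.R AllGenerics.R molecular-io.R
NULL

# normalise conformation input to a list of N x 3 matrices
asConformationList <- function(conformations) {
  if (is(conformations, "Trajectory"))
    lapply(seq_len(nFrames(conformations)),
           function(k) frameCoords(conformations, k))
  else if (is(conformations, "MolecularSystem"))
    list(coords(conformations))
  else if (is.matrix(conformations))
    list(conformations)
  else if (is.list(conformations))
    lapply(conformations, function(x)
      if (is(x, "MolecularSystem")) coords(x) else as.matrix(x))
  else stop("unsupported conformation input")
}

flattenXYZ <- function(m) as.vector(t(m))   # x1,y1,z1,x2,...

# openness proxy: distance of the analysis-set centroid from the fit-set
# centroid; the widest-cleft conformation is the most open one
opennessOf <- function(confs, fitIdx, anaIdx) {
  vapply(confs, function(m) {
    sqrt(sum((colMeans(m[anaIdx, , drop = FALSE]) -
              colMeans(m[fitIdx, , drop = FALSE]))^2))
  }, numeric(1))
}

#' Principal component analysis of domain motion
#'
#' Each conformation is rigid-body superposed onto the first via the fit
#' selection (the reference domain); the covariance of the analysis-set
#' Cartesian coordinates is then eigendecomposed. The two selections are
#' deliberately distinct: superposing on one domain makes the analysis-set
#' displacements pure inter-domain motion.
#'
#' Covariance uses the (n-1) normalisation. Component signs are fixed so
#' that a larger projection means a more open inter-domain cleft (measured
#' by the distance between the analysis-set and fit-set centroids); where a
#' component is uncorrelated with that gauge its first largest-magnitude
#' coefficient is made positive.
#'
#' @param conformations a [Trajectory-class], or a list of N x 3 coordinate
#'   matrices / [MolecularSystem-class] objects sharing one topology.
#' @param fitSelection,analysisSelection [AtomSelection-class] objects or
#'   integer index vectors: the superposition set and the analysed set.
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(conformations, fitSelection, analysisSelection) {
  confs <- asConformationList(conformations)
  if (length(confs) < 2) stop("need at least 2 conformations")
  fitIdx <- asIndices(fitSelection)
  anaIdx <- asIndices(analysisSelection)
  n <- nrow(confs[[1]])
  for (k in seq_along(confs)) {
    if (nrow(confs[[k]]) != n)
      stop("conformation ", k, " has a different atom count")
    if (max(fitIdx, anaIdx) > nrow(confs[[k]]))
      stop("selection not resolvable in conformation ", k)
  }
  ref <- confs[[1]]
  aligned <- lapply(confs, function(m) {
    tf <- kabschSuperpose(m, ref, fitIdx)
    applyTransform(tf, m)
  })
  X <- t(vapply(aligned, function(m)
    flattenXYZ(m[anaIdx, , drop = FALSE]), numeric(3 * length(anaIdx))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  nC <- length(confs)
  vars <- s$d^2 / (nC - 1)
  keep <- seq_len(min(nC - 1, ncol(X)))
  vars <- vars[keep]
  V <- s$v[, keep, drop = FALSE]
  # sign convention
  open <- opennessOf(aligned, fitIdx, anaIdx)
  proj <- Xc %*% V
  for (j in seq_along(keep)) {
    r <- sum(proj[, j] * (open - mean(open)))
    if (abs(r) > 1e-10) {
      if (r < 0) V[, j] <- -V[, j]
    } else {
      i0 <- which.max(abs(V[, j]))
      if (V[i0, j] < 0) V[, j] <- -V[, j]
    }
  }
  tot <- sum(vars)
  new("PCAModel", fitIndices = as.integer(fitIdx),
      analysisIndices = as.integer(anaIdx), refCoords = ref,
      meanCoords = mu, components = V, variances = vars,
      fractions = if (tot > 0) vars / tot else rep(0, length(vars)))
}

#' Project conformations onto a PCA model
#'
#' Conformations are first superposed onto the model's reference via its
#' fit selection; projections are inner products of the centred analysis
#' coordinates with the component vectors. The model's mean conformation
#' projects to zero on every component.
#'
#' @param model a [PCAModel-class].
#' @param conformations as in [fitPCA()].
#' @return numeric matrix, one row per conformation, one column per
#'   component (Angstrom).
#' @export
projectPCA <- function(model, conformations) {
  confs <- asConformationList(conformations)
  for (k in seq_along(confs))
    if (nrow(confs[[k]]) != nrow(model@refCoords))
      stop("conformation ", k, " is incompatible with the model's topology")
  P <- t(vapply(confs, function(m) {
    tf <- kabschSuperpose(m, model@refCoords, model@fitIndices)
    ma <- applyTransform(tf, m)[model@analysisIndices, , drop = FALSE]
    drop((flattenXYZ(ma) - model@meanCoords) %*% model@components)
  }, numeric(ncol(model@components))))
  if (ncol(model@components) == 1) P <- matrix(P, ncol = 1)
  colnames(P) <- paste0("PC", seq_len(ncol(P)))
  P
}

#' Correlation (absolute cosine) between component axes of two models
#'
#' @param modelA,modelB [PCAModel-class] objects with identical analysis
#'   selections.
#' @param component component index (default 1).
#' @return |inner product| of the two unit component vectors, in [0, 1].
#' @export
axisCorrelation <- function(modelA, modelB, component = 1) {
  if (!identical(modelA@analysisIndices, modelB@analysisIndices))
    stop("models have different analysis selections")
  abs(sum(modelA@components[, component] * modelB@components[, component]))
}

#' Screw-axis (Chasles) decomposition of inter-domain motion
#'
#' Superposes the closed conformation onto the open one via the fit
#' selection (removing overall motion of the reference domain), computes
#' the residual rigid transform of the moving selection, and decomposes it
#' into a rotation about, plus a translation along, a unique screw axis.
#' This is a simplified single-transform hinge extraction (no clustering of
#' rotation vectors over many segment pairs).
#'
#' @param open,closed conformations (N x 3 matrices or
#'   [MolecularSystem-class]) sharing one topology.
#' @param fitSelection reference-domain atoms for the initial superposition.
#' @param movingSelection atoms of the moving domain.
#' @return a [ScrewAxis-class].
#' @export
hingeAxis <- function(open, closed, fitSelection, movingSelection) {
  co <- asConformationList(open)[[1]]
  cc <- asConformationList(closed)[[1]]
  fitIdx <- asIndices(fitSelection)
  movIdx <- asIndices(movingSelection)
  tf <- kabschSuperpose(cc, co, fitIdx)
  ccAl <- applyTransform(tf, cc)
  mtf <- kabschSuperpose(co[movIdx, , drop = FALSE],
                         ccAl[movIdx, , drop = FALSE])
  R <- mtf@rotation
  tvec <- as.numeric(mtf@centerRef - R %*% mtf@centerMobile)
  tr <- sum(diag(R))
  cosTh <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cosTh)
  if (theta * 180 / pi < 1)
    stop("ill-conditioned axis: rotation angle < 1 degree ",
         "(motion is (near-)pure translation)")
  if (abs(sin(theta)) > 1e-6) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    nvec <- v / (2 * sin(theta))
  } else {
    # theta ~ pi: axis from the eigenvector of R with eigenvalue +1
    e <- eigen(R)
    k <- which.min(abs(e$values - 1))
    nvec <- Re(e$vectors[, k])
  }
  nvec <- nvec / sqrt(sum(nvec^2))
  d <- sum(nvec * tvec)
  tperp <- tvec - d * nvec
  A <- diag(3) - R + outer(nvec, nvec)
  p <- as.numeric(solve(A, tperp))
  new("ScrewAxis", direction = nvec, point = p,
      angle = theta * 180 / pi, translation = d)
}

#' Classify conformations as open / closed / intermediate
#'
#' @param projection projection value(s) on the first component (Angstrom).
#' @param openThreshold open if projection > this (default +15 A).
#' @param closedThreshold closed if projection < this (default -15 A).
#' @return character vector of "open" / "closed" / "intermediate".
#' @export
classifyConformation <- function(projection, openThreshold = 15,
                                 closedThreshold = -15) {
  ifelse(projection > openThreshold, "open",
         ifelse(projection < closedThreshold, "closed", "intermediate"))
}
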
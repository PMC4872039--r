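#' @include AllClasses.R
NULL

#' Accessors for hydrokin objects
#'
#' Slot access goes through these accessors; the slots themselves are
#' internal.
#'
#' @param x a hydrokin object.
#' @param ... unused.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @param i frame index.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("indices", function(x) standardGeneric("indices"))
#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("variances", function(x) standardGeneric("variances"))
#' @rdname accessors
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("stateTimes", function(x) standardGeneric("stateTimes"))
#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @rdname accessors
#' @export
setGeneric("mapGrid", function(x) standardGeneric("mapGrid"))
#' @rdname accessors
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' @name atoms
#' @rdname accessors
#' @aliases atoms,MolecularSystem-method
setMethod("atoms", "MolecularSystem", function(x, ...) x@atoms)
#' @rdname accessors
setMethod("atoms", "Trajectory", function(x, ...) x@topology@atoms)
#' @rdname accessors
setMethod("coords", "MolecularSystem", function(x, ...) x@coords)
#' @rdname accessors
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= dim(x@coords)[3])
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})
#' @rdname accessors
setMethod("getFrame", "Trajectory", function(x, i) {
  new("MolecularSystem", atoms = x@topology@atoms, coords = frameCoords(x, i))
})
#' @rdname accessors
setMethod("indices", "AtomSelection", function(x) x@indices)
#' @rdname accessors
setMethod("components", "PCAModel", function(x) x@components)
#' @rdname accessors
setMethod("variances", "PCAModel", function(x) x@variances)
#' @rdname accessors
setMethod("varianceFractions", "PCAModel", function(x) x@fractions)
#' @rdname accessors
setMethod("stateLabels", "StateSeries", function(x) x@labels)
#' @rdname accessors
setMethod("stateTimes", "StateSeries", function(x) x@times)
#' @rdname accessors
setMethod("densityValues", "DensityMap", function(x) x@density)
#' @rdname accessors
setMethod("mapGrid", "DensityMap", function(x) x@grid)
#' @rdname accessors
setMethod("mapGrid", "RegionMask", function(x) x@grid)
#' @rdname accessors
setMethod("metadata", "Trajectory", function(x) x@metadata)
#' @rdname accessors
setMethod("metadata", "StateSeries", function(x) x@metadata)

setMethod("show", "MolecularSystem", function(object) {
  cls <- table(object@atoms$class)
  cat("MolecularSystem:", nrow(object@atoms), "atoms (",
      paste(sprintf("%s: %d", names(cls), cls), collapse = ", "), ")\n")
})

setMethod("show", "Trajectory", function(object) {
  t <- object@times
  cat(sprintf("Trajectory: %d atoms x %d frames, t = %g..%g ps\n",
              nAtoms(object), nFrames(object), t[1], t[length(t)]))
})

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection: %d atoms [%s]\n",
              length(object@indices), object@expr))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf(
    "PCAModel: %d analysis atoms, %d components; PC1 fraction %.3f\n",
    length(object@analysisIndices), ncol(object@components),
    object@fractions[1]))
})

setMethod("show", "ScrewAxis", function(object) {
  cat(sprintf(
    "ScrewAxis: direction (%.3f, %.3f, %.3f), angle %.2f deg, pitch %.3f A\n",
    object@direction[1], object@direction[2], object@direction[3],
    object@angle, object@translation))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf(
    "DensityMap: %s voxels at %.2f A, window %g..%g ps, total %.1f e\n",
    paste(object@grid@dim, collapse = "x"), object@grid@spacing,
    object@window[1], object@window[2], sum(object@density)))
})

setMethod("show", "StateSeries", function(object) {
  tab <- table(object@labels)
  cat(sprintf("StateSeries: %d snapshots, states: %s\n",
              length(object@labels),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
})

setMethod("show", "KineticScheme", function(object) {
  cat("KineticScheme:", paste(object@states, collapse = ", "), "\n")
  for (k in seq_len(nrow(object@tau)))
    cat(sprintf("  %s -> %s: tau = %g ps\n", object@tau$from[k],
                object@tau$to[k], object@tau$tau[k]))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf(
    "RateEstimate %s -> %s: tau = %.2f ps (rate %.4g ps^-1, n = %d)\n",
    object@stateA, object@stateB, object@tau, object@rate, object@nDwells))
})

setMethod("show", "TwoGaussianFit", function(object) {
  cat(sprintf(
    "TwoGaussianFit: mu = (%.2f, %.2f) A, separation %.2f A, sigma %.2f A%s%s\n",
    object@mu1, object@mu2, object@separation, object@sigma,
    if (object@sigmaFixed) " (fixed)" else "",
    if (object@unimodal) " [unimodal]" else ""))
})
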
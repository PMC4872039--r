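#' @import methods
NULL

#' MolecularSystem: a topology plus one coordinate set
#'
#' Holds an atom table (name, element, residue number/name, chain, record
#' class) together with one set of Cartesian coordinates in Angstrom.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety} (atom name),
#'   \code{resid} (residue name), \code{resno}, \code{chain}, \code{elesy}
#'   (element symbol) and \code{class} (one of \code{"protein"},
#'   \code{"water"}, \code{"ion"}).
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#'
#' @seealso [readStructure()], [selectAtoms()]
#' @export
setClass("MolecularSystem",
  representation(atoms = "data.frame", coords = "matrix"),
  validity = function(object) {
    msg <- character()
    need <- c("eleno", "elety", "resid", "resno", "chain", "elesy", "class")
    miss <- setdiff(need, names(object@atoms))
    if (length(miss))
      msg <- c(msg, paste("atoms table lacks columns:", paste(miss, collapse = ", ")))
    if (nrow(object@atoms) != nrow(object@coords))
      msg <- c(msg, sprintf("atom count (%d) != coordinate rows (%d)",
                            nrow(object@atoms), nrow(object@coords)))
    if (ncol(object@coords) != 3)
      msg <- c(msg, "coords must have 3 columns")
    if ("class" %in% names(object@atoms) &&
        !all(object@atoms$class %in% c("protein", "water", "ion")))
      msg <- c(msg, "record class must be protein/water/ion")
    if (length(msg)) msg else TRUE
  })

#' Trajectory: ordered coordinate frames sharing one topology
#'
#' @slot topology a [MolecularSystem-class] (its own coordinates are the
#'   reference/template frame).
#' @slot coords numeric array of dim (nAtoms, 3, nFrames), Angstrom.
#' @slot times numeric vector of frame timestamps in ps, strictly increasing.
#' @slot metadata list of generator ground truth or provenance (may be empty).
#' @export
setClass("Trajectory",
  representation(topology = "MolecularSystem", coords = "array",
                 times = "numeric", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3 || d[2] != 3)
      msg <- c(msg, "coords must be an (nAtoms, 3, nFrames) array")
    else {
      if (d[1] != nrow(object@topology@atoms))
        msg <- c(msg, "frame atom count differs from topology")
      if (d[3] != length(object@times))
        msg <- c(msg, "number of frames differs from number of timestamps")
    }
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' AtomSelection: a resolved, named set of atom indices
#'
#' @slot indices sorted unique integer indices into a topology's atom table.
#' @slot expr human-readable description of the predicate that produced them.
#' @export
setClass("AtomSelection",
  representation(indices = "integer", expr = "character"),
  validity = function(object) {
    if (is.unsorted(object@indices, strictly = TRUE))
      "indices must be sorted and unique" else TRUE
  })

#' RigidTransform: proper rotation + translation mapping mobile onto reference
#'
#' Applies as \code{x' = R \%*\% (x - centerMobile) + centerRef} for column
#' 3-vectors; see [applyTransform()].
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot centerMobile,centerRef 3-vectors: fit-selection centroids.
#' @slot rmsd RMSD (Angstrom) over the fit selection after superposition.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", centerMobile = "numeric",
                 centerRef = "numeric", rmsd = "numeric"))

#' PCAModel: principal components of domain motion
#'
#' @slot fitIndices,analysisIndices integer atom indices: the superposition
#'   set and the analysis set.
#' @slot refCoords full coordinates of the superposition reference frame.
#' @slot meanCoords mean (superposed) analysis-set coordinates, flattened
#'   length 3M (x1,y1,z1,x2,...).
#' @slot components orthonormal matrix, 3M rows, one column per component.
#' @slot variances per-component variances (Angstrom^2), non-increasing.
#' @slot fractions variance fractions (sum to 1).
#' @export
setClass("PCAModel",
  representation(fitIndices = "integer", analysisIndices = "integer",
                 refCoords = "matrix", meanCoords = "numeric",
                 components = "matrix", variances = "numeric",
                 fractions = "numeric"),
  validity = function(object) {
    msg <- character()
    G <- crossprod(object@components)
    if (max(abs(G - diag(ncol(object@components)))) > 1e-8)
      msg <- c(msg, "components are not orthonormal")
    if (abs(sum(object@fractions) - 1) > 1e-8)
      msg <- c(msg, "variance fractions must sum to 1")
    if (is.unsorted(rev(object@fractions)))
      msg <- c(msg, "variance fractions must be non-increasing")
    if (length(msg)) msg else TRUE
  })

#' ScrewAxis: Chasles decomposition of a rigid inter-domain transform
#'
#' @slot direction unit 3-vector along the hinge axis.
#' @slot point a point on the axis (Angstrom).
#' @slot angle rotation angle in degrees, in (0, 180].
#' @slot translation translation along the axis (Angstrom).
#' @export
setClass("ScrewAxis",
  representation(direction = "numeric", point = "numeric",
                 angle = "numeric", translation = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
      msg <- c(msg, "direction must be a unit vector")
    if (object@angle <= 0 || object@angle > 180)
      msg <- c(msg, "angle must be in (0, 180] degrees")
    if (length(msg)) msg else TRUE
  })

#' VoxelGrid: axis-aligned voxel lattice
#'
#' Voxel ownership is half-open: a coordinate on a boundary belongs to the
#' lower-index voxel.
#'
#' @slot origin 3-vector, position of the grid's lower corner (Angstrom).
#' @slot dim integer 3-vector (nx, ny, nz).
#' @slot spacing voxel edge length in Angstrom (default 1).
#' @export
setClass("VoxelGrid",
  representation(origin = "numeric", dim = "integer", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
    if (any(object@dim < 1)) msg <- c(msg, "grid dimensions must be positive")
    if (length(msg)) msg else TRUE
  })

#' DensityMap: time-averaged solvent electron density on a voxel grid
#'
#' @slot grid the [VoxelGrid-class].
#' @slot density numeric array dim(grid) of electrons per voxel, averaged
#'   over the window's frames.
#' @slot window numeric length-2 (t_start, t_end) in ps.
#' @slot avgProtein window-average protein structure (a
#'   [MolecularSystem-class], protein atoms only).
#' @export
setClass("DensityMap",
  representation(grid = "VoxelGrid", density = "array", window = "numeric",
                 avgProtein = "MolecularSystem"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@density), as.integer(object@grid@dim)))
      msg <- c(msg, "density array dimensions differ from grid")
    if (any(object@density < 0)) msg <- c(msg, "densities must be >= 0")
    if (length(object@window) == 2 && diff(object@window) <= 0)
      msg <- c(msg, "window length must be > 0")
    if (length(msg)) msg else TRUE
  })

#' RegionMask: boolean voxel mask on a grid
#'
#' @slot grid the [VoxelGrid-class] the mask lives on.
#' @slot mask logical array, same dimensions as the grid.
#' @export
setClass("RegionMask",
  representation(grid = "VoxelGrid", mask = "array"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@mask), as.integer(object@grid@dim)))
      msg <- c(msg, "mask dimensions differ from grid")
    if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' StateSeries: per-frame categorical state labels on a uniform time grid
#'
#' @slot times ps, uniformly spaced.
#' @slot labels character state labels (may include \code{"boundary"} before
#'   [resolveBoundaries()]).
#' @slot metadata list; synthetic generators store their event log here.
#' @export
setClass("StateSeries",
  representation(times = "numeric", labels = "character", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@labels))
      msg <- c(msg, "times and labels differ in length")
    if (length(object@times) > 2) {
      dt <- diff(object@times)
      if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
        msg <- c(msg, "time spacing must be uniform")
    }
    if (length(msg)) msg else TRUE
  })

#' KineticScheme: states and pairwise mean dwell times
#'
#' Used both to generate synthetic Markovian state dynamics and to report
#' fitted transition time constants.
#'
#' @slot states ordered character state labels.
#' @slot tau data.frame with columns \code{from}, \code{to}, \code{tau} (ps):
#'   the mean dwell in \code{from} before a transition to \code{to}. The
#'   adjacency is exactly the set of (from, to) rows.
#' @export
setClass("KineticScheme",
  representation(states = "character", tau = "data.frame"),
  validity = function(object) {
    msg <- character()
    need <- c("from", "to", "tau")
    if (!all(need %in% names(object@tau)))
      msg <- c(msg, "tau needs columns from/to/tau")
    else {
      if (any(object@tau$tau <= 0)) msg <- c(msg, "all tau must be > 0")
      bad <- !(object@tau$from %in% object@states) |
             !(object@tau$to %in% object@states)
      if (any(bad)) msg <- c(msg, "tau refers to undeclared states")
      if (any(object@tau$from == object@tau$to))
        msg <- c(msg, "self-transitions are not allowed")
    }
    if (length(msg)) msg else TRUE
  })

#' RateEstimate: fitted transition time constant for one state pair
#'
#' @slot stateA,stateB the transition A -> B.
#' @slot tau fitted mean residence time (ps).
#' @slot rate 1/tau (ps^-1).
#' @slot nDwells number of dwell records used in the fit.
#' @slot diagnostics list: \code{tauClosedForm} (mean(t_res) - t_min),
#'   \code{residualNorm} of the CDF fit, \code{method}.
#' @export
setClass("RateEstimate",
  representation(stateA = "character", stateB = "character", tau = "numeric",
                 rate = "numeric", nDwells = "integer", diagnostics = "list"),
  validity = function(object) {
    msg <- character()
    if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
    if (abs(object@rate * object@tau - 1) > 1e-8)
      msg <- c(msg, "rate must equal 1/tau")
    if (length(msg)) msg else TRUE
  })

#' TwoGaussianFit: two-component common-sigma Gaussian mixture fit
#'
#' @slot mu1,mu2 component means (Angstrom), mu1 <= mu2.
#' @slot weights length-2 simplex weights (component 1, component 2).
#' @slot sigma common standard deviation (Angstrom).
#' @slot sigmaFixed logical: was sigma held fixed during the fit.
#' @slot separation mu2 - mu1 (Angstrom).
#' @slot unimodal logical: TRUE when the fitted mixture has a single mode
#'   (weights collapsed, or separation below 2 sigma, which guarantees a
#'   unimodal common-sigma mixture density for any weights).
#' @slot diagnostics list: residual norm, bin width, bin-width sensitivity.
#' @export
setClass("TwoGaussianFit",
  representation(mu1 = "numeric", mu2 = "numeric", weights = "numeric",
                 sigma = "numeric", sigmaFixed = "logical",
                 separation = "numeric", unimodal = "logical",
                 diagnostics = "list"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must sum to 1")
    if (object@separation < 0) msg <- c(msg, "separation must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' HingeConfig: synthetic rigid hinge-motion generator settings
#'
#' @slot nFrames number of frames.
#' @slot dt ps per frame.
#' @slot hingeAxis unit 3-vector.
#' @slot hingePoint 3-vector (Angstrom).
#' @slot angleProcess "two_state" or "ou_process".
#' @slot angleOpen,angleClosed hinge angles (degrees) of the two states
#'   (for OU: mean = angleOpen, long-time SD = |angleOpen - angleClosed|/2).
#' @slot dwellTauOpen,dwellTauClosed mean dwell times (ps).
#' @slot atomNoiseSigma isotropic per-atom Gaussian noise SD (Angstrom).
#' @slot seed integer RNG seed.
#' @export
setClass("HingeConfig",
  representation(nFrames = "integer", dt = "numeric", hingeAxis = "numeric",
                 hingePoint = "numeric", angleProcess = "character",
                 angleOpen = "numeric", angleClosed = "numeric",
                 dwellTauOpen = "numeric", dwellTauClosed = "numeric",
                 atomNoiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (abs(sqrt(sum(object@hingeAxis^2)) - 1) > 1e-8)
      msg <- c(msg, "hingeAxis must be a unit vector")
    if (object@dwellTauOpen <= 0 || object@dwellTauClosed <= 0)
      msg <- c(msg, "dwell taus must be > 0")
    if (!object@angleProcess %in% c("two_state", "ou_process"))
      msg <- c(msg, "angleProcess must be two_state or ou_process")
    if (object@atomNoiseSigma < 0) msg <- c(msg, "atomNoiseSigma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' WaterSceneConfig: synthetic solvent-scene generator settings
#'
#' @slot box 3-vector box edge lengths (Angstrom), box spans [0, box].
#' @slot bulkDensity waters per Angstrom^3 (TIP3P-like bulk is ~0.0334).
#' @slot pocketCenter,pocketRadius spherical pocket region (Angstrom).
#' @slot pocketWatersPerState named integer vector: state label -> number of
#'   waters resident in the pocket while in that state.
#' @slot scheme [KineticScheme-class] governing the pocket hydration state.
#' @slot seed integer RNG seed.
#' @export
setClass("WaterSceneConfig",
  representation(box = "numeric", bulkDensity = "numeric",
                 pocketCenter = "numeric", pocketRadius = "numeric",
                 pocketWatersPerState = "integer", scheme = "KineticScheme",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@bulkDensity < 0) msg <- c(msg, "bulkDensity must be >= 0")
    if (any(object@pocketWatersPerState < 0))
      msg <- c(msg, "pocket water counts must be >= 0")
    lo <- object@pocketCenter - object@pocketRadius
    hi <- object@pocketCenter + object@pocketRadius
    if (any(lo < 0) || any(hi > object@box))
      msg <- c(msg, "pocket region must fit inside the box")
    st <- names(object@pocketWatersPerState)
    if (!all(object@scheme@states %in% st))
      msg <- c(msg, "every scheme state needs a pocket water count")
    if (length(msg)) msg else TRUE
  })
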
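#' @include AllClasses.R AllGenerics.R
NULL

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "H2O")
ION_RESNAMES <- c("NA", "CL", "K", "MG", "CA2", "ZN", "SOD", "CLA")

# electron counts per neutral element, used for solvent density maps
ELECTRONS <- c(H = 1, C = 6, N = 7, O = 8, NA. = 11, MG = 12, P = 15,
               S = 16, CL = 17, K = 19, CA = 20, ZN = 30)

classifyRecord <- function(resid) {
  up <- toupper(resid)
  ifelse(up %in% WATER_RESNAMES, "water",
         ifelse(up %in% ION_RESNAMES, "ion", "protein"))
}

elementOf <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                 sub("^[0-9]+", "", elety[miss])), 1, 1))
    el[miss] <- guess
  }
  el
}

electronsOf <- function(elesy) {
  el <- toupper(elesy)
  el[el == "NA"] <- "NA."
  e <- ELECTRONS[el]
  if (anyNA(e))
    stop("no electron count for element(s): ",
         paste(unique(el[is.na(e)]), collapse = ", "))
  unname(e)
}

newMolecularSystem <- function(atoms, coords) {
  rownames(coords) <- NULL
  colnames(coords) <- c("x", "y", "z")
  new("MolecularSystem", atoms = atoms, coords = as.matrix(coords))
}

#' Build a MolecularSystem from vectors of atom attributes
#'
#' Low-level constructor used by the synthetic generators and tests.
#'
#' @param elety atom names; @param resid residue names; @param resno residue
#'   numbers; @param chain chain identifiers; @param coords N x 3 matrix (A).
#' @param elesy element symbols; guessed from `elety` when omitted.
#' @return a [MolecularSystem-class].
#' @export
makeSystem <- function(elety, resid, resno, chain, coords, elesy = NULL) {
  n <- length(elety)
  if (is.null(elesy)) elesy <- elementOf(rep(NA_character_, n), elety)
  atoms <- data.frame(
    eleno = seq_len(n), elety = elety, resid = resid, resno = resno,
    chain = chain, elesy = elesy, class = classifyRecord(resid),
    stringsAsFactors = FALSE)
  newMolecularSystem(atoms, coords)
}

bio3dToSystem <- function(pdb) {
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("file contains no ATOM/HETATM records (empty system)")
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    elesy = elementOf(at$elesy, at$elety),
    class = classifyRecord(at$resid), stringsAsFactors = FALSE)
  newMolecularSystem(atoms, cbind(at$x, at$y, at$z))
}

#' Read a PDB structure file
#'
#' Waters are recognised by residue name (HOH/WAT/TIP3/...), common
#' monatomic ions likewise; everything else is classed as protein.
#'
#' @param path PDB file path.
#' @return a [MolecularSystem-class] with atoms in file order.
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  bio3dToSystem(pdb)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL becomes one frame. Timestamps come from `times` or from `dt`
#' (frame k at (k-1)*dt ps).
#'
#' @param path multi-model PDB file.
#' @param dt frame spacing in ps (default 1).
#' @param times explicit timestamps; overrides `dt`.
#' @param partial if TRUE, a file whose final MODEL block is truncated is
#'   trimmed to its last complete ENDMDL and the earlier frames returned;
#'   if FALSE such a file is an error.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, dt = 1, times = NULL, partial = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (partial) {
    lines <- readLines(path, warn = FALSE)
    last <- max(grep("^ENDMDL", lines), 0L)
    if (last == 0L) stop("partial read: no complete MODEL block in ", path)
    if (last < length(lines) && any(grepl("^(ATOM|HETATM|MODEL)",
                                          lines[(last + 1):length(lines)]))) {
      path <- tempfile(fileext = ".pdb")
      on.exit(unlink(path), add = TRUE)
      writeLines(c(lines[seq_len(last)], "END"), path)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- bio3dToSystem(pdb)
  xyz <- pdb$xyz                        # nFrames x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  n <- nAtoms(topo)
  if (ncol(xyz) != 3 * n)
    stop(sprintf("frame 1: atom-count mismatch (%d coordinates for %d atoms)",
                 ncol(xyz) / 3, n))
  arr <- array(NA_real_, c(n, 3, nf))
  for (k in seq_len(nf))
    arr[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf)
    stop("length(times) != number of frames")
  new("Trajectory", topology = topo, coords = arr, times = times)
}

systemToBio3d <- function(system, xyz) {
  a <- atoms(system)
  list(atom = data.frame(
    type = ifelse(a$class == "protein", "ATOM", "HETATM"),
    eleno = a$eleno, elety = a$elety, alt = NA, resid = a$resid,
    chain = a$chain, resno = a$resno, insert = NA,
    x = 0, y = 0, z = 0, o = 1, b = 0, segid = NA, elesy = a$elesy,
    charge = NA, stringsAsFactors = FALSE), xyz = xyz)
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' @param x a [MolecularSystem-class] or [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "MolecularSystem")) {
    xyz <- matrix(as.vector(t(x@coords)), nrow = 1)
    sys <- x
  } else if (is(x, "Trajectory")) {
    nf <- nFrames(x)
    xyz <- t(vapply(seq_len(nf),
                    function(k) as.vector(t(frameCoords(x, k))),
                    numeric(3 * nAtoms(x))))
    sys <- x@topology
  } else stop("writePDB handles MolecularSystem or Trajectory")
  pdb <- systemToBio3d(sys, xyz)
  a <- pdb$atom
  bio3d::write.pdb(file = path, xyz = pdb$xyz, type = a$type,
                   eleno = a$eleno, elety = a$elety, resid = a$resid,
                   chain = a$chain, resno = a$resno, o = a$o, b = a$b,
                   elesy = a$elesy)
  invisible(path)
}

#' Select atoms of a system by attribute predicates
#'
#' All supplied filters are ANDed. `resno` may be any integer vector, e.g.
#' `c(27:44, 51:75)`.
#'
#' @param x a [MolecularSystem-class] or [Trajectory-class].
#' @param chain,resno,resid,elety,class optional filters (vectors of allowed
#'   values).
#' @param sidechain if TRUE, drop backbone atoms (N, CA, C, O, OXT and the
#'   amide/alpha hydrogens).
#' @return an [AtomSelection-class].
#' @export
selectAtoms <- function(x, chain = NULL, resno = NULL, resid = NULL,
                        elety = NULL, class = NULL, sidechain = FALSE) {
  a <- atoms(x)
  keep <- rep(TRUE, nrow(a))
  desc <- character()
  if (!is.null(chain)) { keep <- keep & a$chain %in% chain
    desc <- c(desc, paste0("chain ", paste(chain, collapse = ","))) }
  if (!is.null(resno)) { keep <- keep & a$resno %in% resno
    desc <- c(desc, sprintf("%d residues", length(unique(resno)))) }
  if (!is.null(resid)) { keep <- keep & a$resid %in% resid
    desc <- c(desc, paste(resid, collapse = ",")) }
  if (!is.null(elety)) { keep <- keep & a$elety %in% elety
    desc <- c(desc, paste(elety, collapse = ",")) }
  if (!is.null(class)) { keep <- keep & a$class %in% class
    desc <- c(desc, paste(class, collapse = ",")) }
  if (sidechain) {
    keep <- keep & !(a$elety %in% c("N", "CA", "C", "O", "OXT", "H", "HA",
                                    "H1", "H2", "H3", "HA2", "HA3"))
    desc <- c(desc, "sidechain")
  }
  new("AtomSelection", indices = which(keep),
      expr = if (length(desc)) paste(desc, collapse = " & ") else "all")
}

#' @rdname selectAtoms
#' @param e1,e2 selections on the same topology.
#' @export
setMethod("|", signature("AtomSelection", "AtomSelection"), function(e1, e2) {
  new("AtomSelection", indices = sort(union(e1@indices, e2@indices)),
      expr = paste0("(", e1@expr, ") | (", e2@expr, ")"))
})

#' @rdname selectAtoms
#' @export
setMethod("&", signature("AtomSelection", "AtomSelection"), function(e1, e2) {
  new("AtomSelection", indices = sort(intersect(e1@indices, e2@indices)),
      expr = paste0("(", e1@expr, ") & (", e2@expr, ")"))
})

asIndices <- function(sel) {
  if (is(sel, "AtomSelection")) sel@indices else as.integer(sel)
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation mapping `mobile` onto
#' `reference` with minimum RMSD over the fit selection. The returned
#' transform can be applied to any atom subset of the same mobile frame.
#'
#' @param mobile,reference N x 3 coordinate matrices (same atom order).
#' @param fitSelection atom indices (or an [AtomSelection-class]) used for
#'   the fit; default: all atoms.
#' @return a [RigidTransform-class]; its `rmsd` slot is the post-fit RMSD
#'   over the fit selection.
#' @export
kabschSuperpose <- function(mobile, reference, fitSelection = NULL) {
  idx <- if (is.null(fitSelection)) seq_len(nrow(mobile))
         else asIndices(fitSelection)
  if (length(idx) < 3) stop("degenerate fit: need >= 3 fit atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  cm <- colMeans(P); cr <- colMeans(Q)
  Pc <- sweep(P, 2, cm); Qc <- sweep(Q, 2, cr)
  # collinearity check: rank of centered fit coordinates
  sv <- svd(Pc)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate fit: fit atoms are collinear")
  H <- crossprod(Pc, Qc)               # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)            # x' = R (x - cm) + cr
  fitted <- sweep(tcrossprod(Pc, R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  new("RigidTransform", rotation = R, centerMobile = cm, centerRef = cr,
      rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a [RigidTransform-class].
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
applyTransform <- function(transform, coords) {
  sweep(tcrossprod(sweep(coords, 2, transform@centerMobile),
                   transform@rotation),
        2, transform@centerRef, "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b N x 3 matrices in the same frame (no fitting is performed).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
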
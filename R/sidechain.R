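#' Forward sidechain construction and rotamer inversion
#'
#' Sidechains are built from ideal internal coordinates (template bond
#' lengths/angles derived from ideal residue geometry) by sequential NeRF
#' placement. Dihedrals governed by a chi angle take the value
#' `chi_k + offset`; all others are fixed template values. Inversion runs the
#' same construction in a canonical frame and solves the rigid placement of
#' the backbone from the fixed functional-group atoms.
#'
#' @name sidechain
NULL

#' Number of chi dihedrals of an identity
#' @param identity three-letter amino-acid code
#' @export
n_chi <- function(identity) {
  if (!identity %in% .std_aa) stop("not a canonical amino acid: ", identity)
  length(.chi_defs[[identity]])
}

#' Template chi values (ideal-geometry defaults) for an identity
#' @inheritParams n_chi
#' @export
template_chi <- function(identity) {
  v <- .template_chi[[identity]]
  if (is.null(v)) numeric(0) else v
}

## canonical backbone frame used for inversion and helix anchors:
## CA at origin, N on +x, C in the xy-plane. Ideal N-CA 1.458, CA-C 1.525,
## angle N-CA-C 111.2 deg.
.canonical_frame <- function() {
  th <- .deg2rad(111.2)
  rbind(N  = c(1.458, 0, 0),
        CA = c(0, 0, 0),
        C  = 1.525 * c(cos(th), sin(th), 0))
}

#' Build a full-atom residue from a backbone frame and chi angles
#'
#' Places all template atoms (sidechain heavy atoms, carbonyl O, and the
#' polar hydrogen of Ser/Thr/Cys) by NeRF from ideal internal coordinates,
#' starting from the given N/CA/C positions. L-chirality is inherited from
#' the templates.
#'
#' @param identity three-letter amino-acid code
#' @param backbone_frame 3 x 3 matrix with rows N, CA, C (Angstrom)
#' @param chi numeric vector of chi dihedrals (degrees); length must match
#'   the identity's chi count
#' @return data.frame with columns `atom`, `x`, `y`, `z`, `element`
#' @export
build_sidechain_forward <- function(identity, backbone_frame = .canonical_frame(),
                                    chi = template_chi(identity)) {
  if (!identity %in% .std_aa) stop("not a canonical amino acid: ", identity)
  if (length(chi) != n_chi(identity)) {
    stop(sprintf("%s requires %d chi angles, got %d", identity,
                 n_chi(identity), length(chi)))
  }
  bf <- as.matrix(backbone_frame)
  rownames(bf) <- c("N", "CA", "C")
  tmpl <- .aa_templates[[identity]]
  pos <- list(N = bf["N", ], CA = bf["CA", ], C = bf["C", ])
  for (i in seq_len(nrow(tmpl))) {
    row <- tmpl[i, ]
    tor <- row$tval
    if (row$ttype != "fixed") {
      k <- as.integer(sub("chi", "", row$ttype))
      tor <- .wrap180(chi[k] + row$tval)
    }
    pos[[row$atom]] <- .nerf(pos[[row$ref1]], pos[[row$ref2]], pos[[row$ref3]],
                             row$bond, row$angle, tor)
  }
  nm <- names(pos)
  data.frame(atom = nm,
             x = vapply(pos, `[`, 0, 1),
             y = vapply(pos, `[`, 0, 2),
             z = vapply(pos, `[`, 0, 3),
             element = vapply(nm, .guess_element, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Measure chi dihedrals of a built residue
#' @param residue data.frame as returned by [build_sidechain_forward()]
#' @param identity three-letter code
#' @return numeric vector of chi angles in degrees
#' @export
measure_chi <- function(residue, identity) {
  defs <- .chi_defs[[identity]]
  if (is.null(defs)) return(numeric(0))
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  rownames(xyz) <- residue$atom
  vapply(defs, function(q) .dihedral4(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ]), 0)
}

#' Default functional-atom sets
#'
#' The terminal rigid group of each identity that a catalytic array pins in
#' space. At least three non-collinear atoms so the inverse-rotamer backbone
#' placement is unique; for Ser/Thr/Cys the idealized polar hydrogen
#' completes the frame.
#'
#' @param identity three-letter code
#' @return character vector of atom names
#' @export
functional_atoms_default <- function(identity) {
  sets <- list(
    ARG = c("NE", "CZ", "NH1", "NH2"),
    LYS = c("CD", "CE", "NZ"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
    ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"),
    ASN = c("CG", "OD1", "ND2"), GLN = c("CD", "OE1", "NE2"),
    SER = c("CB", "OG", "HG"), THR = c("CB", "OG1", "HG1"),
    CYS = c("CB", "SG", "HG"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CD2", "CE2", "CE3", "NE1", "CZ2", "CZ3", "CH2"),
    MET = c("CG", "SD", "CE"),
    LEU = c("CG", "CD1", "CD2"),
    ILE = c("CB", "CG1", "CG2", "CD1"),
    VAL = c("CB", "CG1", "CG2"),
    PRO = c("CB", "CG", "CD")
  )
  v <- sets[[identity]]
  if (is.null(v)) stop("no functional-atom default for identity: ", identity)
  v
}

#' Invert a rotamer: solve backbone placement from fixed functional atoms
#'
#' Builds the identity's sidechain with the given chi angles in a canonical
#' frame, then finds the rigid transform superposing the built functional
#' atoms onto the fixed input coordinates; the transformed N/CA/C is the
#' unique backbone frame reproducing the functional group. The functional
#' atoms themselves are never moved.
#'
#' @param residue list with `identity` (code) and `functional_atoms` (matrix
#'   with named rows, Angstrom), as in a catalytic array; see
#'   [catalytic_residue()].
#' @param chi chi dihedrals (degrees)
#' @return 3 x 3 matrix, rows N/CA/C
#' @export
invert_rotamer <- function(residue, chi) {
  fa <- residue$functional_atoms
  if (is.null(rownames(fa)) || nrow(fa) < 3) {
    stop("functional_atoms must be a matrix of >= 3 named atoms")
  }
  built <- build_sidechain_forward(residue$identity, chi = chi)
  bx <- as.matrix(built[, c("x", "y", "z")])
  rownames(bx) <- built$atom
  missing <- setdiff(rownames(fa), built$atom)
  if (length(missing)) {
    stop("functional atoms not in template for ", residue$identity, ": ",
         paste(missing, collapse = ", "))
  }
  mob <- bx[rownames(fa), , drop = FALSE]
  cen <- sweep(mob, 2, colMeans(mob))
  if (qr(cen, tol = 1e-7)$rank < 2) stop("degenerate functional-atom frame")
  tr <- superpose(mob, as.matrix(fa))
  frame <- .apply_transform(bx[c("N", "CA", "C"), ], tr$rotation, tr$translation)
  rownames(frame) <- c("N", "CA", "C")
  frame
}

#' Construct a catalytic residue description
#'
#' @param identity three-letter code
#' @param functional_atoms matrix of fixed functional-group coordinates with
#'   atom-name rownames; defaults resolve via [functional_atoms_default()].
#' @param source_label free-text provenance label
#' @return object of class `CatalyticResidue`
#' @export
catalytic_residue <- function(identity, functional_atoms, source_label = "") {
  stopifnot(identity %in% .std_aa)
  fa <- as.matrix(functional_atoms)
  if (nrow(fa) < 3) stop("need >= 3 functional atoms to define a rigid frame")
  structure(list(identity = identity, functional_atoms = fa,
                 chi_definitions = .chi_defs[[identity]],
                 source_label = source_label),
            class = "CatalyticResidue")
}

#' Construct a catalytic array
#'
#' @param residues list of [catalytic_residue()] objects
#' @param ligand optional ligand atom table (`atom`, `x`, `y`, `z`,
#'   `element`, `resname`, `resno`)
#' @param name array name
#' @return object of class `CatalyticArray`
#' @export
catalytic_array <- function(residues, ligand = NULL, name = "array") {
  stopifnot(length(residues) >= 1)
  structure(list(residues = residues, ligand = ligand, name = name),
            class = "CatalyticArray")
}
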
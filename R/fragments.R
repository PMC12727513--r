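#' Helical fragments and fragment placement
#'
#' A helical fragment is a short stretch of ideal backbone (N/CA/C/O per
#' residue) in a canonical frame, carrying the per-residue phi/psi used to
#' build it, the anchor position onto which a catalytic residue is grafted,
#' and an abundance weight (observed frequency of the fragment geometry in
#' structural databases; user-supplied).
#'
#' @name fragments
NULL

## ideal backbone internal-coordinate constants (Angstrom / degrees); the
## N-CA/CA-C geometry matches .canonical_frame() so fragment anchors and the
## inversion frame superpose exactly.
.bb_geo <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5, omega = 180)

## Build an N/CA/C/O backbone chain from phi/psi vectors (length = n residues;
## phi[1] and psi[n] are still used to place C1 and On deterministically).
.build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- .bb_geo
  pos <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- .deg2rad(180 - g$ang_n_ca_c)
  C <- CA + g$ca_c * c(cos(th), sin(th), 0)
  pos[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)) {
    p <- pos[[i]]
    pos[[i]]$O <- .nerf(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o,
                        .wrap180(psi[i] + 180))
    if (i < n) {
      Nn <- .nerf(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi[i])
      CAn <- .nerf(p$CA, p$C, Nn, g$n_ca, g$ang_c_n_ca, g$omega)
      Cn <- .nerf(p$C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi[i + 1])
      pos[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn, O = NULL)
    }
  }
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- pos[[i]]
    data.frame(resno = i, atom = c("N", "CA", "C", "O"),
               x = c(p$N[1], p$CA[1], p$C[1], p$O[1]),
               y = c(p$N[2], p$CA[2], p$C[2], p$O[2]),
               z = c(p$N[3], p$CA[3], p$C[3], p$O[3]),
               element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
  }))
}

## recompute phi/psi of a backbone table (NA at termini)
.backbone_dihedrals <- function(bb) {
  n <- max(bb$resno)
  get <- function(i, a) {
    r <- bb[bb$resno == i & bb$atom == a, ]
    c(r$x, r$y, r$z)
  }
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) phi[i] <- .dihedral4(get(i - 1, "C"), get(i, "N"), get(i, "CA"), get(i, "C"))
    if (i < n) psi[i] <- .dihedral4(get(i, "N"), get(i, "CA"), get(i, "C"), get(i + 1, "N"))
  }
  data.frame(resno = seq_len(n), phi = phi, psi = psi)
}

#' Construct a helical fragment
#'
#' @param length number of residues (>= 3)
#' @param phi,psi backbone dihedrals in degrees (scalar, applied to every
#'   residue); defaults are ideal alpha-helix values.
#' @param anchor_index grafting position (default: fragment center); must be
#'   interior (not first or last residue).
#' @param abundance non-negative weight
#' @param id fragment identifier
#' @return object of class `HelicalFragment`
#' @export
helical_fragment <- function(length = 7, phi = -57, psi = -47,
                             anchor_index = NULL, abundance = 1, id = "helix") {
  stopifnot(length >= 3, abundance >= 0)
  if (is.null(anchor_index)) anchor_index <- (length + 1L) %/% 2L
  if (anchor_index <= 1 || anchor_index >= length) {
    stop("anchor_index must be interior to the fragment")
  }
  bb <- .build_backbone(rep(phi, length), rep(psi, length))
  ca <- as.matrix(bb[bb$atom == "CA", c("x", "y", "z")])
  dca <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
  if (any(abs(dca - 3.8) > 0.5)) stop("consecutive CA-CA distances outside 3.8 +/- 0.5 A")
  structure(list(length = length, backbone = bb,
                 phi_psi = .backbone_dihedrals(bb),
                 anchor_index = anchor_index, abundance = abundance, id = id,
                 phi = phi, psi = psi),
            class = "HelicalFragment")
}

#' Read a fragment set from TSV
#'
#' Schema: columns `id`, `length`, `anchor_index` (empty = center), `phi`,
#' `psi`, `abundance`. Each row describes one ideal fragment geometry.
#'
#' @param path TSV path
#' @return list of [helical_fragment()] objects
#' @export
read_fragment_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ai <- df$anchor_index[i]
    if (is.null(ai) || is.na(ai)) ai <- NULL
    helical_fragment(length = df$length[i], phi = df$phi[i], psi = df$psi[i],
                     anchor_index = ai, abundance = df$abundance[i],
                     id = as.character(df$id[i]))
  })
}

#' Write a fragment set to TSV
#' @param fragments list of HelicalFragment
#' @param path output path
#' @export
write_fragment_set <- function(fragments, path) {
  df <- do.call(rbind, lapply(fragments, function(f) {
    data.frame(id = f$id, length = f$length, anchor_index = f$anchor_index,
               phi = f$phi, psi = f$psi, abundance = f$abundance)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## N/CA/C matrix of the fragment's anchor residue
.anchor_frame_of <- function(fragment) {
  bb <- fragment$backbone
  r <- bb[bb$resno == fragment$anchor_index & bb$atom %in% c("N", "CA", "C"), ]
  m <- as.matrix(r[match(c("N", "CA", "C"), r$atom), c("x", "y", "z")])
  rownames(m) <- c("N", "CA", "C")
  m
}

#' Place a fragment onto an inverted-rotamer backbone frame
#'
#' Rigidly transforms the fragment so its anchor-residue N/CA/C superpose
#' onto `anchor_frame` (from [invert_rotamer()]), then rebuilds the catalytic
#' residue full-atom on the anchor position with the rotamer's chi angles.
#'
#' @param fragment HelicalFragment
#' @param anchor_frame 3 x 3 matrix (rows N, CA, C)
#' @param rotamer `list(chi=, probability=)`
#' @param identity three-letter code of the grafted residue
#' @return object of class `FragmentPlacement`
#' @export
place_fragment <- function(fragment, anchor_frame, rotamer, identity) {
  af <- .anchor_frame_of(fragment)
  tr <- superpose(af, as.matrix(anchor_frame))
  bb <- fragment$backbone
  xyz <- .apply_transform(as.matrix(bb[, c("x", "y", "z")]),
                          tr$rotation, tr$translation)
  bb$x <- xyz[, 1]; bb$y <- xyz[, 2]; bb$z <- xyz[, 3]
  anchor_bb <- bb[bb$resno == fragment$anchor_index & bb$atom %in% c("N", "CA", "C"), ]
  fr <- as.matrix(anchor_bb[match(c("N", "CA", "C"), anchor_bb$atom),
                            c("x", "y", "z")])
  rebuilt <- build_sidechain_forward(identity, fr, rotamer$chi)
  structure(list(fragment = fragment, transform = tr, rotamer = rotamer,
                 identity = identity, backbone = bb, rebuilt_residue = rebuilt),
            class = "FragmentPlacement")
}

## all heavy atoms of a placement (fragment backbone + grafted sidechain,
## skipping the duplicated anchor N/CA/C)
.placement_atoms <- function(p) {
  side <- p$rebuilt_residue[!p$rebuilt_residue$atom %in% c("N", "CA", "C"), ]
  at <- rbind(p$backbone[, c("atom", "x", "y", "z", "element")],
              side[, c("atom", "x", "y", "z", "element")])
  at[.is_heavy(at$element), , drop = FALSE]
}
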
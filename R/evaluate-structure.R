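#' Structural design-evaluation metrics
#'
#' Motif RMSDs with symmetric-sidechain handling, solvent-accessible surface
#' area (Shrake-Rupley), spatial aggregation propensity (SAP), core contact
#' density, the composite active-site positioning metric, ensemble
#' flexibility metrics, and SAXS shape descriptors.
#'
#' @name evaluate-structure
NULL

## Black & Mould (1991) hydrophobicity, normalized so glycine = 0
.hydrophobicity <- c(
  ALA = 0.616, ARG = 0.000, ASN = 0.236, ASP = 0.028, CYS = 0.680,
  GLN = 0.251, GLU = 0.043, GLY = 0.501, HIS = 0.165, ILE = 0.943,
  LEU = 0.943, LYS = 0.283, MET = 0.738, PHE = 1.000, PRO = 0.711,
  SER = 0.359, THR = 0.450, TRP = 0.878, TYR = 0.880, VAL = 0.825
) - 0.501

.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971)

## atom-name swaps that relabel chemically equivalent positions
.symmetric_swaps <- list(
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  ARG = list(c("NH1", "NH2"))
)

.backbone_names <- c("N", "CA", "C", "O")

## resolve mapping rows to atom tables; mapping: data.frame with
## model_chain, model_resno, ref_chain, ref_resno
.mapped_residues <- function(model_atoms, ref_atoms, mapping) {
  lapply(seq_len(nrow(mapping)), function(i) {
    m <- model_atoms[model_atoms$chain == mapping$model_chain[i] &
                       model_atoms$resno == mapping$model_resno[i], , drop = FALSE]
    r <- ref_atoms[ref_atoms$chain == mapping$ref_chain[i] &
                     ref_atoms$resno == mapping$ref_resno[i], , drop = FALSE]
    if (nrow(m) == 0L || nrow(r) == 0L) {
      stop(sprintf("mapping row %d unresolvable (%s:%d -> %s:%d)", i,
                   mapping$model_chain[i], mapping$model_resno[i],
                   mapping$ref_chain[i], mapping$ref_resno[i]))
    }
    list(model = m, ref = r)
  })
}

## matched coordinate pair for given atom names, with optional symmetric
## relabelling of the MODEL residue; returns list(model=, ref=) matrices
.match_atoms <- function(m, r, names_wanted, swap = NULL) {
  mn <- m$atom
  if (!is.null(swap)) {
    for (sw in swap) {
      i1 <- mn == sw[1]; i2 <- mn == sw[2]
      mn[i1] <- sw[2]; mn[i2] <- sw[1]
    }
  }
  common <- intersect(intersect(names_wanted, mn), r$atom)
  if (length(common) == 0L) return(NULL)
  list(model = as.matrix(m[match(common, mn), c("x", "y", "z")]),
       ref = as.matrix(r[match(common, r$atom), c("x", "y", "z")]),
       atoms = common)
}

## all combinations of applying/not applying each swap group
.swap_variants <- function(identity) {
  sw <- .symmetric_swaps[[identity]]
  if (is.null(sw)) return(list(NULL))
  n <- length(sw)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    pick <- sw[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    out <- c(out, list(if (length(pick)) pick else NULL))
  }
  out
}

.sidechain_selection <- function(identity) {
  setdiff(.aa_templates[[identity]]$atom, c("O", "HG", "HG1"))
}

#' Motif RMSD between a model and a reference
#'
#' For `"ca"` and `"backbone"` selections, a global least-squares
#' superposition on the selected atoms precedes the RMSD. For
#' `"sidechain-heavy"` and `"functional-group"`, the superposition uses the
#' mapped residues' backbone N/CA/C and the RMSD is taken over the
#' selection, resolving chemically equivalent atom namings (Tyr/Phe ring
#' flips, Asp/Glu/Arg) by the permutation minimizing the RMSD.
#'
#' @param model [Structure]
#' @param reference [Structure] or MotifAssembly
#' @param mapping data.frame with columns `model_chain`, `model_resno`,
#'   `ref_chain`, `ref_resno` (explicit residue correspondence)
#' @param selection one of `"ca"`, `"backbone"`, `"sidechain-heavy"`,
#'   `"functional-group"`
#' @return RMSD in Angstrom
#' @export
motif_rmsd <- function(model, reference, mapping,
                       selection = c("ca", "backbone", "sidechain-heavy",
                                     "functional-group")) {
  selection <- match.arg(selection)
  if (inherits(reference, "MotifAssembly")) {
    reference <- assembly_to_structure(reference)
  }
  ma <- .model_atoms(model)
  ra <- .model_atoms(reference)
  pairs <- .mapped_residues(ma, ra, mapping)
  if (selection %in% c("ca", "backbone")) {
    want <- if (selection == "ca") "CA" else .backbone_names
    got <- lapply(pairs, function(p) .match_atoms(p$model, p$ref, want))
    got <- Filter(Negate(is.null), got)
    if (length(got) == 0L) stop("no matched atoms for selection ", selection)
    A <- do.call(rbind, lapply(got, `[[`, "model"))
    B <- do.call(rbind, lapply(got, `[[`, "ref"))
    return(rmsd(A, B, presuperpose = TRUE))
  }
  # superpose on mapped backbone N/CA/C
  bb <- lapply(pairs, function(p) .match_atoms(p$model, p$ref,
                                               c("N", "CA", "C")))
  bb <- Filter(Negate(is.null), bb)
  A <- do.call(rbind, lapply(bb, `[[`, "model"))
  B <- do.call(rbind, lapply(bb, `[[`, "ref"))
  tr <- superpose(A, B)
  tot_sq <- 0; tot_n <- 0L
  for (p in pairs) {
    identity <- p$ref$resname[1]
    want <- switch(selection,
      "sidechain-heavy" = setdiff(.sidechain_selection(identity), "CB"),
      "functional-group" = tryCatch(functional_atoms_default(identity),
                                    error = function(e) character(0)))
    want <- c(if (selection == "sidechain-heavy") "CB", want)
    if (length(want) == 0L) next  # e.g. glycine carries no selection atoms
    best <- NULL
    for (swap in .swap_variants(identity)) {
      mm <- .match_atoms(p$model, p$ref, want, swap)
      if (is.null(mm)) next
      moved <- .apply_transform(mm$model, tr$rotation, tr$translation)
      ssq <- sum((moved - mm$ref)^2)
      if (is.null(best) || ssq < best$ssq) best <- list(ssq = ssq, n = nrow(mm$ref))
    }
    if (is.null(best)) next
    tot_sq <- tot_sq + best$ssq
    tot_n <- tot_n + best$n
  }
  if (tot_n == 0L) stop("no atoms matched for selection ", selection)
  sqrt(tot_sq / tot_n)
}

## deterministic unit sphere points (golden spiral)
.sphere_points <- function(n = 960) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param atoms atom table (`x`, `y`, `z`, `element`), heavy atoms used
#' @param probe probe radius (Angstrom, default 1.4)
#' @param n_points sphere sample points per atom (default 960)
#' @param radii van der Waals radii map
#' @return numeric vector of per-atom SASA (Angstrom^2) for the heavy atoms,
#'   in input order
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960,
                 radii = clash_params()$vdw_radii) {
  atoms <- atoms[.is_heavy(atoms$element), , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0L) return(numeric(0))
  r <- .atom_radii(atoms$element, list(vdw_radii = radii)) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  sp <- .sphere_points(n_points)
  d2 <- outer(rowSums(xyz^2), rep(1, n)) + outer(rep(1, n), rowSums(xyz^2)) -
    2 * xyz %*% t(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    pts <- sweep(sp * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & dd > r[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    out[i] <- 4 * pi * r[i]^2 * frac
  }
  out
}

## reference SASA of each sidechain heavy atom in the fully exposed isolated
## residue; cached per identity
.ref_sasa_cache <- new.env(parent = emptyenv())
.ref_sidechain_sasa <- function(identity) {
  if (!is.null(.ref_sasa_cache[[identity]])) return(.ref_sasa_cache[[identity]])
  res <- build_sidechain_forward(identity)
  v <- sasa(res)
  names(v) <- res$atom[.is_heavy(res$element)]
  .ref_sasa_cache[[identity]] <- v
  v
}

#' Spatial aggregation propensity (SAP)
#'
#' For each sidechain heavy atom: relative exposure (atom SASA over the
#' fully-exposed reference SASA of that atom in the isolated residue) times
#' the residue hydrophobicity (Black-Mould, glycine = 0). The per-residue
#' SAP is the sum of these contributions over all sidechain heavy atoms
#' within `radius` of the residue's CA; the total is the sum of positive
#' per-residue values.
#'
#' @param s [Structure]
#' @param radius sphere radius at each CA (Angstrom, default 5)
#' @param model model number
#' @return list with `per_residue` (data.frame `chain`, `resno`, `sap`) and
#'   `total`
#' @export
sap_score <- function(s, radius = 5, model = NULL) {
  a <- .model_atoms(s, model)
  a <- a[a$resname %in% .std_aa & .is_heavy(a$element), , drop = FALSE]
  if (nrow(a) == 0L) stop("no protein heavy atoms present")
  bad <- setdiff(unique(a$resname), names(.hydrophobicity))
  if (length(bad)) stop("no hydrophobicity reference for: ", paste(bad, collapse = ", "))
  atom_sasa <- sasa(a)
  is_side <- !(a$atom %in% .backbone_names) & a$atom != "OXT"
  rel <- numeric(nrow(a))
  phi <- numeric(nrow(a))
  for (i in which(is_side)) {
    ref <- .ref_sidechain_sasa(a$resname[i])
    ref_v <- ref[a$atom[i]]
    if (is.na(ref_v)) stop("no reference SASA for atom ", a$resname[i], " ", a$atom[i])
    rel[i] <- if (ref_v > 0) atom_sasa[i] / ref_v else 0
    phi[i] <- .hydrophobicity[a$resname[i]]
  }
  contrib <- rel * phi
  ca <- a[a$atom == "CA", , drop = FALSE]
  side_xyz <- as.matrix(a[, c("x", "y", "z")])
  per <- vapply(seq_len(nrow(ca)), function(k) {
    d2 <- (side_xyz[, 1] - ca$x[k])^2 + (side_xyz[, 2] - ca$y[k])^2 +
      (side_xyz[, 3] - ca$z[k])^2
    sum(contrib[is_side & d2 <= radius^2])
  }, 0)
  list(per_residue = data.frame(chain = ca$chain, resno = ca$resno, sap = per,
                                stringsAsFactors = FALSE),
       total = sum(per[per > 0]))
}

#' Core contact density
#'
#' Mean over residues of the number of heavy atoms belonging to OTHER
#' residues within `neighbor_cutoff` of the residue's CA. Compact, well
#' packed structures score high; pulling chains apart lowers the value.
#'
#' @param s [Structure]
#' @param neighbor_cutoff Angstrom (default 10)
#' @param core_threshold residues with at least this many neighbors count as
#'   core (reported as `core_fraction` attribute; default 16)
#' @param model model number
#' @return scalar density with attribute `core_fraction`
#' @export
core_contacts <- function(s, neighbor_cutoff = 10, core_threshold = 16,
                          model = NULL) {
  a <- .model_atoms(s, model)
  a <- a[a$resname %in% .std_aa & .is_heavy(a$element), , drop = FALSE]
  ca <- a[a$atom == "CA", , drop = FALSE]
  if (nrow(ca) < 2) stop("need at least 2 residues")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rid <- paste(a$chain, a$resno, a$icode)
  counts <- vapply(seq_len(nrow(ca)), function(k) {
    d2 <- (xyz[, 1] - ca$x[k])^2 + (xyz[, 2] - ca$y[k])^2 + (xyz[, 3] - ca$z[k])^2
    sum(d2 <= neighbor_cutoff^2 & rid != paste(ca$chain[k], ca$resno[k], ca$icode[k]))
  }, 0)
  out <- mean(counts)
  attr(out, "core_fraction") <- mean(counts >= core_threshold)
  out
}

#' Active-site geometry description
#'
#' @param hbond_pairs data.frame with columns `donor` and `acceptor`
#'   (`"chain:resno:atom"` refs) and `ideal` (Angstrom, in (2, 5))
#' @param attack_pair one-row data.frame with `nucleophile`, `electrophile`,
#'   `ideal`
#' @export
active_site_geometry <- function(hbond_pairs, attack_pair) {
  stopifnot(all(hbond_pairs$ideal > 2), all(hbond_pairs$ideal < 5),
            attack_pair$ideal > 2, attack_pair$ideal < 5)
  structure(list(hbond_pairs = hbond_pairs, attack_pair = attack_pair),
            class = "ActiveSiteGeometry")
}

.atom_ref_coords <- function(atoms, ref) {
  p <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(p) != 3) stop("atom ref must be 'chain:resno:atom', got: ", ref)
  row <- atoms[atoms$chain == p[1] & atoms$resno == as.integer(p[2]) &
                 atoms$atom == p[3], , drop = FALSE]
  if (nrow(row) == 0L) stop("unresolvable atom ref: ", ref)
  c(row$x[1], row$y[1], row$z[1])
}

#' Composite active-site positioning metric
#'
#' Sum of absolute deviations of the catalytic H-bond distances (measured in
#' the covalent-intermediate complex) and the nucleophilic attack distance
#' (measured in the substrate complex) from their ideal values. Zero iff all
#' distances are ideal; lower is better-positioned.
#'
#' @param substrate_complex [Structure] of the enzyme-substrate complex
#' @param intermediate_complex [Structure] of the covalent-intermediate
#'   complex
#' @param geometry [active_site_geometry()]
#' @return scalar score
#' @export
composite_site_metric <- function(substrate_complex, intermediate_complex,
                                  geometry) {
  ia <- .model_atoms(intermediate_complex)
  sa <- .model_atoms(substrate_complex)
  hb <- geometry$hbond_pairs
  dev <- 0
  for (i in seq_len(nrow(hb))) {
    d <- .vnorm(.atom_ref_coords(ia, hb$donor[i]) -
                  .atom_ref_coords(ia, hb$acceptor[i]))
    dev <- dev + abs(d - hb$ideal[i])
  }
  ap <- geometry$attack_pair
  d <- .vnorm(.atom_ref_coords(sa, ap$nucleophile[1]) -
                .atom_ref_coords(sa, ap$electrophile[1]))
  dev + abs(d - ap$ideal[1])
}

#' Ensemble flexibility metrics
#'
#' Per frame, the whole protein is superposed on the first frame's CA
#' atoms. Reported per catalytic residue: RMSF over sidechain heavy atoms
#' about their time-mean positions; per H-bond pair: the mean absolute
#' deviation of the frame distance from the reference distance; and the
#' mean functional-group displacement from the reference after superposing
#' each frame's catalytic backbone N/CA/C onto the reference backbone.
#'
#' @param ensemble multi-model [Structure] (>= 2 models)
#' @param catalytic_selection data.frame with `chain`, `resno`
#' @param reference list per catalytic residue:
#'   `list(identity=, backbone= (3x3 N/CA/C), functional_atoms= (named matrix))`;
#'   see [assembly_reference()]
#' @param hbond_pairs data.frame with `ref_a`, `ref_b` (`"chain:resno:atom"`)
#'   and `ref_distance` (Angstrom)
#' @return list: `rmsf_per_residue` (data.frame), `hb_distance_deviation`
#'   (data.frame), `fg_displacement` (scalar)
#' @export
ensemble_metrics <- function(ensemble, catalytic_selection, reference = NULL,
                             hbond_pairs = NULL) {
  models <- sort(unique(ensemble$atoms$model))
  if (length(models) < 2) stop("ensemble needs at least 2 models")
  frames <- lapply(models, function(m) .model_atoms(ensemble, m))
  key0 <- paste(frames[[1]]$chain, frames[[1]]$resno, frames[[1]]$atom)
  ca0 <- frames[[1]]$atom == "CA" & frames[[1]]$resname %in% .std_aa
  ref_ca <- as.matrix(frames[[1]][ca0, c("x", "y", "z")])
  aligned <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    key <- paste(f$chain, f$resno, f$atom)
    if (!identical(sort(key), sort(key0))) {
      bad <- setdiff(key0, key)
      stop(sprintf("atom missing in frame %d: %s", i, bad[1]))
    }
    f <- f[match(key0, key), , drop = FALSE]
    tr <- superpose(as.matrix(f[ca0, c("x", "y", "z")]), ref_ca)
    xyz <- .apply_transform(as.matrix(f[, c("x", "y", "z")]),
                            tr$rotation, tr$translation)
    f$x <- xyz[, 1]; f$y <- xyz[, 2]; f$z <- xyz[, 3]
    f
  })
  f1 <- aligned[[1]]
  # RMSF over sidechain heavy atoms of each catalytic residue
  rmsf <- vapply(seq_len(nrow(catalytic_selection)), function(k) {
    sel <- f1$chain == catalytic_selection$chain[k] &
      f1$resno == catalytic_selection$resno[k] &
      .is_heavy(f1$element) & !(f1$atom %in% .backbone_names)
    idx <- which(sel)
    if (length(idx) == 0L) {
      stop("no sidechain heavy atoms for catalytic residue ",
           catalytic_selection$chain[k], ":", catalytic_selection$resno[k])
    }
    stack <- vapply(aligned, function(f) as.matrix(f[idx, c("x", "y", "z")]),
                    matrix(0, length(idx), 3))
    meanpos <- apply(stack, c(1, 2), mean)
    sqrt(mean(apply(stack, 3, function(m) rowSums((m - meanpos)^2))))
  }, 0)
  rmsf_df <- data.frame(chain = catalytic_selection$chain,
                        resno = catalytic_selection$resno, rmsf = rmsf,
                        stringsAsFactors = FALSE)
  hb_df <- NULL
  if (!is.null(hbond_pairs)) {
    hb_df <- do.call(rbind, lapply(seq_len(nrow(hbond_pairs)), function(i) {
      devs <- vapply(aligned, function(f) {
        d <- .vnorm(.atom_ref_coords(f, hbond_pairs$ref_a[i]) -
                      .atom_ref_coords(f, hbond_pairs$ref_b[i]))
        abs(d - hbond_pairs$ref_distance[i])
      }, 0)
      data.frame(ref_a = hbond_pairs$ref_a[i], ref_b = hbond_pairs$ref_b[i],
                 mean_abs_deviation = mean(devs), stringsAsFactors = FALSE)
    }))
  }
  fg <- NA_real_
  if (!is.null(reference)) {
    ref_bb <- do.call(rbind, lapply(reference, function(r) r$backbone))
    ref_fa <- do.call(rbind, lapply(reference, function(r) r$functional_atoms))
    per_frame <- vapply(aligned, function(f) {
      bb <- do.call(rbind, lapply(seq_along(reference), function(k) {
        sel <- f[f$chain == catalytic_selection$chain[k] &
                   f$resno == catalytic_selection$resno[k] &
                   f$atom %in% c("N", "CA", "C"), , drop = FALSE]
        as.matrix(sel[match(c("N", "CA", "C"), sel$atom), c("x", "y", "z")])
      }))
      tr <- superpose(bb, ref_bb)
      fa <- do.call(rbind, lapply(seq_along(reference), function(k) {
        sel <- f[f$chain == catalytic_selection$chain[k] &
                   f$resno == catalytic_selection$resno[k], , drop = FALSE]
        nm <- rownames(reference[[k]]$functional_atoms)
        as.matrix(sel[match(nm, sel$atom), c("x", "y", "z")])
      }))
      moved <- .apply_transform(fa, tr$rotation, tr$translation)
      mean(sqrt(rowSums((moved - ref_fa)^2)))
    }, 0)
    fg <- mean(per_frame)
  }
  list(rmsf_per_residue = rmsf_df, hb_distance_deviation = hb_df,
       fg_displacement = fg)
}

#' Reference geometry for ensemble metrics from a motif assembly
#' @param assembly MotifAssembly
#' @return list usable as `reference` in [ensemble_metrics()]
#' @export
assembly_reference <- function(assembly) {
  lapply(assembly$placements, function(p) {
    bb <- p$backbone[p$backbone$resno == p$fragment$anchor_index &
                       p$backbone$atom %in% c("N", "CA", "C"), ]
    m <- as.matrix(bb[match(c("N", "CA", "C"), bb$atom), c("x", "y", "z")])
    rownames(m) <- c("N", "CA", "C")
    fa_names <- functional_atoms_default(p$identity)
    rr <- p$rebuilt_residue
    fa <- as.matrix(rr[match(fa_names, rr$atom), c("x", "y", "z")])
    rownames(fa) <- fa_names
    list(identity = p$identity, backbone = m, functional_atoms = fa)
  })
}

#' Radius of gyration
#'
#' Mass-weighted over heavy atoms: `Rg = sqrt(sum(m_i |r_i - rbar|^2) / sum(m_i))`.
#'
#' @param s [Structure] or atom table
#' @param model model number
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(s, model = NULL) {
  a <- if (inherits(s, "Structure")) .model_atoms(s, model) else s
  a <- a[.is_heavy(a$element), , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy atoms present")
  m <- .atomic_mass[a$element]
  if (anyNA(m)) stop("no atomic mass for element(s): ",
                     paste(unique(a$element[is.na(m)]), collapse = ", "))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  cen <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, cen)^2)) / sum(m))
}

#' Dimensionless Kratky transform of a SAXS curve
#'
#' Maps (q, I) to (qRg, (qRg)^2 I/I0). For a globular (Guinier-like)
#' scatterer the transformed curve peaks near qRg = sqrt(3) at 3/e.
#'
#' @param q scattering vector (1/Angstrom)
#' @param intensity measured intensity
#' @param rg radius of gyration (Angstrom)
#' @param i0 forward-scattering intensity I(0) (> 0)
#' @return data.frame with `qrg` and `kratky`
#' @export
kratky_dimensionless <- function(q, intensity, rg, i0) {
  if (length(q) == 0L) stop("empty curve")
  stopifnot(length(q) == length(intensity), i0 > 0, rg > 0)
  data.frame(qrg = q * rg, kratky = (q * rg)^2 * intensity / i0)
}
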
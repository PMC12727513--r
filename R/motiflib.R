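#' Motif library construction
#'
#' End-to-end construction of artificial motif libraries from a catalytic
#' array: per-residue inverse-rotamer backbone frames, helical fragment
#' placement, exhaustive clash-free combinatorial assembly, probability and
#' abundance ranking, and multi-model PDB + JSON serialization.
#'
#' @name motiflib
NULL

#' Steric clash parameters
#'
#' A pair of atoms clashes when `d < gamma * (r_i + r_j)` with van der Waals
#' radii `r`. The default `gamma = 0.75` is the common soft-overlap
#' convention.
#'
#' @param vdw_radii named element -> radius (Angstrom) map
#' @param tolerance_factor gamma in (0, 1]
#' @param exempt_pairs optional data.frame of exempt atom-name pairs
#'   (columns `a`, `b`)
#' @export
clash_params <- function(vdw_radii = c(C = 1.7, N = 1.55, O = 1.52, S = 1.8,
                                       P = 1.8, H = 1.2),
                         tolerance_factor = 0.75, exempt_pairs = NULL) {
  stopifnot(tolerance_factor > 0, tolerance_factor <= 1, all(vdw_radii > 0))
  structure(list(vdw_radii = vdw_radii, tolerance_factor = tolerance_factor,
                 exempt_pairs = exempt_pairs), class = "ClashParams")
}

.atom_radii <- function(elements, params) {
  r <- params$vdw_radii[elements]
  if (any(is.na(r))) {
    stop("no van der Waals radius configured for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  as.numeric(r)
}

#' Count steric clashes between two atom sets
#'
#' @param a,b atom tables (`atom`, `x`, `y`, `z`, `element`) or
#'   `FragmentPlacement` objects (heavy atoms are extracted).
#' @param params [clash_params()]
#' @return list with `count` and `pairs` (data.frame `atom_a`, `atom_b`,
#'   `distance`, `threshold`)
#' @export
clash_check <- function(a, b, params = clash_params()) {
  if (inherits(a, "FragmentPlacement")) a <- .placement_atoms(a)
  if (inherits(b, "FragmentPlacement")) b <- .placement_atoms(b)
  a <- a[.is_heavy(a$element), , drop = FALSE]
  b <- b[.is_heavy(b$element), , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(count = 0L, pairs = data.frame()))
  }
  ra <- .atom_radii(a$element, params)
  rb <- .atom_radii(b$element, params)
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  thr <- params$tolerance_factor * outer(ra, rb, "+")
  hit <- which(sqrt(d2) < thr, arr.ind = TRUE)
  if (nrow(hit) && !is.null(params$exempt_pairs)) {
    keynames <- paste(pmin(a$atom[hit[, 1]], b$atom[hit[, 2]]),
                      pmax(a$atom[hit[, 1]], b$atom[hit[, 2]]))
    ex <- paste(pmin(params$exempt_pairs$a, params$exempt_pairs$b),
                pmax(params$exempt_pairs$a, params$exempt_pairs$b))
    hit <- hit[!keynames %in% ex, , drop = FALSE]
  }
  pairs <- data.frame(atom_a = a$atom[hit[, 1]], atom_b = b$atom[hit[, 2]],
                      distance = sqrt(d2[hit]),
                      threshold = thr[hit], stringsAsFactors = FALSE)
  list(count = nrow(pairs), pairs = pairs)
}

## smallest distance/threshold ratio between two atom sets (diagnostics)
.tightest_pair <- function(a, b, params) {
  ra <- .atom_radii(a$element, params); rb <- .atom_radii(b$element, params)
  pa <- as.matrix(a[, c("x", "y", "z")]); pb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  ratio <- sqrt(d2) / (params$tolerance_factor * outer(ra, rb, "+"))
  i <- which.min(ratio)
  rc <- arrayInd(i, dim(ratio))
  list(atom_a = a$atom[rc[1]], atom_b = b$atom[rc[2]],
       distance = sqrt(d2[i]), ratio = ratio[i])
}

#' Score a motif assembly
#'
#' `score = w_rot * mean(log p_i) + w_abund * mean(log(abundance_i + 1))`
#' over the per-residue placements; higher is better. Rotamer probabilities
#' reward common sidechain conformations, abundance rewards frequently
#' observed fragment geometries.
#'
#' @param assembly MotifAssembly (or bare list of placements)
#' @param weights numeric `c(w_rot, w_abund)`
#' @return scalar score
#' @export
score_assembly <- function(assembly, weights = c(1, 1)) {
  pl <- if (inherits(assembly, "MotifAssembly")) assembly$placements else assembly
  p <- vapply(pl, function(x) x$rotamer$probability, 0)
  ab <- vapply(pl, function(x) x$fragment$abundance, 0)
  stopifnot(all(p > 0), all(ab >= 0))
  weights[1] * mean(log(p)) + weights[2] * mean(log(ab + 1))
}

.new_assembly <- function(placements, ligand = NULL, score = NA_real_) {
  structure(list(placements = placements, ligand = ligand, score = score,
                 clash_free = TRUE), class = "MotifAssembly")
}

#' Enumerate clash-free fragment combinations
#'
#' Exact depth-first enumeration over one placement per catalytic residue,
#' with incremental pairwise pruning; every retained combination is also
#' clash-checked against the ligand. The result set is identical to
#' brute-force Cartesian-product filtering.
#'
#' @param candidates list (one element per catalytic residue) of lists of
#'   FragmentPlacement
#' @param ligand optional ligand atom table
#' @param params [clash_params()]
#' @param max_out maximum number of assemblies returned (top-scoring)
#' @param weights score weights, see [score_assembly()]
#' @param max_combinations guard on the exhaustive search size
#' @return list of MotifAssembly, scores non-increasing; if empty, the
#'   attribute `"diagnostic"` describes the tightest clash encountered.
#' @export
enumerate_assemblies <- function(candidates, ligand = NULL,
                                 params = clash_params(), max_out = 100L,
                                 weights = c(1, 1), max_combinations = 1e6) {
  if (length(candidates) == 0L) {
    out <- list(); attr(out, "diagnostic") <- "no candidate lists"; return(out)
  }
  sizes <- vapply(candidates, length, 0L)
  if (any(sizes == 0L)) {
    out <- list()
    attr(out, "diagnostic") <- paste0("empty candidate list for residue(s): ",
                                      paste(which(sizes == 0L), collapse = ", "))
    return(out)
  }
  if (prod(sizes) > max_combinations) {
    stop(sprintf("combination count %g exceeds max_combinations %g",
                 prod(sizes), max_combinations))
  }
  n <- length(candidates)
  atoms <- lapply(candidates, function(cl) lapply(cl, .placement_atoms))
  lig_ok <- lapply(seq_len(n), function(i) {
    vapply(atoms[[i]], function(a) {
      is.null(ligand) || clash_check(a, ligand, params)$count == 0L
    }, TRUE)
  })
  tight <- NULL
  note_tight <- function(a, b) {
    tp <- .tightest_pair(a, b, params)
    if (is.null(tight) || tp$ratio < tight$ratio) tight <<- tp
  }
  # pairwise compatibility tables between residue levels
  compat <- vector("list", n)
  for (i in seq_len(n)) {
    compat[[i]] <- vector("list", i - 1L)
    for (j in seq_len(i - 1L)) {
      m <- matrix(FALSE, length(candidates[[i]]), length(candidates[[j]]))
      for (ii in seq_along(candidates[[i]])) {
        for (jj in seq_along(candidates[[j]])) {
          cc <- clash_check(atoms[[i]][[ii]], atoms[[j]][[jj]], params)
          m[ii, jj] <- cc$count == 0L
          if (cc$count > 0L) note_tight(atoms[[i]][[ii]], atoms[[j]][[jj]])
        }
      }
      compat[[i]][[j]] <- m
    }
  }
  results <- list()
  pick <- integer(n)
  dfs <- function(level) {
    if (level > n) {
      pl <- lapply(seq_len(n), function(i) candidates[[i]][[pick[i]]])
      results[[length(results) + 1L]] <<- pl
      return(invisible())
    }
    for (k in seq_along(candidates[[level]])) {
      if (!lig_ok[[level]][k]) {
        if (!is.null(ligand)) note_tight(atoms[[level]][[k]], ligand)
        next
      }
      ok <- TRUE
      for (j in seq_len(level - 1L)) {
        if (!compat[[level]][[j]][k, pick[j]]) { ok <- FALSE; break }
      }
      if (!ok) next
      pick[level] <<- k
      dfs(level + 1L)
    }
  }
  dfs(1L)
  if (length(results) == 0L) {
    out <- list()
    attr(out, "diagnostic") <- if (is.null(tight)) {
      "no clash-free combination"
    } else {
      sprintf("no clash-free combination; tightest clash %s-%s at %.2f A (ratio %.2f)",
              tight$atom_a, tight$atom_b, tight$distance, tight$ratio)
    }
    return(out)
  }
  asm <- lapply(results, function(pl) {
    a <- .new_assembly(pl, ligand = ligand)
    a$score <- score_assembly(a, weights)
    a
  })
  ord <- order(-vapply(asm, function(a) a$score, 0))  # stable: ties keep index order
  asm <- asm[ord]
  asm[seq_len(min(max_out, length(asm)))]
}

#' Build an artificial motif library from a catalytic array
#'
#' Full pipeline: for each catalytic residue, rotamers compatible with each
#' fragment's anchor phi/psi are inverted to backbone frames and fragments
#' are placed on them; all clash-free combinations are enumerated, scored
#' by rotamer probability and fragment abundance, ranked, and stored with a
#' provenance snapshot. Deterministic for identical config.
#'
#' @param array [catalytic_array()]
#' @param lib [rotamer_library()]
#' @param fragments list of [helical_fragment()]
#' @param config list; recognized fields `min_prob` (default 0.05),
#'   `weights` (c(w_rot, w_abund), default c(1, 1)), `max_out` (default 100),
#'   `clash` ([clash_params()]), `max_combinations` (default 1e6),
#'   `seed` (recorded in provenance; the pipeline itself is deterministic)
#' @return object of class `MotifLibrary`; empty library carries a
#'   machine-readable `$diagnostic`
#' @export
build_motif_library <- function(array, lib, fragments, config = list()) {
  cfg <- utils::modifyList(list(min_prob = 0.05, weights = c(1, 1),
                                max_out = 100L, clash = clash_params(),
                                max_combinations = 1e6, seed = 1L), config)
  candidates <- lapply(array$residues, function(res) {
    out <- list()
    for (f in fragments) {
      pp <- f$phi_psi[f$phi_psi$resno == f$anchor_index, ]
      rots <- compatible_rotamers(res$identity, pp$phi, pp$psi, lib,
                                  min_prob = cfg$min_prob)
      for (rot in rots) {
        frame <- invert_rotamer(res, rot$chi)
        out[[length(out) + 1L]] <- place_fragment(f, frame, rot, res$identity)
      }
    }
    out
  })
  asm <- enumerate_assemblies(candidates, ligand = array$ligand,
                              params = cfg$clash, max_out = cfg$max_out,
                              weights = cfg$weights,
                              max_combinations = cfg$max_combinations)
  structure(list(assemblies = asm,
                 diagnostic = attr(asm, "diagnostic"),
                 array_name = array$name,
                 provenance = list(config = cfg[setdiff(names(cfg), "clash")],
                                   gamma = cfg$clash$tolerance_factor,
                                   seed = cfg$seed,
                                   n_candidates = vapply(candidates, length, 0L))),
            class = "MotifLibrary")
}

#' @export
print.MotifLibrary <- function(x, ...) {
  cat(sprintf("<MotifLibrary> %d assemblies (array '%s')\n",
              length(x$assemblies), x$array_name))
  if (!is.null(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  invisible(x)
}

#' Convert a motif assembly to a Structure
#'
#' One chain per fragment (A, B, ...), grafted catalytic residue full-atom
#' on the anchor position, optional ligand on chain `Z` as HETATM.
#'
#' @param assembly MotifAssembly
#' @param model model number
#' @return [Structure]
#' @export
assembly_to_structure <- function(assembly, model = 1L) {
  rows <- list()
  for (i in seq_along(assembly$placements)) {
    p <- assembly$placements[[i]]
    ch <- LETTERS[i]
    bb <- p$backbone
    side <- p$rebuilt_residue[!p$rebuilt_residue$atom %in% c("N", "CA", "C"), ]
    side$resno <- p$fragment$anchor_index
    resnames <- rep("GLY", p$fragment$length)
    resnames[p$fragment$anchor_index] <- p$identity
    at <- rbind(
      data.frame(atom = bb$atom, resno = bb$resno, x = bb$x, y = bb$y,
                 z = bb$z, element = bb$element, stringsAsFactors = FALSE),
      data.frame(atom = side$atom, resno = side$resno, x = side$x, y = side$y,
                 z = side$z, element = side$element, stringsAsFactors = FALSE))
    at <- at[order(at$resno), ]
    rows[[i]] <- data.frame(
      model = model, record = "ATOM", serial = NA_integer_, atom = at$atom,
      altloc = " ", resname = resnames[at$resno], chain = ch,
      resno = at$resno, icode = " ", x = at$x, y = at$y, z = at$z,
      occ = 1, b = 0, element = at$element, stringsAsFactors = FALSE)
  }
  if (!is.null(assembly$ligand)) {
    lg <- assembly$ligand
    rows[[length(rows) + 1L]] <- data.frame(
      model = model, record = "HETATM", serial = NA_integer_, atom = lg$atom,
      altloc = " ",
      resname = if ("resname" %in% names(lg)) lg$resname else "LIG",
      chain = "Z",
      resno = if ("resno" %in% names(lg)) lg$resno else 1L,
      icode = " ", x = lg$x, y = lg$y, z = lg$z, occ = 1, b = 0,
      element = lg$element, stringsAsFactors = FALSE)
  }
  .new_structure(do.call(rbind, rows))
}

#' Serialize a motif library to multi-model PDB + JSON sidecar
#'
#' One MODEL per assembly; the sidecar records scores, rotamer
#' probabilities, fragment abundances and the provenance snapshot.
#'
#' @param library MotifLibrary
#' @param pdb_path output PDB path
#' @param json_path output JSON path (default: pdb path with .json)
#' @export
write_motif_library <- function(library, pdb_path,
                                json_path = sub("\\.pdb$", ".json", pdb_path)) {
  if (length(library$assemblies) == 0L) stop("empty motif library")
  structs <- lapply(seq_along(library$assemblies), function(i) {
    assembly_to_structure(library$assemblies[[i]], model = i)$atoms
  })
  s <- .new_structure(do.call(rbind, structs))
  write_structure_file(s, pdb_path)
  meta <- list(
    array = library$array_name,
    provenance = library$provenance,
    assemblies = lapply(library$assemblies, function(a) {
      list(score = a$score,
           rotamer_probability = vapply(a$placements,
                                        function(p) p$rotamer$probability, 0),
           abundance = vapply(a$placements,
                              function(p) p$fragment$abundance, 0),
           identities = vapply(a$placements, function(p) p$identity, ""))
    }))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(pdb_path)
}

#' Read back a serialized motif library
#' @param pdb_path PDB written by [write_motif_library()]
#' @param json_path JSON sidecar
#' @return list with `structure` (multi-model [Structure]) and `meta`
#' @export
read_motif_library <- function(pdb_path,
                               json_path = sub("\\.pdb$", ".json", pdb_path)) {
  list(structure = read_structure(pdb_path),
       meta = jsonlite::read_json(json_path, simplifyVector = FALSE))
}
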
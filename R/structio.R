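#' Structure container and PDB-format coordinate I/O
#'
#' A `Structure` holds atomic coordinates as a single atom table (one row per
#' atom) plus minimal header metadata. Multi-MODEL files map to the `model`
#' column, so conformational ensembles and motif libraries are first-class.
#'
#' Columns of `$atoms`: `model`, `record` (ATOM/HETATM), `serial`, `atom`
#' (atom name), `altloc`, `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`,
#' `occ`, `b`, `element`.
#'
#' @name Structure
NULL

.std_aa <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

.new_structure <- function(atoms, header = character()) {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, header = header), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<Structure> %d model(s), %d chain(s), %d residue(s), %d atoms\n",
              length(unique(a$model)), length(unique(a$chain)),
              nrow(unique(a[a$model == a$model[1],
                            c("chain", "resno", "icode")])), nrow(a)))
  invisible(x)
}

#' Number of models in a Structure
#' @param s Structure
#' @export
n_models <- function(s) length(unique(s$atoms$model))

.guess_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA2")) return(substr(two, 1, 2))
  substr(nm, 1, 1)
}

#' Parse a PDB-format coordinate file
#'
#' Maps ATOM/HETATM records of a PDB text into a [Structure]. Multi-MODEL
#' files yield one model each; alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered), with the discarded
#' conformers retained in `attr(s, "altloc_dropped")` for reporting.
#'
#' @param text character scalar (file content) or character vector of lines.
#' @param dialect only `"pdb"` is supported.
#' @return a [Structure]
#' @export
parse_structure <- function(text, dialect = "pdb") {
  if (!identical(dialect, "pdb")) stop("unknown dialect: ", dialect)
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (length(text) == 0L || all(!nzchar(text))) stop("empty coordinate text")
  rec <- substr(text, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_no <- integer(length(text))
  cur <- 1L
  seen_model <- FALSE
  for (i in seq_along(text)) {
    if (startsWith(text[i], "MODEL")) {
      v <- suppressWarnings(as.integer(substr(text[i], 11, 14)))
      cur <- if (is.na(v)) cur + 1L else v
      seen_model <- TRUE
    }
    model_no[i] <- cur
  }
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("no ATOM/HETATM records found")
  ln <- text[idx]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, idx[bad[1]], text[idx[bad[1]]]))
    }
    v
  }
  occ_raw <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ_raw[is.na(occ_raw)] <- 1
  b_raw <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
  b_raw[is.na(b_raw)] <- 0
  elem <- trimws(substr(ln, 77, 78))
  atom_name <- trimws(substr(ln, 13, 16))
  need <- !nzchar(elem)
  if (any(need)) elem[need] <- vapply(atom_name[need], .guess_element, "")
  atoms <- data.frame(
    model = model_no[idx],
    record = trimws(substr(ln, 1, 6)),
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    atom = atom_name,
    altloc = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resno = as.integer(num(23, 26, "residue number")),
    icode = substr(ln, 27, 27),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = occ_raw, b = b_raw, element = toupper(elem),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in input")
  }
  dropped <- atoms[0, ]
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$model, atoms$chain, atoms$resno, atoms$icode, atoms$atom)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ii) {
      ii[which.max(atoms$occ[ii])]
    }), use.names = FALSE)
    keep <- sort(keep)
    dropped <- atoms[setdiff(seq_len(nrow(atoms)), keep), , drop = FALSE]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  hdr <- trimws(text[startsWith(text, "HEADER") | startsWith(text, "TITLE") |
                     startsWith(text, "REMARK")])
  s <- .new_structure(atoms, header = hdr)
  attr(s, "altloc_dropped") <- dropped
  s
}

#' Read a PDB file from disk
#' @param path file path
#' @inheritParams parse_structure
#' @export
read_structure <- function(path, dialect = "pdb") {
  parse_structure(readLines(path, warn = FALSE), dialect = dialect)
}

.fmt_atom_name <- function(name, element) {
  # PDB rule: element right-justified in cols 13-14 for 1-letter elements
  if (nchar(name) >= 4) return(substr(sprintf("%-4s", name), 1, 4))
  if (nchar(element) == 1) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Serialize a Structure to PDB-format text
#'
#' Round-trip guarantee: `parse_structure(write_structure(s))` preserves
#' coordinates to the fixed-width precision (1e-3 Angstrom) and atom order
#' exactly. Multi-model structures emit MODEL/ENDMDL blocks.
#'
#' @param s Structure
#' @param dialect only `"pdb"`
#' @return character scalar (PDB text)
#' @export
write_structure <- function(s, dialect = "pdb") {
  if (!identical(dialect, "pdb")) stop("unknown dialect: ", dialect)
  a <- s$atoms
  if (any(abs(c(a$x, a$y, a$z)) >= 10000)) {
    stop("coordinate overflow: |coordinate| exceeds PDB fixed-width field")
  }
  models <- unique(a$model)
  multi <- length(models) > 1L
  out <- character(0)
  for (m in models) {
    am <- a[a$model == m, , drop = FALSE]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    lines <- vapply(seq_len(nrow(am)), function(i) {
      r <- am[i, ]
      sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              r$record, (i - 1L) %% 99999L + 1L,
              .fmt_atom_name(r$atom, r$element), r$altloc, r$resname,
              r$chain, r$resno, r$icode, r$x, r$y, r$z, r$occ, r$b,
              sprintf("%2s", r$element))
    }, "")
    out <- c(out, lines)
    if (multi) out <- c(out, "ENDMDL")
  }
  paste0(paste(out, collapse = "\n"), "\nEND\n")
}

#' Write a Structure to a PDB file
#' @param s Structure
#' @param path output path
#' @export
write_structure_file <- function(s, path) {
  writeLines(write_structure(s), path)
  invisible(path)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (no reflection) and translation minimizing the
#' RMSD between two ordered, corresponding point sets.
#'
#' @param mobile,target N x 3 coordinate matrices, N >= 3, rows in
#'   correspondence.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` after applying the transform to `mobile`.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target))) stop("dimension mismatch between point sets")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cen <- sweep(mobile, 2, colMeans(mobile))
  if (qr(cen)$rank < 2) stop("degenerate (collinear) point cloud")
  res <- .kabsch(mobile, target)
  if (abs(det(res$rotation) - 1) > 1e-9) stop("superposition failed: improper rotation")
  res
}

#' Root-mean-square deviation between corresponding coordinate sets
#'
#' @param a,b N x 3 coordinate matrices with rows in correspondence.
#' @param presuperpose if `TRUE`, compute after optimal rigid superposition.
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b, presuperpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L) stop("empty selection")
  if (!all(dim(a) == dim(b))) stop("dimension mismatch between point sets")
  if (presuperpose) {
    return(superpose(a, b)$rmsd)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Count points of one set having a neighbor in another
#'
#' Counts points of `points_a` with at least one point of `points_b` within
#' `cutoff` (Euclidean, inclusive boundary `d <= cutoff`).
#'
#' @param points_a M x 3 matrix
#' @param points_b K x 3 matrix
#' @param cutoff distance cutoff in Angstrom, > 0
#' @return integer count
#' @export
neighbor_count <- function(points_a, points_b, cutoff) {
  stopifnot(cutoff > 0)
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  if (nrow(points_a) == 0L || nrow(points_b) == 0L) return(0L)
  d2 <- outer(rowSums(points_a^2), rep(1, nrow(points_b))) +
        outer(rep(1, nrow(points_a)), rowSums(points_b^2)) -
        2 * points_a %*% t(points_b)
  sum(apply(d2, 1, min) <= cutoff^2 + 1e-12)
}

## ---- selection helpers -----------------------------------------------------

.is_heavy <- function(element) !(element %in% c("H", "D"))

#' Extract coordinates from a Structure atom table
#' @param s Structure
#' @param model model number (default: first)
#' @param chain optional chain filter
#' @param atoms optional atom-name filter (e.g. "CA")
#' @param heavy_only drop hydrogens
#' @return N x 3 matrix
#' @export
coords <- function(s, model = NULL, chain = NULL, atoms = NULL, heavy_only = FALSE) {
  a <- s$atoms
  if (is.null(model)) model <- a$model[1]
  a <- a[a$model == model, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!is.null(atoms)) a <- a[a$atom %in% atoms, , drop = FALSE]
  if (heavy_only) a <- a[.is_heavy(a$element), , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

## atom subtable for one model
.model_atoms <- function(s, model = NULL) {
  a <- s$atoms
  if (is.null(model)) model <- a$model[1]
  a[a$model == model, , drop = FALSE]
}

## parse "chain:resno" ligand/residue specs
.parse_resspec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("residue spec must be 'chain:resno', got: ", spec)
  list(chain = parts[1], resno = as.integer(parts[2]))
}
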
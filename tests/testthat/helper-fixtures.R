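# Shared fixtures, built once per test run.

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    val <- switch(name,
      array = make_toy_catalytic_array("ra_tetrad"),
      triad = make_toy_catalytic_array("mbh_triad"),
      rotlib = make_toy_rotamer_library(seed = 1),
      fragments = list(make_ideal_helix(7)),
      library = build_motif_library(fx("array"), fx("rotlib"), fx("fragments"),
                                    config = list(min_prob = 0, max_out = 20)),
      assembly = fx("library")$assemblies[[1]],
      complex = assembly_to_structure(fx("assembly")),
      stop("unknown fixture: ", name))
    cache[[name]] <- val
    val
  }
})

# fixed-width PDB ATOM line builder for parser tests
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(name, 1, 1),
                     altloc = " ", record = "ATOM") {
  nm <- if (nchar(name) >= 4) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, x, y, z, occ, b,
          sprintf("%2s", element))
}

# brute-force rigid superposition oracle: nested grid over Euler angles
grid_superpose_rmsd <- function(mobile, target) {
  rot_zyz <- function(a, b, c) {
    rz <- function(t) {
      t <- t * pi / 180
      matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    }
    ry <- function(t) {
      t <- t * pi / 180
      matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    }
    rz(a) %*% ry(b) %*% rz(c)
  }
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  eval_rmsd <- function(a, b, c) {
    sqrt(mean(rowSums((X %*% t(rot_zyz(a, b, c)) - Y)^2)))
  }
  best <- c(0, 0, 0); best_v <- eval_rmsd(0, 0, 0)
  step <- 15
  grid <- expand.grid(a = seq(0, 345, step), b = seq(0, 180, step),
                      c = seq(0, 345, step))
  for (i in seq_len(nrow(grid))) {
    v <- eval_rmsd(grid$a[i], grid$b[i], grid$c[i])
    if (v < best_v) { best_v <- v; best <- unlist(grid[i, ]) }
  }
  # local refinement around the best cell
  for (step in c(3, 0.5, 0.05)) {
    repeat {
      improved <- FALSE
      for (d in list(c(step, 0, 0), c(-step, 0, 0), c(0, step, 0),
                     c(0, -step, 0), c(0, 0, step), c(0, 0, -step))) {
        cand <- best + d
        v <- eval_rmsd(cand[1], cand[2], cand[3])
        if (v < best_v - 1e-12) { best_v <- v; best <- cand; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  best_v
}
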
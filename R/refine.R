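#' Iterative refinement skeleton with pluggable stage adapters
#'
#' The backbone refinement loop alternates external stages -- sequence
#' design, constrained relax, structure prediction -- that are NOT bundled
#' here. Each stage is an adapter: a pure callable
#' `(design, options) -> list(design=, metrics=)` with a declared
#' determinism flag. Shipped stubs (identity and seeded coordinate jitter)
#' make the loop, metric bookkeeping and top-k selection fully testable
#' offline; real tools plug in behind the same contract.
#'
#' @name refine
NULL

#' Build a design record
#' @param pose [Structure]
#' @param sequence amino-acid string (may be empty before sequence design)
#' @param id design identifier (lineage tie-break key)
#' @param cycle refinement cycle counter
#' @param lineage parent design id
#' @param metrics named list of scalar metrics
#' @export
design_record <- function(pose, sequence = "", id, cycle = 0L, lineage = NA,
                          metrics = list()) {
  structure(list(pose = pose, sequence = sequence, id = id, cycle = cycle,
                 lineage = lineage, metrics = metrics, failed = FALSE),
            class = "DesignRecord")
}

#' Generate harmonic coordinate constraints from a motif assembly
#'
#' One record per selected motif atom, targeting the artificial-motif
#' coordinate; used to bias external relax stages toward the motif geometry.
#'
#' @param assembly MotifAssembly
#' @param sd harmonic width (Angstrom, > 0)
#' @param selection `"backbone"` (N/CA/C plus O of each catalytic residue),
#'   `"backbone+functional"`, or `"all-heavy"`
#' @return data.frame with columns `chain`, `resno`, `atom`, `x`, `y`, `z`, `sd`
#' @export
make_coordinate_constraints <- function(assembly, sd = 0.5,
                                        selection = c("backbone",
                                                      "backbone+functional",
                                                      "all-heavy")) {
  selection <- match.arg(selection)
  stopifnot(sd > 0)
  recs <- list()
  for (i in seq_along(assembly$placements)) {
    p <- assembly$placements[[i]]
    ch <- LETTERS[i]
    bb <- p$backbone[p$backbone$resno == p$fragment$anchor_index &
                       p$backbone$atom %in% c("N", "CA", "C", "O"), ]
    side <- p$rebuilt_residue[!p$rebuilt_residue$atom %in% c("N", "CA", "C"), ]
    side <- side[.is_heavy(side$element), ]
    sel <- switch(selection,
      "backbone" = bb[, c("atom", "x", "y", "z")],
      "backbone+functional" = {
        fa <- side[side$atom %in% functional_atoms_default(p$identity), ]
        rbind(bb[, c("atom", "x", "y", "z")], fa[, c("atom", "x", "y", "z")])
      },
      "all-heavy" = rbind(bb[, c("atom", "x", "y", "z")],
                          side[, c("atom", "x", "y", "z")]))
    recs[[i]] <- data.frame(chain = ch, resno = p$fragment$anchor_index,
                            atom = sel$atom, x = sel$x, y = sel$y, z = sel$z,
                            sd = sd, stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Serialize coordinate constraints
#'
#' Text dialect, one record per line:
#' `CoordinateConstraint <atom> <chain><resno> CA <chain><resno> <x> <y> <z> HARMONIC 0.0 <sd>`
#'
#' @param constraints data.frame from [make_coordinate_constraints()]
#' @param path output path (or NULL to return lines)
#' @export
write_constraints <- function(constraints, path = NULL) {
  lines <- sprintf("CoordinateConstraint %s %s%d CA %s%d %.6f %.6f %.6f HARMONIC 0.0 %.4f",
                   constraints$atom, constraints$chain, constraints$resno,
                   constraints$chain, constraints$resno,
                   constraints$x, constraints$y, constraints$z, constraints$sd)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Parse serialized coordinate constraints
#' @param lines character vector or file path
#' @return data.frame as [make_coordinate_constraints()]
#' @export
read_constraints <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  parts <- strsplit(trimws(lines), "\\s+")
  do.call(rbind, lapply(parts, function(p) {
    if (length(p) != 11 || p[1] != "CoordinateConstraint" || p[9] != "HARMONIC") {
      stop("malformed constraint line: ", paste(p, collapse = " "))
    }
    data.frame(chain = substr(p[3], 1, 1),
               resno = as.integer(substring(p[3], 2)),
               atom = p[2],
               x = as.numeric(p[6]), y = as.numeric(p[7]), z = as.numeric(p[8]),
               sd = as.numeric(p[11]), stringsAsFactors = FALSE)
  }))
}

#' Construct a stage adapter
#' @param stage one of `"sequence_design"`, `"relax"`, `"predict"`
#' @param fn callable `(design, options) -> list(design=, metrics=)`; must
#'   not mutate its input
#' @param deterministic declared determinism flag
#' @export
stage_adapter <- function(stage = c("sequence_design", "relax", "predict"),
                          fn, deterministic = TRUE) {
  stage <- match.arg(stage)
  structure(list(stage = stage, fn = fn, deterministic = deterministic),
            class = "StageAdapter")
}

## RMSD of pose atoms named by constraints to their target coordinates
.constraint_rmsd <- function(pose, constraints) {
  a <- .model_atoms(pose)
  key <- paste(a$chain, a$resno, a$atom)
  want <- paste(constraints$chain, constraints$resno, constraints$atom)
  idx <- match(want, key)
  if (anyNA(idx)) return(NA_real_)
  rmsd(as.matrix(a[idx, c("x", "y", "z")]),
       as.matrix(constraints[, c("x", "y", "z")]))
}

## deterministic stub metrics derived from motif agreement
.stub_metrics <- function(design, options) {
  cr <- if (!is.null(options$constraints)) {
    .constraint_rmsd(design$pose, options$constraints)
  } else NA_real_
  if (is.na(cr)) cr <- 0
  list(motif_backbone_rmsd = cr,
       sidechain_rmsd = cr,           # stubs have no separate sidechain model
       plddt_avg = max(0, min(100, 100 - 25 * cr)))
}

#' Identity stub adapter
#'
#' Passes the pose through unchanged and reports motif-agreement metrics;
#' useful for testing selection arithmetic.
#' @inheritParams stage_adapter
#' @export
identity_adapter <- function(stage) {
  stage_adapter(stage, function(design, options) {
    list(design = design, metrics = .stub_metrics(design, options))
  }, deterministic = TRUE)
}

#' Seeded jitter stub adapter
#'
#' Adds isotropic Gaussian coordinate noise (sd `sigma`), seeded from
#' `options$seed`, the design id and the cycle, so reruns are byte-identical.
#' @inheritParams stage_adapter
#' @param sigma noise standard deviation (Angstrom)
#' @export
jitter_adapter <- function(stage, sigma = 0.1) {
  force(sigma)
  stage_adapter(stage, function(design, options) {
    seed <- (as.integer(options$seed %||% 1L) * 131L +
               as.integer(sum(utf8ToInt(as.character(design$id)))) * 7L +
               as.integer(design$cycle)) %% .Machine$integer.max
    pose <- design$pose
    n <- nrow(pose$atoms)
    noise <- withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = sigma), n, 3))
    pose$atoms$x <- pose$atoms$x + noise[, 1]
    pose$atoms$y <- pose$atoms$y + noise[, 2]
    pose$atoms$z <- pose$atoms$z + noise[, 3]
    design$pose <- pose
    list(design = design, metrics = .stub_metrics(design, options))
  }, deterministic = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select top designs by z-score-weighted composite
#'
#' `composite = sum_m weight_m * zscore(metric_m)`; the sign convention
#' lives in the weights (negative weight for lower-is-better metrics such as
#' RMSDs, positive for pLDDT). Deterministic tie-break by lineage id, then
#' design id.
#'
#' @param designs list of DesignRecord
#' @param weights named metric -> weight map
#' @param k number to keep
#' @return top k designs in rank order
#' @export
select_top <- function(designs, weights, k) {
  if (length(designs) == 0L) return(designs)
  mt <- sapply(names(weights), function(m) {
    v <- vapply(designs, function(d) {
      if (is.null(d$metrics[[m]])) {
        stop("design '", d$id, "' is missing metric: ", m)
      }
      as.numeric(d$metrics[[m]])
    }, 0)
    v
  })
  mt <- matrix(mt, nrow = length(designs),
               dimnames = list(NULL, names(weights)))
  z <- apply(mt, 2, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  z <- matrix(z, nrow = length(designs))
  comp <- as.numeric(z %*% unlist(weights))
  key_lineage <- vapply(designs, function(d) as.character(d$lineage %||% ""), "")
  key_id <- vapply(designs, function(d) as.character(d$id), "")
  ord <- order(-comp, key_lineage, key_id)
  out <- designs[ord][seq_len(min(k, length(designs)))]
  for (i in seq_along(out)) out[[i]]$metrics$composite <- comp[ord][i]
  out
}

#' Run one refinement cycle
#'
#' Applies sequence design, constrained relax, sequence redesign and
#' structure prediction in order, merges the per-stage metrics into each
#' design, and keeps `ceil(keep_fraction * n)` designs by the z-score
#' composite. Failed adapters produce per-design failure records and the
#' loop continues; if every design fails, an error is raised.
#'
#' @param designs list of DesignRecord
#' @param adapters named list with elements `sequence_design`, `relax`,
#'   `predict` ([stage_adapter()] objects)
#' @param constraints coordinate-constraint table (passed to adapters via
#'   options)
#' @param config list: `keep_fraction` (default 0.5), `ranking_weights`
#'   (default `c(sidechain_rmsd = -2, motif_backbone_rmsd = -1, plddt_avg = 1)`),
#'   `seed` (default 1)
#' @return list of surviving DesignRecord (cycle counter advanced)
#' @export
run_refinement_cycle <- function(designs, adapters, constraints = NULL,
                                 config = list()) {
  cfg <- utils::modifyList(
    list(keep_fraction = 0.5,
         ranking_weights = c(sidechain_rmsd = -2, motif_backbone_rmsd = -1,
                             plddt_avg = 1),
         seed = 1L), config)
  stopifnot(cfg$keep_fraction > 0, cfg$keep_fraction <= 1)
  need <- c("sequence_design", "relax", "predict")
  if (!all(need %in% names(adapters))) {
    stop("adapters must provide stages: ", paste(need, collapse = ", "))
  }
  options <- list(constraints = constraints, seed = cfg$seed)
  order_ <- c("sequence_design", "relax", "sequence_design", "predict")
  out <- lapply(designs, function(d) {
    d$lineage <- d$id
    d$cycle <- d$cycle + 1L
    for (st in order_) {
      res <- tryCatch(adapters[[st]]$fn(d, options), error = function(e) e)
      if (inherits(res, "error")) {
        d$failed <- TRUE
        d$metrics$failure <- conditionMessage(res)
        return(d)
      }
      d <- res$design
      d$metrics <- utils::modifyList(d$metrics, res$metrics)
    }
    d
  })
  ok <- Filter(function(d) !isTRUE(d$failed), out)
  if (length(ok) == 0L) stop("all designs failed in refinement cycle")
  keep <- ceiling(cfg$keep_fraction * length(designs))
  select_top(ok, cfg$ranking_weights, keep)
}

#' Run the full refinement loop
#' @inheritParams run_refinement_cycle
#' @param n_cycles number of cycles (>= 1)
#' @export
run_refinement <- function(designs, adapters, constraints = NULL,
                           config = list(), n_cycles = 3) {
  stopifnot(n_cycles >= 1)
  for (i in seq_len(n_cycles)) {
    designs <- run_refinement_cycle(designs, adapters, constraints, config)
  }
  designs
}
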
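#' Backbone-dependent rotamer libraries
#'
#' A rotamer library maps (identity, phi bin, psi bin) to a list of rotamers,
#' each a vector of chi means with an occurrence probability. Bins tile
#' (-180, 180] x (-180, 180] with a fixed width (default 10 degrees); an
#' angle belongs to the bin whose half-open interval (lo, hi] contains it.
#' The on-disk format is a TSV with columns `identity`, `phi`, `psi` (bin
#' centers), `chi1`..`chi4` (unused chis empty/NA) and `prob`.
#'
#' @name rotamer-library
NULL

## 1-based bin index for an angle in (-180, 180]
.ppbin <- function(angle, width) {
  a <- .wrap180(angle)
  i <- ceiling((a + 180) / width)
  pmin(pmax(i, 1L), as.integer(round(360 / width)))
}

.bin_center <- function(i, width) -180 + (i - 0.5) * width

#' Construct a rotamer library
#' @param entries data.frame with columns `identity`, `phi`, `psi` (degrees;
#'   any angle inside the intended bin), `chi1`..`chi4`, `prob`.
#' @param bin_width bin width in degrees (must divide 360)
#' @return object of class `RotamerLibrary`
#' @export
rotamer_library <- function(entries, bin_width = 10) {
  stopifnot(360 %% bin_width == 0)
  need <- c("identity", "phi", "psi", "prob")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "))
  }
  if (any(entries$prob <= 0)) stop("rotamer probabilities must be > 0")
  entries$phi_bin <- .ppbin(entries$phi, bin_width)
  entries$psi_bin <- .ppbin(entries$psi, bin_width)
  key <- paste(entries$identity, entries$phi_bin, entries$psi_bin)
  sums <- tapply(entries$prob, key, sum)
  if (any(sums > 1 + 1e-6)) {
    stop("per-bin rotamer probabilities sum to more than 1: ",
         names(sums)[which.max(sums)])
  }
  structure(list(entries = entries, bin_width = bin_width),
            class = "RotamerLibrary")
}

#' @export
print.RotamerLibrary <- function(x, ...) {
  cat(sprintf("<RotamerLibrary> %d rotamers, %d identities, %g deg bins\n",
              nrow(x$entries), length(unique(x$entries$identity)), x$bin_width))
  invisible(x)
}

#' Read a rotamer library from TSV
#' @param path TSV path (columns identity, phi, psi, chi1..chi4, prob)
#' @param bin_width bin width in degrees
#' @export
read_rotamer_library <- function(path, bin_width = 10) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  rotamer_library(df, bin_width = bin_width)
}

#' Write a rotamer library to TSV
#' @param lib RotamerLibrary
#' @param path output path
#' @export
write_rotamer_library <- function(lib, path) {
  cols <- intersect(c("identity", "phi", "psi", "chi1", "chi2", "chi3", "chi4",
                      "prob"), names(lib$entries))
  utils::write.table(lib$entries[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Rotamers compatible with a backbone phi/psi combination
#'
#' Returns the rotamers stored in the (phi, psi) bin with probability at
#' least `min_prob`, sorted by descending probability (stable order).
#'
#' @param identity three-letter code
#' @param phi,psi backbone dihedrals (degrees)
#' @param lib RotamerLibrary
#' @param min_prob minimum probability
#' @return list of rotamers, each `list(chi = numeric, probability = numeric)`
#' @export
compatible_rotamers <- function(identity, phi, psi, lib, min_prob = 0) {
  e <- lib$entries
  if (!identity %in% e$identity) stop("identity absent from library: ", identity)
  sel <- e$identity == identity &
    e$phi_bin == .ppbin(phi, lib$bin_width) &
    e$psi_bin == .ppbin(psi, lib$bin_width) &
    e$prob >= min_prob
  rows <- e[sel, , drop = FALSE]
  if (nrow(rows) == 0L) return(list())
  rows <- rows[order(-rows$prob), , drop = FALSE]
  nch <- n_chi(identity)
  chicols <- paste0("chi", seq_len(nch))
  lapply(seq_len(nrow(rows)), function(i) {
    chi <- if (nch > 0) as.numeric(rows[i, chicols]) else numeric(0)
    list(chi = chi, probability = rows$prob[i])
  })
}
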
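# Chemical-shift-based order/disorder estimation: secondary shifts
# against random-coil references, a random-coil-index style order
# parameter, and ordered/disordered region segmentation.

.rc_cache <- new.env(parent = emptyenv())

#' Random-coil reference chemical shifts
#'
#' Per-residue-type random-coil reference shifts for the six backbone
#' atoms, compiled from the standard random-coil tables of the
#' Wishart-school chemical-shift literature (glycine has no CB entry,
#' proline no amide H/N). Neighbour-residue corrections are deliberately
#' omitted; secondary-shift contrasts at the helix/coil scale dwarf them.
#'
#' @return data frame with columns `aa`, `atom`, `shift_ppm`.
#' @export
random_coil_reference <- function() {
  if (is.null(.rc_cache$ref)) {
    path <- system.file("extdata", "random_coil_shifts.tsv",
                        package = "fingermap", mustWork = TRUE)
    .rc_cache$ref <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .rc_cache$ref
}

#' Secondary chemical shifts against a random-coil reference
#'
#' `ddelta(atom, residue) = observed - reference(residue_type, atom)`.
#' Atoms absent from either the table or the reference (e.g. glycine CB)
#' are omitted, never imputed.
#'
#' @param table a `shift_table`.
#' @param reference a reference data frame as from
#'   [random_coil_reference()].
#' @return data frame with columns `residue`, `aa`, `atom`, `delta_ppm`.
#' @export
secondary_shifts <- function(table, reference = random_coil_reference()) {
  bad <- setdiff(unique(table$aa), unique(reference$aa))
  if (length(bad)) {
    res <- table$residue[table$aa %in% bad][[1L]]
    stop(sprintf("residue %d: type '%s' absent from the random-coil reference",
                 res, table$aa[table$aa %in% bad][[1L]]))
  }
  key_t <- paste(table$aa, table$atom)
  key_r <- paste(reference$aa, reference$atom)
  hit <- match(key_t, key_r)
  keep <- !is.na(hit)
  out <- data.frame(residue = table$residue[keep], aa = table$aa[keep],
                    atom = table$atom[keep],
                    delta_ppm = table$shift_ppm[keep] -
                      reference$shift_ppm[hit[keep]])
  rownames(out) <- NULL
  out
}

#' Default atom weights for the random-coil index
#'
#' Heavy-atom secondary shifts carry most of the structural signal; proton
#' shifts are up-weighted to put their smaller ppm range on a comparable
#' scale, and 15N is down-weighted for its poor coil-reference precision.
#' @return named numeric vector over [SUPPORTED_ATOMS].
#' @export
rci_default_weights <- function() {
  c(CA = 1, CB = 1, C = 1, N = 0.2, H = 2.5, HA = 2.5)
}

#' RCI-style order parameter from a shift table
#'
#' Per residue, computes the weighted mean absolute secondary shift `A_i`
#' over available atoms, smooths it with a centred moving average of size
#' `window`, and maps it to a random-coil index `rci_i = 1 / max(A_i,
#' floor)` and an order-parameter estimate `s2_i = clamp(1 - c * rci_i, 0,
#' 1)`. Larger secondary shifts therefore always give larger s2 (more
#' order); a table at exact random-coil values gives s2 = 0 everywhere.
#' Defaults (`floor = 0.05` ppm, `c = 0.15`) place canonical-amplitude
#' helix around s2 = 0.83 and pure coil with sub-0.1-ppm noise at 0.
#'
#' @param table a `shift_table`.
#' @param weights named per-atom weights (default
#'   [rci_default_weights()]).
#' @param window odd smoothing window size (default 3; 1 = unsmoothed).
#' @param floor lower bound on `A_i` (ppm) guarding the reciprocal.
#' @param scale_c slope of the rci-to-s2 map.
#' @param reference random-coil reference table.
#' @return a `disorder_profile` data frame: `residue`, `n_atoms`,
#'   `a_bar_ppm` (smoothed), `rci`, `s2`, `flagged` (TRUE when < 2 atoms
#'   were available; such residues get NA, never fabricated values).
#' @export
rci_s2 <- function(table, weights = rci_default_weights(), window = 3L,
                   floor = 0.05, scale_c = 0.15,
                   reference = random_coil_reference()) {
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  sec <- secondary_shifts(table, reference)
  sec <- sec[sec$atom %in% names(weights), , drop = FALSE]
  residues <- sort(unique(table$residue))
  a_raw <- n_atoms <- numeric(length(residues))
  for (i in seq_along(residues)) {
    rows <- sec[sec$residue == residues[[i]], , drop = FALSE]
    n_atoms[[i]] <- nrow(rows)
    if (nrow(rows) >= 1L) {
      w <- weights[rows$atom]
      a_raw[[i]] <- sum(w * abs(rows$delta_ppm)) / sum(w)
    } else {
      a_raw[[i]] <- NA_real_
    }
  }
  flagged <- n_atoms < 2L
  usable <- sum(!flagged)
  if (usable < window) {
    stop("too few residues with >= 2 reference atoms for the requested window")
  }
  a_use <- ifelse(flagged, NA_real_, a_raw)
  half <- (window - 1L) %/% 2L
  a_smooth <- vapply(seq_along(residues), function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(residues), i + half)
    win <- a_use[lo:hi]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  rci <- 1 / pmax(a_smooth, floor)
  s2 <- pmin(pmax(1 - scale_c * rci, 0), 1)
  out <- data.frame(residue = residues, n_atoms = as.integer(n_atoms),
                    a_bar_ppm = a_smooth, rci = rci, s2 = s2,
                    flagged = flagged)
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "floor") <- floor
  attr(out, "scale_c") <- scale_c
  class(out) <- c("disorder_profile", "data.frame")
  out
}

#' Segment a disorder profile into ordered and disordered regions
#'
#' Residues with `s2 > s2_cutoff` are ordered, others disordered; maximal
#' runs shorter than `min_run` are merged into their neighbours (shortest
#' run first, leftmost on ties), so isolated single-residue flips do not
#' fragment the segmentation. Gaps in residue numbering split regions.
#'
#' @param profile a `disorder_profile`.
#' @param s2_cutoff order threshold (default 0.7).
#' @param min_run minimum region length in residues (default 3).
#' @return data frame with columns `start`, `end`, `state` (`"ordered"` /
#'   `"disordered"`).
#' @export
classify_regions <- function(profile, s2_cutoff = 0.7, min_run = 3L) {
  keep <- !is.na(profile$s2)
  res <- profile$residue[keep]
  lab <- ifelse(profile$s2[keep] > s2_cutoff, "ordered", "disordered")
  if (length(res) == 0L) return(data.frame(start = integer(0),
                                           end = integer(0),
                                           state = character(0)))
  # split on numbering gaps, segment each contiguous block
  block <- cumsum(c(1L, diff(res) != 1L))
  out <- lapply(split(seq_along(res), block), function(idx) {
    l <- lab[idx]
    repeat {
      r <- rle(l)
      if (length(r$lengths) <= 1L || all(r$lengths >= min_run)) break
      short <- which(r$lengths < min_run)
      k <- short[which.min(r$lengths[short])]
      r$values[[k]] <- if (r$values[[k]] == "ordered") "disordered" else "ordered"
      l <- inverse.rle(r)
    }
    r <- rle(l)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = res[idx][starts], end = res[idx][ends],
               state = r$values, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
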
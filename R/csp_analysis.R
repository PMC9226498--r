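# Combined amide chemical-shift perturbations, fast-exchange trajectory
# diagnostics, and interface hotspot calling.

#' Combined amide chemical-shift perturbation between two peak lists
#'
#' For every residue present in both lists,
#' `CSP = sqrt(ddelta_H^2 + (alpha_n * ddelta_N)^2)` with differences taken
#' endpoint minus reference. `alpha_n` (default 0.14) makes the 15N
#' dimension commensurate with 1H, the standard amide weighting. The
#' profile also carries `relative_csp = CSP / max(CSP)` for comparison
#' with relative-perturbation bar plots.
#'
#' @param reference,endpoint `peak_list` data frames (apo and
#'   near-saturation points of a titration).
#' @param alpha_n 15N scaling factor in (0, 1].
#' @param reference_label,endpoint_label free-text labels.
#' @return a `csp_profile` data frame with columns `residue`, `csp_ppm`,
#'   `relative_csp`; attributes `alpha_n`, `omitted` (residues present in
#'   only one list), labels.
#' @export
combined_csp <- function(reference, endpoint, alpha_n = 0.14,
                         reference_label = "reference",
                         endpoint_label = "endpoint") {
  if (alpha_n <= 0 || alpha_n > 1) stop("alpha_n must lie in (0, 1]")
  shared <- intersect(reference$residue, endpoint$residue)
  if (length(shared) == 0L) {
    stop("peak lists share no residues: cannot compute CSP")
  }
  omitted <- sort(union(setdiff(reference$residue, shared),
                        setdiff(endpoint$residue, shared)))
  i <- match(shared, reference$residue)
  j <- match(shared, endpoint$residue)
  dh <- endpoint$h_ppm[j] - reference$h_ppm[i]
  dn <- endpoint$n_ppm[j] - reference$n_ppm[i]
  csp <- sqrt(dh^2 + (alpha_n * dn)^2)
  mx <- max(csp)
  out <- data.frame(residue = shared, csp_ppm = csp,
                    relative_csp = if (mx > 0) csp / mx else 0)
  out <- out[order(out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha_n") <- alpha_n
  attr(out, "omitted") <- omitted
  attr(out, "reference_label") <- reference_label
  attr(out, "endpoint_label") <- endpoint_label
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' CSP profile of a titration series (apo vs highest-ratio point)
#'
#' Convenience wrapper: the endpoint is the last (highest ligand:protein
#' ratio) point, the closest available approximation to saturation.
#' @param series a `titration_series`.
#' @inheritParams combined_csp
#' @return a `csp_profile`.
#' @export
csp_from_series <- function(series, alpha_n = 0.14) {
  combined_csp(series[[1L]]$peaks, series[[length(series)]]$peaks,
               alpha_n = alpha_n, reference_label = "apo",
               endpoint_label = sprintf("point %d", length(series)))
}

#' Per-residue peak trajectories with a fast-exchange collinearity check
#'
#' Under fast exchange with a single binding event, each residue's peak
#' moves along the straight segment between its free and bound positions.
#' For every residue with at least two observed points this fits a total
#' least-squares line through the (1H, alpha_n * 15N) coordinates and
#' reports the maximum perpendicular distance (ppm, 1H scale) as a
#' deviation-from-linearity statistic; large values flag residues whose
#' motion is inconsistent with two-state fast exchange.
#'
#' @param series a `titration_series`.
#' @param alpha_n 15N scaling factor.
#' @param tol flag threshold (ppm); default `3 *` a robust noise estimate
#'   (MAD about zero of all perpendicular residuals).
#' @return data frame with columns `residue`, `n_points`, `max_perp_ppm`,
#'   `flagged`; attributes `trajectories` (per-residue point tables),
#'   `excluded` (residues with < 2 points), `tol`.
#' @export
peak_trajectories <- function(series, alpha_n = 0.14, tol = NULL) {
  apo <- series[[1L]]$peaks
  ratios <- vapply(series, function(p) p$l_total / p$p_total, numeric(1))
  traj <- lapply(apo$residue, function(r) {
    rows <- lapply(seq_along(series), function(t) {
      pk <- series[[t]]$peaks
      k <- match(r, pk$residue)
      if (is.na(k)) return(NULL)
      data.frame(ratio = ratios[[t]], h_ppm = pk$h_ppm[k], n_ppm = pk$n_ppm[k])
    })
    do.call(rbind, rows)
  })
  names(traj) <- as.character(apo$residue)
  npts <- vapply(traj, nrow, integer(1))
  excluded <- apo$residue[npts < 2L]
  keep <- npts >= 2L
  stats_out <- vapply(traj[keep], function(tr) {
    xy <- cbind(tr$h_ppm, alpha_n * tr$n_ppm)
    xy <- sweep(xy, 2L, colMeans(xy))
    if (nrow(xy) == 2L) return(0)
    # principal axis = TLS line; residuals = projections on the minor axis
    ev <- eigen(crossprod(xy), symmetric = TRUE)
    perp <- abs(xy %*% ev$vectors[, 2L])
    max(perp)
  }, numeric(1))
  all_perp <- unlist(lapply(traj[keep], function(tr) {
    xy <- cbind(tr$h_ppm, alpha_n * tr$n_ppm)
    xy <- sweep(xy, 2L, colMeans(xy))
    if (nrow(xy) == 2L) return(numeric(0))
    ev <- eigen(crossprod(xy), symmetric = TRUE)
    as.numeric(xy %*% ev$vectors[, 2L])
  }))
  if (is.null(tol)) {
    noise <- if (length(all_perp)) stats::mad(all_perp, center = 0) else 0
    tol <- 3 * noise
  }
  out <- data.frame(residue = apo$residue[keep], n_points = npts[keep],
                    max_perp_ppm = stats_out,
                    flagged = stats_out > tol)
  rownames(out) <- NULL
  attr(out, "trajectories") <- traj[keep]
  attr(out, "excluded") <- excluded
  attr(out, "tol") <- tol
  out
}

#' Call interface hotspot residues from a CSP profile
#'
#' Thresholds the profile either at `mean + k * SD` over all residues
#' (method `"ksd"`, default k = 1) or at the q-th quantile (method
#' `"quantile"`). Residues strictly above the threshold are hotspots; the
#' full ranked profile should always be reported alongside the call.
#'
#' @param profile a `csp_profile`.
#' @param method `"ksd"` or `"quantile"`.
#' @param k SD multiplier for `"ksd"`.
#' @param q probability for `"quantile"`.
#' @return a `hotspot_call` list: `hotspots` (sorted residue numbers),
#'   `threshold_value` (ppm), `method` descriptor.
#' @export
call_hotspots <- function(profile, method = c("ksd", "quantile"), k = 1,
                          q = 0.9) {
  method <- match.arg(method)
  if (nrow(profile) == 0L) stop("empty CSP profile")
  if (method == "ksd") {
    if (nrow(profile) < 2L) {
      stop("ksd hotspot calling needs >= 2 residues (SD undefined)")
    }
    thr <- mean(profile$csp_ppm) + k * stats::sd(profile$csp_ppm)
    desc <- sprintf("mean + %g*SD", k)
  } else {
    thr <- stats::quantile(profile$csp_ppm, q, names = FALSE)
    desc <- sprintf("quantile q=%g", q)
  }
  structure(list(hotspots = sort(profile$residue[profile$csp_ppm > thr]),
                 threshold_value = thr, method = desc),
            class = "hotspot_call")
}

#' @export
print.hotspot_call <- function(x, ...) {
  cat(sprintf("Hotspots (%s, threshold %.4g ppm): %s\n", x$method,
              x$threshold_value,
              if (length(x$hotspots)) paste(x$hotspots, collapse = ", ")
              else "none"))
  invisible(x)
}
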
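# End-to-end driver: titration -> CSP -> hotspots -> Kd fit -> zinc-finger
# numbering/profile -> disorder -> structure painting, with a
# machine-readable MANIFEST and deterministic outputs under fixed seeds.

.known_config_keys <- c(
  "series_manifest", "alpha_n", "hotspot.method", "hotspot.k", "hotspot.q",
  "fit.boot", "fit.seed", "sequence", "sequence_start", "profile.alignment",
  "profile.lambda", "profile.n_null", "disorder.shifts", "disorder.window",
  "disorder.cutoff", "structure_pdb", "out_dir", "seed")

#' Build a validated run configuration
#'
#' Configuration is a flat set of dotted keys; unknown keys are rejected so
#' typos fail loudly. Only `series_manifest` and `out_dir` are mandatory;
#' stages whose inputs are absent are skipped.
#'
#' @param ... key = value pairs among: `series_manifest`, `out_dir`,
#'   `alpha_n` (default 0.14), `hotspot.method` ("ksd"/"quantile"),
#'   `hotspot.k`, `hotspot.q`, `fit.boot` (bootstrap replicates; 0 skips
#'   the CI), `fit.seed`, `sequence` (one-letter string for zinc-finger
#'   annotation), `sequence_start`, `profile.alignment` (aligned FASTA
#'   path), `profile.lambda`, `profile.n_null`, `disorder.shifts` (shift
#'   table path), `disorder.window`, `disorder.cutoff`, `structure_pdb`,
#'   `seed`.
#' @return a `run_config` list with defaults filled in.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (k in c("series_manifest", "out_dir")) {
    if (is.null(cfg[[k]])) stop(sprintf("config key '%s' is required", k))
  }
  defaults <- list(alpha_n = 0.14, hotspot.method = "ksd", hotspot.k = 1,
                   hotspot.q = 0.9, fit.boot = 200L, fit.seed = 1L,
                   sequence_start = 1L, profile.lambda = 1,
                   profile.n_null = 2000L, disorder.window = 3L,
                   disorder.cutoff = 0.7, seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a key = value text file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' auto-typed (numeric when parseable).
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop(sprintf("malformed config line: '%s'", lines[bad][[1L]]))
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1)))
  typed <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(typed) <- keys
  do.call(run_config, typed)
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- cfg[order(names(cfg))]
  writeLines(sprintf("%s=%s", names(flat),
                     vapply(flat, function(v) paste(format(v), collapse = ","),
                            character(1))), tmp)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full interface-mapping pipeline
#'
#' Stages: read the titration series; CSP profile (apo vs highest-ratio
#' point) and trajectory diagnostics; hotspot call; global Kd fit with
#' bootstrap CI restricted to the called hotspot residues; optional C2H2
#' annotation and helix-position table of the supplied sequence; optional
#' profile atypicality of its first finger; optional disorder profile;
#' optional B-factor painting of a structure by CSP. All outputs are
#' written under `out_dir`; a MANIFEST.json records the package version,
#' config hash, stage status and output files. Given identical
#' configuration the TSV/JSON outputs are byte-identical across runs.
#'
#' @param config a [run_config()].
#' @return list of stage results, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "fingermap",
                   version = as.character(utils::packageVersion("fingermap")),
                   config_hash = .config_hash(config),
                   stages = list(), outputs = character(0))
  results <- list()
  log <- character(0)
  say <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
    message(sprintf(fmt, ...))
  }
  finish <- function(failed_stage = NULL, err = NULL) {
    if (!is.null(failed_stage)) {
      manifest$stages[[failed_stage]] <<- paste("FAILED:",
                                                conditionMessage(err))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      finish(name, e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  series <- stage("read_series", read_titration(config$series_manifest))
  manifest$stages$read_series <- sprintf("%d points", length(series))
  say("read titration series: %d points, %d apo residues", length(series),
      nrow(series[[1L]]$peaks))

  csp <- stage("csp", csp_from_series(series, alpha_n = config$alpha_n))
  traj <- stage("csp", peak_trajectories(series, alpha_n = config$alpha_n))
  hot <- stage("hotspots", {
    if (config$hotspot.method == "ksd") {
      call_hotspots(csp, "ksd", k = config$hotspot.k)
    } else {
      call_hotspots(csp, "quantile", q = config$hotspot.q)
    }
  })
  csp_out <- as.data.frame(csp)
  csp_out$hotspot <- csp_out$residue %in% hot$hotspots
  .write_tsv(csp_out, file.path(out_dir, "csp.tsv"))
  .write_tsv(traj[, c("residue", "n_points", "max_perp_ppm", "flagged")],
             file.path(out_dir, "trajectories.tsv"))
  manifest$stages$csp <- sprintf("%d residues", nrow(csp_out))
  manifest$stages$hotspots <- sprintf("%d hotspots above %.4g ppm (%s)",
                                      length(hot$hotspots),
                                      hot$threshold_value, hot$method)
  manifest$outputs <- c(manifest$outputs, "csp.tsv", "trajectories.tsv")
  say("CSP: %d residues; hotspots: %s", nrow(csp_out),
      paste(hot$hotspots, collapse = ", "))

  fit <- stage("fitkd", {
    f <- fit_kd(series, alpha_n = config$alpha_n,
                residue_subset = if (length(hot$hotspots) >= 3L)
                  hot$hotspots else NULL,
                fix_free_shifts = FALSE)
    if (config$fit.boot >= 100L) {
      ci <- bootstrap_kd_ci(series, f, n_boot = as.integer(config$fit.boot),
                            seed = as.integer(config$fit.seed))
      f$kd_ci <- c(ci[["low"]], ci[["high"]])
    }
    f
  })
  fit_report <- list(kd_M = fit$kd_hat, kd_mM = 1e3 * fit$kd_hat,
                     kd_ci_M = fit$kd_ci, rss = fit$rss,
                     n_points_used = fit$n_points_used,
                     residues = fit$residues, max_fb = fit$max_fb,
                     lower_bound_regime = fit$lower_bound_regime,
                     alpha_n = fit$alpha_n,
                     bootstrap_seed = as.integer(config$fit.seed),
                     delta_bound = fit$delta_bound)
  jsonlite::write_json(fit_report, file.path(out_dir, "binding_fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$stages$fitkd <- sprintf("Kd = %.4g M", fit$kd_hat)
  manifest$outputs <- c(manifest$outputs, "binding_fit.json")
  say("global Kd = %.4g M (%.3g mM)", fit$kd_hat, 1e3 * fit$kd_hat)
  results$fit <- fit

  if (!is.null(config$sequence)) {
    zf <- stage("zfpos", {
      anns <- annotate_c2h2(config$sequence,
                            start_residue = as.integer(config$sequence_start))
      if (length(anns) == 0L) stop("no C2H2 finger found in sequence")
      anns
    })
    ann <- zf[[1L]]
    span <- ann$start:ann$end
    pos_tab <- data.frame(
      residue = span,
      aa = strsplit(ann$seq, "")[[1L]],
      helix_position = vapply(span, helix_position, integer(1),
                              annotation = ann),
      dna_binding = span %in% dna_binding_residues(ann)$residue,
      hotspot = span %in% hot$hotspots)
    .write_tsv(pos_tab, file.path(out_dir, "zf_positions.tsv"))
    manifest$stages$zfpos <- sprintf("%d finger(s); helix +1 = residue %d",
                                     length(zf), ann$helix_start)
    manifest$outputs <- c(manifest$outputs, "zf_positions.tsv")
    say("C2H2 finger %d-%d, helix +1 = residue %d", ann$start, ann$end,
        ann$helix_start)
    results$zf <- zf

    if (!is.null(config$profile.alignment)) {
      prof_res <- stage("profile", {
        aln <- read_alignment(config$profile.alignment)
        prof <- build_profile(aln, lambda = config$profile.lambda)
        cmap <- stats::setNames(
          vapply(c(-1L, 1L, 2L, 3L, 6L), function(p)
            residue_at_position(ann, p) - ann$start + 1L, integer(1)),
          c("-1", "1", "2", "3", "6"))
        score <- atypicality_score(ann, prof, cmap,
                                   n_null = as.integer(config$profile.n_null),
                                   seed = as.integer(config$seed))
        list(profile = prof, score = score)
      })
      jsonlite::write_json(
        list(per_position = prof_res$score$per_position,
             total_log_odds = prof_res$score$total,
             percentile = prof_res$score$percentile,
             information_content_bits = information_content(prof_res$profile)),
        file.path(out_dir, "atypicality.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
      manifest$stages$profile <- sprintf("total log-odds %.3f",
                                         prof_res$score$total)
      manifest$outputs <- c(manifest$outputs, "atypicality.json")
      say("DNA-binding-position atypicality: total log-odds %.3f (percentile %.3f)",
          prof_res$score$total, prof_res$score$percentile)
      results$profile <- prof_res
    }
  }

  if (!is.null(config$disorder.shifts)) {
    dis <- stage("disorder", {
      tab <- read_shift_table(config$disorder.shifts)
      prof <- rci_s2(tab, window = as.integer(config$disorder.window))
      regions <- classify_regions(prof, s2_cutoff = config$disorder.cutoff)
      list(profile = prof, regions = regions)
    })
    dtab <- as.data.frame(dis$profile)
    dtab$region <- NA_character_
    for (i in seq_len(nrow(dis$regions))) {
      sel <- dtab$residue >= dis$regions$start[[i]] &
        dtab$residue <= dis$regions$end[[i]]
      dtab$region[sel] <- dis$regions$state[[i]]
    }
    .write_tsv(dtab, file.path(out_dir, "disorder.tsv"))
    manifest$stages$disorder <- sprintf("%d region(s)", nrow(dis$regions))
    manifest$outputs <- c(manifest$outputs, "disorder.tsv")
    say("disorder: %d region(s)", nrow(dis$regions))
    results$disorder <- dis
  }

  if (!is.null(config$structure_pdb)) {
    stage("paint", {
      sc <- stats::setNames(csp$csp_ppm, csp$residue)
      paint_structure(config$structure_pdb, scores = sc, default = 0,
                      outfile = file.path(out_dir, "painted.pdb"))
    })
    manifest$stages$paint <- "B-factors = CSP (ppm)"
    manifest$outputs <- c(manifest$outputs, "painted.pdb")
    say("painted structure by CSP -> painted.pdb")
  }

  results$csp <- csp
  results$hotspots <- hot
  finish()
  invisible(results)
}
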
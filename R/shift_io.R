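# On-disk formats: shift-table TSV, amide peak-list TSV, titration manifest
# TSV, a minimal NMR-STAR v3 Atom_chem_shift loop subset, aligned FASTA, and
# fixed-column PDB B-factor painting. All TSVs are UTF-8 with '.' decimals.

#' Backbone atoms supported throughout the package
#'
#' Chemical-shift records are restricted to the six backbone atoms used for
#' secondary-shift and order-parameter analysis.
#' @export
SUPPORTED_ATOMS <- c("H", "N", "CA", "CB", "C", "HA")

#' The twenty standard amino acids, one-letter codes, alphabetical
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y")

.read_source_lines <- function(source) {
  if (!inherits(source, "connection") && !file.exists(source)) {
    stop(sprintf("file not found: %s", source))
  }
  readLines(source, warn = FALSE)
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a per-residue chemical-shift table
#'
#' Parses either the package's TSV dialect (header
#' `residue  aa  atom  shift_ppm`) or a minimal NMR-STAR v3 subset: the
#' `Atom_chem_shift` loop columns `Comp_index_ID`, `Comp_ID`, `Atom_ID`,
#' `Val`, which is what BMRB chemical-shift depositions provide. Rows whose
#' atom is outside [SUPPORTED_ATOMS] are skipped and counted in the parse
#' report (`attr(x, "skipped")`).
#'
#' @param source path to a file, or a connection.
#' @param dialect `"tsv"` (default) or `"nmrstar"`.
#' @param sample_label free-text label stored on the returned table.
#' @return A `shift_table`: a data frame with columns `residue` (integer,
#'   1-based), `aa` (one-letter code), `atom`, `shift_ppm`, plus attributes
#'   `sample_label` and `skipped` (count of unsupported-atom rows).
#' @export
read_shift_table <- function(source, dialect = c("tsv", "nmrstar"),
                             sample_label = "") {
  dialect <- match.arg(dialect)
  lines <- .read_source_lines(source)
  if (dialect == "tsv") {
    .parse_shift_tsv(lines, sample_label)
  } else {
    .parse_shift_nmrstar(lines, sample_label)
  }
}

.parse_shift_tsv <- function(lines, sample_label) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in shift table")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("residue", "aa", "atom", "shift_ppm"))) {
    stop("shift table header must be 'residue\taa\tatom\tshift_ppm'")
  }
  body <- lines[-1L]
  if (length(body) == 0L) stop("no records in shift table")
  rows <- strsplit(body, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  skipped <- 0L
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    lineno <- i + 1L
    if (length(f) != 4L) {
      stop(sprintf("malformed shift-table row at line %d: expected 4 fields, got %d",
                   lineno, length(f)))
    }
    res <- .num_or_na(f[[1L]])
    shift <- .num_or_na(f[[4L]])
    if (is.na(res) || res < 1 || res != round(res)) {
      stop(sprintf("malformed shift-table row at line %d: bad residue number '%s'",
                   lineno, f[[1L]]))
    }
    if (is.na(shift) || !is.finite(shift)) {
      stop(sprintf("malformed shift-table row at line %d: bad shift '%s'",
                   lineno, f[[4L]]))
    }
    atom <- toupper(trimws(f[[3L]]))
    if (!atom %in% SUPPORTED_ATOMS) {
      skipped <- skipped + 1L
      next
    }
    out[[i]] <- data.frame(residue = as.integer(res),
                           aa = toupper(trimws(f[[2L]])),
                           atom = atom, shift_ppm = shift,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) stop("no records in shift table")
  tab <- do.call(rbind, out)
  .finish_shift_table(tab, sample_label, skipped)
}

.finish_shift_table <- function(tab, sample_label, skipped) {
  key <- paste(tab$residue, tab$atom)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][[1L]]
    stop(sprintf("duplicate (residue, atom) entry: %s", dup))
  }
  tab <- tab[order(tab$residue, match(tab$atom, SUPPORTED_ATOMS)), ,
             drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "sample_label") <- sample_label
  attr(tab, "skipped") <- skipped
  class(tab) <- c("shift_table", "data.frame")
  tab
}

.parse_shift_nmrstar <- function(lines, sample_label) {
  lines <- trimws(lines)
  need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
  tag_idx <- grep("^_Atom_chem_shift\\.", lines)
  if (length(tag_idx) == 0L) stop("no Atom_chem_shift loop found")
  tags <- sub("^_Atom_chem_shift\\.", "", lines[tag_idx])
  if (!all(need %in% tags)) {
    stop(sprintf("Atom_chem_shift loop lacks required columns: %s",
                 paste(setdiff(need, tags), collapse = ", ")))
  }
  first_data <- max(tag_idx) + 1L
  body <- lines[first_data:length(lines)]
  stop_at <- grep("^(stop_|save_)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[[1L]] - 1L)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  if (length(body) == 0L) stop("no records in Atom_chem_shift loop")
  skipped <- 0L
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "[[:space:]]+")[[1L]]
    if (length(f) < length(tags)) {
      stop(sprintf("malformed NMR-STAR data row %d: expected %d fields",
                   i, length(tags)))
    }
    res <- .num_or_na(f[[match("Comp_index_ID", tags)]])
    comp <- toupper(f[[match("Comp_ID", tags)]])
    atom <- toupper(f[[match("Atom_ID", tags)]])
    val <- .num_or_na(f[[match("Val", tags)]])
    if (is.na(res) || is.na(val)) {
      stop(sprintf("malformed NMR-STAR data row %d", i))
    }
    if (!atom %in% SUPPORTED_ATOMS) {
      skipped <- skipped + 1L
      next
    }
    aa <- if (comp %in% names(AA_THREE_TO_ONE)) AA_THREE_TO_ONE[[comp]] else "X"
    out[[i]] <- data.frame(residue = as.integer(res), aa = aa, atom = atom,
                           shift_ppm = val, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) stop("no records in shift table")
  .finish_shift_table(do.call(rbind, out), sample_label, skipped)
}

#' Write a shift table in the TSV dialect
#'
#' Numeric fields are written with 17 significant digits so that
#' write-then-read reproduces the table field-for-field.
#' @param x a `shift_table`.
#' @param path output file path.
#' @export
write_shift_table <- function(x, path) {
  lines <- c("residue\taa\tatom\tshift_ppm",
             sprintf("%d\t%s\t%s\t%.17g", x$residue, x$aa, x$atom,
                     x$shift_ppm))
  writeLines(lines, path)
  invisible(path)
}

#' Read an amide peak list (residue, 1H ppm, 15N ppm)
#'
#' One row per backbone amide; prolines (no amide proton) and unassigned
#' residues are simply absent, never encoded as sentinels.
#' @param source path or connection to a TSV with header
#'   `residue  h_ppm  n_ppm`.
#' @return a `peak_list` data frame with columns `residue`, `h_ppm`, `n_ppm`.
#' @export
read_peak_list <- function(source) {
  lines <- .read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no records in peak list")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("residue", "h_ppm", "n_ppm"))) {
    stop("peak list header must be 'residue\th_ppm\tn_ppm'")
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  parsed <- lapply(seq_along(rows), function(i) {
    f <- rows[[i]]
    if (length(f) != 3L) {
      stop(sprintf("malformed peak-list row at line %d", i + 1L))
    }
    res <- .num_or_na(f[[1L]])
    h <- .num_or_na(f[[2L]])
    n <- .num_or_na(f[[3L]])
    if (is.na(res) || res < 1 || !is.finite(h) || !is.finite(n)) {
      stop(sprintf("malformed peak-list row at line %d", i + 1L))
    }
    c(res, h, n)
  })
  m <- do.call(rbind, parsed)
  pk <- data.frame(residue = as.integer(m[, 1L]), h_ppm = m[, 2L],
                   n_ppm = m[, 3L])
  if (anyDuplicated(pk$residue)) {
    stop(sprintf("duplicate residue %d in peak list",
                 pk$residue[duplicated(pk$residue)][[1L]]))
  }
  pk <- pk[order(pk$residue), , drop = FALSE]
  rownames(pk) <- NULL
  class(pk) <- c("peak_list", "data.frame")
  pk
}

#' @rdname read_peak_list
#' @param x a `peak_list`.
#' @param path output file path.
#' @export
write_peak_list <- function(x, path) {
  lines <- c("residue\th_ppm\tn_ppm",
             sprintf("%d\t%.17g\t%.17g", x$residue, x$h_ppm, x$n_ppm))
  writeLines(lines, path)
  invisible(path)
}

.validate_series <- function(points) {
  if (length(points) < 2L) stop("titration series needs at least 2 points")
  ratios <- vapply(points, function(p) p$l_total / p$p_total, numeric(1))
  points <- points[order(ratios)]
  if (points[[1L]]$l_total != 0) {
    stop("titration series lacks an apo reference point (l_total = 0)")
  }
  apo_res <- points[[1L]]$peaks$residue
  for (i in seq_along(points)[-1L]) {
    extra <- setdiff(points[[i]]$peaks$residue, apo_res)
    if (length(extra)) {
      stop(sprintf("residue %d present at titration point %d but absent from the apo point",
                   extra[[1L]], i))
    }
  }
  class(points) <- "titration_series"
  points
}

#' Read a titration series from a manifest
#'
#' The manifest is a TSV with header `p_total_M  l_total_M  peaklist_path`;
#' peak-list paths are resolved relative to the manifest's directory. Points
#' are sorted by ligand:protein ratio; the first point must be the apo
#' reference (`l_total = 0`), and every residue observed at a later point
#' must be assigned in the apo spectrum.
#'
#' @param manifest path to the manifest TSV.
#' @return a `titration_series`: a list of points, each with `p_total`,
#'   `l_total` (mol/L) and `peaks` (a [read_peak_list()] data frame).
#' @export
read_titration <- function(manifest) {
  lines <- .read_source_lines(manifest)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty titration manifest")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("p_total_M", "l_total_M", "peaklist_path"))) {
    stop("manifest header must be 'p_total_M\tl_total_M\tpeaklist_path'")
  }
  base <- dirname(manifest)
  points <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L) stop(sprintf("malformed manifest row at line %d", i))
    p <- .num_or_na(f[[1L]])
    l <- .num_or_na(f[[2L]])
    if (is.na(p) || p <= 0 || is.na(l) || l < 0) {
      stop(sprintf("malformed manifest row at line %d: bad concentrations", i))
    }
    path <- f[[3L]]
    if (!file.exists(path)) path <- file.path(base, f[[3L]])
    if (!file.exists(path)) {
      stop(sprintf("peak list not found: %s (manifest line %d)", f[[3L]], i))
    }
    list(p_total = p, l_total = l, peaks = read_peak_list(path))
  })
  .validate_series(points)
}

#' Write a titration series as a manifest plus per-point peak lists
#'
#' @param series a `titration_series`.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within `dir`.
#' @return the manifest path, invisibly.
#' @export
write_titration <- function(series, dir, manifest = "manifest.tsv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- character(length(series))
  for (i in seq_along(series)) {
    fn <- sprintf("point_%02d.tsv", i)
    write_peak_list(series[[i]]$peaks, file.path(dir, fn))
    rows[[i]] <- sprintf("%.17g\t%.17g\t%s", series[[i]]$p_total,
                         series[[i]]$l_total, fn)
  }
  path <- file.path(dir, manifest)
  writeLines(c("p_total_M\tl_total_M\tpeaklist_path", rows), path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param source path to an aligned FASTA file.
#' @return named character vector of equal-length uppercase gapped
#'   sequences (gap = `-`), class `alignment`.
#' @export
read_alignment <- function(source) {
  seqs <- seqinr::read.fasta(source, seqtype = "AA", set.attributes = FALSE,
                             forceDNAtolower = FALSE)
  if (length(seqs) < 1L) stop("alignment contains no sequences")
  out <- vapply(seqs, function(s) toupper(paste(s, collapse = "")),
                character(1))
  widths <- nchar(out)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequences have unequal lengths")
  }
  allowed <- c(AA_ALPHABET, "X", "-")
  chars <- unique(strsplit(paste(out, collapse = ""), "")[[1L]])
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    stop(sprintf("invalid symbol(s) in alignment: %s",
                 paste(bad, collapse = ", ")))
  }
  class(out) <- "alignment"
  out
}

#' Write an alignment as aligned FASTA
#' @param aln named character vector of gapped sequences.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  nm <- names(aln)
  if (is.null(nm)) nm <- sprintf("seq%04d", seq_along(aln))
  writeLines(as.vector(rbind(paste0(">", nm), unclass(aln))), path)
  invisible(path)
}

#' Paint per-residue scores into the B-factor column of a PDB file
#'
#' Rewrites only columns 61-66 (the isotropic B-factor) of ATOM/HETATM
#' records; every other byte of the file is preserved, so structures can be
#' coloured by CSP or order parameter in any molecular viewer. Scores are
#' clipped to `[0, 999.99]` and formatted to two decimals.
#'
#' @param infile path to a fixed-column PDB file.
#' @param scores numeric vector of per-residue scores, names = residue
#'   numbers.
#' @param default value for residues without a score.
#' @param outfile optional output path; if given, painted lines are written
#'   there.
#' @return character vector of painted PDB lines, invisibly when `outfile`
#'   is given.
#' @export
paint_structure <- function(infile, scores = numeric(0), default = 0,
                            outfile = NULL) {
  lines <- readLines(infile, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records: not a readable PDB file")
  idx <- which(is_atom)
  resno <- suppressWarnings(as.integer(trimws(substr(lines[idx], 23L, 26L))))
  if (anyNA(resno)) stop("unreadable residue numbers in PDB ATOM records")
  val <- rep(default, length(idx))
  if (length(scores)) {
    hit <- match(as.character(resno), names(scores))
    val[!is.na(hit)] <- scores[hit[!is.na(hit)]]
  }
  val <- pmin(pmax(val, 0), 999.99)
  bcol <- sprintf("%6.2f", val)
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    line <- lines[[i]]
    if (nchar(line) < 66L) line <- formatC(line, width = -66L)
    substr(line, 61L, 66L) <- bcol[[k]]
    lines[[i]] <- line
  }
  if (!is.null(outfile)) {
    writeLines(lines, outfile)
    return(invisible(lines))
  }
  lines
}
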
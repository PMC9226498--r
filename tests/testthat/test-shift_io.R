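test_that("shift-table TSV parsing handles good rows, skips, and errors", {
  path <- write_tmp(shift_tsv_lines(c("1\tA\tH\t8.20",
                                      "2\tG\tH\t8.31",
                                      "3\tL\tH\t8.05")))
  tab <- read_shift_table(path)
  expect_s3_class(tab, "shift_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$residue, 1:3)
  expect_equal(attr(tab, "skipped"), 0L)

  # unsupported atom rows are skipped and counted
  path2 <- write_tmp(shift_tsv_lines(c("1\tA\tH\t8.20", "1\tA\tHB\t1.39")))
  tab2 <- read_shift_table(path2)
  expect_equal(nrow(tab2), 1L)
  expect_equal(attr(tab2, "skipped"), 1L)

  expect_error(read_shift_table(write_tmp(character(0))), "no records")
  expect_error(read_shift_table(write_tmp(shift_tsv_lines(character(0)))),
               "no records")
  expect_error(read_shift_table(
    write_tmp(shift_tsv_lines(c("1\tA\tH\t8.2", "1\tA\tH\t8.3")))),
    "duplicate")
  expect_error(read_shift_table(
    write_tmp(shift_tsv_lines(c("1\tA\tH\t8.2", "2\tA\tH")))),
    "line 3")
  expect_error(read_shift_table(
    write_tmp(shift_tsv_lines("x\tA\tH\t8.2"))), "line 2")
})

test_that("minimal NMR-STAR subset reader extracts the chem-shift loop", {
  star <- c("data_test", "save_shifts", "loop_",
            "_Atom_chem_shift.ID",
            "_Atom_chem_shift.Comp_index_ID",
            "_Atom_chem_shift.Comp_ID",
            "_Atom_chem_shift.Atom_ID",
            "_Atom_chem_shift.Val",
            "1 5 ALA H 8.21",
            "2 5 ALA N 123.4",
            "3 5 ALA HB 1.40",
            "4 6 GLY CA 45.2",
            "stop_", "save_")
  tab <- read_shift_table(write_tmp(star, ".str"), dialect = "nmrstar")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "skipped"), 1L)
  expect_equal(tab$aa[tab$residue == 5][1], "A")
  expect_equal(tab$shift_ppm[tab$atom == "CA"], 45.2)
  expect_error(read_shift_table(write_tmp("data_x", ".str"),
                                dialect = "nmrstar"), "loop")
})

test_that("write-then-read is the identity on shift tables and titrations", {
  tab <- simulate_disorder_shifts("CCHH", amplitude = 1, noise_sd = 0.3,
                                  seed = 11)
  path <- tempfile()
  write_shift_table(tab, path)
  back <- read_shift_table(path, sample_label = attr(tab, "sample_label"))
  expect_identical(back$residue, tab$residue)
  expect_identical(back$atom, tab$atom)
  expect_identical(back$shift_ppm, tab$shift_ppm)

  ser <- simulate_titration(small_titration_spec(seed = 4))
  dir <- tempfile()
  man <- write_titration(ser, dir)
  back <- read_titration(man)
  expect_equal(length(back), length(ser))
  for (i in seq_along(ser)) {
    expect_identical(back[[i]]$peaks$h_ppm, ser[[i]]$peaks$h_ppm)
    expect_identical(back[[i]]$l_total, ser[[i]]$l_total)
  }
})

test_that("titration manifests are validated and sorted", {
  ser <- simulate_titration(small_titration_spec(seed = 4))
  dir <- tempfile()
  write_titration(ser, dir)

  # shuffle the manifest rows: reader must return ascending ratios
  man <- file.path(dir, "manifest.tsv")
  lines <- readLines(man)
  writeLines(c(lines[1], rev(lines[-1])), man)
  back <- read_titration(man)
  ratios <- vapply(back, function(p) p$l_total / p$p_total, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(back[[1]]$l_total, 0)

  # drop the apo point -> error
  writeLines(lines[-2], man)
  expect_error(read_titration(man), "apo")

  # residue missing from apo -> error naming it
  write_titration(ser, dir)
  apo <- ser[[1]]$peaks[-1, ]
  write_peak_list(apo, file.path(dir, "point_01.tsv"))
  expect_error(read_titration(man),
               as.character(ser[[1]]$peaks$residue[1]))
})

test_that("aligned FASTA reading validates width and alphabet", {
  path <- write_tmp(c(">a", "acd-efghikLMN", ">b", "ACDWEFGHIKLMN"), ".afa")
  aln <- read_alignment(path)
  expect_length(aln, 2L)
  expect_equal(unique(nchar(aln)), 13L)
  expect_equal(aln[["a"]], "ACD-EFGHIKLMN")  # uppercased

  ragged <- write_tmp(c(">a", "ACDEF", ">b", "ACD"), ".afa")
  expect_error(read_alignment(ragged), "ragged")
  badsym <- write_tmp(c(">a", "AC*EF"), ".afa")
  expect_error(read_alignment(badsym), "invalid symbol")

  # round trip preserves names, width and content
  out <- tempfile(fileext = ".afa")
  write_alignment(aln, out)
  expect_identical(unclass(read_alignment(out)), unclass(aln))
})

test_that("paint_structure rewrites only the B-factor column", {
  pdb <- write_tmp(tiny_pdb_lines(), ".pdb")
  painted <- paint_structure(pdb, scores = c("1" = 0.5, "2" = 1e6))
  orig <- readLines(pdb)
  atom <- startsWith(orig, "ATOM")
  # non-ATOM lines untouched
  expect_identical(painted[!atom], orig[!atom])
  # every byte outside columns 61-66 is untouched
  strip <- function(x) paste0(substr(x, 1, 60), substr(x, 67, nchar(x)))
  expect_identical(strip(painted[atom]), strip(orig[atom]))
  b <- as.numeric(substr(painted[atom], 61, 66))
  resno <- as.integer(substr(painted[atom], 23, 26))
  expect_equal(unique(b[resno == 1]), 0.50)
  expect_equal(unique(b[resno == 2]), 999.99)  # clipped
  expect_equal(unique(b[resno == 3]), 0)       # default

  # no scores: B = default everywhere, everything else identical
  painted2 <- paint_structure(pdb, default = 7.25)
  expect_identical(strip(painted2[atom]), strip(orig[atom]))
  expect_equal(unique(as.numeric(substr(painted2[atom], 61, 66))), 7.25)

  expect_error(paint_structure(write_tmp("not a pdb")), "ATOM")
})
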
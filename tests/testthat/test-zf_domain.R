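test_that("the CLAMP-like finger is annotated with the published anchoring", {
  fr <- clamp_zf_fragment()
  anns <- annotate_c2h2(fr$seq, fr$start)
  expect_length(anns, 1L)
  ann <- anns[[1]]
  expect_equal(ann$helix_start, 139L)
  expect_equal(ann$his2, 149L)        # the coordinating histidine H149
  expect_equal(ann$start, 127L)
  expect_equal(ann$end, 153L)

  # all nine published helix-relative labels from helix_start = 139
  labels <- c(`138` = -1L, `139` = 1L, `141` = 3L, `142` = 4L, `143` = 5L,
              `144` = 6L, `146` = 8L, `147` = 9L, `150` = 12L)
  got <- vapply(as.integer(names(labels)), helix_position, integer(1),
                annotation = ann)
  expect_equal(got, unname(labels))
})

test_that("motif scanning handles negatives and tandem fingers", {
  expect_length(annotate_c2h2(strrep("A", 40)), 0L)
  expect_error(annotate_c2h2("ACDEF"), "too short")

  # two concatenated canonical fingers, non-overlapping, in order
  finger <- "CPECGKSFSQSSNLQKHQRTH"
  tandem <- paste0("MA", finger, "TGEKP", finger, "GG")
  anns <- annotate_c2h2(tandem, start_residue = 1L)
  expect_length(anns, 2L)
  expect_lt(anns[[1]]$end, anns[[2]]$start)
  expect_equal(anns[[2]]$his1 - anns[[1]]$his1,
               nchar(finger) + nchar("TGEKP"))
  for (a in anns) {
    expect_true(a$cys1 < a$cys2 && a$cys2 < a$his1 && a$his1 < a$his2)
    expect_true(a$helix_start <= a$his1 && a$his1 <= a$helix_end)
  }
})

test_that("helix_position and residue_at_position are mutually inverse", {
  ann <- annotate_c2h2(clamp_zf_fragment()$seq, 127L)[[1]]
  for (r in ann$start:ann$end) {
    pos <- helix_position(r, ann)
    expect_true(pos != 0L)
    expect_equal(residue_at_position(ann, pos), r)
  }
  expect_error(helix_position(126L, ann), "outside")
  expect_error(residue_at_position(ann, 0L), "0")
  expect_error(residue_at_position(ann, 99L), "outside")
})

test_that("DNA-binding positions are the five canonical keys", {
  ann <- annotate_c2h2(clamp_zf_fragment()$seq, 127L)[[1]]
  dnb <- dna_binding_residues(ann)
  expect_equal(dnb$position, c(-1L, 1L, 2L, 3L, 6L))
  expect_equal(dnb$residue, c(138L, 139L, 140L, 141L, 144L))
  expect_equal(dnb$aa[dnb$position == -1], "H")   # H138
  expect_equal(dnb$aa[dnb$position == 1], "L")    # L139
  expect_equal(dnb$aa[dnb$position == 3], "L")    # L141
  expect_equal(dnb$aa[dnb$position == 6], "A")    # A144

  # synthetic finger: helix positions are plain arithmetic on helix_start
  ann10 <- annotate_c2h2("CPECGKSFSQSSNLQKHQRTH", 1L)[[1]]
  dnb10 <- dna_binding_residues(ann10)
  hs <- ann10$helix_start
  expect_equal(dnb10$residue, c(hs - 1L, hs, hs + 1L, hs + 2L, hs + 5L))
})

test_that("profile probabilities follow the pseudocount formula", {
  aln <- structure(c(a = "AC", b = "AD"), class = "alignment")
  prof0 <- build_profile(aln, lambda = 0)
  expect_equal(unname(prof0$probs["A", 1]), 1)
  expect_equal(colSums(prof0$probs), c(1, 1))

  prof1 <- build_profile(aln, lambda = 1)
  expect_equal(unname(prof1$probs["A", 1]), (2 + 0.05) / 3, tolerance = 1e-12)
  expect_equal(unname(prof1$probs["C", 2]), (1 + 0.05) / 3, tolerance = 1e-12)
  expect_true(all(prof1$probs > 0))
  expect_equal(colSums(prof1$probs), c(1, 1))

  # gaps excluded from counts; all-gap columns fall back to background
  gappy <- structure(c(a = "A-", b = "A-"), class = "alignment")
  pg <- build_profile(gappy, lambda = 0)
  expect_equal(pg$flagged_columns, 2L)
  expect_equal(pg$probs[, 2], pg$background)

  expect_error(build_profile(character(0)), "empty")
  expect_error(build_profile(aln, background = rep(0.1, 5)), "length-20")
})

test_that("information content behaves like a relative entropy", {
  unif <- structure(sapply(AA_ALPHABET, function(a) a), class = "alignment")
  prof <- build_profile(unif, lambda = 0)   # 20 seqs, 1 column, uniform
  expect_equal(information_content(prof), 0)

  point <- build_profile(structure("W", class = "alignment"), lambda = 0)
  expect_equal(information_content(point), log2(20), tolerance = 1e-12)

  # IC >= 0 on random profiles
  ps <- profile_spec(lapply(1:5, function(i) {
    p <- rexp(20); p / sum(p)
  }), 100, seed = 41)
  prof <- build_profile(sample_alignment(ps))
  expect_true(all(information_content(prof) >= 0))
})

test_that("atypicality log-odds match hand arithmetic", {
  # profile with known probabilities at the five mapped columns
  probs <- matrix(0.05, 20, 5, dimnames = list(AA_ALPHABET, NULL))
  probs["H", 1] <- 0.01; probs["A", 1] <- 0.09   # renormalised row pair
  prof <- structure(list(probs = probs, background = setNames(rep(0.05, 20),
                                                              AA_ALPHABET),
                         lambda = 0, flagged_columns = integer(0)),
                    class = "position_profile")
  ann <- annotate_c2h2(clamp_zf_fragment()$seq, 127L)[[1]]  # -1 residue is H
  cmap <- setNames(1:5, c("-1", "1", "2", "3", "6"))
  sc <- atypicality_score(ann, prof, cmap, n_null = 200, seed = 3)
  expect_equal(sc$per_position$log_odds[1], log2(0.01 / 0.05),
               tolerance = 1e-12)
  expect_equal(sc$per_position$log_odds[1], -2.3219, tolerance = 1e-4)
  # positions whose residue probability equals background score 0
  expect_equal(sc$per_position$log_odds[2:5], rep(0, 4))
  expect_equal(sc$total, sum(sc$per_position$log_odds))
  expect_error(atypicality_score(ann, prof, cmap[1:3], seed = 1), "position")
})

test_that("the most probable finger maximises the atypicality total", {
  ps <- profile_spec(lapply(1:21, function(i) {
    p <- rexp(20)^2; p / sum(p)
  }), 400, seed = 77)
  aln <- sample_alignment(ps)
  prof <- build_profile(aln, lambda = 1)
  # build a query carrying the columnwise argmax at every mapped position
  cmap <- setNames(c(5, 6, 7, 8, 11), c("-1", "1", "2", "3", "6"))
  ann <- annotate_c2h2("CPECGKSFSQSSNLQKHQRTH", 1L)[[1]]
  best_aa <- rownames(prof$probs)[apply(prof$probs[, cmap], 2, which.max)]
  seqv <- strsplit(ann$seq, "")[[1]]
  for (i in seq_along(cmap)) {
    r <- residue_at_position(ann, as.integer(names(cmap)[i]))
    seqv[r - ann$start + 1] <- best_aa[i]
  }
  ann$seq <- paste(seqv, collapse = "")
  best <- atypicality_score(ann, prof, cmap, n_null = 100, seed = 1)$total
  # any single substitution at a mapped position scores no higher
  for (i in seq_along(cmap)) {
    r <- residue_at_position(ann, as.integer(names(cmap)[i]))
    for (a in c("A", "W", "K")) {
      v <- strsplit(ann$seq, "")[[1]]
      v[r - ann$start + 1] <- a
      alt <- ann
      alt$seq <- paste(v, collapse = "")
      sc <- atypicality_score(alt, prof, cmap, n_null = 100, seed = 1)$total
      expect_lte(sc, best + 1e-12)
    }
  }
})

test_that("null atypicality percentiles are uniform on (0, 1)", {
  ps <- profile_spec(lapply(1:21, function(i) {
    p <- rexp(20); p / sum(p)
  }), 500, seed = 88)
  prof <- build_profile(sample_alignment(ps), lambda = 1)
  cmap <- setNames(c(5, 6, 7, 8, 11), c("-1", "1", "2", "3", "6"))
  ann0 <- annotate_c2h2("CPECGKSFSQSSNLQKHQRTH", 1L)[[1]]

  set.seed(99)
  pct <- vapply(1:2000, function(i) {
    v <- strsplit(ann0$seq, "")[[1]]
    for (j in seq_along(cmap)) {
      r <- residue_at_position(ann0, as.integer(names(cmap)[j]))
      v[r - ann0$start + 1] <- sample(AA_ALPHABET, 1,
                                      prob = prof$probs[, cmap[j]])
    }
    ann <- ann0
    ann$seq <- paste(v, collapse = "")
    atypicality_score(ann, prof, cmap, n_null = 400, seed = i)$percentile
  }, numeric(1))
  expect_gt(stats::ks.test(pct, "punif")$p.value, 0.01)
})
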
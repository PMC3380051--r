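uniform_matrix <- function(frame = 4, value = 1) {
  grid <- tidyr::expand_grid(terminus = c("N", "C"),
                             offset = seq.int(-frame, frame),
                             aa = c("A", "C", "D", "E", "F", "G", "H", "I",
                                    "K", "L", "M", "N", "P", "Q", "R", "S",
                                    "T", "V", "W", "Y"))
  grid$score <- value
  structure(grid, class = c("pref_matrix", class(grid)),
            frame = as.integer(frame), mode = "integer")
}

test_that("preference matrix covers all amino acids over both frames", {
  ds <- small_dataset(n_proteins = 8, seed = 31)
  pm <- build_preference_matrix(ds$proteins, ds$annotations, frame = 4)
  expect_equal(nrow(pm), 20L * 2L * 9L)
  expect_setequal(unique(pm$score), c(-1, 1))
  expect_equal(attr(pm, "frame"), 4L)

  lo <- build_preference_matrix(ds$proteins, ds$annotations, mode = "logodds")
  expect_true(all(is.finite(lo$score)))
})

test_that("a residue enriched at a boundary position scores +1 there", {
  set.seed(32)
  seqs <- vapply(1:10, function(i) random_seq(80, 320 + i), character(1))
  # force every TM region to start with L
  seqs <- paste0(substr(seqs, 1, 29), "L", substr(seqs, 31, 80))
  prot <- tibble::tibble(id = paste0("p", 1:10), sequence = seqs)
  ann <- tibble::tibble(id = prot$id, start = 30L, end = 50L, label = "TM")
  pm <- build_preference_matrix(prot, ann)
  expect_equal(pm$score[pm$terminus == "N" & pm$offset == 0 & pm$aa == "L"], 1)
})

test_that("integer scores on random sequences show no systematic sign", {
  set.seed(33)
  prot <- tibble::tibble(id = paste0("p", 1:40),
                         sequence = vapply(1:40, function(i)
                           random_seq(120, 500 + i), character(1)))
  ann <- tibble::tibble(id = prot$id, start = 41L, end = 63L, label = "TM")
  pm <- build_preference_matrix(prot, ann)
  # 360 ±1 scores; with no composition signal the positive fraction stays
  # within binomial noise of 1/2 (the > comparison gives a mild minus bias
  # for letters absent from a column, so the band is generous)
  frac_pos <- mean(pm$score > 0)
  expect_gt(frac_pos, 0.25)
  expect_lt(frac_pos, 0.75)
})

test_that("candidate enumeration uses the stretch window terminals", {
  stretch <- tibble::tibble(id = "btl", first = 213L, last = 227L,
                            n_windows = 15L, span_start = 213L,
                            span_end = 246L)
  cand <- enumerate_candidates(stretch)
  expect_setequal(unique(cand$start), 213:227)
  expect_setequal(unique(cand$end), 232:246)
  expect_equal(nrow(cand), 225L)          # all 15 x 15 pairs have start < end
  expect_true(any(cand$start == 220 & cand$end == 238))

  one <- enumerate_candidates(tibble::tibble(first = 5L, last = 5L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 5L)
  expect_equal(one$end, 24L)
})

test_that("candidate scoring matches a brute-force position sum", {
  seq1 <- random_seq(80, 41)
  pm <- build_preference_matrix(
    tibble::tibble(id = "p", sequence = seq1),
    tibble::tibble(id = "p", start = 30L, end = 52L, label = "TM"))
  cand <- tibble::tibble(start = c(25L, 31L, 28L), end = c(50L, 55L, 47L))
  got <- score_candidates(cand, seq1, pm)
  ch <- strsplit(seq1, "")[[1]]
  brute <- function(s, e) {
    tot <- 0
    for (p in -4:4) {
      tot <- tot + pm$score[pm$terminus == "N" & pm$offset == p &
                              pm$aa == ch[s + p]]
      tot <- tot + pm$score[pm$terminus == "C" & pm$offset == p &
                              pm$aa == ch[e + p]]
    }
    tot
  }
  for (i in seq_len(nrow(got))) {
    expect_equal(got$score[i], brute(got$start[i], got$end[i]))
  }

  # the all-(+1) matrix scores every full-frame candidate at 2*(2f+1)
  all1 <- score_candidates(cand, seq1, uniform_matrix(value = 1))
  expect_true(all(all1$score == 18))
  # an uninformative all-zero matrix scores 0
  all0 <- score_candidates(cand, seq1, uniform_matrix(value = 0))
  expect_true(all(all0$score == 0))

  expect_warning(
    score_candidates(tibble::tibble(start = 2L, end = 40L), seq1, pm),
    "frame exceeds")
})

test_that("final selection ranks qualifying candidates and falls back cleanly", {
  region <- tibble::tibble(start = 221L, end = 238L)

  # crafted scores: (220, 238) strictly highest among qualifying candidates
  scored <- tibble::tibble(
    start = c(220L, 213L, 215L, 226L),
    end = c(238L, 246L, 230L, 239L),
    score = c(13, 12, 11, 9)) |>
    dplyr::arrange(dplyr::desc(score))
  fin <- select_final(scored, region)
  expect_equal(c(fin$start, fin$end), c(220L, 238L))
  expect_equal(fin$source, "refined")

  # every candidate violating the length bounds -> initial region returned
  bad_len <- tibble::tibble(start = c(220L, 221L), end = c(230L, 231L),
                            score = c(5, 4))
  fb <- select_final(bad_len, region)
  expect_equal(c(fb$start, fb$end), c(221L, 238L))
  expect_equal(fb$source, "initial")

  # equal scores: the longer candidate wins (ordering from score_candidates)
  seq1 <- random_seq(80, 77)
  tie <- score_candidates(tibble::tibble(start = c(30L, 30L),
                                         end = c(50L, 48L)),
                          seq1, uniform_matrix(value = 1))
  expect_equal(tie$end[1], 50L)

  expect_warning(fb2 <- select_final(tie[0, ], region), "falling back")
  expect_equal(fb2$source, "initial")

  # the refined region always covers the central region's midpoint
  set.seed(44)
  for (i in 1:8) {
    sc <- tibble::tibble(start = sample(210:225, 12, TRUE),
                         end = sample(230:248, 12, TRUE),
                         score = sample(-5:15, 12, TRUE)) |>
      dplyr::arrange(dplyr::desc(score))
    fin_i <- select_final(sc, region)
    if (fin_i$source == "refined") {
      mid <- (region$start + region$end) / 2
      expect_true(fin_i$start <= mid && fin_i$end >= mid)
      expect_true(fin_i$end - fin_i$start + 1 >= 17 &&
                    fin_i$end - fin_i$start + 1 <= 25)
    }
  }
})

test_that("preference matrix TSV round trip preserves scores", {
  ds <- small_dataset(n_proteins = 6, seed = 34)
  pm <- build_preference_matrix(ds$proteins, ds$annotations)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_preference_matrix(pm, f)
  back <- read_preference_matrix(f)
  merged <- dplyr::inner_join(tibble::as_tibble(pm), tibble::as_tibble(back),
                              by = c("terminus", "offset", "aa"))
  expect_equal(nrow(merged), nrow(pm))
  expect_equal(merged$score.x, merged$score.y)
})
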
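test_that("windowed composition counts only the target amino acid", {
  expect_equal(composition("AAAAAAAAGGGGGGGGGGGG", "A"), 0.40)
  expect_equal(composition("QQQQQ", "Q"), 1.0)
  expect_equal(composition("AXAX", "A"), 0.5)  # X lengthens, never counts
  expect_equal(composition("AXAX", "X"), 0)
  expect_error(composition("", "A"), "empty")
})

test_that("linear dispersion is 1 for even spacing and penalizes clustering", {
  expect_equal(linear_dispersion("AGAGAGAGAG", "A"), 1.0)
  expect_equal(linear_dispersion("GGGGGGGGGG", "A"), 1.0)  # k < 2
  expect_equal(linear_dispersion("AAAAAAAAAA", "A"), 1.0)  # k = W
  # contiguous run = the most clustered arrangement
  expect_equal(linear_dispersion("AAAAAGGGGGGGGGGGGGGG", "A"), 0)
  expect_equal(linear_dispersion(strrep("AAAG", 5), "A"),
               oracle_dispersion(strrep("AAAG", 5), "A"))
})

test_that("dispersion matches the brute-force placement-enumeration oracle", {
  set.seed(401)
  for (rep in 1:25) {
    W <- sample(8:20, 1)
    k <- sample(2:min(6, W), 1)
    pos <- sort(sample(W, k))
    chars <- rep("G", W)
    chars[pos] <- "A"
    win <- paste(chars, collapse = "")
    expect_equal(linear_dispersion(win, "A"), oracle_dispersion(win, "A"),
                 tolerance = 1e-12)
  }
})

test_that("passing windows match spec examples", {
  spec <- lcd_class_spec("Q")
  expect_identical(find_passing_windows(strrep("Q", 25), spec), 1:6)
  expect_length(find_passing_windows("ACDEFGHIKLMNPQRSTVWY", spec), 0)
  expect_length(find_passing_windows("QQQ", spec), 0)  # shorter than W
})

test_that("passing windows equal the exhaustive per-window oracle", {
  set.seed(402)
  freq_sets <- list(background_freqs("uniform"),
                    background_freqs("falciparum-like"))
  specs <- c(all_class_specs(c("N", "Q", "K", "A")),
             all_class_specs(c("NK", "KN", "QN", "HQ")))
  for (rep in 1:6) {
    L <- sample(40:200, 1)
    seqstr <- random_sequence(L, freq_sets[[1 + rep %% 2]])
    for (spec in specs) {
      expect_identical(find_passing_windows(seqstr, spec),
                       oracle_passing_windows(seqstr, spec))
    }
  }
})

test_that("window merging unions overlapping spans", {
  m <- merge_windows(c(1, 2, 3), 20)
  expect_equal(m, data.frame(start = 1L, end = 22L))
  m <- merge_windows(c(1, 50), 20)
  expect_equal(m, data.frame(start = c(1L, 50L), end = c(20L, 69L)))
  expect_equal(nrow(merge_windows(integer(0), 20)), 0)
  expect_error(merge_windows(c(3, 1), 20), "sorted")
  # random start sets against the residue-set-union oracle
  set.seed(403)
  for (rep in 1:30) {
    W <- sample(3:20, 1)
    starts <- sort(sample(100, sample(1:15, 1)))
    expect_equal(merge_windows(starts, W),
                 oracle_merge_intervals(starts, W),
                 ignore_attr = TRUE)
  }
})

test_that("scan_protein reports merged domains with span compositions", {
  pr <- scan_protein(strrep("Q", 60), lcd_class_spec("Q"))
  expect_equal(nrow(pr), 1)
  expect_equal(pr$start, 1L)
  expect_equal(pr$end, 60L)
  expect_equal(pr$primary_comp, 1.0)
  expect_equal(pr$sequence, strrep("Q", 60))

  expect_equal(nrow(scan_protein(strrep("A", 19), lcd_class_spec("A"))), 0)

  s <- paste0("M", strrep("HQ", 15), strrep("L", 30))
  got <- scan_protein(s, lcd_class_spec("H", "Q"))
  want <- oracle_lcd_intervals(s, lcd_class_spec("H", "Q"))
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # the merged span covers the planted repeat region
  expect_true(got$start[1] <= 2 && got$end[nrow(got)] >= 25)
})

test_that("proteome scan equals independent per-class scans", {
  p <- proteome("T1", c(p1 = strrep("N", 40)))
  lc <- scan_proteome(p, all_class_specs())
  # direct per-class rescan must agree class by class
  for (lab in unique(lc$class_label)) {
    spec <- all_class_specs(lab)[[1]]
    solo <- scan_protein(strrep("N", 40), spec, "p1")
    expect_equal(lc[lc$class_label == lab, c("start", "end")],
                 solo[, c("start", "end")], ignore_attr = TRUE)
  }
  # N primary present; no secondary class (no second residue at 20%)
  expect_true("N" %in% lc$class_label)
  expect_false(any(nchar(lc$class_label) == 2))

  expect_equal(nrow(scan_proteome(proteome("E", character(0)))), 0)
})

test_that("scanning recovers planted LCDs and never overlaps intervals", {
  gp <- generate_planted_proteome(30, "HQ", 6, c(60, 150), seed = 42,
                                  proteome_id = "PLT")
  lc <- scan_proteome(gp$proteome, all_class_specs(c("HQ", "H", "Q")))
  tr <- gp$truth$planted
  for (i in seq_len(nrow(tr))) {
    hit <- lc$class_label == "HQ" & lc$accession == tr$accession[i] &
      lc$start <= tr$end[i] & lc$end >= tr$start[i]
    expect_true(any(hit))
  }
  # intervals for one (protein, class) never overlap
  for (key in split(seq_len(nrow(lc)),
                    paste(lc$accession, lc$class_label))) {
    iv <- lc[key, , drop = FALSE]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1)
      expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
  }
})

test_that("scanning is deterministic and monotone in thresholds", {
  set.seed(405)
  seqstr <- random_sequence(300, background_freqs("falciparum-like"))
  lc1 <- scan_protein(seqstr, lcd_class_spec("N", "K"))
  lc2 <- scan_protein(seqstr, lcd_class_spec("N", "K"))
  expect_identical(lc1, lc2)
  # raising any threshold never adds passing windows
  base <- find_passing_windows(seqstr, lcd_class_spec("N", "K",
    primary_threshold = 0.30, secondary_threshold = 0.20,
    dispersion_threshold = 0.3))
  for (c1 in c(0.35, 0.40, 0.50)) {
    tighter <- find_passing_windows(seqstr, lcd_class_spec("N", "K",
      primary_threshold = c1, secondary_threshold = 0.20,
      dispersion_threshold = 0.3))
    expect_true(all(tighter %in% base))
    base_c <- tighter
  }
  for (delta in c(0.4, 0.5, 0.7)) {
    tighter <- find_passing_windows(seqstr, lcd_class_spec("N", "K",
      primary_threshold = 0.30, secondary_threshold = 0.20,
      dispersion_threshold = delta))
    expect_true(all(tighter %in% base))
  }
})
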
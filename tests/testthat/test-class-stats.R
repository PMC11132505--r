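make_lcd_rows <- function(...) {
  rows <- list(...)
  if (!length(rows))
    return(data.frame(proteome_id = character(0), accession = character(0),
                      class_label = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0), primary_comp = numeric(0),
                      secondary_comp = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(rows, function(r)
    data.frame(proteome_id = "T", accession = r[[1]], class_label = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               length = as.integer(r[[4]]) - as.integer(r[[3]]) + 1L,
               sequence = "", primary_comp = NA_real_,
               secondary_comp = NA_real_, stringsAsFactors = FALSE)))
}

two_prot <- proteome("T", c(p1 = strrep("Q", 40), p2 = strrep("A", 60)))

test_that("class count tables use interval-union residue semantics", {
  tab <- count_class_table(empty <- make_lcd_rows()[0, ], two_prot)
  expect_equal(nrow(tab), 0)
  expect_equal(attr(tab, "n_proteins_total"), 2)
  expect_equal(attr(tab, "n_residues_total"), 100)

  tab <- count_class_table(make_lcd_rows(list("p1", "Q", 1, 20)), two_prot)
  expect_equal(tab$n_lcd_residues, 20L)
  expect_equal(tab$n_proteins_with_lcd, 1L)

  # overlapping LCDs of the same class count each residue once
  tab <- count_class_table(make_lcd_rows(list("p1", "Q", 1, 20),
                                         list("p1", "Q", 11, 30)),
                           two_prot)
  expect_equal(tab$n_lcd_residues, 30L)
  expect_equal(tab$n_lcds, 2L)
  expect_equal(tab$n_proteins_with_lcd, 1L)

  expect_error(count_class_table(make_lcd_rows(list("nope", "Q", 1, 20)),
                                 two_prot), "absent")
})

test_that("organism-level frequency counts organisms with >= 1 LCD", {
  mk <- function(has_hq) {
    lc <- if (has_hq) make_lcd_rows(list("p1", "HQ", 1, 20)) else
      make_lcd_rows()[0, ]
    count_class_table(lc, two_prot)
  }
  tables <- list(mk(TRUE), mk(TRUE), mk(FALSE), mk(FALSE))
  fr <- organism_level_frequency(tables, c("HQ", "NK"))
  expect_equal(unname(fr["HQ"]), 50.0)
  expect_equal(unname(fr["NK"]), 0.0)
  # invariant to organism ordering
  expect_equal(organism_level_frequency(rev(tables), c("HQ", "NK")), fr)
  expect_error(organism_level_frequency(list()), "empty")
})

test_that("rarity bins follow the printed boundaries and partition [0,100]", {
  expect_equal(rarity_category(0), "absent")
  expect_equal(rarity_category(5), "rare")       # lower bound inclusive
  expect_equal(rarity_category(75), "very common")
  expect_equal(rarity_category(c(0.01, 4.99, 19.99, 49.9, 74.9, 100)),
               c("very rare", "very rare", "rare", "normal", "common",
                 "very common"))
  expect_error(rarity_category(-1), "\\[0, 100\\]")
  # every grid value falls in exactly one bin
  grid <- seq(0, 100, by = 0.25)
  cats <- rarity_category(grid)
  expect_true(all(cats %in% c("absent", "very rare", "rare", "normal",
                              "common", "very common")))
  expect_equal(length(cats), length(grid))
})

test_that("per-residue occupancy is the unioned percentage of the proteome", {
  tab <- count_class_table(make_lcd_rows(list("p1", "Q", 1, 20)), two_prot)
  expect_equal(per_residue_occupancy(tab, "Q"), 100 * 20 / 100)
  expect_equal(per_residue_occupancy(tab, "NK"), 0)
  solo <- proteome("S", c(p1 = strrep("Q", 40)))
  tab2 <- count_class_table(make_lcd_rows(list("p1", "Q", 1, 40)), solo)
  expect_equal(per_residue_occupancy(tab2, "Q"), 100)
})

test_that("secondary shares normalize to 100 within a primary class", {
  lc <- rbind(make_lcd_rows(list("p1", "HQ", 1, 20)),
              make_lcd_rows(list("p1", "HQ", 40, 60))[0, ],
              make_lcd_rows(list("p2", "HQ", 1, 20)),
              make_lcd_rows(list("p2", "HQ", 30, 50)),
              make_lcd_rows(list("p1", "HP", 21, 40)))
  tab <- count_class_table(lc, two_prot)
  sh <- secondary_share(tab, "H")
  expect_equal(unname(sh["HQ"]), 75.0)
  expect_equal(unname(sh["HP"]), 25.0)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  # undefined, not zero, when no secondary LCD with that primary exists
  expect_null(secondary_share(tab, "W"))
})

test_that("domain-specific classes use strict printed inequalities", {
  freqs <- list(
    Eukaryota = c(HQ = 16.0, NK = 30.0, GG = 15.0),
    Archaea = c(HQ = 1.0, NK = 2.0, GG = 0),
    Bacteria = c(HQ = 0.0, NK = 1.0, GG = 0),
    Viruses = c(HQ = 1.9, NK = 0.5, GG = 0))
  got <- domain_specific_classes(freqs, "Eukaryota")
  expect_true("HQ" %in% got)     # 16 > 15, all others < 2
  expect_false("NK" %in% got)    # archaea at 2.0 is not < 2
  expect_false("GG" %in% got)    # 15.0 is not > 15
  expect_error(domain_specific_classes(freqs["Eukaryota"], "Eukaryota"),
               "other domain")
})

test_that("co-occurrence counts merge reciprocal classes UpSet-style", {
  lc <- rbind(make_lcd_rows(list("k1", "CS", 1, 20)),
              make_lcd_rows(list("k1", "SC", 30, 50)))
  got <- co_occurrence_counts(lc)
  expect_equal(got$combination, "CS|SC")
  expect_equal(got$n_proteins, 1L)

  lc <- rbind(make_lcd_rows(list("a", "CR", 1, 20), list("a", "CS", 30, 50)),
              make_lcd_rows(list("b", "CR", 1, 20), list("b", "SC", 30, 50)),
              make_lcd_rows(list("c", "CS", 1, 20)))
  got <- co_occurrence_counts(lc)
  expect_equal(got$n_proteins[got$combination == "CR|RC+CS|SC"], 2L)
  expect_equal(got$n_proteins[got$combination == "CS|SC"], 1L)

  # random tables match brute-force per-protein set enumeration
  set.seed(77)
  labs <- c("CS", "SC", "CR", "CT", "TC")
  lc <- do.call(rbind, lapply(1:40, function(i)
    make_lcd_rows(list(paste0("p", sample(8, 1)), sample(labs, 1),
                       1, 20))))
  got <- co_occurrence_counts(lc)
  brute <- table(vapply(split(lc$class_label, lc$accession), function(cl)
    paste(sort(unique(reciprocal_label(cl))), collapse = "+"),
    character(1)))
  expect_equal(got$n_proteins[match(names(brute), got$combination)],
               as.integer(brute))
})

test_that("spatial distinctness needs min_outside residues beyond the other span", {
  a <- list(accession = "p", start = 1, end = 30)
  expect_false(spatially_distinct(a, list(accession = "p", start = 5,
                                          end = 25)))
  expect_true(spatially_distinct(list(accession = "p", start = 1, end = 20),
                                 list(accession = "p", start = 21,
                                      end = 40)))
  expect_true(spatially_distinct(a, list(accession = "p", start = 25,
                                         end = 50)))  # 26 outside
  # 25..49 has only 19 residues outside 1..30: one short of the default
  expect_false(spatially_distinct(a, list(accession = "p", start = 25,
                                          end = 49)))
  expect_error(spatially_distinct(a, list(accession = "q", start = 1,
                                          end = 40)), "same protein")
})

test_that("max single-clan share respects the annotation floor", {
  clan_map <- c(p1 = "CL0001", p2 = "CL0001", p3 = "CL0001",
                p4 = "CL0001", p5 = "CL0001", p6 = "CL0001",
                p7 = "CL0002", p8 = "CL0002", p9 = "CL0003",
                p10 = "CL0004")
  expect_equal(max_single_clan_share(paste0("p", 1:10), as.list(clan_map)),
               60.0)
  expect_true(is.na(max_single_clan_share(paste0("p", 1:4),
                                          as.list(clan_map))))
  # unannotated proteins stay out of the denominator
  expect_equal(max_single_clan_share(c(paste0("p", 1:10), "px", "py"),
                                     as.list(clan_map)), 60.0)
  # random maps match brute-force per-clan counting
  set.seed(88)
  for (rep in 1:10) {
    accs <- paste0("a", 1:20)
    cm <- as.list(stats::setNames(sample(paste0("CL", 1:4), 20,
                                         replace = TRUE), accs))
    drop <- sample(accs, 5)
    cm[drop] <- NULL
    got <- max_single_clan_share(accs, cm)
    annotated <- setdiff(accs, drop)
    brute <- 100 * max(table(unlist(cm[annotated]))) / length(annotated)
    expect_equal(got, brute)
  }
})

test_that("domain mean occupancy averages per-organism percentages", {
  t1 <- count_class_table(make_lcd_rows(list("p1", "Q", 1, 20)), two_prot)
  solo <- proteome("S", c(p1 = strrep("Q", 40)))
  t2 <- count_class_table(make_lcd_rows(list("p1", "Q", 1, 40)), solo)
  # unweighted mean of 20% and 100%, not pooled 60/140
  expect_equal(mean_occupancy(list(t1, t2), "Q"), 60)
})
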
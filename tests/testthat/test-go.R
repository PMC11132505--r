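write_obo <- function(lines) {
  f <- withr::local_tempfile(fileext = ".obo",
                             .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", "", lines), f)
  f
}

term <- function(id, name = id, isa = NULL, obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    "namespace: biological_process",
    if (obsolete) "is_obsolete: true",
    vapply(isa, function(p) paste0("is_a: ", p, " ! x"), character(1)),
    "")
}

test_that("ontology loading computes longest-path depths", {
  f <- write_obo(c(term("GO:1"), term("GO:2", isa = "GO:1"),
                   term("GO:3", isa = "GO:2")))
  ont <- load_ontology(f)
  expect_equal(ont$terms$depth[match(c("GO:1", "GO:2", "GO:3"),
                                     ont$terms$go_id)], c(0, 1, 2))
  # diamond: paths of length 2 and 3 -> depth 3 (longest), level 2
  f <- write_obo(c(term("GO:1"), term("GO:2", isa = "GO:1"),
                   term("GO:3", isa = "GO:2"),
                   term("GO:4", isa = c("GO:2", "GO:3"))))
  ont <- load_ontology(f)
  i <- match("GO:4", ont$terms$go_id)
  expect_equal(ont$terms$depth[i], 3)
  expect_equal(ont$terms$level[i], 2)
  expect_equal(ont$terms$depth[i],
               oracle_longest_path(ont$parents, "GO:4"))
  # obsolete terms skipped; dangling is_a dropped with a warning
  f <- write_obo(c(term("GO:1"), term("GO:9", obsolete = TRUE),
                   term("GO:2", isa = c("GO:1", "GO:404"))))
  expect_warning(ont <- load_ontology(f), "unknown term")
  expect_false("GO:9" %in% ont$terms$go_id)
  # cycles are a format error
  f <- write_obo(c(term("GO:1", isa = "GO:2"), term("GO:2", isa = "GO:1")))
  expect_error(load_ontology(f), "cycle")
})

test_that("GAF loading restricts to the proteome and honours NOT", {
  p <- proteome("G", c(p1 = "MKQ", p2 = "MAA"))
  f <- withr::local_tempfile(fileext = ".gaf")
  rows <- c("!gaf-version: 2.2",
            paste(c("DB", "p1", "p1", "", "GO:1", "R", "IEA", "", "P",
                    "", "", "", "", "", "", "", ""), collapse = "\t"),
            paste(c("DB", "p1", "p1", "involved_in", "GO:2", "R", "IEA",
                    "", "P", "", "", "", "", "", "", "", ""),
                  collapse = "\t"),
            paste(c("DB", "p1", "p1", "NOT|involved_in", "GO:3", "R",
                    "IEA", "", "P", "", "", "", "", "", "", "", ""),
                  collapse = "\t"),
            paste(c("DB", "absent", "x", "", "GO:1", "R", "IEA", "", "P",
                    "", "", "", "", "", "", "", ""), collapse = "\t"))
  writeLines(rows, f)
  ann <- load_annotations(f, p)
  expect_equal(sort(ann$p1), c("GO:1", "GO:2"))
  expect_null(ann$absent)
  writeLines("!only comments", f)
  expect_length(load_annotations(f, p), 0)
})

test_that("GO enrichment matches the hypergeometric tail and filters by depth", {
  chain <- c(term("GO:1"))
  for (i in 2:6) chain <- c(chain, term(paste0("GO:", i),
                                        isa = paste0("GO:", i - 1)))
  f <- write_obo(chain)
  ont <- load_ontology(f)
  pop <- paste0("u", 1:100)
  study <- paste0("u", 1:10)
  ann <- stats::setNames(rep(list("GO:6"), 10),
                         c(paste0("u", 1:5), paste0("u", 51:55)))
  res <- go_enrich(study, pop, ann, ont, min_depth = 4)
  expect_equal(res$study_count, 5L)
  expect_equal(res$pop_count, 10L)
  # one-sided hypergeometric upper tail, here m = 1 test so p_adj = p_raw
  p_exact <- sum(stats::dhyper(5:10, 10, 90, 10))
  expect_equal(res$p_raw, p_exact, tolerance = 1e-12)
  expect_equal(res$p_adj, p_exact, tolerance = 1e-12)
  expect_true(res$significant)
  # a term with no study hit has enrichment p of 1
  ann2 <- c(ann, stats::setNames(list("GO:5"), "u99"))
  res2 <- go_enrich(study, pop, ann2, ont, min_depth = 4)
  expect_equal(res2$p_raw[res2$go_id == "GO:5"], 1)
  # the depth filter drops records but never alters p or m
  ann3 <- c(ann, stats::setNames(list("GO:2"), "u60"))
  res3 <- go_enrich(study, pop, ann3, ont, min_depth = 4)
  expect_false("GO:2" %in% res3$go_id)
  expect_equal(attr(res3, "m"), 2L)
  expect_equal(res3$p_adj[res3$go_id == "GO:6"],
               sidak(p_exact, 2), tolerance = 1e-12)
  # order invariance
  res4 <- go_enrich(rev(study), sample(pop), ann, ont, min_depth = 4)
  expect_equal(res4$p_raw, res$p_raw)
  expect_error(go_enrich(c(study, "nope"), pop, ann, ont), "subset")
})

test_that("a planted class-term association is recovered end to end", {
  study <- generate_study(default_study_config(n_organisms = 3,
                                               n_proteins = 30),
                          out_dir = withr::local_tempdir(), seed = 4)
  ont <- load_ontology(study$files$obo)
  euk <- names(study$proteomes)[vapply(study$proteomes, function(p)
    p$domain_of_life == "Eukaryota", logical(1))]
  per_org <- list()
  for (pid in euk) {
    p <- study$proteomes[[pid]]
    lcds <- scan_proteome(p, all_class_specs(c("HQ", "Q")))
    ann <- load_annotations(study$files[[paste0("gaf_", pid)]], p)
    per_org[[pid]] <- go_enrich_classes(lcds, p, ann, ont)
  }
  deep <- study$go$deep_id
  hit <- vapply(per_org, function(rec)
    any(rec$class_label == "HQ" & rec$go_id == deep & rec$significant),
    logical(1))
  expect_true(all(hit))
  sm <- shared_pair_summary(per_org)
  row <- sm[sm$class_label == "HQ" & sm$go_id == deep, ]
  expect_equal(row$pct_organisms, 100)
  # unplanted percentage arithmetic: drop one organism's significance
  per_org2 <- per_org
  per_org2[[1]]$significant <- FALSE
  sm2 <- shared_pair_summary(per_org2)
  expect_equal(sm2$pct_organisms[sm2$class_label == "HQ" &
                                   sm2$go_id == deep],
               100 * (length(euk) - 1) / length(euk))
  # pairs significant nowhere are not emitted
  for (i in seq_along(per_org2)) per_org2[[i]]$significant <- FALSE
  expect_equal(nrow(shared_pair_summary(per_org2)), 0)
})

test_that("null annotations stay below the nominal significance rate", {
  # many simulated organisms, no class-term association planted
  chain <- c(term("GO:1"))
  for (i in 2:6) chain <- c(chain, term(paste0("GO:", i),
                                        isa = paste0("GO:", i - 1)))
  f <- write_obo(chain)
  ont <- load_ontology(f)
  set.seed(606)
  n_sig <- 0L; n_pairs <- 0L
  for (org in 1:100) {
    pop <- paste0("u", 1:60)
    study <- sample(pop, 8)        # stand-in LCD class protein set
    ann <- stats::setNames(
      lapply(1:60, function(i) paste0("GO:", sample(4:6, 1))), pop)
    res <- go_enrich(study, pop, ann, ont, min_depth = 4)
    n_sig <- n_sig + sum(res$significant)
    n_pairs <- n_pairs + nrow(res)
  }
  expect_lt(n_sig / n_pairs, 0.05)
})
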
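# Synthetic proteomes, ontologies and annotations with known ground
# truth, so every pipeline stage can be validated without downloads.
#
# Planted LCDs interleave their target residues evenly (Bresenham-style
# spacing), which guarantees the dispersion criterion is met with a wide
# margin regardless of the exact dispersion formula, and target
# compositions are requested with a comfortable margin above the search
# thresholds (0.50 primary / 0.30 secondary by default against the
# 0.40 / 0.20 defaults).

#' Named background amino-acid frequency presets
#'
#' "uniform": all 20 amino acids at 0.05. "uniprot-like": average
#' frequencies of well-characterized proteomes. "falciparum-like":
#' strongly skewed with elevated N and K, emulating the A/T-rich-genome
#' compositional bias of *Plasmodium falciparum*, the paradigm case of
#' composition-driven LCD abundance.
#'
#' @param preset One of "uniform", "uniprot-like", "falciparum-like".
#' @return Named numeric vector over the 20 canonical amino acids,
#'   summing to 1.
#' @export
background_freqs <- function(preset = c("uniform", "uniprot-like",
                                        "falciparum-like")) {
  preset <- match.arg(preset)
  f <- switch(preset,
    "uniform" = stats::setNames(rep(0.05, 20), AA20),
    "uniprot-like" = c(A = 0.0826, C = 0.0139, D = 0.0546, E = 0.0672,
                       F = 0.0387, G = 0.0707, H = 0.0228, I = 0.0591,
                       K = 0.0580, L = 0.0965, M = 0.0241, N = 0.0406,
                       P = 0.0475, Q = 0.0393, R = 0.0553, S = 0.0665,
                       T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292),
    "falciparum-like" = c(A = 0.040, C = 0.015, D = 0.050, E = 0.060,
                          F = 0.035, G = 0.040, H = 0.020, I = 0.070,
                          K = 0.105, L = 0.070, M = 0.020, N = 0.135,
                          P = 0.030, Q = 0.030, R = 0.030, S = 0.060,
                          T = 0.040, V = 0.045, W = 0.010, Y = 0.045))
  f / sum(f)
}

#' Generate a background proteome with i.i.d. residues
#'
#' Every protein starts with "M"; the remaining residues are drawn
#' independently from \code{freqs}. Deterministic under \code{seed}.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer pair (min, max) of protein lengths, or an
#'   explicit length vector of length \code{n_proteins}.
#' @param freqs Background frequencies (see \code{\link{background_freqs}}).
#' @param seed Integer seed.
#' @param proteome_id,domain_of_life,clade Metadata for the proteome.
#' @return List with elements \code{proteome} and \code{truth} (list:
#'   planted data.frame, background_freqs, lengths, seed).
#' @export
generate_background_proteome <- function(n_proteins,
                                         length_range = c(80L, 200L),
                                         freqs = background_freqs("uniform"),
                                         seed = 1L,
                                         proteome_id = "SYN0001",
                                         domain_of_life = "Unknown",
                                         clade = "") {
  if (abs(sum(freqs) - 1) > 1e-12)
    stop("background frequencies must sum to 1")
  if (any(freqs < 0)) stop("background frequencies must be non-negative")
  with_seed(seed, {
    lens <- if (length(length_range) == n_proteins && n_proteins != 2) {
      as.integer(length_range)
    } else if (length(length_range) == 2) {
      sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    } else as.integer(length_range)
    if (length(lens) != n_proteins)
      stop("length_range must be a (min, max) pair or one length per protein")
    if (any(lens < 1)) stop("protein lengths must be >= 1")
    seqs <- vapply(lens, function(L) {
      if (L == 1) return("M")
      paste0("M", paste(sample(names(freqs), L - 1L, replace = TRUE,
                               prob = freqs), collapse = ""))
    }, character(1))
    names(seqs) <- sprintf("%s_P%04d", proteome_id, seq_len(n_proteins))
    list(proteome = proteome(proteome_id, seqs, domain_of_life, clade),
         truth = list(planted = empty_truth_table(),
                      background_freqs = freqs,
                      lengths = lens, seed = seed))
  })
}

empty_truth_table <- function() {
  data.frame(accession = character(0), class_label = character(0),
             start = integer(0), end = integer(0),
             primary_target_comp = numeric(0),
             secondary_target_comp = numeric(0),
             stringsAsFactors = FALSE)
}

# Evenly spread n_put marks among n_slots slots (Bresenham): returns the
# 1-based slot indices that receive a mark.
even_positions <- function(n_slots, n_put) {
  if (n_put == 0) return(integer(0))
  i <- seq_len(n_slots)
  which(floor(i * n_put / n_slots) > floor((i - 1) * n_put / n_slots))
}

#' Plant an LCD of a given class into a protein
#'
#' Overwrites the interval [start, start + length - 1] of the target
#' protein with a sequence hitting the requested compositions: the
#' primary (and secondary) residues are interleaved evenly so the
#' dispersion criterion is met, and the remaining positions are drawn
#' from \code{fill_freqs} restricted to letters other than the planted
#' ones. Residues outside the interval are never altered.
#'
#' @param p A \code{\link{proteome}}.
#' @param accession Protein to modify.
#' @param class_label Class to plant ("Q" or "HQ" style).
#' @param start 1-based start of the planted interval.
#' @param length Interval length (>= window size for detectability).
#' @param primary_comp Target primary composition (default 0.5).
#' @param secondary_comp Target secondary composition (default 0.3;
#'   ignored for primary classes).
#' @param fill_freqs Frequencies for the non-target positions.
#' @param seed Integer seed for the fill draw.
#' @return List with elements \code{proteome} and \code{planted} (one
#'   truth row).
#' @export
plant_lcd <- function(p, accession, class_label, start, length,
                      primary_comp = 0.5, secondary_comp = 0.3,
                      fill_freqs = background_freqs("uniform"),
                      seed = 1L) {
  stopifnot(inherits(p, "proteome"))
  if (!accession %in% names(p$sequences))
    stop("unknown accession: ", accession)
  seqlen <- nchar(p$sequences[[accession]])
  end <- start + length - 1L
  if (start < 1 || end > seqlen)
    stop("planted interval [", start, ", ", end,
         "] outside protein of length ", seqlen)
  primary <- substr(class_label, 1, 1)
  secondary <- if (nchar(class_label) == 2) substr(class_label, 2, 2)
               else NULL
  n_p <- ceiling(primary_comp * length)
  n_s <- if (is.null(secondary)) 0L else ceiling(secondary_comp * length)
  if (n_p + n_s > length)
    stop("target compositions exceed the interval length")
  span <- character(length)
  pos_p <- even_positions(length, n_p)
  span[pos_p] <- primary
  rest <- setdiff(seq_len(length), pos_p)
  if (n_s > 0) {
    pos_s <- rest[even_positions(length(rest), n_s)]
    span[pos_s] <- secondary
    rest <- setdiff(rest, pos_s)
  }
  if (length(rest)) {
    pool <- fill_freqs[setdiff(names(fill_freqs), c(primary, secondary))]
    pool <- pool / sum(pool)
    span[rest] <- with_seed(seed, sample(names(pool), length(rest),
                                         replace = TRUE, prob = pool))
  }
  seqs <- p$sequences
  old <- seqs[[accession]]
  seqs[[accession]] <- paste0(substr(old, 1, start - 1),
                              paste(span, collapse = ""),
                              substr(old, end + 1, seqlen))
  row <- data.frame(accession = accession, class_label = class_label,
                    start = as.integer(start), end = as.integer(end),
                    primary_target_comp = primary_comp,
                    secondary_target_comp =
                      if (is.null(secondary)) NA_real_ else secondary_comp,
                    stringsAsFactors = FALSE)
  list(proteome = proteome(p$proteome_id, seqs, p$domain_of_life, p$clade),
       planted = row)
}

#' Generate a proteome with planted LCDs
#'
#' Convenience wrapper: background proteome plus \code{n_planted} LCDs of
#' one class planted into distinct proteins (interval placed mid-protein
#' where it fits, else at position 2).
#'
#' @inheritParams generate_background_proteome
#' @param class_label Class to plant.
#' @param n_planted Number of proteins receiving one planted LCD each.
#' @param lcd_length Planted interval length (default 30).
#' @param primary_comp,secondary_comp Target compositions.
#' @return List with \code{proteome} and \code{truth} as in
#'   \code{\link{generate_background_proteome}}; \code{truth$planted} has
#'   one row per planted LCD.
#' @export
generate_planted_proteome <- function(n_proteins, class_label, n_planted,
                                      length_range = c(80L, 200L),
                                      lcd_length = 30L,
                                      primary_comp = 0.5,
                                      secondary_comp = 0.3,
                                      freqs = background_freqs("uniform"),
                                      seed = 1L,
                                      proteome_id = "SYN0001",
                                      domain_of_life = "Unknown",
                                      clade = "") {
  if (n_planted > n_proteins)
    stop("cannot plant more LCDs than proteins")
  gen <- generate_background_proteome(n_proteins, length_range, freqs,
                                      seed, proteome_id, domain_of_life,
                                      clade)
  p <- gen$proteome
  targets <- with_seed(seed + 1L,
                       sample(names(p$sequences), n_planted))
  planted <- list()
  for (i in seq_along(targets)) {
    acc <- targets[i]
    L <- nchar(p$sequences[[acc]])
    if (L < lcd_length + 1L)
      stop("protein ", acc, " too short for the planted LCD")
    start <- max(2L, (L - lcd_length) %/% 2L)
    res <- plant_lcd(p, acc, class_label, start, lcd_length,
                     primary_comp, secondary_comp, freqs,
                     seed = seed + 100L + i)
    p <- res$proteome
    planted[[i]] <- res$planted
  }
  gen$proteome <- p
  gen$truth$planted <- do.call(rbind, c(list(empty_truth_table()), planted))
  gen
}

#' Write a toy GO ontology as OBO
#'
#' A biological_process root with a linear is_a chain deep enough that
#' the terminal term sits at \code{depth} (>= 4 for the reporting
#' filter), plus \code{n_shallow} shallow sibling terms directly under
#' the root used as background annotations.
#'
#' @param path Output OBO path.
#' @param depth Depth of the deepest (association-target) term.
#' @param n_shallow Number of depth-1 background terms.
#' @return Invisibly, a list: \code{deep_id} (the depth-\code{depth}
#'   term), \code{shallow_ids}.
#' @export
write_toy_obo <- function(path, depth = 5L, n_shallow = 4L) {
  fmt <- function(i) sprintf("GO:SYN%04d", i)
  lines <- c("format-version: 1.2", "")
  add_term <- function(id, name, isa = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      "namespace: biological_process",
      if (!is.null(isa)) paste0("is_a: ", isa, " ! parent"), "")
  }
  lines <- c(lines, add_term(fmt(0), "synthetic biological process root"))
  chain <- fmt(seq_len(depth))
  for (i in seq_len(depth))
    lines <- c(lines, add_term(chain[i],
                               paste("synthetic nested process level", i),
                               if (i == 1) fmt(0) else chain[i - 1]))
  shallow <- if (n_shallow > 0) fmt(100L + seq_len(n_shallow))
             else character(0)
  for (j in seq_along(shallow))
    lines <- c(lines, add_term(shallow[j],
                               paste("synthetic background process", j),
                               fmt(0)))
  writeLines(lines, path)
  invisible(list(deep_id = chain[depth], shallow_ids = shallow))
}

#' Write a toy GAF 2.2 annotation file
#'
#' @param path Output path.
#' @param annotations Named list accession -> character vector of GO ids.
#' @param db Database label for column 1.
#' @return Invisibly, \code{path}.
#' @export
write_toy_gaf <- function(path, annotations, db = "SYNDB") {
  lines <- "!gaf-version: 2.2"
  for (acc in names(annotations)) {
    for (go in annotations[[acc]]) {
      f <- c(db, acc, acc, "involved_in", go, "SYN:0001", "IEA", "",
             "P", acc, "", "protein", "taxon:0000", "20220822", db,
             "", "")
      lines <- c(lines, paste(f, collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Default configuration for a miniature synthetic survey
#'
#' Four domains of life with a handful of organisms each. The planted
#' structure mirrors the broad observations the pipeline is meant to
#' recover: eukaryotes carry Q-rich and HQ LCDs (HQ planted in
#' eukaryotes only, making it eukaryote-specific), bacteria and archaea
#' carry a sparser A-rich complement, viruses carry almost none, and the
#' HQ class carries a GO association (the deep toy term) in eukaryotes.
#'
#' @param n_organisms Organisms per domain (default 5).
#' @param n_proteins Proteins per organism (default 60).
#' @return Config list consumed by \code{\link{generate_study}}.
#' @export
default_study_config <- function(n_organisms = 5L, n_proteins = 60L) {
  list(
    n_proteins = n_proteins,
    length_range = c(80L, 160L),
    background = "uniprot-like",
    lcd_length = 30L,
    primary_comp = 0.5,
    secondary_comp = 0.3,
    domains = list(
      Eukaryota = list(n_organisms = n_organisms, clade = "Metazoa",
                       planted = list(
                         list(class_label = "Q", n = 6L),
                         list(class_label = "HQ", n = 5L))),
      Bacteria = list(n_organisms = n_organisms, clade = "Proteobacteria",
                      planted = list(list(class_label = "A", n = 3L))),
      Archaea = list(n_organisms = n_organisms, clade = "Euryarchaeota",
                     planted = list(list(class_label = "A", n = 2L))),
      Viruses = list(n_organisms = n_organisms, clade = "Uroviricota",
                     planted = list())),
    go_association = list(class_label = "HQ", domain = "Eukaryota"),
    clan_class = "Q", clan_id = "CL0001")
}

#' Generate a complete self-contained synthetic study
#'
#' Writes, under \code{out_dir}: one FASTA per organism, a metadata TSV
#' (proteome_id, domain_of_life, lineage), a toy OBO ontology, one GAF
#' per organism of the GO-association domain, a Pfam-style clan TSV, and
#' a truth TSV of all planted LCDs. Proteins of the GO-associated class
#' are annotated with the deep toy term; other proteins receive shallow
#' background annotations. Byte-identical output under a fixed seed.
#'
#' @param config See \code{\link{default_study_config}}.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-organism seeds are derived from
#'   it deterministically.
#' @return List: \code{proteomes} (named list of proteome objects),
#'   \code{truth} (data.frame with proteome_id column), \code{files}
#'   (named paths), \code{go} (deep/shallow term ids),
#'   \code{go_annotations} (named list per organism).
#' @export
generate_study <- function(config = default_study_config(),
                           out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  freqs <- background_freqs(config$background)
  proteomes <- list()
  truth_all <- list()
  meta <- list()
  org_counter <- 0L
  for (dom in names(config$domains)) {
    dc <- config$domains[[dom]]
    for (k in seq_len(dc$n_organisms)) {
      org_counter <- org_counter + 1L
      pid <- sprintf("SYNUP%04d_%s", org_counter, substr(dom, 1, 3))
      org_seed <- seed * 1000L + org_counter
      planted_spec <- dc$planted
      if (!length(planted_spec)) {
        gen <- generate_background_proteome(
          config$n_proteins, config$length_range, freqs, org_seed, pid,
          dom, dc$clade)
      } else {
        gen <- NULL
        for (pl in planted_spec) {
          if (is.null(gen)) {
            gen <- generate_planted_proteome(
              config$n_proteins, pl$class_label, pl$n,
              config$length_range, config$lcd_length,
              config$primary_comp, config$secondary_comp,
              freqs, org_seed, pid, dom, dc$clade)
          } else {
            # plant further classes into the already-generated proteome
            p <- gen$proteome
            avail <- setdiff(names(p$sequences),
                             gen$truth$planted$accession)
            if (length(avail) < pl$n)
              stop("config plants more LCDs than proteins available in ",
                   pid)
            targets <- with_seed(org_seed + 7L * match(pl$class_label,
                                                       all_class_labels()),
                                 sample(avail, pl$n))
            for (i in seq_along(targets)) {
              acc <- targets[i]
              L <- nchar(p$sequences[[acc]])
              start <- max(2L, (L - config$lcd_length) %/% 2L)
              res <- plant_lcd(p, acc, pl$class_label, start,
                               config$lcd_length, config$primary_comp,
                               config$secondary_comp, freqs,
                               seed = org_seed + 500L + i)
              p <- res$proteome
              gen$truth$planted <- rbind(gen$truth$planted, res$planted)
            }
            gen$proteome <- p
          }
        }
      }
      proteomes[[pid]] <- gen$proteome
      if (nrow(gen$truth$planted))
        truth_all[[pid]] <- cbind(data.frame(proteome_id = pid,
                                             stringsAsFactors = FALSE),
                                  gen$truth$planted)
      meta[[pid]] <- data.frame(proteome_id = pid,
                                domain_of_life = dom,
                                lineage = paste(dom, dc$clade, sep = "; "),
                                stringsAsFactors = FALSE)
    }
  }
  files <- list()
  for (pid in names(proteomes)) {
    fp <- file.path(out_dir, paste0(pid, ".fasta"))
    write_fasta(proteomes[[pid]], fp)
    files[[paste0("fasta_", pid)]] <- fp
  }
  meta_df <- if (length(meta)) do.call(rbind, meta) else
    data.frame(proteome_id = character(0), domain_of_life = character(0),
               lineage = character(0), stringsAsFactors = FALSE)
  files$metadata <- file.path(out_dir, "metadata.tsv")
  write_table(meta_df, files$metadata)
  truth_df <- if (length(truth_all)) do.call(rbind, truth_all) else
    cbind(data.frame(proteome_id = character(0)), empty_truth_table())
  rownames(truth_df) <- NULL
  files$truth <- file.path(out_dir, "truth.tsv")
  write_table(truth_df, files$truth)
  files$obo <- file.path(out_dir, "go.obo")
  go_ids <- write_toy_obo(files$obo, depth = 5L, n_shallow = 4L)
  # GO annotations: planted-association proteins get the deep term; every
  # protein gets one shallow term (deterministic round-robin) so the
  # population universe is well covered.
  assoc <- config$go_association
  go_annotations <- list()
  for (pid in names(proteomes)) {
    p <- proteomes[[pid]]
    ann <- list()
    accs <- names(p$sequences)
    for (i in seq_along(accs))
      ann[[accs[i]]] <-
        go_ids$shallow_ids[(i - 1L) %% length(go_ids$shallow_ids) + 1L]
    if (!is.null(assoc) && p$domain_of_life == assoc$domain &&
        pid %in% names(truth_all)) {
      tr <- truth_all[[pid]]
      hit <- unique(tr$accession[tr$class_label == assoc$class_label])
      for (acc in hit) ann[[acc]] <- c(ann[[acc]], go_ids$deep_id)
    }
    go_annotations[[pid]] <- ann
    gp <- file.path(out_dir, paste0(pid, ".gaf"))
    write_toy_gaf(gp, ann)
    files[[paste0("gaf_", pid)]] <- gp
  }
  # Pfam-style clan map: proteins carrying the clan_class LCD share one
  # clan; a sprinkling of other proteins get singleton clans.
  clan_rows <- list()
  for (pid in names(truth_all)) {
    tr <- truth_all[[pid]]
    hit <- unique(tr$accession[tr$class_label == config$clan_class])
    if (length(hit))
      clan_rows[[pid]] <- data.frame(proteome_id = pid, accession = hit,
                                     clan = config$clan_id,
                                     stringsAsFactors = FALSE)
  }
  clan_df <- if (length(clan_rows)) do.call(rbind, clan_rows) else
    data.frame(proteome_id = character(0), accession = character(0),
               clan = character(0), stringsAsFactors = FALSE)
  rownames(clan_df) <- NULL
  files$clans <- file.path(out_dir, "clans.tsv")
  write_table(clan_df, files$clans)
  list(proteomes = proteomes, truth = truth_df, files = files,
       go = go_ids, go_annotations = go_annotations)
}
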
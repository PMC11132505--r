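# Descriptive LCD statistics: per-class counts, organism-level
# frequencies and rarity bins, per-residue occupancy, secondary-class
# shares, domain-specific classes, co-occurrence and Pfam-clan
# concentration.

interval_union_size <- function(start, end) {
  if (!length(start)) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 0L) {
      if (end[i] > cur_e) cur_e <- end[i]
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Per-class LCD count table for one proteome
#'
#' For every LCD class observed in \code{lcds}, tallies the number of
#' proteins with at least one LCD, the number of LCDs, and the number of
#' residues occupied (the union of [start, end] intervals per protein, so
#' overlapping LCDs of the same class count each residue once). Proteome
#' totals and metadata are carried along.
#'
#' @param lcds LCD data.frame from \code{\link{scan_proteome}} (may be a
#'   subset; all accessions must exist in \code{p}).
#' @param p The \code{\link{proteome}} that was scanned.
#' @return Object of class \code{class_count_table}: a data.frame with
#'   columns proteome_id, class_label, n_proteins_with_lcd, n_lcds,
#'   n_lcd_residues, and attributes \code{n_proteins_total},
#'   \code{n_residues_total}, \code{domain_of_life}, \code{clade}.
#' @export
count_class_table <- function(lcds, p) {
  stopifnot(inherits(p, "proteome"))
  if (nrow(lcds)) {
    unknown <- setdiff(unique(lcds$accession), names(p$sequences))
    if (length(unknown))
      stop("LCD table references accession(s) absent from proteome: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (nrow(lcds)) {
    cls_levels <- sort(unique(lcds$class_label))
    by_class <- split(seq_len(nrow(lcds)),
                      factor(lcds$class_label, cls_levels))
    n_res <- vapply(by_class, function(idx) {
      sum(vapply(split(idx, lcds$accession[idx]), function(i)
        interval_union_size(lcds$start[i], lcds$end[i]), integer(1)))
    }, integer(1))
    tab <- data.frame(
      proteome_id = p$proteome_id,
      class_label = cls_levels,
      n_proteins_with_lcd = vapply(by_class, function(idx)
        length(unique(lcds$accession[idx])), integer(1)),
      n_lcds = lengths(by_class),
      n_lcd_residues = n_res,
      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(proteome_id = character(0),
                      class_label = character(0),
                      n_proteins_with_lcd = integer(0),
                      n_lcds = integer(0),
                      n_lcd_residues = integer(0),
                      stringsAsFactors = FALSE)
  }
  structure(tab,
            proteome_id = p$proteome_id,
            n_proteins_total = length(p$sequences),
            n_residues_total = n_residues(p),
            domain_of_life = p$domain_of_life,
            clade = p$clade,
            class = c("class_count_table", class(tab)))
}

count_for_class <- function(table, class_label, col) {
  i <- match(class_label, table$class_label)
  if (is.na(i)) 0L else table[[col]][i]
}

#' Organism-level LCD class frequency
#'
#' Percentage of organisms in a group with at least one LCD of each
#' class.
#'
#' @param tables List of \code{\link{count_class_table}} results, one per
#'   organism in the group.
#' @param classes Class labels to report (default: all 400).
#' @return Named numeric vector of percentages in [0, 100].
#' @export
organism_level_frequency <- function(tables, classes = all_class_labels()) {
  if (!length(tables)) stop("empty organism group")
  n <- length(tables)
  hits <- vapply(classes, function(cl)
    sum(vapply(tables, function(tb)
      count_for_class(tb, cl, "n_proteins_with_lcd") >= 1L, logical(1))),
    numeric(1))
  100 * hits / n
}

#' Rarity category of an organism-level frequency
#'
#' Bins: absent (x = 0), very rare (0 < x < 5), rare (5 <= x < 20),
#' normal (20 <= x < 50), common (50 <= x < 75), very common (x >= 75).
#'
#' @param x Percentage(s) in [0, 100].
#' @return Character vector of category labels.
#' @export
rarity_category <- function(x) {
  if (any(x < 0 | x > 100)) stop("frequency must be in [0, 100]")
  vapply(x, function(v) {
    if (v == 0) "absent"
    else if (v < 5) "very rare"
    else if (v < 20) "rare"
    else if (v < 50) "normal"
    else if (v < 75) "common"
    else "very common"
  }, character(1))
}

#' Per-residue occupancy of one LCD class
#'
#' Percentage of all residues in the proteome lying within the union of
#' the class's LCDs.
#'
#' @param table A \code{\link{count_class_table}}.
#' @param class_label Class to report.
#' @return Percentage in [0, 100].
#' @export
per_residue_occupancy <- function(table, class_label) {
  total <- attr(table, "n_residues_total")
  if (is.null(total) || total <= 0) stop("proteome has no residues")
  100 * count_for_class(table, class_label, "n_lcd_residues") / total
}

#' Secondary-class share within a primary amino acid
#'
#' For each secondary class XY sharing the primary amino acid X, the
#' number of XY LCDs divided by the total number of secondary LCDs with
#' primary X, as a percentage. Undefined (NULL) when no secondary LCD
#' with that primary exists.
#'
#' @param table A \code{\link{count_class_table}}.
#' @param primary_aa Primary amino-acid letter.
#' @return Named numeric vector over the 19 XY classes summing to 100,
#'   or NULL when undefined.
#' @export
secondary_share <- function(table, primary_aa) {
  labs <- paste0(primary_aa, setdiff(AA20, primary_aa))
  counts <- vapply(labs, function(cl)
    count_for_class(table, cl, "n_lcds"), numeric(1))
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  100 * counts / tot
}

#' Classes specific to one domain of life
#'
#' Classes whose organism-level frequency exceeds \code{in_min} percent in
#' the target domain while staying below \code{out_max} percent in each of
#' the other domains, evaluated independently (strict inequalities on both
#' sides).
#'
#' @param freqs Named list of per-class frequency vectors (as returned by
#'   \code{\link{organism_level_frequency}}), one per domain of life; must
#'   contain \code{target_domain} and at least one other domain.
#' @param target_domain Domain to test (e.g. "Eukaryota").
#' @param in_min Minimum frequency in the target domain (default 15).
#' @param out_max Maximum frequency in every other domain (default 2).
#' @return Character vector of class labels.
#' @export
domain_specific_classes <- function(freqs, target_domain,
                                    in_min = 15, out_max = 2) {
  if (!target_domain %in% names(freqs))
    stop("no frequencies supplied for domain ", target_domain)
  others <- setdiff(names(freqs), target_domain)
  if (!length(others)) stop("need frequencies for at least one other domain")
  classes <- names(freqs[[target_domain]])
  keep <- freqs[[target_domain]] > in_min
  for (d in others) {
    fo <- freqs[[d]][classes]
    fo[is.na(fo)] <- 0
    keep <- keep & (fo < out_max)
  }
  classes[keep]
}

#' Co-occurrence counts of LCD-class combinations across proteins
#'
#' Per protein, the set of reciprocal-merged class categories present
#' (XY and YX collapse to one canonical label, see
#' \code{\link{reciprocal_label}}); identical sets are counted across
#' proteins, UpSet-style.
#'
#' @param lcds LCD data.frame.
#' @param class_filter Optional set of class labels to restrict to before
#'   merging reciprocals.
#' @return data.frame with columns \code{combination} (categories joined
#'   by "+", sorted) and \code{n_proteins}.
#' @export
co_occurrence_counts <- function(lcds, class_filter = NULL) {
  if (!is.null(class_filter))
    lcds <- lcds[lcds$class_label %in% class_filter, , drop = FALSE]
  if (!nrow(lcds))
    return(data.frame(combination = character(0),
                      n_proteins = integer(0), stringsAsFactors = FALSE))
  combos <- vapply(split(lcds$class_label, lcds$accession), function(cls)
    paste(sort(unique(reciprocal_label(cls))), collapse = "+"),
    character(1))
  tab <- table(combos)
  data.frame(combination = names(tab), n_proteins = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Are two LCDs on the same protein spatially distinct?
#'
#' TRUE when at least \code{min_outside} residues of \code{lcd_b} lie
#' outside the span of \code{lcd_a}.
#'
#' @param lcd_a,lcd_b Single-row LCD records (lists or data.frame rows
#'   with accession, start, end).
#' @param min_outside Minimum residues of b outside a (default 20).
#' @return Logical.
#' @export
spatially_distinct <- function(lcd_a, lcd_b, min_outside = 20) {
  if (lcd_a$accession != lcd_b$accession)
    stop("spatially_distinct compares LCDs on the same protein")
  len_b <- lcd_b$end - lcd_b$start + 1
  overlap <- max(0, min(lcd_a$end, lcd_b$end) -
                   max(lcd_a$start, lcd_b$start) + 1)
  (len_b - overlap) >= min_outside
}

#' Maximum single-clan share of an LCD class's proteins
#'
#' The largest percentage of the class's Pfam-annotated proteins assigned
#' to any one clan. Only proteins with at least one clan annotation enter
#' the denominator; NA when fewer than \code{min_n} annotated proteins
#' exist.
#'
#' @param class_proteins Character vector of accessions with an LCD of the
#'   class.
#' @param clan_map Named list or named character vector mapping accession
#'   to clan(s).
#' @param min_n Minimum annotated proteins required (default 5).
#' @return Percentage in (0, 100], or NA_real_ when undefined.
#' @export
max_single_clan_share <- function(class_proteins, clan_map, min_n = 5) {
  class_proteins <- unique(class_proteins)
  clans_of <- lapply(class_proteins, function(a) {
    v <- clan_map[[a]]
    if (is.null(v)) character(0) else unique(as.character(v))
  })
  annotated <- lengths(clans_of) > 0
  n_annot <- sum(annotated)
  if (n_annot < min_n) return(NA_real_)
  clan_counts <- table(unlist(clans_of[annotated]))
  100 * max(clan_counts) / n_annot
}

#' Domain-level mean per-residue occupancy
#'
#' Unweighted arithmetic mean, over the organisms of a group, of each
#' organism's per-residue occupancy for a class (not pooled over
#' residues).
#'
#' @param tables List of \code{\link{count_class_table}} per organism.
#' @param class_label Class to report.
#' @return Mean percentage.
#' @export
mean_occupancy <- function(tables, class_label) {
  if (!length(tables)) stop("empty organism group")
  mean(vapply(tables, per_residue_occupancy, numeric(1),
              class_label = class_label))
}
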
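# GO-term enrichment for LCD-class protein sets.
#
# The ontology is read from OBO 1.2 ([Term] stanzas; id, name, namespace,
# is_a, is_obsolete), annotations from GAF 2.x. Depth is the longest
# is_a path from the namespace root (the convention ontology tools call
# "depth", as opposed to the shortest-path "level", selectable by flag).

NAMESPACE_CODES <- c(biological_process = "BP",
                     cellular_component = "CC",
                     molecular_function = "MF")

#' Load a gene ontology from an OBO file
#'
#' Consumes [Term] stanzas (id, name, namespace, is_a); obsolete terms
#' are skipped and is_a references to unknown terms dropped with a
#' warning. Depths are the longest path to the namespace root over is_a
#' edges; shortest-path levels are also computed.
#'
#' @param path Path to an OBO 1.2-style file.
#' @return Object of class \code{go_ontology}: list with data.frame
#'   \code{terms} (go_id, name, namespace, depth, level) and list
#'   \code{parents} keyed by go_id.
#' @export
load_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  ids <- character(0); names_ <- character(0); ns <- character(0)
  parents <- list()
  stanza_ends <- c(which(grepl("^\\[", lines)), length(lines) + 1L)
  for (s in term_starts) {
    e <- min(stanza_ends[stanza_ends > s]) - 1L
    block <- lines[s:e]
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    nsv <- sub("^namespace: *", "", grep("^namespace:", block,
                                         value = TRUE)[1])
    isa <- sub("^is_a: *([^ !]+).*$", "\\1",
               grep("^is_a:", block, value = TRUE))
    if (is.na(id)) next
    ids <- c(ids, id)
    names_ <- c(names_, if (is.na(nm)) "" else nm)
    ns <- c(ns, if (!is.na(nsv) && nsv %in% names(NAMESPACE_CODES))
      NAMESPACE_CODES[[nsv]] else if (is.na(nsv)) "" else nsv)
    parents[[id]] <- isa
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
  dangling <- setdiff(unlist(parents), ids)
  if (length(dangling)) {
    warning("dropping is_a reference(s) to unknown term(s): ",
            paste(utils::head(dangling, 5), collapse = ", "))
    parents <- lapply(parents, function(pp) pp[pp %in% ids])
  }
  depths <- longest_path_depths(ids, parents)
  levels <- longest_path_depths(ids, parents, longest = FALSE)
  structure(list(terms = data.frame(go_id = ids, name = names_,
                                    namespace = unname(ns),
                                    depth = depths[ids],
                                    level = levels[ids],
                                    stringsAsFactors = FALSE),
                 parents = parents),
            class = "go_ontology")
}

# Longest (or shortest) path from each term up to its root, by
# memoized recursion over is_a edges; cycles raise a format error.
longest_path_depths <- function(ids, parents, longest = TRUE) {
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  visiting <- stats::setNames(rep(FALSE, length(ids)), ids)
  comb <- if (longest) max else min
  walk <- function(id) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    if (visiting[[id]]) stop("cycle detected in ontology at ", id)
    visiting[[id]] <<- TRUE
    pp <- parents[[id]]
    d <- if (!length(pp)) 0 else
      1 + comb(vapply(pp, walk, numeric(1)))
    visiting[[id]] <<- FALSE
    depth[[id]] <<- d
    d
  }
  for (id in ids) walk(id)
  depth
}

#' All is_a ancestors of a term
#' @param ont A \code{go_ontology}.
#' @param go_id Term accession.
#' @return Character vector of ancestor accessions (excluding the term).
#' @export
go_ancestors <- function(ont, go_id) {
  seen <- character(0)
  frontier <- ont$parents[[go_id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(ont$parents[frontier])), seen)
  }
  seen
}

#' Load GO annotations from a GAF file
#'
#' GAF 2.x tab-separated rows; comment lines (!) skipped, rows with a
#' NOT qualifier skipped, rows for accessions absent from the proteome
#' excluded. Direct annotations only unless \code{propagate} is TRUE, in
#' which case each annotation is extended to all is_a ancestors.
#'
#' @param path Path to a GAF file.
#' @param p A \code{\link{proteome}} restricting the accession universe.
#' @param ont Optional \code{go_ontology}, required when
#'   \code{propagate = TRUE}.
#' @param propagate Propagate annotations to ancestors (default FALSE).
#' @return Named list: accession -> character vector of GO ids.
#' @export
load_annotations <- function(path, p, ont = NULL, propagate = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  ann <- list()
  bad <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) { bad <- bad + 1L; next }
    if (grepl("(^|\\|)NOT(\\||$)", f[4])) next
    acc <- f[2]; go <- f[5]
    if (!acc %in% names(p$sequences)) next
    ann[[acc]] <- union(ann[[acc]], go)
  }
  if (bad) warning("skipped ", bad, " malformed GAF row(s) in ",
                   basename(path))
  if (propagate) {
    if (is.null(ont)) stop("propagation requires an ontology")
    ann <- lapply(ann, function(gs)
      union(gs, unique(unlist(lapply(gs, function(g)
        go_ancestors(ont, g))))))
  }
  ann
}

#' GO-term enrichment of a study set against a population
#'
#' For every term annotating at least one population protein, a Fisher's
#' exact test of the study-vs-population 2x2 table (one-sided toward
#' enrichment by default), followed by single-step Sidak correction with
#' m = number of terms tested. Reported records are filtered to
#' depth >= \code{min_depth}, but all tested terms count toward m.
#'
#' @param study Character vector of accessions (must be a subset of
#'   \code{population}).
#' @param population Character vector of background accessions.
#' @param annotations Named list accession -> GO ids (see
#'   \code{\link{load_annotations}}).
#' @param ont A \code{go_ontology}.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param min_depth Minimum ontology depth for reporting (default 4).
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @param use_level Use shortest-path level instead of longest-path depth
#'   for the reporting filter.
#' @return data.frame: go_id, name, namespace, depth, study_count,
#'   study_n, pop_count, pop_n, p_raw, p_adj, significant. Attribute
#'   \code{m} records the number of tests corrected for.
#' @export
go_enrich <- function(study, population, annotations, ont,
                      alpha = 0.05, min_depth = 4,
                      alternative = c("greater", "two.sided"),
                      use_level = FALSE) {
  alternative <- match.arg(alternative)
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population))
    stop("study set must be a subset of the population")
  study_n <- length(study); pop_n <- length(population)
  ann <- annotations[names(annotations) %in% population]
  term_to_acc <- list()
  for (acc in names(ann)) for (g in ann[[acc]])
    term_to_acc[[g]] <- c(term_to_acc[[g]], acc)
  terms <- names(term_to_acc)
  if (!length(terms)) return(empty_go_table())
  pop_count <- lengths(term_to_acc)
  study_count <- vapply(term_to_acc, function(accs)
    sum(accs %in% study), integer(1))
  p_raw <- vapply(seq_along(terms), function(i) {
    sc <- study_count[i]; pc <- pop_count[i]
    if (alternative == "greater") {
      stats::phyper(sc - 1, pc, pop_n - pc, study_n, lower.tail = FALSE)
    } else {
      fisher_exact_2x2(sc, study_n - sc, pc - sc,
                       (pop_n - study_n) - (pc - sc))
    }
  }, numeric(1))
  p_raw <- pmin(1, pmax(p_raw, .Machine$double.xmin))
  m <- length(terms)
  p_adj <- sidak(p_raw, m)
  ti <- match(terms, ont$terms$go_id)
  depth <- if (use_level) ont$terms$level[ti] else ont$terms$depth[ti]
  res <- data.frame(go_id = terms,
                    name = ont$terms$name[ti],
                    namespace = ont$terms$namespace[ti],
                    depth = depth,
                    study_count = unname(study_count),
                    study_n = study_n,
                    pop_count = unname(pop_count),
                    pop_n = pop_n,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[!is.na(res$depth) & res$depth >= min_depth, , drop = FALSE]
  res <- res[order(res$p_adj, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m") <- m
  res
}

empty_go_table <- function() {
  structure(data.frame(go_id = character(0), name = character(0),
                       namespace = character(0), depth = numeric(0),
                       study_count = integer(0), study_n = integer(0),
                       pop_count = integer(0), pop_n = integer(0),
                       p_raw = numeric(0), p_adj = numeric(0),
                       significant = logical(0), stringsAsFactors = FALSE),
            m = 0L)
}

#' GO enrichment for every LCD class of one organism
#'
#' Study set per class = proteins with at least one LCD of the class;
#' population = all proteins of the proteome present in the annotation
#' universe intersected with the proteome (the full proteome by
#' default).
#'
#' @param lcds LCD table for the organism.
#' @param p The \code{\link{proteome}}.
#' @param annotations,ont,alpha,min_depth,alternative See
#'   \code{\link{go_enrich}}.
#' @return data.frame with a leading class_label column.
#' @export
go_enrich_classes <- function(lcds, p, annotations, ont,
                              alpha = 0.05, min_depth = 4,
                              alternative = "greater") {
  population <- names(p$sequences)
  out <- list()
  for (lab in sort(unique(lcds$class_label))) {
    study <- unique(lcds$accession[lcds$class_label == lab])
    rec <- go_enrich(study, population, annotations, ont,
                     alpha = alpha, min_depth = min_depth,
                     alternative = alternative)
    if (nrow(rec))
      out[[length(out) + 1L]] <-
        cbind(data.frame(class_label = lab, stringsAsFactors = FALSE), rec)
  }
  if (!length(out))
    return(cbind(data.frame(class_label = character(0),
                            stringsAsFactors = FALSE), empty_go_table()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-organism sharing of LCD class / GO term pairs
#'
#' For every (class, term) pair significantly enriched in at least one
#' organism of the group, the percentage of the group's organisms in
#' which the pair is significant. Pairs significant nowhere are not
#' emitted.
#'
#' @param per_organism Named list (organism -> data.frame from
#'   \code{\link{go_enrich_classes}}).
#' @param group_size Denominator; defaults to \code{length(per_organism)}
#'   (all organisms of the group with GO analyses available).
#' @return data.frame: class_label, go_id, n_significant, pct_organisms.
#' @export
shared_pair_summary <- function(per_organism,
                                group_size = length(per_organism)) {
  if (!group_size) stop("empty organism group")
  pairs <- list()
  for (org in names(per_organism)) {
    rec <- per_organism[[org]]
    sig <- rec[rec$significant, c("class_label", "go_id"), drop = FALSE]
    if (nrow(sig))
      pairs[[org]] <- unique(paste(sig$class_label, sig$go_id,
                                   sep = "\r"))
  }
  if (!length(pairs))
    return(data.frame(class_label = character(0), go_id = character(0),
                      n_significant = integer(0),
                      pct_organisms = numeric(0), stringsAsFactors = FALSE))
  tab <- table(unlist(pairs))
  keys <- names(tab)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  res <- data.frame(class_label = vapply(parts, `[`, "", 1),
                    go_id = vapply(parts, `[`, "", 2),
                    n_significant = as.integer(tab),
                    pct_organisms = 100 * as.integer(tab) / group_size,
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(-res$pct_organisms, res$class_label, res$go_id), ,
      drop = FALSE]
}
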
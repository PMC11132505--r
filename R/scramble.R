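# Scrambled-proteome null model and enrichment statistics.
#
# Each proteome is scrambled once: initiator residues are set aside, the
# remaining residues of all proteins are pooled and Fisher-Yates
# shuffled, the pool is re-segmented into the original protein lengths
# (minus the initiator), and each initiator is prepended back. The
# scrambled proteome therefore preserves the protein count, every
# protein's length and first residue, and the whole-proteome residue
# multiset, while destroying local composition clusters.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  code
}

#' Scramble a proteome under length/composition constraints
#'
#' @param p A \code{\link{proteome}}.
#' @param seed Integer seed; the permutation is drawn from R's
#'   Mersenne-Twister generator, so a fixed seed gives identical output.
#' @return A \code{proteome} with id suffixed "_scrambled", identical
#'   protein count, per-protein lengths, initiator residues, and residue
#'   multiset. Length-1 proteins contribute nothing to the pool and
#'   survive unchanged.
#' @export
scramble_proteome <- function(p, seed) {
  stopifnot(inherits(p, "proteome"))
  seqs <- p$sequences
  if (!length(seqs))
    return(proteome(paste0(p$proteome_id, "_scrambled"), seqs,
                    p$domain_of_life, p$clade))
  chars <- strsplit(seqs, "", fixed = TRUE)
  initiators <- vapply(chars, `[`, "", 1)
  tails <- lapply(chars, function(x) x[-1])
  pool <- unlist(tails, use.names = FALSE)
  if (length(pool) > 1)
    pool <- with_seed(seed, pool[sample.int(length(pool))])
  lens <- lengths(tails)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- vapply(seq_along(seqs), function(i) {
    if (lens[i] == 0L) return(initiators[i])
    paste0(initiators[i],
           paste(pool[starts[i]:ends[i]], collapse = ""))
  }, character(1))
  names(out) <- names(seqs)
  proteome(paste0(p$proteome_id, "_scrambled"), out,
           p$domain_of_life, p$clade)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p from the hypergeometric distribution with fixed margins: the
#' sum of the probabilities of all tables as or less probable than the
#' observed one (with the conventional 1 + 1e-7 relative tolerance on
#' "as probable"). Computed directly from \code{stats::dhyper}; agrees
#' with \code{stats::fisher.test}.
#'
#' @param a,b,c,d Non-negative counts: a/b = group 1 with/without the
#'   property, c/d = group 2 with/without.
#' @return Two-sided p-value in (0, 1], or NA_real_ for an all-zero
#'   table.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  if (m + n2 == 0) return(NA_real_)
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  # guard against underflow to 0 on extreme tables: p must stay in (0, 1]
  min(1, max(p, .Machine$double.xmin))
}

#' Log odds ratio with Woolf confidence interval and pseudocount rule
#'
#' When either with-LCD cell (a or c) is zero, 1 is added to all four
#' cells and the estimate flagged biased; the without-LCD cells (b, d)
#' never trigger the pseudocount. The 95\% CI is
#' lnOR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d) on the (possibly
#' adjusted) table.
#'
#' @param a,b,c,d Non-negative counts (see
#'   \code{\link{fisher_exact_2x2}}).
#' @return List with lnOR, ci_low, ci_high, biased; lnOR is NA when a
#'   without-cell is zero even after adjustment.
#' @export
ln_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  biased <- (a == 0 || c == 0)
  if (biased) {
    a <- a + 1; b <- b + 1; c <- c + 1; d <- d + 1
  }
  if (b == 0 || d == 0)
    return(list(lnOR = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                biased = biased))
  lnor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(lnOR = lnor, ci_low = lnor - 1.96 * se,
       ci_high = lnor + 1.96 * se, biased = biased)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Sorts p ascending, applies adjusted_(i) = 1 - (1 - p_(i))^(m - i + 1)
#' with a running maximum to enforce step-down monotonicity, caps at 1,
#' and maps back to the input order. m counts only the p-values supplied.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Single-step Sidak correction
#'
#' adjusted = 1 - (1 - p)^m with m = \code{length(p)} (or an explicit
#' test count when some tests are not carried in \code{p}).
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param m Number of tests (default \code{length(p)}).
#' @return Adjusted p-values in the input order.
#' @export
sidak <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  pmin(1, 1 - (1 - p)^m)
}

#' Original-vs-scrambled LCD enrichment analysis for one organism
#'
#' Scrambles the proteome once with \code{seed}, rescans it with the same
#' class specs, and for every class builds the 2x2 table (a = original
#' proteins with an LCD, b = without, c/d = the same for the scrambled
#' proteome). Classes with at least one LCD instance in either proteome
#' are tested (two-sided Fisher by default) and Holm-Sidak corrected
#' across those represented classes only; unrepresented classes are
#' carried with NA p-values and flagged not significant.
#'
#' @param p A \code{\link{proteome}}.
#' @param lcds_orig LCD table from scanning \code{p} with \code{specs}.
#' @param seed Integer scramble seed.
#' @param specs Class specs used for both scans.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param alternative "two.sided" (default), "greater" or "less", passed
#'   to the Fisher test.
#' @return data.frame with one row per class: class_label, a, b, c, d,
#'   p_raw, p_adj, lnOR, ci_low, ci_high, biased, represented,
#'   significant, direction ("enriched", "depleted" or "none"); the
#'   scramble seed is attached as attribute \code{seed}.
#' @export
enrichment_analysis <- function(p, lcds_orig, seed,
                                specs = all_class_specs(),
                                alpha = 0.05,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(p, "proteome"))
  scr <- scramble_proteome(p, seed)
  lcds_scr <- scan_proteome(scr, specs)
  n_total <- length(p$sequences)
  labels <- vapply(specs, `[[`, "", "label")
  n_with <- function(lcds, lab)
    length(unique(lcds$accession[lcds$class_label == lab]))
  a <- vapply(labels, n_with, integer(1), lcds = lcds_orig)
  c_ <- vapply(labels, n_with, integer(1), lcds = lcds_scr)
  b <- n_total - a
  d <- n_total - c_
  represented <- (a + c_) > 0
  p_raw <- rep(NA_real_, length(labels))
  if (any(represented)) {
    p_raw[represented] <- mapply(function(aa, bb, cc, dd) {
      if (alternative == "two.sided") fisher_exact_2x2(aa, bb, cc, dd)
      else stats::fisher.test(matrix(c(aa, cc, bb, dd), 2),
                              alternative = alternative)$p.value
    }, a[represented], b[represented], c_[represented], d[represented])
  }
  p_adj <- rep(NA_real_, length(labels))
  if (any(represented)) p_adj[represented] <- holm_sidak(p_raw[represented])
  ors <- mapply(function(aa, bb, cc, dd) ln_odds_ratio(aa, bb, cc, dd),
                a, b, c_, d, SIMPLIFY = FALSE)
  lnor <- vapply(ors, `[[`, numeric(1), "lnOR")
  significant <- !is.na(p_adj) & p_adj < alpha
  direction <- ifelse(!significant | is.na(lnor), "none",
                      ifelse(lnor > 0, "enriched",
                             ifelse(lnor < 0, "depleted", "none")))
  res <- data.frame(
    class_label = labels,
    a = a, b = b, c = c_, d = d,
    p_raw = p_raw, p_adj = p_adj,
    lnOR = lnor,
    ci_low = vapply(ors, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(ors, `[[`, numeric(1), "ci_high"),
    biased = vapply(ors, `[[`, logical(1), "biased"),
    represented = represented,
    significant = significant,
    direction = direction,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "seed") <- seed
  attr(res, "alternative") <- alternative
  res
}

#' Cross-organism enrichment summary for a group
#'
#' Per class: the percentage of the group's organisms with significant
#' enrichment (p_adj < alpha and lnOR > 0), the percentage with
#' significant depletion (lnOR < 0), and the median lnOR. Denominators
#' are all organisms in the group; classes unrepresented in an organism
#' count as not significant, and biased lnOR estimates are included in
#' the median.
#'
#' @param results List of \code{\link{enrichment_analysis}} data.frames,
#'   one per organism in the group.
#' @return data.frame: class_label, pct_enriched, pct_depleted,
#'   median_lnOR.
#' @export
domain_enrichment_summary <- function(results) {
  if (!length(results)) stop("empty organism group")
  labels <- results[[1]]$class_label
  n <- length(results)
  enr <- dep <- numeric(length(labels))
  med <- numeric(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    rows <- lapply(results, function(r) r[r$class_label == lab, ])
    sig <- vapply(rows, function(r)
      nrow(r) == 1 && isTRUE(r$significant), logical(1))
    ln <- vapply(rows, function(r)
      if (nrow(r) == 1) r$lnOR else NA_real_, numeric(1))
    enr[i] <- 100 * sum(sig & !is.na(ln) & ln > 0) / n
    dep[i] <- 100 * sum(sig & !is.na(ln) & ln < 0) / n
    med[i] <- stats::median(ln, na.rm = TRUE)
  }
  data.frame(class_label = labels, pct_enriched = enr,
             pct_depleted = dep, median_lnOR = med,
             stringsAsFactors = FALSE)
}
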
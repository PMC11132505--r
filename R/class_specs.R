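#' Define one LCD class search
#'
#' An LCD class is defined by a primary amino acid (and optionally a
#' secondary amino acid), a sliding-window size, minimum windowed
#' composition thresholds, and a minimum linear dispersion. The class
#' label is the primary letter alone ("Q") for the 20 primary classes, or
#' the ordered pair ("HQ") for the 380 secondary classes. The ordering is
#' positional: "HQ" applies the primary threshold to H and the secondary
#' threshold to Q, even if Q's realized composition ends up higher.
#'
#' @param primary_aa Single canonical amino-acid letter.
#' @param secondary_aa Single canonical letter distinct from
#'   \code{primary_aa}, or \code{NULL}/\code{NA} for a primary class.
#' @param window Window size in residues (default 20).
#' @param primary_threshold Minimum windowed fraction of the primary amino
#'   acid (default 0.40).
#' @param secondary_threshold Minimum windowed fraction of the secondary
#'   amino acid (default 0.20; ignored for primary classes).
#' @param dispersion_threshold Minimum linear dispersion, applied
#'   separately to each searched amino acid (default 0.5).
#' @return A list of class \code{lcd_class_spec}.
#' @export
lcd_class_spec <- function(primary_aa, secondary_aa = NULL,
                           window = 20L,
                           primary_threshold = 0.40,
                           secondary_threshold = 0.20,
                           dispersion_threshold = 0.5) {
  if (length(secondary_aa) == 1 && (is.na(secondary_aa) || !nzchar(secondary_aa)))
    secondary_aa <- NULL
  if (!is.character(primary_aa) || nchar(primary_aa) != 1 ||
      !(primary_aa %in% AA20))
    stop("primary_aa must be one of the 20 canonical amino-acid letters")
  if (!is.null(secondary_aa)) {
    if (!(secondary_aa %in% AA20))
      stop("secondary_aa must be a canonical amino-acid letter")
    if (secondary_aa == primary_aa)
      stop("secondary_aa must differ from primary_aa")
  }
  window <- as.integer(window)
  if (is.na(window) || window < 2) stop("window must be >= 2")
  if (!(primary_threshold > 0 && primary_threshold <= 1))
    stop("primary_threshold must be in (0, 1]")
  if (!(secondary_threshold > 0 && secondary_threshold <= 1))
    stop("secondary_threshold must be in (0, 1]")
  if (!is.null(secondary_aa) &&
      primary_threshold + secondary_threshold > 1 + 1e-12)
    stop("Invalid threshold: primary + secondary composition thresholds ",
         "exceed 100%")
  if (dispersion_threshold < 0 || dispersion_threshold > 1)
    stop("dispersion_threshold must be in [0, 1]")
  structure(list(primary_aa = primary_aa,
                 secondary_aa = secondary_aa,
                 window = window,
                 primary_threshold = primary_threshold,
                 secondary_threshold = secondary_threshold,
                 dispersion_threshold = dispersion_threshold,
                 label = paste0(primary_aa, secondary_aa %||% "")),
            class = "lcd_class_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lcd_class_spec <- function(x, ...) {
  cat(sprintf(
    "<lcd_class_spec %s> window=%d, primary %s>=%.0f%%%s, dispersion>=%.2f\n",
    x$label, x$window, x$primary_aa, 100 * x$primary_threshold,
    if (is.null(x$secondary_aa)) "" else
      sprintf(", secondary %s>=%.0f%%", x$secondary_aa,
              100 * x$secondary_threshold),
    x$dispersion_threshold))
  invisible(x)
}

#' The full 400-class search set
#'
#' Builds the 20 primary-class specs followed by the 380 ordered
#' secondary-class specs, in the fixed lexicographic order used for
#' signature keys.
#'
#' @inheritParams lcd_class_spec
#' @param classes Optional character vector of class labels ("Q", "HQ",
#'   ...) to restrict the set.
#' @return Named list of \code{lcd_class_spec} objects keyed by label.
#' @export
all_class_specs <- function(classes = NULL, window = 20L,
                            primary_threshold = 0.40,
                            secondary_threshold = 0.20,
                            dispersion_threshold = 0.5) {
  labels <- all_class_labels()
  if (!is.null(classes)) {
    bad <- setdiff(classes, labels)
    if (length(bad))
      stop("unknown class label(s): ", paste(bad, collapse = ", "))
    labels <- labels[labels %in% classes]
  }
  specs <- lapply(labels, function(lab) {
    lcd_class_spec(substr(lab, 1, 1),
                   if (nchar(lab) == 2) substr(lab, 2, 2) else NULL,
                   window = window,
                   primary_threshold = primary_threshold,
                   secondary_threshold = secondary_threshold,
                   dispersion_threshold = dispersion_threshold)
  })
  names(specs) <- labels
  specs
}

#' All 400 class labels in canonical order
#'
#' 20 primary labels (alphabetical) followed by 380 ordered secondary
#' labels (lexicographic), fixing the key order of occupancy signatures.
#'
#' @return Character vector of length 400.
#' @export
all_class_labels <- function() {
  sec <- as.vector(t(outer(AA20, AA20, paste0)))
  sec <- sec[substr(sec, 1, 1) != substr(sec, 2, 2)]
  c(AA20, sort(sec))
}

#' Collapse a secondary label and its reciprocal to one canonical label
#'
#' "HQ" and "QH" both map to "HQ|QH" (alphabetical concatenation);
#' primary labels are returned unchanged.
#'
#' @param labels Character vector of class labels.
#' @return Character vector of canonical (reciprocal-merged) labels.
#' @export
reciprocal_label <- function(labels) {
  vapply(labels, function(lab) {
    if (nchar(lab) != 2) return(lab)
    pair <- sort(c(lab, paste0(substr(lab, 2, 2), substr(lab, 1, 1))))
    paste(pair, collapse = "|")
  }, character(1), USE.NAMES = FALSE)
}
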
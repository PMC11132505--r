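#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino-acid one-letter codes, in the fixed order used
#' throughout the package for class labels and signature keys.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DOMAINS_OF_LIFE <- c("Archaea", "Bacteria", "Eukaryota", "Viruses")

#' Construct a proteome object
#'
#' A proteome is a named list holding an identifier, domain-of-life and
#' clade metadata, and a named character vector of protein sequences
#' (names are accessions).
#'
#' @param proteome_id Character scalar identifier (e.g. "UP000001450_36329").
#' @param sequences Named character vector of uppercase amino-acid sequences.
#' @param domain_of_life One of "Archaea", "Bacteria", "Eukaryota",
#'   "Viruses", "Unknown".
#' @param clade Character scalar; the first lineage term after the domain
#'   of life, or "" when unknown.
#' @return An object of class \code{proteome}.
#' @export
proteome <- function(proteome_id, sequences,
                     domain_of_life = "Unknown", clade = "") {
  stopifnot(is.character(sequences))
  if (length(sequences) > 0) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("every protein needs a non-empty accession")
    if (anyDuplicated(names(sequences)))
      stop("duplicate accessions in proteome: ",
           paste(unique(names(sequences)[duplicated(names(sequences))]),
                 collapse = ", "))
    if (any(nchar(sequences) < 1))
      stop("empty sequence for record(s): ",
           paste(names(sequences)[nchar(sequences) < 1], collapse = ", "))
  }
  domain_of_life <- match.arg(domain_of_life,
                              c(DOMAINS_OF_LIFE, "Unknown"))
  structure(list(proteome_id = as.character(proteome_id),
                 domain_of_life = domain_of_life,
                 clade = as.character(clade),
                 sequences = sequences),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome %s> %d proteins, %d residues (%s%s)\n",
              x$proteome_id, length(x$sequences),
              sum(nchar(x$sequences)), x$domain_of_life,
              if (nzchar(x$clade)) paste0("; ", x$clade) else ""))
  invisible(x)
}

#' Total residue count of a proteome
#' @param p A \code{proteome}.
#' @return Integer total number of residues.
#' @export
n_residues <- function(p) sum(nchar(p$sequences))

#' Read a protein FASTA file into a proteome
#'
#' Accessions are taken from the header token before the first whitespace;
#' UniProt-style \code{db|ACC|name} headers yield \code{ACC}. Sequences are
#' uppercased and stripped of whitespace; trailing/internal \code{*} (stop)
#' characters are removed with a warning.
#'
#' @param path Path to a FASTA file.
#' @param proteome_id Identifier for the proteome; defaults to the file
#'   name without extension.
#' @param domain_of_life,clade Optional metadata (see \code{\link{proteome}}).
#' @return A \code{proteome}.
#' @export
read_fasta <- function(path, proteome_id = NULL,
                       domain_of_life = "Unknown", clade = "") {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  if (is.null(proteome_id))
    proteome_id <- sub("\\.[^.]*$", "", basename(path))
  aas <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(aas))
  if (any(grepl("\\*", seqs))) {
    warning("stripping '*' (stop) characters from ",
            sum(grepl("\\*", seqs)), " sequence(s) in ", basename(path))
    seqs <- gsub("\\*", "", seqs)
  }
  headers <- names(aas)
  if (is.null(headers)) headers <- rep("", length(seqs))
  acc <- vapply(headers, parse_fasta_accession, character(1),
                USE.NAMES = FALSE)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(acc[empty], collapse = ", "))
  names(seqs) <- acc
  proteome(proteome_id, seqs, domain_of_life, clade)
}

parse_fasta_accession <- function(header) {
  tok <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
  if (is.na(tok) || !nzchar(tok)) stop("FASTA record with empty header")
  parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 3 && nzchar(parts[2])) parts[2] else tok
}

#' Write a proteome to FASTA
#'
#' @param p A \code{proteome}.
#' @param path Output file path.
#' @param width Line width for wrapped sequences.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(p, path, width = 60L) {
  set <- Biostrings::BStringSet(p$sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse a taxonomic lineage string into domain of life and clade
#'
#' Scans semicolon- or comma-separated lineage terms for the first
#' recognized domain of life (Archaea, Bacteria, Eukaryota, Viruses); the
#' next term, when present, is the clade. Unrecognizable input yields
#' \code{("Unknown", "")} rather than an error.
#'
#' @param lineage Character scalar, e.g. "Eukaryota; Metazoa; Chordata".
#' @return List with elements \code{domain_of_life} and \code{clade}.
#' @export
parse_lineage <- function(lineage) {
  if (is.null(lineage) || length(lineage) != 1 || is.na(lineage))
    return(list(domain_of_life = "Unknown", clade = ""))
  terms <- trimws(strsplit(as.character(lineage), "[;,]")[[1]])
  terms <- terms[nzchar(terms)]
  hit <- match(TRUE, terms %in% DOMAINS_OF_LIFE)
  if (is.na(hit)) return(list(domain_of_life = "Unknown", clade = ""))
  clade <- if (hit < length(terms)) terms[hit + 1L] else ""
  list(domain_of_life = terms[hit], clade = clade)
}

#' Read proteome metadata from a sidecar TSV
#'
#' Expects columns \code{proteome_id}, \code{domain_of_life} (optional) and
#' \code{lineage} (optional). When \code{domain_of_life} is absent it is
#' derived from \code{lineage} via \code{\link{parse_lineage}}.
#'
#' @param path Path to a tab-separated metadata file with a header row.
#' @return data.frame with columns proteome_id, domain_of_life, clade.
#' @export
read_proteome_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"proteome_id" %in% names(md))
    stop("metadata file lacks a proteome_id column: ", path)
  if (!"domain_of_life" %in% names(md) || !"clade" %in% names(md)) {
    lin <- if ("lineage" %in% names(md)) md$lineage else
      rep(NA_character_, nrow(md))
    parsed <- lapply(lin, parse_lineage)
    if (!"domain_of_life" %in% names(md))
      md$domain_of_life <- vapply(parsed, `[[`, "", "domain_of_life")
    if (!"clade" %in% names(md))
      md$clade <- vapply(parsed, `[[`, "", "clade")
  }
  md[, c("proteome_id", "domain_of_life", "clade",
         setdiff(names(md), c("proteome_id", "domain_of_life", "clade")))]
}

#' Write a results table as TSV
#'
#' Tab-separated with a header row; numeric columns rendered with 6
#' significant digits; rows sorted by the first schema column for
#' deterministic output.
#'
#' @param rows data.frame of results.
#' @param path Output path.
#' @param schema Ordered character vector of column names; every column
#'   must be present in \code{rows}.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(rows, path, schema = names(rows)) {
  missing <- setdiff(schema, names(rows))
  if (length(missing))
    stop("rows are missing schema column(s): ",
         paste(missing, collapse = ", "))
  out <- rows[, schema, drop = FALSE]
  if (nrow(out) > 1) out <- out[order(out[[1]], method = "radix"), ,
                                drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by \code{\link{write_table}}
#' @param path Path to the file.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
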
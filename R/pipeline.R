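# End-to-end survey orchestration: scan -> stats -> enrichment -> GO ->
# signatures over a directory of proteome FASTAs, driven by one config.

#' Build a run configuration
#'
#' @param input_dir Directory of proteome FASTA files (one per organism).
#' @param metadata Path to the metadata TSV (proteome_id,
#'   domain_of_life/lineage), or NULL.
#' @param out_dir Output directory.
#' @param classes "all" or a character vector of class labels.
#' @param window,primary_threshold,secondary_threshold,
#'   dispersion_threshold Scanner settings (defaults 20, 0.40, 0.20,
#'   0.5).
#' @param seed Scramble seed (default 42).
#' @param alpha Significance level (default 0.05).
#' @param min_depth GO reporting depth (default 4).
#' @param obo,gaf_dir Optional ontology path and directory of per-
#'   organism GAF files named <proteome_id>.gaf; GO stage skipped when
#'   absent.
#' @param exclude Proteome ids excluded from every summary.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(input_dir, metadata = NULL, out_dir,
                       classes = "all", window = 20L,
                       primary_threshold = 0.40,
                       secondary_threshold = 0.20,
                       dispersion_threshold = 0.5,
                       seed = 42L, alpha = 0.05, min_depth = 4L,
                       obo = NULL, gaf_dir = NULL,
                       exclude = character(0)) {
  cls <- if (identical(classes, "all")) NULL else classes
  # validate thresholds up front via a representative spec
  lcd_class_spec("Q", "N", window, primary_threshold,
                 secondary_threshold, dispersion_threshold)
  structure(list(input_dir = input_dir, metadata = metadata,
                 out_dir = out_dir, classes = cls, window = window,
                 primary_threshold = primary_threshold,
                 secondary_threshold = secondary_threshold,
                 dispersion_threshold = dispersion_threshold,
                 seed = as.integer(seed), alpha = alpha,
                 min_depth = min_depth, obo = obo, gaf_dir = gaf_dir,
                 exclude = exclude),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys match \code{\link{run_config}}
#'   arguments.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full LCD survey
#'
#' Stages: read proteomes (+metadata), scan all classes, per-organism
#' count tables, organism-level frequencies per domain, scrambled-
#' proteome enrichment, GO enrichment (when ontology/annotations are
#' configured), occupancy signatures and distance matrix. All stage
#' outputs are TSVs under \code{out_dir}; a manifest YAML records every
#' parameter, seed and per-stage row count, so a rerun with the same
#' config is bit-identical.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list of the in-memory stage results (proteomes,
#'   lcds, tables, frequencies, enrichment, go, signatures, manifest).
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fastas <- sort(list.files(config$input_dir, pattern = "\\.fa(sta)?$",
                            full.names = TRUE))
  meta <- if (!is.null(config$metadata))
    read_proteome_metadata(config$metadata) else NULL
  specs <- all_class_specs(config$classes, config$window,
                           config$primary_threshold,
                           config$secondary_threshold,
                           config$dispersion_threshold)
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("out_dir"))],
                   n_organisms = 0L, stages = list())
  proteomes <- list(); lcds <- list(); tables <- list()
  for (f in fastas) {
    pid <- sub("\\.[^.]*$", "", basename(f))
    if (pid %in% config$exclude) next
    dom <- "Unknown"; clade <- ""
    if (!is.null(meta)) {
      i <- match(pid, meta$proteome_id)
      if (!is.na(i)) { dom <- meta$domain_of_life[i]; clade <- meta$clade[i] }
    }
    p <- read_fasta(f, pid, dom, clade)
    proteomes[[pid]] <- p
    lc <- scan_proteome(p, specs)
    lcds[[pid]] <- lc
    tables[[pid]] <- count_class_table(lc, p)
    message(sprintf("[scan] %s: %d proteins, %d LCDs",
                    pid, length(p$sequences), nrow(lc)))
  }
  manifest$n_organisms <- length(proteomes)
  if (!length(proteomes)) {
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    return(invisible(list(proteomes = proteomes, manifest = manifest)))
  }
  all_lcds <- do.call(rbind, lcds)
  rownames(all_lcds) <- NULL
  write_table(all_lcds, file.path(config$out_dir, "lcds.tsv"))
  manifest$stages$scan <- list(rows = nrow(all_lcds))
  count_rows <- do.call(rbind, lapply(tables, function(tb) {
    df <- as.data.frame(tb)
    df$n_proteins_total <- rep(attr(tb, "n_proteins_total"), nrow(df))
    df$n_residues_total <- rep(attr(tb, "n_residues_total"), nrow(df))
    df
  }))
  rownames(count_rows) <- NULL
  write_table(count_rows, file.path(config$out_dir, "class_counts.tsv"))
  manifest$stages$counts <- list(rows = nrow(count_rows))
  doms <- vapply(proteomes, `[[`, "", "domain_of_life")
  freq_rows <- list()
  freqs_by_domain <- list()
  for (dom in sort(unique(doms))) {
    tb <- tables[doms == dom]
    fr <- organism_level_frequency(tb)
    freqs_by_domain[[dom]] <- fr
    freq_rows[[dom]] <- data.frame(domain_of_life = dom,
                                   class_label = names(fr),
                                   pct_organisms = unname(fr),
                                   rarity = rarity_category(unname(fr)),
                                   stringsAsFactors = FALSE)
  }
  freq_df <- do.call(rbind, freq_rows)
  rownames(freq_df) <- NULL
  write_table(freq_df[freq_df$pct_organisms > 0 |
                        nchar(freq_df$class_label) == 1, ],
              file.path(config$out_dir, "organism_frequencies.tsv"))
  manifest$stages$frequencies <- list(rows = nrow(freq_df))
  enr <- list()
  for (pid in names(proteomes)) {
    e <- enrichment_analysis(proteomes[[pid]], lcds[[pid]],
                             seed = config$seed, specs = specs,
                             alpha = config$alpha)
    e <- e[e$represented, , drop = FALSE]
    e <- cbind(data.frame(proteome_id = rep(pid, nrow(e)),
                          stringsAsFactors = FALSE), e)
    enr[[pid]] <- e
    message(sprintf("[enrich] %s: %d represented classes, %d significant",
                    pid, nrow(e), sum(e$significant)))
  }
  enr_df <- do.call(rbind, enr)
  rownames(enr_df) <- NULL
  write_table(enr_df, file.path(config$out_dir, "enrichment.tsv"))
  manifest$stages$enrichment <- list(rows = nrow(enr_df),
                                     seed = config$seed)
  go_res <- NULL
  if (!is.null(config$obo) && !is.null(config$gaf_dir)) {
    ont <- load_ontology(config$obo)
    per_org <- list()
    for (pid in names(proteomes)) {
      gf <- file.path(config$gaf_dir, paste0(pid, ".gaf"))
      if (!file.exists(gf)) next
      ann <- load_annotations(gf, proteomes[[pid]])
      per_org[[pid]] <- go_enrich_classes(lcds[[pid]], proteomes[[pid]],
                                          ann, ont,
                                          alpha = config$alpha,
                                          min_depth = config$min_depth)
      message(sprintf("[go] %s: %d class/term records", pid,
                      nrow(per_org[[pid]])))
    }
    if (length(per_org)) {
      go_df <- do.call(rbind, lapply(names(per_org), function(pid)
        cbind(data.frame(proteome_id = rep(pid, nrow(per_org[[pid]])),
                         stringsAsFactors = FALSE), per_org[[pid]])))
      rownames(go_df) <- NULL
      write_table(go_df, file.path(config$out_dir, "go_enrichment.tsv"))
      shared <- list()
      for (dom in sort(unique(doms))) {
        sub <- per_org[names(per_org) %in% names(doms)[doms == dom]]
        if (!length(sub)) next
        sm <- shared_pair_summary(sub, group_size = sum(doms == dom))
        if (nrow(sm))
          shared[[dom]] <- cbind(data.frame(domain_of_life = dom,
                                            stringsAsFactors = FALSE), sm)
      }
      if (length(shared)) {
        shared_df <- do.call(rbind, shared)
        rownames(shared_df) <- NULL
        write_table(shared_df,
                    file.path(config$out_dir, "go_shared_pairs.tsv"))
      }
      go_res <- list(per_organism = per_org,
                     shared = if (length(shared)) shared_df else NULL)
      manifest$stages$go <- list(organisms = length(per_org))
    }
  }
  sigs <- lapply(tables, build_signature)
  sig_mat <- t(vapply(sigs, unclass, numeric(400)))
  sig_df <- cbind(data.frame(proteome_id = names(sigs),
                             stringsAsFactors = FALSE),
                  as.data.frame(sig_mat))
  write_table(sig_df, file.path(config$out_dir, "signatures.tsv"))
  manifest$stages$signatures <- list(rows = nrow(sig_df))
  dmat <- signature_distance_matrix(sigs)
  if (nrow(dmat) >= 2) {
    ddf <- cbind(data.frame(proteome_id = rownames(dmat),
                            stringsAsFactors = FALSE),
                 as.data.frame(dmat))
    write_table(ddf, file.path(config$out_dir, "distance_matrix.tsv"))
    if (nrow(dmat) >= 3) {
      tree <- complete_linkage_cluster(dmat)
      as_newick(tree, file.path(config$out_dir, "dendrogram.nwk"))
    }
  }
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(proteomes = proteomes, lcds = lcds, tables = tables,
                 frequencies = freqs_by_domain, enrichment = enr,
                 go = go_res, signatures = sigs, manifest = manifest))
}
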
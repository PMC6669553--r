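# End-to-end orchestration: one call runs annotation, repeat discovery and,
# when inputs are given, variant classification, species demarcation and
# gene-content comparison, collecting per-stage status into one report.

#' Run the genome report pipeline
#'
#' Stages always run: genome stats (length, G+C), ORF scan + overlap filter,
#' tandem-repeat detection, hr clustering (when `core_motifs` given) and
#' motif counts. Optional stages run when their inputs are supplied. A stage
#' that errors is marked failed and the remaining stages still run.
#'
#' @param genome A [circular_genome()] or a path to a FASTA/GenBank file.
#' @param reference_proteins Named character vector for homology labelling.
#' @param core_names Core-gene labels (subset of the reference names).
#' @param variants Variant tibble ([read_variants()]) or a path.
#' @param marker_alignments Named list of marker alignments (gene -> named
#'   character vector) including `query_taxon`, for species demarcation.
#' @param query_taxon Query taxon name inside the marker alignments.
#' @param compare_proteomes Named list of proteomes (genome id -> named
#'   character vector) for RBH/Venn comparison; the first is taken as the
#'   query genome.
#' @param params List overriding defaults: `min_aa` (50), `max_overlap`
#'   (0.5), `min_unit` (10), `max_unit` (100), `min_copies` (3),
#'   `min_identity` (85), `core_motifs` (the four hr core motifs),
#'   `hr_window` (2000), `hr_min_hits` (2), `min_score` (50),
#'   `min_coverage` (50), `t_low` (0.015), `t_high` (0.05).
#' @return A `baculo_report`: list with `stats`, `orfs`, `repeats`, `hrs`,
#'   `motif_counts`, `variant_effects`, `variant_summary`, `species_calls`,
#'   `venn`, `ortholog_groups`, `params`, `stage_status`.
#' @export
run_report <- function(genome,
                       reference_proteins = NULL, core_names = character(),
                       variants = NULL,
                       marker_alignments = NULL, query_taxon = NULL,
                       compare_proteomes = NULL,
                       params = list()) {
  p <- utils::modifyList(default_params(), params)
  status <- list()
  out <- list(params = p)
  run_stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE, value = NULL,
                                             msg = conditionMessage(e)))
    status[[name]] <<- if (res$ok) "ok" else paste("failed:", res$msg)
    res$value
  }

  if (is.character(genome)) {
    genome <- if (grepl("\\.(gb|gbk|genbank)$", genome)) {
      read_genbank(genome)$genome
    } else {
      read_fasta(genome)[[1]]
    }
  }
  out$genome <- genome
  out$stats <- run_stage("stats", tibble::tibble(
    genome_id = genome$id, length_bp = genome$length,
    gc_percent = gc_content(genome), topology = genome$topology
  ))

  orfs <- run_stage("orfs", {
    cand <- scan_orfs(genome, min_aa = p$min_aa)
    filter_overlaps(cand, max_fraction = p$max_overlap,
                    genome_length = genome$length)
  })
  if (!is.null(orfs) && !is.null(reference_proteins)) {
    orfs <- run_stage("homology", label_homologs(
      orfs, reference_proteins, min_score = p$min_score,
      core_names = core_names
    )) %||% orfs
  }
  out$orfs <- orfs

  out$repeats <- run_stage("repeats", find_tandem_repeats(
    genome, min_unit = p$min_unit, max_unit = p$max_unit,
    min_copies = p$min_copies, min_identity = p$min_identity
  ))
  out$hrs <- run_stage("hrs", cluster_hrs(
    genome, p$core_motifs, window = p$hr_window, min_hits = p$hr_min_hits
  ))
  out$motif_counts <- run_stage("motif_counts", tibble::tibble(
    motif = p$core_motifs,
    count_both_strands = purrr::map_int(p$core_motifs, count_motif,
                                        genome = genome),
    count_forward = purrr::map_int(p$core_motifs, count_motif,
                                   genome = genome, strands = "forward")
  ))

  if (!is.null(variants)) {
    if (is.character(variants)) variants <- read_variants(variants)
    out$variant_effects <- run_stage("variants",
                                     classify_variants(variants, orfs, genome))
    if (!is.null(out$variant_effects)) {
      out$variant_summary <- summarize_variants(out$variant_effects)
    }
  }

  if (!is.null(marker_alignments) && !is.null(query_taxon)) {
    out$species_calls <- run_stage("demarcation", demarcate_species(
      marker_alignments, query_taxon, t_low = p$t_low, t_high = p$t_high
    ))
  }

  if (!is.null(compare_proteomes)) {
    cmp <- run_stage("comparison", compare_gene_content(
      compare_proteomes, min_score = p$min_score,
      min_coverage = p$min_coverage
    ))
    out$venn <- cmp$venn
    out$ortholog_groups <- cmp$groups
  }

  out$stage_status <- tibble::tibble(
    stage = names(status), status = unname(unlist(status))
  )
  structure(out, class = "baculo_report")
}

default_params <- function() {
  list(
    min_aa = 50L, max_overlap = 0.5,
    min_unit = 10L, max_unit = 100L, min_copies = 3, min_identity = 85,
    core_motifs = c("TTACGAGAACATT", "GTACTCGAAAA", "AAAATAGAACA",
                    "TTTTTAGCGATG"),
    hr_window = 2000L, hr_min_hits = 3L,
    min_score = 60, min_coverage = 50,
    t_low = 0.015, t_high = 0.050
  )
}

#' All-against-all gene-content comparison
#'
#' Runs [reciprocal_best_hits()] over every genome pair, merges the pairs
#' into ortholog groups and returns the Venn partition.
#'
#' @param proteomes Named list (genome id -> named character vector).
#' @param min_score,min_coverage RBH thresholds.
#' @return A list: `rbh` (all pairs), `groups`, `venn`.
#' @export
compare_gene_content <- function(proteomes, min_score = 60,
                                 min_coverage = 50) {
  gids <- names(proteomes)
  stopifnot(length(gids) >= 2L, !is.null(gids))
  pairs <- utils::combn(gids, 2L, simplify = FALSE)
  rbh <- purrr::map_dfr(pairs, function(pr) {
    hits <- reciprocal_best_hits(proteomes[[pr[1]]], proteomes[[pr[2]]],
                                 min_score = min_score,
                                 min_coverage = min_coverage)
    dplyr::mutate(hits, genome_a = pr[1], genome_b = pr[2], .before = 1L)
  })
  groups <- build_ortholog_groups(rbh, proteomes)
  list(rbh = rbh, groups = groups, venn = venn_partition(groups, gids))
}

#' @export
print.baculo_report <- function(x, ...) {
  s <- x$stats
  cat("== genome report ==\n")
  if (!is.null(s)) {
    cat(sprintf("genome:   %s  %s bp  G+C %.1f%%  (%s)\n", s$genome_id,
                format(s$length_bp, big.mark = ","), s$gc_percent, s$topology))
  }
  if (!is.null(x$orfs)) {
    cat(sprintf("ORFs:     %d retained", nrow(x$orfs)))
    if ("core_gene" %in% names(x$orfs)) {
      cat(sprintf("  (%d core, %d unique)", sum(x$orfs$core_gene),
                  sum(x$orfs$label == "unique")))
    }
    cat("\n")
  }
  if (!is.null(x$repeats)) cat(sprintf("repeats:  %d tandem arrays\n", nrow(x$repeats)))
  if (!is.null(x$hrs)) cat(sprintf("hrs:      %d regions\n", nrow(x$hrs)))
  if (!is.null(x$variant_summary)) {
    v <- x$variant_summary
    cat(sprintf("SNVs:     %d total, %d coding (%d syn / %d non-syn), mean freq %.1f%%\n",
                v$n_total, v$n_coding, v$n_synonymous, v$n_non_synonymous,
                v$mean_frequency))
  }
  if (!is.null(x$species_calls)) {
    cat(sprintf("species:  %d/%d marker comparisons call different_species\n",
                sum(x$species_calls$decision == "different_species"),
                nrow(x$species_calls)))
  }
  if (!is.null(x$venn)) {
    cat(sprintf("venn:     %d ortholog groups over %d genomes\n",
                sum(x$venn$count), max(x$venn$n_genomes)))
  }
  bad <- x$stage_status$status != "ok"
  if (any(bad)) {
    cat("failed stages:", paste(x$stage_status$stage[bad], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' Emits `orfs.gff3`, `orfs.csv`, `proteins.faa`, `repeats.csv`, `hrs.csv`,
#' `motif_counts.csv`, plus variant/species/venn tables when present, and a
#' `report.json` with the summary numbers.
#'
#' @param report A `baculo_report`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- report$genome
  if (!is.null(report$orfs) && nrow(report$orfs)) {
    feats <- report$orfs
    feats$label[!nzchar(feats$label)] <-
      sprintf("orf%03d", seq_len(sum(!nzchar(feats$label))))
    write_gff3(feats[, c("genome_id", "start", "end", "strand", "kind",
                         "label")],
               file.path(dir, "orfs.gff3"), g)
    write_table(dplyr::select(feats, -"protein"), file.path(dir, "orfs.csv"))
    aa <- Biostrings::AAStringSet(feats$protein)
    names(aa) <- feats$label
    Biostrings::writeXStringSet(aa, file.path(dir, "proteins.faa"))
  }
  for (nm in c("repeats", "motif_counts", "variant_summary", "species_calls",
               "venn", "ortholog_groups")) {
    if (!is.null(report[[nm]])) {
      write_table(report[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  if (!is.null(report$hrs) && nrow(report$hrs)) {
    write_table(dplyr::select(report$hrs, -"motif_hits"),
                file.path(dir, "hrs.csv"))
  }
  if (!is.null(report$variant_effects)) {
    write_table(report$variant_effects, file.path(dir, "variant_effects.csv"))
  }
  jsonlite::write_json(as.list(glance(report)), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a K2P distance matrix into one row per pair
#'
#' @param x A `k2p_dist`.
#' @param ... Unused.
#' @return A tibble: `taxon_a`, `taxon_b`, `d`, `defined`, `n_sites`.
#' @method tidy k2p_dist
#' @export
tidy.k2p_dist <- function(x, ...) {
  taxa <- rownames(x$d)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    taxon_a = taxa[idx[, 1]], taxon_b = taxa[idx[, 2]],
    d = x$d[idx], defined = x$defined[idx], n_sites = x$n_sites[idx]
  )
}

#' @rdname tidy.k2p_dist
#' @method glance k2p_dist
#' @export
glance.k2p_dist <- function(x, ...) {
  up <- upper.tri(x$d)
  tibble::tibble(
    n_taxa = nrow(x$d),
    min_d = min(x$d[up][is.finite(x$d[up])]),
    max_d = max(x$d[up][is.finite(x$d[up])]),
    n_saturated = sum(!x$defined[up])
  )
}

#' One-row summary of a genome report
#'
#' @param x A `baculo_report`.
#' @param ... Unused.
#' @method glance baculo_report
#' @export
glance.baculo_report <- function(x, ...) {
  tibble::tibble(
    genome_id = x$stats$genome_id,
    length_bp = x$stats$length_bp,
    gc_percent = x$stats$gc_percent,
    n_orfs = if (is.null(x$orfs)) NA_integer_ else nrow(x$orfs),
    n_core = if (!is.null(x$orfs) && "core_gene" %in% names(x$orfs))
      sum(x$orfs$core_gene) else NA_integer_,
    n_unique = if (!is.null(x$orfs) && "label" %in% names(x$orfs))
      sum(x$orfs$label == "unique") else NA_integer_,
    n_tandem_repeats = if (is.null(x$repeats)) NA_integer_ else nrow(x$repeats),
    n_hrs = if (is.null(x$hrs)) NA_integer_ else nrow(x$hrs),
    n_snvs = if (is.null(x$variant_summary)) NA_integer_ else
      x$variant_summary$n_total,
    all_stages_ok = all(x$stage_status$status == "ok")
  )
}

#' Tidy a genome report into its ORF table
#'
#' @param x A `baculo_report`.
#' @param ... Unused.
#' @method tidy baculo_report
#' @export
tidy.baculo_report <- function(x, ...) x$orfs

# ---- plots ------------------------------------------------------------------

#' Genome map of ORFs and repeat regions
#'
#' @param object A `baculo_report`.
#' @param ... Unused.
#' @return A ggplot: ORFs as strand-separated arrows along the genome
#'   coordinate, repeat regions as shaded bands.
#' @method autoplot baculo_report
#' @export
autoplot.baculo_report <- function(object, ...) {
  orfs <- object$orfs
  stopifnot(!is.null(orfs))
  orfs <- dplyr::mutate(orfs, y = ifelse(.data$strand == "+", 1, -1))
  pl <- ggplot2::ggplot(orfs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y,
                   yend = .data$y, colour = .data$strand),
      linewidth = 3, lineend = "butt"
    ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::scale_y_continuous(breaks = c(-1, 1), labels = c("-", "+"),
                                limits = c(-1.6, 1.6)) +
    ggplot2::labs(x = "genome position (bp)", y = "strand",
                  title = object$stats$genome_id) +
    ggplot2::theme_minimal()
  if (!is.null(object$hrs) && nrow(object$hrs)) {
    pl <- pl + ggplot2::geom_rect(
      data = object$hrs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -1.5, ymax = 1.5, alpha = 0.2, fill = "orange"
    )
  }
  pl
}

#' Heatmap of a K2P distance matrix
#'
#' @param object A `k2p_dist`.
#' @param ... Unused.
#' @method autoplot k2p_dist
#' @export
autoplot.k2p_dist <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::bind_rows(
    long,
    dplyr::rename(long, taxon_a = "taxon_b", taxon_b = "taxon_a")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$taxon_a, .data$taxon_b,
                                     fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$d)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(name = "K2P d") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Variant frequency histogram by effect class
#'
#' @param effects Output of [classify_variants()].
#' @param binwidth Histogram bin width (frequency scale).
#' @export
plot_variant_frequencies <- function(effects, binwidth = 0.02) {
  prim <- effects[effects$primary, , drop = FALSE]
  ggplot2::ggplot(prim, ggplot2::aes(.data$frequency, fill = .data$effect)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "stack") +
    ggplot2::labs(x = "allele frequency", y = "SNVs") +
    ggplot2::theme_minimal()
}

#' Bar chart of a Venn partition
#'
#' @param venn Output of [venn_partition()]; empty subsets are dropped.
#' @export
plot_venn_counts <- function(venn) {
  venn <- venn[venn$count > 0L, , drop = FALSE]
  ggplot2::ggplot(venn, ggplot2::aes(stats::reorder(.data$subset, .data$count),
                                     .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ortholog groups") +
    ggplot2::theme_minimal()
}
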
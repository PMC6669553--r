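# Intrapopulation SNV classification against the ORF annotation:
# synonymous / non-synonymous / intergenic, plus frequency summaries.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Read SNVs from a VCF or delimited table
#'
#' VCF 4.x rows are read with `vcfR`; the allele frequency is taken from the
#' INFO field named by `af_field`. Delimited tables need named columns
#' `position` (1-based), `ref`, `alt`, `frequency` and optionally `depth`.
#' Coordinates are converted to 0-based; multi-allelic rows are split into
#' one record per alternate allele; indel rows are skipped with a counted
#' warning (attribute `n_skipped_indels`).
#'
#' @param path Input file.
#' @param format `"vcf"` or `"table"`; guessed from the extension by default.
#' @param af_field INFO key holding the allele frequency (VCF mode).
#' @return A tibble: `position` (0-based), `ref`, `alt`, `frequency`,
#'   `depth`; attribute `n_skipped_indels`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "table"),
                          af_field = "AF") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    af_raw <- vcfR::extract.info(v, element = af_field)
    if (all(is.na(af_raw))) {
      stop("VCF has no INFO/", af_field, " field", call. = FALSE)
    }
    dp_raw <- suppressWarnings(vcfR::extract.info(v, element = "DP",
                                                  as.numeric = TRUE))
    raw <- tibble::tibble(
      pos1 = as.integer(fix$POS), ref = toupper(fix$REF),
      alt = toupper(fix$ALT), af = af_raw,
      depth = if (is.null(dp_raw)) NA_integer_ else as.integer(dp_raw)
    )
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    names(raw) <- tolower(names(raw))
    stopifnot(all(c("position", "ref", "alt", "frequency") %in% names(raw)))
    raw <- tibble::tibble(
      pos1 = as.integer(raw$position), ref = toupper(raw$ref),
      alt = toupper(raw$alt), af = as.character(raw$frequency),
      depth = if ("depth" %in% names(raw)) as.integer(raw$depth) else NA_integer_
    )
  }
  # split multi-allelic rows (ALT and AF comma-separated in parallel)
  out <- raw |>
    dplyr::mutate(alt = strsplit(.data$alt, ","),
                  af = strsplit(.data$af, ",")) |>
    tidyr::unnest(c("alt", "af")) |>
    dplyr::mutate(frequency = as.numeric(.data$af))
  is_indel <- nchar(out$ref) != 1L | nchar(out$alt) != 1L
  n_indels <- sum(is_indel)
  if (n_indels > 0L) {
    warning(n_indels, " indel record(s) skipped (SNVs only)")
  }
  out <- out[!is_indel, , drop = FALSE]
  res <- tibble::tibble(
    position = out$pos1 - 1L, ref = out$ref, alt = out$alt,
    frequency = out$frequency, depth = out$depth
  )
  attr(res, "n_skipped_indels") <- n_indels
  res
}

# 0-based codon context of genome position p inside ORF (start, end, strand)
codon_context <- function(p, start, end, strand, L) {
  span <- end - start
  if (strand == "+") {
    off <- ((p - start) %% L)
  } else {
    off <- ((end - 1L - p) %% L)   # offset from the 5' end on the minus strand
  }
  if (off >= span) return(NULL)
  list(codon_index = off %/% 3L + 1L, codon_pos = off %% 3L + 1L, offset = off)
}

#' Classify SNVs against the ORF annotation
#'
#' Each variant is mapped to every retained ORF covering it (wrap-aware on
#' circular genomes). For minus-strand ORFs ref/alt are complemented before
#' codon substitution. The codon is rebuilt from the genome, the alternate
#' base substituted at the in-codon offset, and both codons translated with
#' the standard code; a stop-codon change counts as coding (nonsense folds
#' into non-synonymous). Variants covered by two or more ORFs get one row per
#' ORF with `primary = TRUE` on the longest.
#'
#' @param variants Tibble from [read_variants()] (0-based `position`, `ref`,
#'   `alt`, `frequency`).
#' @param orfs Retained ORF tibble ([filter_overlaps()] output).
#' @param genome The [circular_genome()] the coordinates refer to.
#' @return A tibble: the variant columns plus `gene_label`, `codon_index`,
#'   `codon_position`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect` (`synonymous` / `non_synonymous` / `intergenic`), `primary`.
#' @export
classify_variants <- function(variants, orfs, genome) {
  L <- genome$length
  if (nrow(variants) == 0L) {
    return(tibble::tibble(
      position = integer(), ref = character(), alt = character(),
      frequency = numeric(), gene_label = character(),
      codon_index = integer(), codon_position = integer(),
      ref_codon = character(), alt_codon = character(),
      ref_aa = character(), alt_aa = character(), effect = character(),
      primary = logical()
    ))
  }
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    gbase <- circular_subsequence(genome, v$position, v$position + 1L)
    if (gbase != v$ref) {
      stop("ref mismatch at position ", v$position,
           ": genome has ", gbase, ", variant says ", v$ref, call. = FALSE)
    }
    hits <- list()
    for (j in seq_len(nrow(orfs))) {
      ctx <- codon_context(v$position, orfs$start[j], orfs$end[j],
                           orfs$strand[j], L)
      if (is.null(ctx)) next
      strand <- orfs$strand[j]
      cstart <- if (strand == "+") {
        orfs$start[j] + (ctx$codon_index - 1L) * 3L
      } else {
        orfs$end[j] - ctx$codon_index * 3L
      }
      ref_codon <- circular_subsequence(genome, cstart, cstart + 3L)
      if (strand == "-") ref_codon <- revcomp(ref_codon)
      ref_b <- if (strand == "+") v$ref else unname(COMPLEMENT[v$ref])
      alt_b <- if (strand == "+") v$alt else unname(COMPLEMENT[v$alt])
      stopifnot(substr(ref_codon, ctx$codon_pos, ctx$codon_pos) == ref_b)
      alt_codon <- ref_codon
      substr(alt_codon, ctx$codon_pos, ctx$codon_pos) <- alt_b
      ref_aa <- unname(GENETIC_CODE_TBL[ref_codon])
      alt_aa <- unname(GENETIC_CODE_TBL[alt_codon])
      hits[[length(hits) + 1L]] <- tibble::tibble(
        gene_label = if (nzchar(orfs$label[j])) orfs$label[j] else
          sprintf("orf_%d_%s", orfs$start[j], orfs$strand[j]),
        orf_length = orfs$length_nt[j],
        codon_index = ctx$codon_index, codon_position = ctx$codon_pos,
        ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = ref_aa, alt_aa = alt_aa,
        effect = ifelse(ref_aa == alt_aa, "synonymous", "non_synonymous")
      )
    }
    if (length(hits) == 0L) {
      ann <- tibble::tibble(
        gene_label = "intergenic", orf_length = NA_integer_,
        codon_index = NA_integer_, codon_position = NA_integer_,
        ref_codon = NA_character_, alt_codon = NA_character_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        effect = "intergenic", primary = TRUE
      )
    } else {
      ann <- dplyr::bind_rows(hits)
      ann$primary <- seq_len(nrow(ann)) == which.max(ann$orf_length)
    }
    rows[[i]] <- dplyr::bind_cols(
      v[rep(1L, nrow(ann)), c("position", "ref", "alt", "frequency")], ann
    )
  }
  dplyr::bind_rows(rows) |> dplyr::select(-"orf_length")
}

#' Summarise classified variants
#'
#' Counts by effect class plus the mean and sample (n-1) standard deviation
#' of the frequency (as percent, one decimal) over coding variants and over
#' all variants. Only `primary` rows are counted, so each SNV contributes
#' once.
#'
#' @param effects Output of [classify_variants()].
#' @return A one-row tibble: `n_total`, `n_coding`, `n_synonymous`,
#'   `n_non_synonymous`, `n_intergenic`, `mean_frequency`, `sd_frequency`
#'   (coding variants), `mean_frequency_all`, `sd_frequency_all`.
#' @examples
#' \dontrun{summarize_variants(classify_variants(vars, orfs, genome))}
#' @export
summarize_variants <- function(effects) {
  prim <- if (nrow(effects)) effects[effects$primary, , drop = FALSE] else effects
  coding <- prim[prim$effect != "intergenic", , drop = FALSE]
  pct <- function(x, f) if (nrow(x) == 0L) NA_real_ else round(f(x$frequency * 100), 1)
  tibble::tibble(
    n_total = nrow(prim),
    n_coding = nrow(coding),
    n_synonymous = sum(coding$effect == "synonymous"),
    n_non_synonymous = sum(coding$effect == "non_synonymous"),
    n_intergenic = sum(prim$effect == "intergenic"),
    mean_frequency = pct(coding, mean),
    sd_frequency = pct(coding, stats::sd),
    mean_frequency_all = pct(prim, mean),
    sd_frequency_all = pct(prim, stats::sd)
  )
}
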
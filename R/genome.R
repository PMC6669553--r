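#' Circular genome container
#'
#' A topology-aware nucleotide sequence. Coordinates throughout the package are
#' 0-based half-open; on a circular genome a feature may run past the end
#' (`end > length`) and is wrapped only at format boundaries (GFF3, GenBank).
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N` (lowercase folded).
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `circular_genome` with fields `id`, `sequence`,
#'   `topology` and `length`.
#' @examples
#' g <- circular_genome("toy", "ATGAAATAA")
#' genome_length(g)
#' @export
circular_genome <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(paste0(sequence, collapse = ""))
  if (nchar(sequence) == 0L) {
    stop("genome '", id, "': empty sequence", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("genome '", id, "': non-IUPAC characters beyond N: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "), call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, topology = topology,
         length = nchar(sequence)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp (%s), G+C %.1f%%\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              gc_content(x)))
  invisible(x)
}

#' @rdname circular_genome
#' @param genome A `circular_genome`.
#' @export
genome_length <- function(genome) genome$length

is_circular <- function(genome) identical(genome$topology, "circular")

#' Extract a (possibly wrapped) subsequence
#'
#' 0-based half-open coordinates; on circular genomes `end` may exceed the
#' genome length and the extraction wraps through the origin. `start` is
#' reduced modulo the genome length first, so any integer position is valid.
#'
#' @param genome A `circular_genome`.
#' @param start,end 0-based half-open span, `end > start`.
#' @return A character scalar of length `end - start`.
#' @export
circular_subsequence <- function(genome, start, end) {
  L <- genome$length
  if (end <= start) stop("end must be > start", call. = FALSE)
  span <- end - start
  start <- ((start %% L) + L) %% L
  if (!is_circular(genome) && start + span > L) {
    stop("span runs off the end of a linear genome", call. = FALSE)
  }
  if (span > L) stop("span longer than the genome", call. = FALSE)
  doubled <- paste0(genome$sequence, genome$sequence)
  substr(doubled, start + 1L, start + span)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file, one or more records.
#' @param topology Applied to every record (the format itself carries none).
#' @return A list of [circular_genome()] objects, one per record.
#' @export
read_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  purrr::map2(ids, as.character(set),
              function(id, s) circular_genome(id, s, topology))
}

#' Write genomes to FASTA
#'
#' @param genomes A `circular_genome` or list of them.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(purrr::map_chr(genomes, "sequence"))
  names(set) <- purrr::map_chr(genomes, "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' G+C content of a genome
#'
#' Percent of unambiguous bases that are G or C; `N` sites are excluded from
#' the denominator (the convention is this package's choice, reported to one
#' decimal as the field prints it).
#'
#' @param genome A `circular_genome` or a DNA string.
#' @return Percent, rounded to one decimal.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(genome) {
  seq <- if (inherits(genome, "circular_genome")) genome$sequence else toupper(genome)
  counts <- table(factor(strsplit(seq, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("all-N sequence: G+C content undefined", call. = FALSE)
  round(100 * sum(counts[c("G", "C")]) / denom, 1)
}

# ---- feature table ----------------------------------------------------------

#' Build a feature tibble row set
#'
#' Features are plain tibbles (one row per locus) with 0-based half-open
#' coordinates; origin-spanning features carry `end > L` (unwrapped) so the
#' span length `end - start` is single-valued.
#'
#' @param genome_id,start,end,strand,kind,label Parallel vectors.
#' @return A tibble with those columns.
#' @export
feature_tbl <- function(genome_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        kind = character(), label = character()) {
  tibble::tibble(
    genome_id = as.character(genome_id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), kind = as.character(kind),
    label = as.character(label)
  )
}

validate_features <- function(features, L) {
  stopifnot(all(features$start >= 0), all(features$start < L),
            all(features$end > features$start), all(features$end <= 2L * L),
            all(features$strand %in% c("+", "-")))
  invisible(features)
}

# ---- GenBank flat-file reading ---------------------------------------------
# Minimal parser: LOCUS topology, FEATURES (location + /gene or /product or
# /label), ORIGIN sequence. GenBank 1-based inclusive a..b -> start = a-1,
# end = b; complement(...) -> strand "-"; join(a..L,1..b) on a circular record
# is preserved as one unwrapped feature with end = L + b.

parse_genbank_location <- function(loc, L) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  parts <- if (grepl("^join\\(", loc)) {
    strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
  } else loc
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
  single <- regmatches(parts, regexec("^<?(\\d+)>?$", parts))
  spans <- purrr::map2(m, single, function(ab, s) {
    if (length(ab) == 3L) as.integer(ab[2:3])
    else if (length(s) == 2L) rep(as.integer(s[2]), 2L)
    else stop("malformed GenBank location: ", loc, call. = FALSE)
  })
  start <- spans[[1]][1] - 1L
  end <- spans[[1]][2]
  if (length(spans) > 1L) {
    for (sp in spans[-1]) {
      if (sp[1] == 1L && !is.na(L)) {
        end <- L + sp[2]          # origin-spanning join
      } else {
        end <- sp[2]              # plain multi-exon join: outer span
      }
    }
  }
  list(start = start, end = end, strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses the ORIGIN sequence plus CDS/repeat_region features into the
#' package's 0-based half-open convention. `join(a..L,1..b)` on a circular
#' record becomes one unwrapped feature with `end = L + b`.
#'
#' @param path GenBank flat file.
#' @return A list with `genome` (a [circular_genome()]) and `features`
#'   (a feature tibble).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  topology <- if (length(locus) && grepl("circular", locus[1])) "circular" else "linear"
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else "genbank_record"
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank file has no ORIGIN block: ", path, call. = FALSE)
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  L <- nchar(sequence)

  feat_start <- grep("^FEATURES", lines)
  rows <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
    # feature lines start at col 6; continuation/qualifier lines at col 22
    key_idx <- grep("^ {5}\\S", block)
    for (i in seq_along(key_idx)) {
      from <- key_idx[i]
      to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(block)
      key <- trimws(substr(block[from], 1, 20))
      if (!key %in% c("CDS", "repeat_region", "gene")) next
      body <- trimws(substr(block[from:to], 22, nchar(block[from:to])))
      # location may continue over lines until the first qualifier
      qual_at <- grep("^/", body)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
      loc <- paste(body[seq_len(loc_end)], collapse = "")
      label <- NA_character_
      for (q in c("gene", "product", "label", "note", "rpt_type")) {
        hit <- grep(paste0("^/", q, "="), body, value = TRUE)
        if (length(hit)) { label <- gsub('^/[a-z_]+="?|"$', "", hit[1]); break }
      }
      pl <- parse_genbank_location(loc, L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genome_id = id, start = pl$start, end = pl$end, strand = pl$strand,
        kind = key, label = label
      )
    }
  }
  features <- if (length(rows)) dplyr::bind_rows(rows) else feature_tbl()
  features$label[is.na(features$label)] <- ""
  list(genome = circular_genome(id, sequence, topology), features = features)
}

#' Fetch a GenBank record from NCBI
#'
#' Thin wrapper over the NCBI E-utilities `efetch` endpoint; needs network
#' access. The deposited genome this pipeline reproduces is accession
#' MK558262.
#'
#' @param accession GenBank accession.
#' @param dest Destination file (GenBank flat format).
#' @param timeout Seconds before the download is abandoned.
#' @return `dest`, invisibly.
#' @export
fetch_genbank <- function(accession, dest = tempfile(fileext = ".gb"),
                          timeout = 60) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=gbwithparts&retmode=text&id=", accession
  )
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  invisible(dest)
}

# ---- GFF3 write/read --------------------------------------------------------

#' Write features as GFF3
#'
#' Coordinates are re-encoded 1-based inclusive. An origin-spanning feature
#' (`end > L`) is emitted as two lines sharing one `ID` attribute, tiling the
#' wrapped span.
#'
#' @param features Feature tibble (see [feature_tbl()]).
#' @param path Output path.
#' @param genome The `circular_genome` the features annotate (for length).
#' @export
write_gff3 <- function(features, path, genome) {
  L <- genome$length
  validate_features(features, L)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, L))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    id <- sprintf("feat%04d", i)
    attrs <- sprintf("ID=%s;Name=%s", id,
                     ifelse(nzchar(f$label), f$label, id))
    spans <- if (f$end <= L) {
      list(c(f$start + 1L, f$end))
    } else {
      list(c(f$start + 1L, L), c(1L, f$end - L))  # two-part wrapped feature
    }
    for (sp in spans) {
      lines <- c(lines, paste(
        genome$id, "baculoscan", f$kind, sp[1], sp[2], ".", f$strand, ".",
        attrs, sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file back into a feature tibble
#'
#' Two-part features sharing an `ID` (the wrapped-origin encoding of
#' [write_gff3()]) are re-joined into one unwrapped feature.
#'
#' @param path GFF3 file.
#' @param genome_length Needed to re-join wrapped two-part features.
#' @return A feature tibble.
#' @export
read_gff3 <- function(path, genome_length = NA_integer_) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"),
                         col_types = "ccciicccc", progress = FALSE)
  if (nrow(raw) == 0L) return(feature_tbl())
  raw$id <- stringr::str_match(raw$attributes, "ID=([^;]+)")[, 2]
  raw$name <- stringr::str_match(raw$attributes, "Name=([^;]+)")[, 2]
  out <- raw |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 1L) {
        tibble::tibble(genome_id = d$seqid, start = d$start - 1L, end = d$end,
                       strand = d$strand, kind = d$type, label = d$name)
      } else {
        # wrapped pair: the part touching the end comes first
        d <- d[order(-d$start), ]
        if (is.na(genome_length)) stop("genome_length needed to re-join wrapped feature")
        tibble::tibble(genome_id = d$seqid[1], start = d$start[1] - 1L,
                       end = genome_length + d$end[2], strand = d$strand[1],
                       kind = d$type[1], label = d$name[1])
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"id") |>
    dplyr::arrange(.data$start)
  out$label[is.na(out$label)] <- ""
  out
}

#' Write a tibble as comma-delimited text with a header row
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
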
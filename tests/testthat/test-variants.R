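write_test_vcf <- function(path, rows) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows
  ), path)
}

test_that("VCF rows become 0-based records; multi-allelics split; indels skipped", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c(
    "g\t10\t.\tA\tG\t.\tPASS\tAF=0.455",
    "g\t20\t.\tA\tG,T\t.\tPASS\tAF=0.2,0.1",
    "g\t30\t.\tAT\tA\t.\tPASS\tAF=0.3"
  ))
  expect_warning(v <- read_variants(f), "indel")
  expect_equal(nrow(v), 3L)
  expect_equal(v$position[1], 9L)
  expect_equal(v$ref[1], "A")
  expect_equal(v$alt[1], "G")
  expect_equal(v$frequency[1], 0.455)
  expect_equal(v$position[2:3], c(19L, 19L))
  expect_equal(v$alt[2:3], c("G", "T"))
  expect_equal(v$frequency[2:3], c(0.2, 0.1))
  expect_equal(attr(v, "n_skipped_indels"), 1L)
})

test_that("delimited variant tables read with 1-based positions", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(position = c(5, 8), ref = c("C", "G"),
                                  alt = c("T", "A"),
                                  frequency = c(0.4, 0.25)), f)
  v <- read_variants(f)
  expect_equal(v$position, c(4L, 7L))
  expect_equal(v$frequency, c(0.4, 0.25))
})

test_that("codon-level classification matches the code table on both strands", {
  # + strand ORF: ATG GCT AAA TAA at positions 3..15
  seqs <- paste0("CCC", "ATGGCTAAATAA", "GGGGG")
  g <- circular_genome("g", seqs, "linear")
  orfs <- tibble::tibble(genome_id = "g", start = 3L, end = 15L, strand = "+",
                         frame = 0L, length_nt = 12L, length_codons = 3L,
                         protein = "MAK", label = "geneA", kind = "CDS")
  # third position GCT -> GCC: synonymous Ala
  v1 <- tibble::tibble(position = 8L, ref = "T", alt = "C", frequency = 0.5,
                       depth = NA_integer_)
  e1 <- classify_variants(v1, orfs, g)
  expect_equal(e1$effect, "synonymous")
  expect_equal(e1$ref_codon, "GCT")
  expect_equal(e1$alt_codon, "GCC")
  expect_equal(e1$codon_index, 2L)
  expect_equal(e1$codon_position, 3L)
  # ATG -> ATA at codon 1: Met -> Ile
  v2 <- tibble::tibble(position = 5L, ref = "G", alt = "A", frequency = 0.5,
                       depth = NA_integer_)
  e2 <- classify_variants(v2, orfs, g)
  expect_equal(e2$effect, "non_synonymous")
  expect_equal(e2$ref_aa, "M")
  expect_equal(e2$alt_aa, "I")
  # variant in the stop codon is coding; stop-loss is non-synonymous
  v3 <- tibble::tibble(position = 13L, ref = "A", alt = "C", frequency = 0.5,
                       depth = NA_integer_)
  e3 <- classify_variants(v3, orfs, g)
  expect_equal(e3$effect, "non_synonymous")
})

test_that("minus-strand variants are complemented before codon substitution", {
  # minus-strand ORF whose first codon is GAA (Glu); genome carries its
  # reverse complement TTC at the ORF's 3'-coordinate end
  cds <- paste0("ATG", "GAA", paste(rep("GGC", 48), collapse = ""), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  g <- circular_genome("g", paste0("AAAA", rc, "TTTT"), "linear")
  start <- 4L
  end <- start + nchar(cds)
  orfs <- tibble::tibble(genome_id = "g", start = start, end = end,
                         strand = "-", frame = 0L,
                         length_nt = nchar(cds), length_codons = 50L,
                         protein = translate_cds(cds), label = "rev", kind = "CDS")
  # codon 2 position 1 on the coding strand: G of GAA; genome base is C
  p <- end - 1L - 3L                       # coding offset 3
  v <- tibble::tibble(position = p, ref = "C", alt = "T", frequency = 0.4,
                      depth = NA_integer_)
  e <- classify_variants(v, orfs, g)
  expect_equal(e$ref_codon, "GAA")
  expect_equal(e$alt_codon, "AAA")         # C->T on genome = G->A on coding
  expect_equal(e$ref_aa, "E")
  expect_equal(e$alt_aa, "K")
  expect_equal(e$effect, "non_synonymous")
})

test_that("a reference mismatch is a hard error naming the position", {
  g <- circular_genome("g", "ACGTACGT", "linear")
  v <- tibble::tibble(position = 2L, ref = "A", alt = "T", frequency = 0.1,
                      depth = NA_integer_)
  expect_error(classify_variants(v, empty_orf_tbl(), g), "position 2")
})

test_that("variant summaries match hand computation and planted truth", {
  # {0.30, 0.40, 0.50} -> mean 40.0, sd 10.0
  g <- circular_genome("g", paste0("CCC", "ATGGCTAAAGCGTAA", "GG"), "linear")
  orfs <- tibble::tibble(genome_id = "g", start = 3L, end = 18L, strand = "+",
                         frame = 0L, length_nt = 15L, length_codons = 4L,
                         protein = "MAKA", label = "a", kind = "CDS")
  v <- tibble::tibble(position = c(8L, 11L, 14L), ref = c("T", "A", "G"),
                      alt = c("C", "G", "A"),
                      frequency = c(0.30, 0.40, 0.50), depth = NA_integer_)
  s <- summarize_variants(classify_variants(v, orfs, g))
  expect_equal(s$mean_frequency, 40.0)
  expect_equal(s$sd_frequency, 10.0)
  expect_equal(s$n_total, 3L)
  expect_equal(s$n_coding, s$n_synonymous + s$n_non_synonymous)
  # empty input: zero counts, undefined frequency stats
  s0 <- summarize_variants(classify_variants(v[0, ], orfs, g))
  expect_equal(s0$n_total, 0L)
  expect_true(is.na(s0$mean_frequency))
})

test_that("planted variant composition is recovered exactly", {
  sim <- simulate_genome(genome_design(length = 40000, n_orfs = 25),
                         seed = 31)
  sv <- simulate_variants(sim$genome, sim$truth$orfs, n = 200,
                          frac_coding = 0.9, frac_syn = 120 / 180, seed = 32)
  eff <- classify_variants(sv$variants, sim$truth$orfs, sim$genome)
  s <- summarize_variants(eff)
  expect_equal(s$n_total, 200L)
  expect_equal(s$n_coding, 180L)
  expect_equal(s$n_synonymous, 120L)
  expect_equal(s$n_non_synonymous, 60L)
  expect_equal(s$n_intergenic, 20L)
  prim <- eff[eff$primary, ]
  expect_equal(prim$effect[order(prim$position)],
               sv$truth$effect[order(sv$truth$position)])
})

test_that("classification commutes with genome rotation", {
  sim <- simulate_genome(genome_design(length = 20000, n_orfs = 10),
                         seed = 41)
  g <- sim$genome
  L <- genome_length(g)
  sv <- simulate_variants(g, sim$truth$orfs, n = 40, seed = 42)
  eff <- classify_variants(sv$variants, sim$truth$orfs, g)
  rot <- 7321L
  g2 <- circular_genome("rot", circular_subsequence(g, rot, rot + L))
  orfs2 <- dplyr::mutate(sim$truth$orfs, start = (start - rot) %% L,
                         end = start + length_nt)
  v2 <- dplyr::mutate(sv$variants, position = (position - rot) %% L)
  eff2 <- classify_variants(v2, orfs2, g2)
  expect_equal(
    dplyr::arrange(eff, position)$effect,
    dplyr::arrange(eff2, (position + rot) %% L)$effect
  )
})

test_that("for every coding variant the reference codon translates to the annotated residue", {
  sim <- simulate_genome(genome_design(length = 15000, n_orfs = 8), seed = 51)
  sv <- simulate_variants(sim$genome, sim$truth$orfs, n = 60, seed = 52)
  eff <- classify_variants(sv$variants, sim$truth$orfs, sim$genome)
  coding <- eff[eff$effect != "intergenic", ]
  orfs <- sim$truth$orfs
  for (i in seq_len(nrow(coding))) {
    row <- coding[i, ]
    orf <- orfs[orfs$label == row$gene_label, ]
    expect_equal(row$ref_aa,
                 substr(orf$protein, row$codon_index, row$codon_index),
                 info = paste("variant at", row$position))
  }
})
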
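# Annotation parsing, canonical names, spacers and summaries.

test_that("canonicalize_name maps synonyms deterministically", {
  expect_equal(canonicalize_name("tRNA-Leu^UUA"), "L1")
  expect_equal(canonicalize_name("tRNA-Leu^GUA"), "L2")
  expect_equal(canonicalize_name("ND1"), "ND1")
  expect_equal(canonicalize_name("cytochrome b"), "Cytb")
  expect_equal(canonicalize_name(c("s-rRNA", "12S ribosomal RNA", "rrnS")),
               rep("r12S", 3))
  expect_equal(canonicalize_name("D-loop"), "CR")
  expect_equal(canonicalize_name(c("COX1", "COI", "CO1")), rep("COI", 3))
  expect_equal(canonicalize_name("no such gene"), "OTHER")
  # serine tRNAs disambiguated
  expect_equal(canonicalize_name(c("tRNA-Ser^UCA", "tRNA-Ser^UGC")),
               c("S1", "S2"))
})

test_that("coordinate tables round-trip and intergenic column is validated", {
  ann <- symphurus_annotation("orientalis")
  expect_s3_class(ann, "mito_annotation")
  expect_equal(ann$genome_length, 17498L)

  tmp <- tempfile(fileext = ".tsv")
  write_table(ann, tmp)
  ann2 <- read_table(tmp, taxon = ann$taxon)
  expect_equal(ann2$features[c("name", "start", "end", "strand")],
               ann$features[c("name", "start", "end", "strand")])

  # corrupt one intergenic entry -> strict validation fails, warn-only passes
  tab <- read.delim(tmp, comment.char = "#")
  tab$intergenic[3] <- tab$intergenic[3] + 5L
  bad <- tempfile(fileext = ".tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_table(bad), "intergenic")
  expect_warning(read_table(bad, validate = "warn"), "intergenic")
})

test_that("read_table rejects malformed tables", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tfrom\tto\tstrand", "ND1\tten\t20\tH"), bad)
  expect_error(read_table(bad), "non-numeric")
  writeLines(c("name\tfrom\tto\tstrand", "ND1\t30\t20\tH"), bad)
  expect_error(read_table(bad), "end < start")
  writeLines(c("name\tfrom\tto\tstrand", "ND1\t1\t20\tH", "ND1\t30\t50\tH"),
             bad)
  expect_error(read_table(bad), "duplicate")
})

test_that("single-feature table yields an annotation with no spacers", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("name\tfrom\tto\tstrand", "CR\t1\t100\tH"), p)
  ann <- read_table(p)
  expect_equal(nrow(ann$features), 1L)
  expect_equal(nrow(compute_spacers(ann)), 0L)
})

test_that("spacer arithmetic: abutting, overlapping and wrap pairs", {
  ann <- mito_annotation(
    data.frame(name = c("ND1", "ND2"), start = c(1L, 11L), end = c(10L, 20L),
               strand = "H"), circular = FALSE)
  sp <- compute_spacers(ann)
  expect_equal(sp$length, 0L)

  # wrap spacer: (genome_length - left_end) + (right_start - 1)
  ann2 <- mito_annotation(
    data.frame(name = c("ND1", "CR"), start = c(5L, 50L), end = c(40L, 90L),
               strand = "H"), genome_length = 100L)
  sp2 <- compute_spacers(ann2)
  expect_equal(sp2$length[sp2$wraps_origin], (100L - 90L) + (5L - 1L))
})

test_that("walking features plus spacers covers the whole circle", {
  for (sp in c("plagiusa", "orientalis")) {
    ann <- symphurus_annotation(sp)
    f <- ann$features[ann$features$feature_class != "origin", ]
    gaps <- compute_spacers(ann)
    expect_equal(sum(f$end - f$start + 1L) + sum(gaps$length),
                 ann$genome_length, info = sp)
  }
})

test_that("summary tallies classes, strands and large spacers", {
  sm <- summarize_annotation(symphurus_annotation("plagiusa"))
  expect_equal(unname(sm$class_counts[c("PCG", "tRNA", "rRNA",
                                        "control_region")]),
               c(13L, 22L, 2L, 1L), ignore_attr = TRUE)
  expect_true("ND6" %in% sm$l_strand_genes)
  expect_equal(sum(sm$strand_counts["tRNA", "L"]), 8L)

  # gap-free synthetic annotation has no large spacers
  cfg <- simulation_config(seed = 11, gap_range = c(0, 0))
  ann <- generate_annotation(gene_order(reference_order()), config = cfg)
  expect_equal(nrow(summarize_annotation(ann)$large_spacers), 0L)
})

test_that("GenBank flat files parse to canonical annotations", {
  gb <- write_gb_fixture(tempfile(fileext = ".gb"))
  ann <- read_genbank(gb)
  f <- ann$features
  expect_equal(ann$genome_length, 1200L)
  expect_true(ann$circular)
  expect_equal(f$start[f$name == "F"], 1L)
  expect_equal(f$end[f$name == "F"], 69L)
  expect_equal(f$strand[f$name == "F"], "H")
  expect_equal(f$name[f$start == 70L], "r12S")
  expect_equal(f$strand[f$name == "Q"], "L")
  # codon_recognized disambiguates the two leucine tRNAs
  expect_equal(f$name[f$start == 540L], "L1")
  expect_equal(f$name[f$start == 620L], "L2")
  expect_equal(f$feature_class[f$name == "CR"], "control_region")

  notgb <- tempfile()
  writeLines("just text", notgb)
  expect_error(read_genbank(notgb), "LOCUS")
})
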
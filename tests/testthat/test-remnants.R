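# Remnant-site prediction and correspondence with observed spacers.

symphurus_labels <- c("F", "r12S", "V", "r16S", "L1", "ND1", "I", "Q", "M",
                      "ND2", "W", "A", "N")

test_that("the inferred Symphurus event predicts the five published sites", {
  ev <- tdrl_event(c(3, 9), copy1_survivors = c(4, 9))
  sites <- predict_remnant_sites(ev, symphurus_labels, flanks = c("CR", "C"))
  expect_equal(nrow(sites), 5L)
  expect_equal(sites$left_flank, c("r12S", "r16S", "M", "V", "Q"))
  expect_equal(sites$right_flank, c("r16S", "M", "V", "L1", "ND2"))
  expect_equal(sites$lost_genes,
               list("V", c("L1", "ND1", "I", "Q"), character(), "r16S", "M"))
  expect_equal(sites$is_seam, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # full junction enumeration is available on request
  all_sites <- predict_remnant_sites(ev, symphurus_labels,
                                     flanks = c("CR", "C"),
                                     keep_empty = TRUE)
  expect_equal(nrow(all_sites), 8L)  # seven survivor junctions span 8 pairs
  expect_equal(attr(all_sites, "survivor_chain"),
               c("r12S", "r16S", "M", "V", "L1", "ND1", "I", "Q", "ND2"))
})

test_that("an event losing one whole copy leaves a single seam site", {
  ev <- tdrl_event(c(3, 6), copy1_survivors = 3:6)
  sites <- predict_remnant_sites(ev, symphurus_labels, flanks = c("CR", "C"))
  expect_equal(nrow(sites), 1L)
  expect_true(sites$is_seam)
  # the degraded second copy sits at the interval's right edge
  expect_equal(sites$left_flank, "ND1")   # rank 6 survivor
  expect_equal(sites$right_flank, "I")    # rank 7 flank
  expect_equal(sites$lost_genes[[1]], c("V", "r16S", "L1", "ND1"))
})

test_that("correspondence matches Gaps A-E and flags Gap F outside", {
  ann <- symphurus_annotation("orientalis")
  rep <- tdrl_report(ann)
  corr <- rep$correspondence
  expect_equal(corr$n_matched, 5L)
  expect_equal(corr$matches$spacer_length, c(65L, 98L, 100L, 31L, 117L))
  expect_equal(nrow(corr$unmatched_predictions), 0L)
  expect_equal(nrow(corr$unmatched_spacers), 0L)
  expect_equal(corr$outside_region$left_gene, "ND2")
  expect_equal(corr$outside_region$right_gene, "W")
  expect_equal(corr$outside_region$length, 37L)
})

test_that("empty prediction vs no qualifying spacers gives an empty report", {
  ev <- tdrl_event(c(3, 6), copy1_survivors = 3:6)
  sites <- predict_remnant_sites(ev, symphurus_labels, flanks = c("CR", "C"))
  empty_sp <- data.frame(left_gene = character(), right_gene = character(),
                         length = integer(), left_end = integer(),
                         right_start = integer(), wraps_origin = logical())
  corr <- correspond(sites[0, ], empty_sp)
  expect_equal(corr$n_matched, 0L)
  expect_equal(nrow(corr$unmatched_predictions), 0L)
  expect_equal(nrow(corr$outside_region), 0L)
})

test_that("simulated events: predicted sites equal simulator ground truth", {
  set.seed(19)
  for (i in 1:40) {
    sim <- simulate_tdrl(simulation_config())
    sites <- predict_remnant_sites(sim$event, sim$window$ref_genes,
                                   flanks = c("CR", "C"))
    expect_equal(sites$left_flank, sim$remnants$left_flank)
    expect_equal(sites$right_flank, sim$remnants$right_flank)
    expect_equal(sites$lost_genes, sim$remnants$lost_genes)
    expect_equal(sites$is_seam, sim$remnants$is_seam)
  }
})

test_that("simulated annotation closes the loop: sites match planted gaps", {
  set.seed(23)
  for (i in 1:10) {
    sim <- simulate_tdrl(simulation_config())
    sites <- predict_remnant_sites(sim$event, sim$window$ref_genes,
                                   flanks = c("CR", "C"))
    ord <- gene_order(c("CR", sim$window$genes, reference_order()[15:38]),
                      anchor = "F")
    ann <- generate_annotation(ord, remnants = sites,
                               config = simulation_config())
    corr <- correspond(sites, compute_spacers(ann))
    expect_equal(corr$n_matched, nrow(sites))
    expect_equal(nrow(corr$unmatched_predictions), 0L)
  }
})
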
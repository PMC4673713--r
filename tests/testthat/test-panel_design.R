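test_that("Wallace rule and nearest-neighbor models behave as documented", {
  # 2(A+T) + 4(G+C) with 4 of each
  expect_equal(melting_temperature("AATTGGCC", model = "wallace"), 24)
  # auto switches to Wallace below 14 nt
  expect_equal(melting_temperature("AATTGGCC"), 24)
  # appending a G/C pair does not lower the Tm
  base <- "ACGTACGTACGTACGTACGT"
  expect_gte(melting_temperature(paste0(base, "GC")),
             melting_temperature(base))
  expect_error(melting_temperature("A"), "too short")
  expect_error(melting_temperature("ACGTN"), "non-ACGT")
})

test_that("nearest-neighbor Tm matches the independent parameter-sum oracle", {
  set.seed(10)
  for (i in 1:30) {
    p <- random_dna_str(sample(14:35, 1))
    expect_equal(melting_temperature(p, model = "nearest_neighbor"),
                 oracle_tm_nn(p), tolerance = 0.1 / 60)
  }
})

test_that("forward cores grow from the STOP terminus to the first Tm crossing", {
  fix <- simulate_genome(n_genes = 10, seed = 13)
  fl <- fixture_loci(fix)
  cfg <- design_config()
  panel <- design_panel(fl$resolved$loci, fl$genome, cfg)
  expect_gt(nrow(panel$pairs), 0L)
  for (i in seq_len(nrow(panel$pairs))) {
    p <- panel$pairs[i, ]
    loc <- fl$resolved$loci[fl$resolved$loci$gene_id == p$gene_id, ]
    # mRNA-sense 3' terminus of the forward core is the STOP codon
    expect_true(substr(p$forward_core, nchar(p$forward_core) - 2,
                       nchar(p$forward_core)) %in% c("TAA", "TAG", "TGA"))
    # recompute the greedy length with the oracle: first L in 18..35
    # whose Tm reaches 60, else 35
    lens <- cfg$min_len:cfg$max_len
    cores <- vapply(lens, function(L) {
      if (loc$strand == "+") {
        extract_interval_sequence(fl$genome, loc$contig_id,
                                  loc$stop_end0 - L, loc$stop_end0, "+")
      } else {
        extract_interval_sequence(fl$genome, loc$contig_id,
                                  loc$stop_start0, loc$stop_start0 + L, "-")
      }
    }, character(1))
    tms <- vapply(cores, oracle_tm_nn, numeric(1))
    expected_len <- if (any(tms >= cfg$target_tm)) {
      lens[which(tms >= cfg$target_tm)[1]]
    } else max(lens)
    expect_identical(nchar(p$forward_core), expected_len)
    expect_identical(p$expected_insert_length, loc$insert_length)
  }
})

test_that("contexts that never reach the target Tm fall back to max length", {
  at_run <- paste(rep("AT", 60), collapse = "")
  g <- Biostrings::DNAStringSet(c(chrT = paste0(
    at_run, "TAA", paste(rep("AT", 200), collapse = ""))))
  locus <- resolve_utr_locus(
    make_tx_row(strand = "+", tx_start0 = 0, tx_end0 = 200,
                stop_start0 = 120, stop_end0 = 123,
                exons = cbind(start0 = 0L, end0 = 523L)), g)
  pair <- design_primer_cores(locus, g)
  expect_identical(pair$status, "ok")
  expect_identical(nchar(pair$forward_core), 35L)
  expect_match(pair$flags, "tm-below-target")
})

test_that("insufficient exonic runway is a design failure", {
  set.seed(11)
  g <- Biostrings::DNAStringSet(c(chrT = random_dna_str(3000)))
  locus <- resolve_utr_locus(
    make_tx_row(strand = "+", tx_start0 = 1000, tx_end0 = 2300,
                stop_start0 = 1010, stop_end0 = 1013,
                exons = cbind(start0 = 1000L, end0 = 2400L)), g)
  expect_identical(design_primer_cores(locus, g)$status,
                   "stop too close to exon start")
})

test_that("N inside a mandatory core span is rejected", {
  set.seed(12)
  s <- random_dna_str(3000)
  substr(s, 1496, 1496) <- "N"   # inside any forward core ending at 1503
  g <- Biostrings::DNAStringSet(c(chrT = s))
  locus <- make_tx_row(strand = "+", tx_start0 = 1000, tx_end0 = 2300,
                       stop_start0 = 1500, stop_end0 = 1503,
                       exons = cbind(start0 = 1000L, end0 = 2400L))
  loc <- resolve_utr_locus(locus, g)
  expect_identical(design_primer_cores(loc, g)$status, "N in core span")
})

test_that("Gateway tails are the exact attB2/attB3 sequences", {
  expect_identical(ATTB2, "GGGGACAGCTTTCTTGTACAAAGTGGAG")
  expect_identical(ATTB3, "GGGGACAACTTTGTATAATAAAGTTG")
  expect_identical(nchar(ATTB2), 28L)
  expect_identical(nchar(ATTB3), 26L)
  pair <- data.frame(forward_core = "ATGCGTTAA", reverse_core = "TTGACCA",
                     forward_tailed = NA_character_,
                     reverse_tailed = NA_character_, stringsAsFactors = FALSE)
  tailed <- attach_gateway_tails(pair)
  expect_identical(tailed$forward_tailed,
                   "GGGGACAGCTTTCTTGTACAAAGTGGAGATGCGTTAA")
  expect_identical(tailed$reverse_tailed,
                   "GGGGACAACTTTGTATAATAAAGTTGTTGACCA")
  expect_identical(tailed$forward_core, "ATGCGTTAA")
  expect_error(attach_gateway_tails(tailed), "double tailing")
  pre <- data.frame(forward_core = paste0(ATTB2, "ATG"),
                    reverse_core = "TTGACCA",
                    forward_tailed = NA_character_,
                    reverse_tailed = NA_character_, stringsAsFactors = FALSE)
  expect_error(attach_gateway_tails(pre), "double tailing")
})

test_that("panel design filters by insert length and is deterministic", {
  fix <- simulate_genome(n_genes = 10, seed = 14)
  fl <- fixture_loci(fix)
  panel <- design_panel(fl$resolved$loci, fl$genome)
  # generator plants one insert below 200 and one above 2500
  expect_true(all(c("length filter") %in% panel$failures$status))
  filtered <- panel$failures[panel$failures$status == "length filter", ]
  expect_true(all(filtered$expected_insert_length < 200 |
                    filtered$expected_insert_length > 2500))
  expect_true(all(panel$pairs$expected_insert_length >= 200 &
                    panel$pairs$expected_insert_length <= 2500))
  # every tailed primer carries its Gateway prefix
  expect_true(all(startsWith(panel$pairs$forward_tailed, ATTB2)))
  expect_true(all(startsWith(panel$pairs$reverse_tailed, ATTB3)))
  # byte-identical sheet on re-run
  s1 <- tempfile(fileext = ".tsv"); s2 <- tempfile(fileext = ".tsv")
  write_panel_sheet(panel, s1)
  write_panel_sheet(design_panel(fl$resolved$loci, fl$genome), s2)
  expect_identical(readLines(s1), readLines(s2))
  expect_error(design_panel(fl$resolved$loci[0, ], fl$genome), "empty")
})

test_that("a mirrored fixture designs the same primer panel", {
  fix <- simulate_genome(n_genes = 8, seed = 15)
  fl <- fixture_loci(fix)
  flm <- fixture_loci(mirror_fixture(fix))
  p1 <- design_panel(fl$resolved$loci, fl$genome)$pairs
  p2 <- design_panel(flm$resolved$loci, flm$genome)$pairs
  p1 <- p1[order(p1$gene_id), ]; p2 <- p2[order(p2$gene_id), ]
  expect_identical(p1$forward_core, p2$forward_core)
  expect_identical(p1$reverse_core, p2$reverse_core)
  expect_identical(p1$tm_f, p2$tm_f)
  expect_identical(p1$expected_insert_length, p2$expected_insert_length)
})
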
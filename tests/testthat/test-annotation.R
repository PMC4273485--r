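test_that("find_target_sites locates exact and variant targets", {
  expect_equal(find_target_sites("GGTTAAGG", "TTAA", 0), 2)
  expect_equal(find_target_sites("GGGG", "TTAA", 0), integer(0))
  # the variant duplications seen in the field data all lie within 2
  # mismatches of TTAA
  for (v in c("CTAT", "ATAT", "CTAA"))
    expect_true(2 %in% find_target_sites(paste0("GG", v, "GG"), "TTAA", 2))
  # N counts as a mismatch, never as a match
  expect_equal(find_target_sites("GGTTANGG", "TTAA", 0), integer(0))
})

test_that("find_terminal_inverted_repeats matches exact construction", {
  itr <- "CCCAGATTAGCCT"
  seq <- paste0(itr, paste(rep("N", 50), collapse = ""), revcomp(itr))
  hit <- find_terminal_inverted_repeats(seq, 13, 0, 13)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$left_start, 0)
  expect_equal(hit$right_start, 63)
  # one substitution in the right copy
  right <- revcomp("CCCAGATTAGCCA")
  seq1 <- paste0(itr, paste(rep("N", 50), collapse = ""), right)
  expect_equal(nrow(find_terminal_inverted_repeats(seq1, 13, 0, 13)), 0)
  hit1 <- find_terminal_inverted_repeats(seq1, 13, 1, 13)
  expect_equal(hit1$mismatches, 1)
  # the observed variant ITR is found at 1 mismatch against the canonical end
  seqv <- paste0("ACCAGATTAGCCT", paste(rep("G", 30), collapse = ""),
                 revcomp(itr))
  hitv <- find_terminal_inverted_repeats(seqv, 13, 1, 13)
  expect_equal(nrow(hitv), 1)
  expect_equal(hitv$mismatches, 1)
  # shorter than two repeats: empty, not an error
  expect_equal(nrow(find_terminal_inverted_repeats("ACGTACGT", 13, 0, 13)), 0)
})

test_that("find_terminal_inverted_repeats agrees with brute force", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(60:200, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    len <- sample(4:8, 1)
    mm <- sample(0:2, 1)
    window <- sample(len:30, 1)
    mine <- find_terminal_inverted_repeats(seq, len, mm, window)
    ref <- brute_force_itr(seq, len, mm, window)
    expect_equal(mine, ref)
  }
})

test_that("find_subterminal_repeats recovers planted asymmetric pairs", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 8)
  hits <- find_subterminal_repeats(e, 25, exclusion = 13, max_mismatch = 0)
  s5 <- tpl$subterminal_offsets[1]
  s3 <- tpl$total_length - tpl$subterminal_offsets[2] - 25L
  planted <- hits[hits$left_start == s5 & hits$right_start == s3, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$asymmetry,
               tpl$subterminal_offsets[1] - tpl$subterminal_offsets[2])
  # no interior inverted repeat of length 25 in a poly-purine sequence
  none <- find_subterminal_repeats(
    paste(rep(c("A", "G"), 150), collapse = ""), 25, 13, 0)
  expect_equal(nrow(none), 0)
  # symmetric construction detected with asymmetry 0
  core <- "GCCTTATCCGAAGTCATAGGTCAAC"
  sym <- paste0(paste(rep("C", 20), collapse = ""), core,
                paste(rep("T", 40), collapse = ""), revcomp(core),
                paste(rep("C", 20), collapse = ""))
  sh <- find_subterminal_repeats(sym, 25, 13, 0)
  expect_true(any(sh$asymmetry == 0))
})

test_that("find_orfs enumerates ATG-to-stop frames on both strands", {
  o <- find_orfs("ATGAAATAA", 1)
  expect_length(o, 1)  # the reverse strand TTATTTCAT holds no ATG
  expect_equal(o[[1]]$protein, "MK")
  expect_equal(o[[1]]$start, 0)
  expect_equal(o[[1]]$end, 9)
  expect_equal(find_orfs("CCCCCC", 1), list())
  # reverse strand coordinates map back to the input
  s <- revcomp("ATGAAATAA")
  ro <- find_orfs(s, 1)
  best <- ro[[1]]
  expect_equal(best$strand, "-")
  expect_equal(best$protein, "MK")
  expect_equal(substr(revcomp(s), nchar(s) - best$end + 1,
                      nchar(s) - best$start), "ATGAAATAA")
})

test_that("check_ddd_motif verifies aspartates and flags offenders", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 4)
  prot <- find_orfs(e, 50)[[1]]$protein
  chk <- check_ddd_motif(prot, tpl$ddd_positions)
  expect_true(chk$ok)
  expect_true(all(chk$residues == "D"))
  # mutate one position
  broken <- prot
  substr(broken, tpl$ddd_positions[2], tpl$ddd_positions[2]) <- "E"
  chk2 <- check_ddd_motif(broken, tpl$ddd_positions)
  expect_false(chk2$ok)
  expect_equal(unname(chk2$residues[2]), "E")
  expect_true(check_ddd_motif("DAA", 1)$ok)
  expect_error(check_ddd_motif("DAA", 9), "beyond protein end")
})

test_that("scan_signals reports literal motif positions", {
  expect_equal(scan_signals("CCAATC")$caat, 1)
  expect_equal(scan_signals("AATAAA")$polya, 0)
  s <- scan_signals("GGGGGG")
  expect_equal(lengths(s), c(caat = 0L, tata = 0L, polya = 0L))
  # overlapping TATA occurrences are all reported
  expect_equal(scan_signals("TATATA")$tata, c(0, 2))
})

test_that("annotate_element round-trips built elements", {
  for (seed in c(3, 17)) {
    tpl <- mini_template()
    e <- build_element(tpl, seed = seed)
    emb <- embed_element(e, seed = seed + 100)
    anns <- annotate_element(emb$genome, mini_config(tpl))
    expect_length(anns, 1)
    ann <- anns[[1]]
    expect_equal(unname(ann$span),
                 c(emb$element_start, emb$element_start + tpl$total_length))
    expect_true(ann$tsd$canonical)
    expect_equal(ann$tsd$left_seq, "TTAA")
    expect_equal(ann$tsd$right_seq, "TTAA")
    expect_equal(ann$itr$mismatches, 0)
    expect_equal(unname(ann$orf$start), tpl$orf_offset)
    expect_equal(nchar(ann$orf$protein), tpl$orf_codons)
    expect_true(ann$ddd$ok)
    expect_true(tpl$signal_offsets$caat %in% ann$signals$caat)
    expect_true(tpl$signal_offsets$polya %in% ann$signals$polya)
    s5 <- tpl$subterminal_offsets[1]
    expect_true(any(ann$subterminal$left_start == s5))
    expect_identical(ann$sequence, e)
  }
})

test_that("annotation has reverse-complement symmetry", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 21)
  emb <- embed_element(e, seed = 22)
  fwd <- annotate_element(emb$genome, mini_config(tpl))
  rev <- annotate_element(revcomp(emb$genome), mini_config(tpl))
  expect_length(fwd, 1)
  expect_length(rev, 1)
  n <- nchar(emb$genome)
  expect_equal(unname(rev[[1]]$span),
               unname(c(n - fwd[[1]]$span["end"], n - fwd[[1]]$span["start"])))
  expect_equal(rev[[1]]$orf$strand, "-")
  expect_equal(rev[[1]]$orf$protein, fwd[[1]]$orf$protein)
})

test_that("annotate_element reports nothing on empty genomes and all planted elements", {
  set.seed(91)
  bare <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  expect_equal(annotate_element(bare), list())
  tpl <- mini_template()
  e <- build_element(tpl, seed = 31)
  set.seed(33)
  g <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  g <- paste0(substr(g, 1, 100), "TTAA", substr(g, 105, 400), "TTAA",
              substr(g, 405, 600))
  g1 <- plant_insertion(g, 400, e, "TTAA")  # insert right-to-left
  g2 <- plant_insertion(g1, 100, e, "TTAA")
  anns <- annotate_element(g2, mini_config(tpl))
  expect_length(anns, 2)
  starts <- sort(vapply(anns, function(a) unname(a$span["start"]), numeric(1)))
  expect_equal(starts, c(104, 404 + nchar(e) + 4))
})

test_that("reported coordinates re-extract the reported sequences", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 12)
  emb <- embed_element(e, seed = 13)
  ann <- annotate_element(emb$genome, mini_config(tpl))[[1]]
  g <- emb$genome
  expect_equal(substr(g, ann$span["start"] + 1, ann$span["end"]),
               ann$sequence)
  expect_equal(substr(g, ann$tsd$left_pos + 1, ann$tsd$left_pos + 4),
               ann$tsd$left_seq)
  expect_equal(substr(g, ann$tsd$right_pos + 1, ann$tsd$right_pos + 4),
               ann$tsd$right_seq)
  # independent translation check on the ORF substring (stop excluded)
  orf_nt <- substr(ann$sequence, ann$orf$start + 1, ann$orf$end - 3)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(orf_nt)))
  expect_equal(prot, ann$orf$protein)
})

test_that("transcript arithmetic counts UTRs plus codons and stop", {
  expect_equal(transcript_arithmetic(111, 505, 119), 1748)
  expect_equal(transcript_arithmetic(0, 0, 0), 3)
  expect_equal(transcript_arithmetic(111, 505, 0), 1629)
})
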
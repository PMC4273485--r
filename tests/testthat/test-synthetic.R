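test_that("build_element realizes its template and is deterministic", {
  tpl <- mini_template()
  e1 <- build_element(tpl, seed = 5)
  e2 <- build_element(tpl, seed = 5)
  e3 <- build_element(tpl, seed = 6)
  expect_identical(e1, e2)
  expect_false(e1 == e3)
  expect_equal(nchar(e1), tpl$total_length)
  expect_equal(substr(e1, 1, 13), tpl$itr_seq)
  expect_equal(substr(e1, nchar(e1) - 12, nchar(e1)), revcomp(tpl$itr_seq))
  s5 <- tpl$subterminal_offsets[1]
  expect_equal(substr(e1, s5 + 1, s5 + 25), tpl$subterminal_seq)
  s3 <- tpl$total_length - tpl$subterminal_offsets[2] - 25L
  expect_equal(substr(e1, s3 + 1, s3 + 25), revcomp(tpl$subterminal_seq))
  sig <- scan_signals(e1)
  expect_true(tpl$signal_offsets$caat %in% sig$caat)
  expect_true(tpl$signal_offsets$tata %in% sig$tata)
  expect_true(tpl$signal_offsets$polya %in% sig$polya)
})

test_that("infeasible templates are rejected with the collision named", {
  expect_error(element_template(total_length = 300L, orf_codons = 505L),
               "does not fit")
  # polyA colliding with the right ITR
  expect_error(
    element_template(total_length = 400L, subterminal_offsets = c(40L, 45L),
                     orf_codons = 70L, orf_offset = 90L,
                     ddd_positions = c(5L, 10L, 15L, 20L),
                     signal_offsets = list(caat = 16L, tata = 70L,
                                           polya = 390L)),
    "overlap")
})

test_that("plant_insertion duplicates the target motif on both sides", {
  g <- "GGGGTTAACCCC"
  out <- plant_insertion(g, 4, "AGAGAG", "TTAA")
  expect_equal(out, "GGGGTTAAAGAGAGTTAACCCC")
  expect_equal(nchar(out), nchar(g) + 6 + 4)
  # degenerate empty element: pure duplication
  expect_equal(nchar(plant_insertion(g, 4, "", "TTAA")), nchar(g) + 4)
  # wrong target
  expect_error(plant_insertion(g, 0, "AGAGAG", "TTAA"), "target mismatch")
})

test_that("mutate_copy honors rates, reports exact mutations, reproducibly", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 2)
  orf <- orf_span_of(tpl)
  zero <- mutation_rates(sub = c(five_prime = 0, orf = 0, three_prime = 0),
                         indel = c(five_prime = 0, orf = 0, three_prime = 0))
  m0 <- mutate_copy(e, orf, zero, seed = 1)
  expect_identical(m0$seq, e)
  expect_equal(nrow(m0$mutations), 0)

  rates <- mutation_rates(sub = c(five_prime = 0.01, orf = 0.01,
                                  three_prime = 0.01),
                          indel = c(five_prime = 0.002, orf = 0.002,
                                    three_prime = 0.005))
  m1 <- mutate_copy(e, orf, rates, seed = 7)
  m2 <- mutate_copy(e, orf, rates, seed = 7)
  expect_identical(m1$mutations, m2$mutations)
  expect_identical(m1$seq, m2$seq)
  # substitutions recorded faithfully
  subs <- m1$mutations[m1$mutations$type == "sub", ]
  for (r in seq_len(nrow(subs))) {
    expect_equal(substr(e, subs$position[r] + 1, subs$position[r] + 1),
                 subs$ref[r])
    expect_false(subs$alt[r] == subs$ref[r])
  }
})

test_that("a dominant 3' indel rate yields 3'-heavy mutation counts", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 3)
  orf <- orf_span_of(tpl)
  rates <- mutation_rates(sub = c(five_prime = 0.001, orf = 0.001,
                                  three_prime = 0.001),
                          indel = c(five_prime = 0.001, orf = 0.001,
                                    three_prime = 0.05))
  region_events <- c(0, 0, 0)
  for (s in 1:100) {
    mu <- mutate_copy(e, orf, rates, seed = s)$mutations
    idl <- mu[mu$type != "sub", ]
    region_events <- region_events + tabulate(idl$region, 3)
  }
  # rate per base is 50x the others; region 3 must dominate even though it
  # is the shortest region
  expect_gt(region_events[3], region_events[1])
  expect_gt(region_events[3], region_events[2])
})

test_that("simulated populations obey degenerate insertion probabilities", {
  tpl <- mini_template()
  sc1 <- population_scenario(population_ids = c("A", "B"), n_loci = 2,
                             insertion_prob = 1, individuals_per_group = 3,
                             locus_spacing = 150, enzyme_upstream = 60,
                             seed = 4)
  sim1 <- simulate_populations(sc1, tpl)
  expect_true(all(sim1$truth$alleles$copies == 2L))
  expect_true(all(sim1$truth$presence == 1L))

  sc0 <- population_scenario(population_ids = c("A", "B"), n_loci = 2,
                             insertion_prob = 0, individuals_per_group = 3,
                             locus_spacing = 150, enzyme_upstream = 60,
                             seed = 4)
  sim0 <- simulate_populations(sc0, tpl)
  expect_true(all(sim0$truth$alleles$copies == 0L))
  # no insertion: genomes equal the reference
  expect_true(all(sim0$genomes == sim0$reference))
})

test_that("realized allele frequencies stay in the binomial 99% envelope", {
  tpl <- mini_template()
  pops <- sprintf("P%02d", 1:21)
  sc <- population_scenario(population_ids = pops, n_loci = 1,
                            insertion_prob = 0.25, individuals_per_group = 45,
                            locus_spacing = 150, enzyme_upstream = 60,
                            seed = 9)
  sim <- simulate_populations(sc, tpl)
  af <- vapply(pops, function(p) {
    d <- sim$truth$alleles[sim$truth$alleles$population == p, ]
    sum(d$copies) / (2 * nrow(d))
  }, numeric(1))
  # joint envelope over the 21 populations (Bonferroni-adjusted binomial
  # quantiles at n = 90 alleles), so the simultaneous coverage is ~99%
  a <- 0.005 / 21
  lo <- qbinom(a, 90, 0.25) / 90
  hi <- qbinom(1 - a, 90, 0.25) / 90
  expect_true(all(af >= lo & af <= hi))
  # and the marginal 99% envelope holds for the vast majority
  lo1 <- qbinom(0.005, 90, 0.25) / 90
  hi1 <- qbinom(0.995, 90, 0.25) / 90
  expect_gte(sum(af >= lo1 & af <= hi1), 19)
})

test_that("simulated copy sets are exactly consistent with mutate_copy", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 3)
  orf <- orf_span_of(tpl)
  rates <- mutation_rates(sub = c(five_prime = 0.01, orf = 0.01,
                                  three_prime = 0.01),
                          indel = c(five_prime = 0.003, orf = 0.003,
                                    three_prime = 0.006))
  cs <- simulate_copy_set(e, orf, n_copies = 4, rates, seed = 11)
  truth <- attr(cs, "truth")
  for (i in seq_along(cs$sequences)) {
    applied <- pletools:::apply_mutation_events(e, truth$events[[i]])$seq
    expect_identical(unname(gsub("-", "", cs$sequences[i], fixed = TRUE)),
                     applied)
  }
  # ORF mapped correctly: ungapped width of copies without indels
  expect_true(cs$width >= nchar(e))
})
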
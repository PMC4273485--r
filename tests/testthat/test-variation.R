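make_cs <- function(seqs, orf, id = "g") aligned_copy_set(seqs, orf, id)

test_that("region partition covers the alignment with the stated widths", {
  seqs <- c(a = paste(rep("A", 2406), collapse = ""),
            b = paste(rep("A", 2406), collapse = ""))
  cs <- make_cs(seqs, c(613, 2131))
  iv <- partition_regions(cs)
  expect_equal(unname(iv$five_prime), c(0L, 613L))
  expect_equal(unname(iv$orf), c(613L, 2131L))
  expect_equal(unname(iv$three_prime), c(2131L, 2406L))
  expect_equal(diff(iv$five_prime), 613)
  expect_equal(diff(iv$orf), 1518)
  expect_equal(diff(iv$three_prime), 275)
  # ORF spanning everything -> empty outside regions
  cs2 <- make_cs(seqs, c(0, 2406))
  iv2 <- partition_regions(cs2)
  expect_equal(diff(iv2$five_prime), 0)
  expect_equal(diff(iv2$three_prime), 0)
  expect_equal(count_variant_positions(cs2, iv2$five_prime), 0)
  expect_equal(region_length(cs2, iv2$five_prime), 0)
})

test_that("variant columns count substitutions and gaps, N and padding ignored", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AAGAAAA-AA",
            d = "AAAAANAAAA")
  cs <- make_cs(seqs, c(0, 10))
  # column 3 {A,A,G,A} and column 8 {A,A,-,A} are variant; the N column is not
  expect_equal(count_variant_positions(cs, c(0, 10)), 2)
  expect_equal(count_variant_positions(cs, c(0, 3)), 1)
  # identical copies: zero everywhere
  same <- make_cs(c(a = "ACGT", b = "ACGT"), c(0, 4))
  expect_equal(count_variant_positions(same, c(0, 4)), 0)
  # terminal gap runs are padding, not deletions
  pad <- make_cs(c(a = "--CGTACGTA", b = "ACCGTACGTA", c = "ACCGTACG--"),
                 c(0, 10))
  expect_equal(count_variant_positions(pad, c(0, 10)), 0)
})

test_that("additivity and duplication invariance of Nv/L/Rv", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 9)
  orf <- orf_span_of(tpl)
  rates <- mutation_rates(sub = c(five_prime = 0.02, orf = 0.02,
                                  three_prime = 0.02),
                          indel = c(five_prime = 0.004, orf = 0.004,
                                    three_prime = 0.008))
  cs <- simulate_copy_set(e, orf, 4, rates, seed = 30)
  iv <- partition_regions(cs)
  total <- count_variant_positions(cs, c(0, cs$width))
  parts <- sum(vapply(iv, function(x) count_variant_positions(cs, x),
                      numeric(1)))
  expect_equal(total, parts)
  # duplicating every sequence changes nothing
  dup <- aligned_copy_set(c(cs$sequences, stats::setNames(cs$sequences,
                                                          paste0("d", 1:4))),
                          cs$orf, "dup")
  for (r in iv) {
    expect_equal(count_variant_positions(dup, r),
                 count_variant_positions(cs, r))
    expect_equal(region_length(dup, r), region_length(cs, r))
  }
})

test_that("region length averages ungapped bases", {
  w278 <- paste(rep("A", 278), collapse = "")
  cs <- make_cs(c(a = w278, b = w278), c(0, 278))
  expect_equal(region_length(cs, c(0, 278)), 278.0)
  # one deletion among five copies in a width-614 interval
  w <- paste(rep("G", 614), collapse = "")
  del <- paste0(substr(w, 1, 100), "-", substr(w, 102, 614))
  cs5 <- make_cs(c(a = w, b = w, c = w, d = w, e = del), c(0, 614))
  expect_equal(region_length(cs5, c(0, 614)), 613.8)
})

test_that("variation_rate divides Nv by L and rejects empty regions", {
  expect_equal(round(variation_rate(3.8, 613.2), 4), 0.0062)
  expect_equal(round(variation_rate(8, 1518), 4), 0.0053)
  expect_equal(variation_rate(0, 100), 0)
  expect_error(variation_rate(1, 0), "undefined rate")
})

test_that("SVPs are maximal same-subset gap runs at or above the threshold", {
  # an 11-base deletion in one copy
  base <- paste(rep("ACGTT", 20), collapse = "")
  gap11 <- paste0(substr(base, 1, 40), paste(rep("-", 11), collapse = ""),
                  substr(base, 52, 100))
  cs <- make_cs(c(a = base, b = base, c = gap11, d = base), c(0, 100))
  svp <- detect_svps(cs)
  expect_equal(nrow(svp), 1)
  expect_equal(svp$kind, "deletion")
  expect_equal(svp$length, 11)
  expect_equal(svp$members, "c")
  expect_equal(svp$start, 40)
  # a 7-base insertion shared by one copy (gaps in the others)
  ins7 <- c(a = "AAAA-------TTTT", b = "AAAA-------TTTT",
            c = "AAAACCCCCCCTTTT", d = "AAAA-------TTTT")
  svp2 <- detect_svps(make_cs(ins7, c(0, 15)))
  expect_equal(svp2$kind, "insertion")
  expect_equal(svp2$length, 7)
  expect_equal(svp2$members, "c")
  # 2-base events fall below the default threshold
  two <- c(a = "AAAA--TTTT", b = "AAAACCTTTT", c = "AAAACCTTTT")
  expect_equal(nrow(detect_svps(make_cs(two, c(0, 10)))), 0)
  expect_equal(nrow(detect_svps(make_cs(two, c(0, 10)), min_len = 2)), 1)
})

test_that("hotspot profile is flat at zero without variation and peaks at a variant column", {
  same <- make_cs(c(a = paste(rep("ACG", 40), collapse = ""),
                    b = paste(rep("ACG", 40), collapse = "")), c(0, 120))
  hp <- hotspot_profile(list(same))
  expect_true(all(hp$score == 0))
  expect_equal(hp$argmax, 0)
  one <- c(a = paste(rep("A", 60), collapse = ""),
           b = paste0(paste(rep("A", 40), collapse = ""), "G",
                      paste(rep("A", 19), collapse = "")))
  hp1 <- hotspot_profile(list(make_cs(one, c(0, 60))), window = 1)
  expect_equal(hp1$argmax, 40)
})

test_that("elevated 3' indel rates put the hotspot in the 3' region", {
  tpl <- element_template()
  e <- build_element(tpl, seed = 3)
  orf <- orf_span_of(tpl)
  rates <- mutation_rates(sub = c(five_prime = 0.002, orf = 0.002,
                                  three_prime = 0.002),
                          indel = c(five_prime = 0, orf = 0,
                                    three_prime = 0.004))
  hits <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    css <- lapply(1:8, function(g)
      simulate_copy_set(e, orf, 4, rates, seed = r * 1000 + g,
                        group_id = paste0("g", g)))
    hp <- hotspot_profile(css)
    if (hp$argmax >= orf[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("variation_report summarizes per group and pools both ways", {
  tpl <- mini_template()
  e <- build_element(tpl, seed = 2)
  orf <- orf_span_of(tpl)
  css <- lapply(1:5, function(g)
    simulate_copy_set(e, orf, 4, mutation_rates(), seed = g,
                      group_id = paste0("g", g)))
  rep5 <- variation_report(css)
  expect_equal(nrow(rep5$per_group), 15)
  expect_true(all(abs(rep5$per_group$Rv -
                        rep5$per_group$Nv / rep5$per_group$L) < 1e-12,
                  na.rm = TRUE))
  expect_equal(rep5$summary$region, c("five_prime", "orf", "three_prime"))
  expect_true(all(rep5$summary$Rv_sem >= 0))
})

test_that("permutation test returns p near 1 under the null and is reproducible", {
  per <- expand.grid(group = paste0("g", 1:6),
                     region = c("five_prime", "orf", "three_prime"),
                     stringsAsFactors = FALSE)
  per$Rv <- rep(c(0.006, 0.006, 0.006), each = 6)  # identical across regions
  cr <- compare_region_rates(per, n_perm = 500, seed = 1)
  expect_true(all(cr$pairs$p > 0.99))
  # all regions share a letter
  expect_equal(length(unique(cr$letters)), 1)
  cr2 <- compare_region_rates(per, n_perm = 500, seed = 1)
  expect_identical(cr$pairs, cr2$pairs)
})

test_that("a strong 3' contrast is detected at alpha 0.01 in most runs", {
  tpl <- element_template()
  e <- build_element(tpl, seed = 3)
  orf <- orf_span_of(tpl)
  rates <- mutation_rates(sub = c(five_prime = 0.0015, orf = 0.0015,
                                  three_prime = 0.006),
                          indel = c(five_prime = 0, orf = 0, three_prime = 0))
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    css <- lapply(1:21, function(g)
      simulate_copy_set(e, orf, 4, rates, seed = r * 500 + g,
                        group_id = paste0("g", g)))
    cr <- compare_region_rates(variation_report(css), n_perm = 500,
                               seed = r)
    p3 <- cr$pairs$p[(cr$pairs$region1 == "three_prime" |
                        cr$pairs$region2 == "three_prime")]
    if (all(p3 < 0.01)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
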
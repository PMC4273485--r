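#' Expected occupied-site amplicon length
#'
#' Flanking PCR across an insertion locus yields a short amplicon from empty
#' chromosomes and a long one from occupied chromosomes. The default
#' convention adds the element length to the empty-site amplicon
#' (264 + 2406 = 2670 for the element modeled here); setting `tsd_len = 4`
#' additionally counts the extra target-site duplication copy created by
#' insertion.
#'
#' @param empty_len Empty-site amplicon length (bp).
#' @param element_len Element length (bp).
#' @param tsd_len Extra duplicated target bases to count (default 0).
#' @return Integer expected occupied-site amplicon length.
#' @export
#' @examples
#' expected_amplicon(264, 2406)      # 2670
#' expected_amplicon(264, 2406, 4)   # 2674
expected_amplicon <- function(empty_len, element_len, tsd_len = 0L) {
  stopifnot(empty_len > 0, element_len >= 0, tsd_len >= 0)
  as.integer(empty_len + element_len + tsd_len)
}

#' Classify flanking-PCR amplicon lengths into an insertion call
#'
#' An individual showing only the short (empty-site) product is called
#' absent; both products, heterozygous; only the long product,
#' homozygous-present; neither, ambiguous. A band matches an expected length
#' when it lies within `tol` bases (gel resolution).
#'
#' @param lengths Numeric vector of observed amplicon lengths (possibly
#'   empty).
#' @param short_expect,long_expect Expected empty/occupied lengths.
#' @param tol Matching tolerance in bases (default 30).
#' @return One of `"absent"`, `"heterozygous"`, `"homozygous_present"`,
#'   `"ambiguous"`.
#' @export
#' @examples
#' classify_amplicons(c(264, 2670))  # heterozygous
classify_amplicons <- function(lengths, short_expect = 264L,
                               long_expect = 2670L, tol = 30L) {
  stopifnot(tol >= 0)
  has_short <- any(abs(lengths - short_expect) <= tol)
  has_long <- any(abs(lengths - long_expect) <= tol)
  if (has_short && has_long) "heterozygous"
  else if (has_short) "absent"
  else if (has_long) "homozygous_present"
  else "ambiguous"
}

CARRIER_CALLS <- c("heterozygous", "homozygous_present")

#' Estimate per-population insertion frequencies
#'
#' The carrier frequency of each replicate group is the fraction of its
#' individuals called heterozygous or homozygous-present; the population
#' estimate is the mean of the group frequencies with SEM computed as the
#' sample standard deviation (n - 1) over the square root of the number of
#' groups — the replication structure of a `groups x individuals` field
#' design (3 x 15 in the study modeled here).
#'
#' @param calls Data frame with columns `individual`, `population`, `group`,
#'   `call` (values as returned by [classify_amplicons()]).
#' @return Data frame with one row per population: `population`, `mean`,
#'   `sem`, `n_groups`, `n_per_group`; per-group frequencies are attached as
#'   attribute `group_freq`.
#' @export
estimate_frequency <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("individual", "population", "group", "call") %in% names(calls)))
  pops <- unique(calls$population)
  gf_rows <- list()
  out <- do.call(rbind, lapply(pops, function(pop) {
    d <- calls[calls$population == pop, ]
    sizes <- table(d$group)
    if (length(sizes) < 2L)
      stop(sprintf("population %s has fewer than 2 replicate groups", pop),
           call. = FALSE)
    if (length(unique(as.integer(sizes))) != 1L)
      stop(sprintf("population %s has unequal group sizes (%s)", pop,
                   paste(sizes, collapse = ", ")), call. = FALSE)
    freqs <- vapply(names(sizes), function(g) {
      mean(d$call[d$group == g] %in% CARRIER_CALLS)
    }, numeric(1))
    gf_rows[[length(gf_rows) + 1L]] <<- data.frame(
      population = pop, group = names(sizes), frequency = unname(freqs))
    data.frame(population = pop, mean = mean(freqs),
               sem = stats::sd(freqs) / sqrt(length(freqs)),
               n_groups = length(freqs),
               n_per_group = as.integer(sizes[1]))
  }))
  rownames(out) <- NULL
  attr(out, "group_freq") <- do.call(rbind, gf_rows)
  out
}

#' Rank populations by insertion frequency
#'
#' Orders populations by descending mean frequency with competition ("1224")
#' ranking: tied means share the smallest rank and the following rank is
#' skipped accordingly.
#'
#' @param estimates Data frame from [estimate_frequency()] (needs
#'   `population` and `mean`).
#' @return The estimates sorted by descending mean with a `rank` column.
#' @export
#' @examples
#' rank_populations(data.frame(population = c("a", "b", "c"),
#'                             mean = c(0.5, 0.8, 0.5)))$rank  # 1 2 2
rank_populations <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("population", "mean") %in% names(estimates)))
  out <- estimates[order(-estimates$mean, estimates$population), , drop = FALSE]
  out$rank <- vapply(out$mean, function(m) 1L + sum(out$mean > m), integer(1))
  rownames(out) <- NULL
  out
}

#' Simulate flanking-PCR amplicon calls
#'
#' Draws carrier status per individual at the given true carrier frequency
#' and emits the amplicon length lists a gel would show (empty-site band for
#' non-carriers; both bands for carriers, which are heterozygous by default
#' as in the field data).
#'
#' @param true_freq True carrier frequency in the population.
#' @param population Population label.
#' @param n_groups,n_per_group Replicate design (defaults 3 x 15).
#' @param short_len,long_len Amplicon lengths emitted.
#' @param seed Integer seed.
#' @return Data frame of calls suitable for [estimate_frequency()], with a
#'   `lengths` list column of the simulated amplicon lengths and attribute
#'   `realized_freq`, the realized carrier fraction.
#' @export
simulate_amplicon_calls <- function(true_freq, population = "pop1",
                                    n_groups = 3L, n_per_group = 15L,
                                    short_len = 264L, long_len = 2670L,
                                    seed = 1L) {
  stopifnot(true_freq >= 0, true_freq <= 1)
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
      carrier <- stats::rbinom(n_per_group, 1L, true_freq) == 1L
      data.frame(individual = sprintf("%s.g%d.i%d", population, g,
                                      seq_len(n_per_group)),
                 population = population, group = g, carrier = carrier)
    }))
    rows$lengths <- lapply(rows$carrier, function(cr)
      if (cr) c(short_len, long_len) else short_len)
    rows$call <- vapply(rows$lengths, classify_amplicons, character(1),
                        short_expect = short_len, long_expect = long_len)
    attr(rows, "realized_freq") <- mean(rows$carrier)
    rows
  })
}
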
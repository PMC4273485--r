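#' Aligned set of element copies
#'
#' Container for >= 2 equal-length gapped DNA sequences (one multiple
#' alignment of element copies from one population/group) together with the
#' ORF interval in alignment coordinates. Leading and trailing gap runs of
#' each sequence are treated as alignment padding, not variation: they are
#' excluded from variant-position counts and length averages.
#'
#' @param sequences Named character vector of aligned sequences (alphabet
#'   `A C G T N -`), all the same length.
#' @param orf 0-based half-open ORF interval in alignment coordinates.
#' @param group_id Label (e.g. the source population).
#' @return Object of class `aligned_copy_set`.
#' @export
aligned_copy_set <- function(sequences, orf, group_id = "group1") {
  stopifnot(is.character(sequences), length(sequences) >= 2L)
  sequences <- vapply(sequences, as_dna, character(1), gaps = TRUE,
                      USE.NAMES = TRUE)
  w <- unique(nchar(sequences))
  if (length(w) != 1L)
    stop("all aligned sequences must have the same length", call. = FALSE)
  orf <- check_interval(orf, w, "orf")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("copy", seq_along(sequences))
  structure(list(group_id = group_id, sequences = sequences, orf = orf,
                 width = w),
            class = "aligned_copy_set")
}

#' @export
print.aligned_copy_set <- function(x, ...) {
  cat(sprintf("<aligned_copy_set> %s: %d copies, width %d, ORF [%d, %d)\n",
              x$group_id, length(x$sequences), x$width, x$orf[1], x$orf[2]))
  invisible(x)
}

#' Read an aligned copy set from FASTA
#'
#' @param path Aligned FASTA path (gaps as `-`).
#' @param orf 0-based half-open ORF interval in alignment coordinates.
#' @param group_id Label; defaults to the file name without extension.
#' @return An [aligned_copy_set()].
#' @export
read_copy_set <- function(path, orf, group_id = NULL) {
  if (is.null(group_id))
    group_id <- sub("\\.[^.]*$", "", basename(path))
  aligned_copy_set(read_fasta(path), orf = orf, group_id = group_id)
}

# character matrix with terminal padding replaced by NA and N by NA
copyset_matrix <- function(copyset, mask = TRUE) {
  M <- do.call(rbind, strsplit(unname(copyset$sequences), "", fixed = TRUE))
  if (mask) {
    for (r in seq_len(nrow(M))) {
      ng <- which(M[r, ] != "-")
      if (!length(ng)) { M[r, ] <- NA_character_; next }
      if (ng[1] > 1L) M[r, 1:(ng[1] - 1L)] <- NA_character_
      if (ng[length(ng)] < ncol(M)) M[r, (ng[length(ng)] + 1L):ncol(M)] <- NA_character_
    }
    M[M == "N"] <- NA_character_
  }
  M
}

# logical vector over alignment columns: >= 2 distinct scored symbols
# (gap counts as a symbol; N and terminal padding are ignored)
variant_columns <- function(copyset) {
  M <- copyset_matrix(copyset)
  nc <- ncol(M)
  out <- logical(nc)
  # vectorized fast path: compare all rows to the first non-NA symbol per column
  ref <- apply(M, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) NA_character_ else col[1]
  })
  cmp <- M != matrix(ref, nrow(M), nc, byrow = TRUE)
  out <- colSums(cmp, na.rm = TRUE) > 0L
  out[is.na(ref)] <- FALSE
  out
}

#' Partition an alignment into the three element regions
#'
#' Splits the alignment into the 5' region outside the ORF, the ORF (from
#' initiator to termination codon), and the 3' region outside the ORF —
#' contiguous, non-overlapping intervals covering the alignment. Regions may
#' be empty when the ORF touches an alignment end.
#'
#' @param copyset An [aligned_copy_set()].
#' @return Named list of 0-based half-open intervals: `five_prime`, `orf`,
#'   `three_prime`.
#' @export
partition_regions <- function(copyset) {
  stopifnot(inherits(copyset, "aligned_copy_set"))
  list(five_prime = c(0L, copyset$orf[1]),
       orf = copyset$orf,
       three_prime = c(copyset$orf[2], copyset$width))
}

#' Count variant positions in an alignment interval
#'
#' A column is one variant position when it holds at least two distinct
#' symbols among its copies, with the gap character counted as a symbol (so
#' insertions, deletions, transitions and transversions each mark a column)
#' and `N` matching nothing. A multi-column indel therefore contributes one
#' variant position per column; its single-event character is captured
#' separately by [detect_svps()].
#'
#' @param copyset An [aligned_copy_set()].
#' @param interval 0-based half-open alignment interval.
#' @return Integer count Nv.
#' @export
count_variant_positions <- function(copyset, interval) {
  stopifnot(inherits(copyset, "aligned_copy_set"))
  interval <- check_interval(interval, copyset$width)
  if (interval[1] == interval[2]) return(0L)
  v <- variant_columns(copyset)
  sum(v[(interval[1] + 1L):interval[2]])
}

#' Mean ungapped length of an alignment interval
#'
#' The region length L is the mean, over the copies, of the number of
#' non-gap bases falling in the interval (terminal padding excluded), so
#' fractional lengths arise when copies carry indels.
#'
#' @param copyset An [aligned_copy_set()].
#' @param interval 0-based half-open alignment interval.
#' @return Numeric mean length L.
#' @export
region_length <- function(copyset, interval) {
  stopifnot(inherits(copyset, "aligned_copy_set"))
  interval <- check_interval(interval, copyset$width)
  if (interval[1] == interval[2]) return(0)
  M <- copyset_matrix(copyset)[, (interval[1] + 1L):interval[2], drop = FALSE]
  mean(rowSums(!is.na(M) & M != "-"))
}

#' Variation rate
#'
#' `Rv = Nv / L`: variant positions per base of region length.
#'
#' @param nv Variant-position count.
#' @param l Region length (> 0).
#' @return Numeric rate.
#' @export
#' @examples
#' round(variation_rate(3.8, 613.2), 4)  # 0.0062
variation_rate <- function(nv, l) {
  if (any(l <= 0)) stop("undefined rate: region length must be > 0",
                        call. = FALSE)
  nv / l
}

#' Per-region variation report across copy sets
#'
#' For each copy set (group) and each of the three regions, computes the
#' mean ungapped length L, the variant-position count Nv and the rate
#' Rv = Nv / L, then summarizes across groups as mean and SEM (sample SD /
#' sqrt(groups)). Two pooled rates are reported per region: the mean of
#' per-group rates (`Rv_mean`, the "average of ratios") and the ratio of
#' pooled means (`Rv_pooled = mean(Nv) / mean(L)`); these differ in the
#' third decimal for short regions.
#'
#' @param copysets List of [aligned_copy_set()] objects.
#' @return List with `per_group` (long data frame: group, region, L, Nv, Rv)
#'   and `summary` (per region: means and SEMs plus `Rv_pooled`).
#' @export
variation_report <- function(copysets) {
  stopifnot(length(copysets) >= 1L)
  regions <- c("five_prime", "orf", "three_prime")
  per <- do.call(rbind, lapply(copysets, function(cs) {
    iv <- partition_regions(cs)
    do.call(rbind, lapply(regions, function(r) {
      L <- region_length(cs, iv[[r]])
      Nv <- count_variant_positions(cs, iv[[r]])
      data.frame(group = cs$group_id, region = r, L = L, Nv = Nv,
                 Rv = if (L > 0) Nv / L else NA_real_)
    }))
  }))
  rownames(per) <- NULL
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  summary <- do.call(rbind, lapply(regions, function(r) {
    d <- per[per$region == r, ]
    data.frame(region = r,
               L_mean = mean(d$L), L_sem = sem(d$L),
               Nv_mean = mean(d$Nv), Nv_sem = sem(d$Nv),
               Rv_mean = mean(d$Rv), Rv_sem = sem(d$Rv),
               Rv_pooled = if (mean(d$L) > 0) mean(d$Nv) / mean(d$L) else NA_real_)
  }))
  rownames(summary) <- NULL
  list(per_group = per, summary = summary)
}

#' Detect special variation positions (indels of >= min_len bases)
#'
#' A special variation position (SVP) is a maximal run of consecutive
#' alignment columns in which the same non-empty subset of copies carries
#' gaps, with run length at least `min_len` (default 3). When the gapped
#' copies are the minority the event is reported as a deletion carried by
#' them; when they are the majority it is an insertion carried by the
#' ungapped copies (ties count as deletions).
#'
#' @param copyset An [aligned_copy_set()].
#' @param min_len Minimum indel length (default 3).
#' @return Data frame with `start`, `end` (0-based half-open alignment
#'   interval), `kind` (`insertion`/`deletion`), `length`, `members`
#'   (comma-separated copy names carrying the event).
#' @export
detect_svps <- function(copyset, min_len = 3L) {
  stopifnot(inherits(copyset, "aligned_copy_set"), min_len >= 1L)
  M <- copyset_matrix(copyset)
  gap <- !is.na(M) & M == "-"
  key <- apply(gap, 2, function(col) paste(as.integer(col), collapse = ""))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  nm <- names(copyset$sequences)
  for (k in seq_along(r$values)) {
    subset <- which(strsplit(r$values[k], "", fixed = TRUE)[[1]] == "1")
    if (!length(subset) || r$lengths[k] < min_len) next
    minority <- length(subset) <= nrow(M) - length(subset)
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts[k] - 1L, end = ends[k],
      kind = if (minority) "deletion" else "insertion",
      length = r$lengths[k],
      members = paste(nm[if (minority) subset else setdiff(seq_len(nrow(M)),
                                                           subset)],
                      collapse = ","))
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0), length = integer(0),
                      members = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled per-column variability profile and hotspot
#'
#' Pools the per-column variant indicator over several copy sets sharing one
#' reference coordinate system, smooths it with a centered sliding window
#' (partial windows at the edges), and reports the first position attaining
#' the maximum of the smoothed profile — the variability hotspot.
#'
#' Copy sets from [simulate_copy_set()] carry an alignment-to-template
#' coordinate map; when every set has one, profiles are pooled on the shared
#' template coordinates (inserted columns pooled onto the template position
#' they follow), so independently aligned groups of different widths are
#' comparable. Otherwise all sets must have equal width.
#'
#' @param copysets List of [aligned_copy_set()] objects.
#' @param window Odd window size (default 11).
#' @return List with `score` (per-column pooled variant frequency),
#'   `smoothed`, `argmax` (0-based column of the smoothed maximum; first
#'   column when the profile is flat) and `window`.
#' @export
hotspot_profile <- function(copysets, window = 11L) {
  stopifnot(length(copysets) >= 1L, window >= 1L, window %% 2L == 1L)
  maps <- lapply(copysets, attr, "template_map")
  if (all(!vapply(maps, is.null, logical(1)))) {
    tlens <- vapply(copysets, attr, integer(1), "template_length")
    if (length(unique(tlens)) != 1L)
      stop("all copy sets must share one template length", call. = FALSE)
    tlen <- tlens[1]
    V <- vapply(seq_along(copysets), function(k) {
      v <- variant_columns(copysets[[k]])
      tv <- logical(tlen)
      tv[maps[[k]][v] + 1L] <- TRUE
      tv
    }, logical(tlen))
  } else {
    widths <- vapply(copysets, function(cs) cs$width, integer(1))
    if (length(unique(widths)) != 1L)
      stop("all copy sets must share one coordinate system (equal widths)",
           call. = FALSE)
    V <- vapply(copysets, variant_columns, logical(widths[1]))
  }
  score <- rowMeans(V)
  half <- (window - 1L) %/% 2L
  n <- length(score)
  smoothed <- vapply(seq_len(n), function(i) {
    mean(score[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  list(score = score, smoothed = smoothed,
       argmax = which.max(smoothed) - 1L, window = as.integer(window))
}

#' Permutation comparison of per-region variation rates
#'
#' For each pair of regions, performs a two-sided paired permutation test on
#' the per-group rates: the statistic is the mean over groups of the
#' within-group rate difference, and the null is generated by independently
#' permuting the two region labels within each group (sign flips). Regions
#' are then summarized with a compact letter display at the given alpha:
#' regions sharing a letter are not significantly different.
#'
#' @param per_group Long data frame with columns `group`, `region`, `Rv`
#'   (e.g. `variation_report(...)$per_group`), or a [variation_report()]
#'   result list.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param alpha Significance level for the letter display (default 0.01).
#' @return List with `pairs` (data frame: region1, region2, mean_diff, p)
#'   and `letters` (named character vector).
#' @export
compare_region_rates <- function(per_group, n_perm = 10000L, seed = 1L,
                                 alpha = 0.01) {
  if (is.list(per_group) && !is.data.frame(per_group) &&
      !is.null(per_group$per_group))
    per_group <- per_group$per_group
  stopifnot(is.data.frame(per_group),
            all(c("group", "region", "Rv") %in% names(per_group)),
            n_perm >= 100L)
  regions <- unique(per_group$region)
  groups <- unique(per_group$group)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  get_rv <- function(r) {
    d <- per_group[per_group$region == r, ]
    d$Rv[match(groups, d$group)]
  }
  rv <- vapply(regions, get_rv, numeric(length(groups)))

  combs <- utils::combn(length(regions), 2L)
  pairs <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      i <- combs[1, k]; j <- combs[2, k]
      d <- rv[, i] - rv[, j]
      obs <- mean(d)
      signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                      nrow = n_perm)
      null <- rowMeans(signs * matrix(d, n_perm, length(d), byrow = TRUE))
      p <- (1 + sum(abs(null) >= abs(obs) - 1e-15)) / (n_perm + 1)
      data.frame(region1 = regions[i], region2 = regions[j],
                 mean_diff = obs, p = p)
    }))
  })

  # compact letter display: maximal sets of mutually non-different regions
  nr <- length(regions)
  sig <- matrix(FALSE, nr, nr, dimnames = list(regions, regions))
  for (k in seq_len(nrow(pairs)))
    sig[pairs$region1[k], pairs$region2[k]] <-
      sig[pairs$region2[k], pairs$region1[k]] <- pairs$p[k] < alpha
  subsets <- list()
  for (mask in seq_len(2^nr - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(nr) - 1L)) > 0L)
    if (all(!sig[idx, idx])) subsets[[length(subsets) + 1L]] <- idx
  }
  # keep maximal subsets only
  keep <- vapply(seq_along(subsets), function(i) {
    !any(vapply(seq_along(subsets), function(j) {
      i != j && all(subsets[[i]] %in% subsets[[j]])
    }, logical(1)))
  }, logical(1))
  subsets <- subsets[keep]
  means <- colMeans(rv)
  ord <- order(-vapply(subsets, function(s) max(means[s]), numeric(1)))
  subsets <- subsets[ord]
  letters_out <- stats::setNames(rep("", nr), regions)
  for (i in seq_along(subsets))
    letters_out[subsets[[i]]] <- paste0(letters_out[subsets[[i]]], LETTERS[i])
  list(pairs = pairs, letters = letters_out)
}
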
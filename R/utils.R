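#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (alphabet `A C G T N`, case
#'   preserved for upper case input; gaps `-` are complemented to themselves).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("CCCAGATTAGCCT")
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a DNA sequence argument; returns a plain upper-case string.
# `gaps` additionally admits "-" (aligned input).
as_dna <- function(seq, gaps = FALSE, arg = "seq") {
  if (inherits(seq, "XString") || inherits(seq, "XStringSet"))
    seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop(sprintf("`%s` must be a single character string", arg), call. = FALSE)
  s <- toupper(seq)
  alphabet <- if (gaps) "ACGTN-" else "ACGTN"
  bad <- gsub(sprintf("[%s]", alphabet), "", s)
  if (nzchar(bad))
    stop(sprintf("`%s` contains non-DNA characters: %s", arg,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = " ")),
         call. = FALSE)
  if (!nzchar(s)) stop(sprintf("`%s` is empty", arg), call. = FALSE)
  s
}

# Number of mismatches of `pattern` at every start of `xc` (a character
# vector of single bases). An N in the subject never matches anything.
slide_mismatch <- function(xc, pattern) {
  pc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  k <- length(pc)
  n <- length(xc)
  if (n < k) return(integer(0))
  m <- integer(n - k + 1L)
  for (off in seq_len(k)) {
    xs <- xc[seq.int(off, n - k + off)]
    m <- m + (xs != pc[off] | xs == "N")
  }
  m
}

# Pairwise mismatch counts between the `len`-mers of `xc` starting at
# 1-based positions `i` and the reverse complements of the `len`-mers
# starting at `j`. Vectorised over pairs (i, j).
itr_pair_mismatch <- function(xc, i, j, len) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X", `-` = "X")
  m <- integer(length(i))
  for (k in 0:(len - 1L)) {
    a <- xc[i + k]
    b <- comp[xc[j + len - 1L - k]]
    m <- m + (a != b | a == "N" | b == "X")
  }
  m
}

# All (i, j) pairs (1-based starts, i < j) such that the len-mer at i equals
# the reverse complement of the len-mer at j with <= max_mismatch mismatches
# and the implied span j + len - i lies in [min_span, max_span].
# Seeded by an exact hash join on (max_mismatch + 1) pigeonhole fragments,
# so at least one fragment of a qualifying pair always matches exactly.
# Candidate starts can be restricted either by ranges or by explicit
# position vectors (1-based).
find_inverted_pairs <- function(seq, len, max_mismatch = 0L,
                                min_span = 2L * len, max_span = nchar(seq),
                                left_range = NULL, right_range = NULL,
                                left_positions = NULL, right_positions = NULL) {
  s <- as_dna(seq)
  n <- nchar(s)
  empty <- data.frame(left_start = integer(0), right_start = integer(0),
                      length = integer(0), mismatches = integer(0))
  if (n < 2L * len) return(empty)
  xc <- strsplit(s, "", fixed = TRUE)[[1]]
  rc <- revcomp(s)
  if (is.null(left_positions)) {
    if (is.null(left_range)) left_range <- c(1L, n - len + 1L)
    is <- seq.int(max(1L, left_range[1]), min(n - len + 1L, left_range[2]))
  } else is <- left_positions[left_positions >= 1L & left_positions <= n - len + 1L]
  if (is.null(right_positions)) {
    if (is.null(right_range)) right_range <- c(1L, n - len + 1L)
    js <- seq.int(max(1L, right_range[1]), min(n - len + 1L, right_range[2]))
  } else js <- right_positions[right_positions >= 1L & right_positions <= n - len + 1L]
  if (!length(is) || !length(js)) return(empty)

  nparts <- max_mismatch + 1L
  sizes <- rep(len %/% nparts, nparts)
  extra <- len %% nparts
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  offs <- cumsum(c(0L, sizes[-nparts]))

  acc_i <- vector("list", 0L)
  acc_j <- vector("list", 0L)
  for (p in seq_len(nparts)) {
    o <- offs[p]; w <- sizes[p]
    lkey <- substring(s, is + o, is + o + w - 1L)
    # revcomp of seq[j, j+len) is rc[n - j - len + 2, ...] (1-based)
    rstart <- n - js - len + 2L
    rkey <- substring(rc, rstart + o, rstart + o + w - 1L)
    lsplit <- split(is, lkey)
    rsplit <- split(js, rkey)
    keys <- intersect(names(lsplit), names(rsplit))
    keys <- keys[!grepl("N", keys, fixed = TRUE)]
    for (k in keys) {
      li <- lsplit[[k]]; rj <- rsplit[[k]]
      acc_i[[length(acc_i) + 1L]] <- rep(li, times = length(rj))
      acc_j[[length(acc_j) + 1L]] <- rep(rj, each = length(li))
    }
  }
  cand_i <- unlist(acc_i, use.names = FALSE)
  cand_j <- unlist(acc_j, use.names = FALSE)
  if (!length(cand_i)) return(empty)
  span <- cand_j + len - cand_i
  keep <- cand_i < cand_j & span >= min_span & span <= max_span
  cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
  if (!length(cand_i)) return(empty)
  dup <- duplicated(cand_i * (n + 1) + cand_j)
  cand_i <- cand_i[!dup]; cand_j <- cand_j[!dup]
  mm <- itr_pair_mismatch(xc, cand_i, cand_j, len)
  keep <- mm <= max_mismatch
  if (!any(keep)) return(empty)
  out <- data.frame(left_start = cand_i[keep] - 1L,
                    right_start = cand_j[keep] - 1L,
                    length = len,
                    mismatches = mm[keep])
  out <- out[order(out$mismatches, out$left_start, out$right_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random i.i.d. uniform DNA string.
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# 0-based half-open interval sanity check.
check_interval <- function(x, width, arg = "interval") {
  if (length(x) != 2L || any(is.na(x)) || x[1] < 0 || x[2] < x[1] || x[2] > width)
    stop(sprintf("`%s` must be a 0-based half-open interval within [0, %d]",
                 arg, width), call. = FALSE)
  as.integer(x)
}

#' Write sequences to a FASTA file
#'
#' Thin wrapper around [Biostrings::writeXStringSet()] accepting a named
#' character vector (gapped sequences allowed).
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
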
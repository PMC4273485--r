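# Small element template for fast structural tests: same anatomy as the
# default, scaled to 400 bp with a 70-codon ORF.
mini_template <- function() {
  element_template(total_length = 400L,
                   subterminal_offsets = c(40L, 45L),
                   orf_codons = 70L,
                   orf_offset = 90L,
                   ddd_positions = c(5L, 10L, 15L, 20L),
                   signal_offsets = list(caat = 16L, tata = 70L, polya = 360L))
}

mini_config <- function(tpl = mini_template()) {
  annotation_config(min_orf_codons = 50L, ddd_positions = tpl$ddd_positions)
}

orf_span_of <- function(tpl) {
  c(tpl$orf_offset, tpl$orf_offset + 3L * (tpl$orf_codons + 1L))
}

# Embed an element in a random host with a TTAA target at a known 0-based
# position and an upstream HindIII site; returns genome and truth positions.
embed_element <- function(element, flank5 = 120L, flank3 = 80L, seed = 1L,
                          enzyme_upstream = 60L) {
  set.seed(seed)
  left <- paste(sample(c("A", "C", "G", "T"), flank5, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), flank3, replace = TRUE),
                 collapse = "")
  genome <- paste0(left, "TTAA", right)
  tsd_pos <- flank5  # 0-based start of TTAA
  # plant an enzyme site ending upstream of the target
  e0 <- tsd_pos - enzyme_upstream
  genome <- paste0(substr(genome, 1, e0), "AAGCTT",
                   substr(genome, e0 + 7, nchar(genome)))
  list(genome = plant_insertion(genome, tsd_pos, element, "TTAA"),
       tsd_pos = tsd_pos, enzyme_start = e0,
       element_start = tsd_pos + 4L)
}

# Independent naive UPGMA oracle: cluster distances are recomputed at every
# step as the arithmetic mean of ALL original leaf-pair distances (the
# textbook definition), rather than by the incremental Lance-Williams
# update; same lexicographic tie rule. Returns the cophenetic matrix.
naive_upgma_cophenetic <- function(D) {
  labels <- colnames(D)
  clusters <- lapply(labels, identity)
  co <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        tie <- abs(d - best_d) <= 1e-15 &&
          (key[1] < best_key[1] ||
             (key[1] == best_key[1] && key[2] < best_key[2]))
        if (d < best_d - 1e-15 || tie) {
          best <- c(i, j); best_d <- d; best_key <- key
        }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    co[a, b] <- best_d
    co[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  co
}

# Random presence matrix guaranteed valid (no all-zero site; one universal
# site so every population pair shares at least one site).
random_presence_matrix <- function(n_sites, n_pops, p = 0.4) {
  m <- matrix(rbinom(n_sites * n_pops, 1L, p), n_sites, n_pops)
  m[1, ] <- 1L
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  colnames(m) <- paste0("P", sprintf("%02d", seq_len(n_pops)))
  rownames(m) <- paste0("site_", seq_len(nrow(m)))
  presence_matrix(m)
}

# Brute-force terminal inverted repeat scan for the oracle-equivalence test.
brute_force_itr <- function(seq, len, max_mm, window) {
  xc <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  n <- length(xc)
  out <- data.frame(left_start = integer(0), right_start = integer(0),
                    length = integer(0), mismatches = integer(0))
  if (n < 2 * len) return(out)
  for (i in 1:min(window - len + 1, n - 2 * len + 1)) {
    for (j in max(n - window + 1, i + len):(n - len + 1)) {
      mm <- 0L
      for (k in 0:(len - 1)) {
        a <- xc[i + k]; b <- comp[xc[j + len - 1 - k]]
        if (a != b || a == "N" || b == "?") mm <- mm + 1L
      }
      if (mm <= max_mm)
        out <- rbind(out, data.frame(left_start = i - 1L, right_start = j - 1L,
                                     length = len, mismatches = mm))
    }
  }
  out <- out[order(out$mismatches, out$left_start, out$right_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
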
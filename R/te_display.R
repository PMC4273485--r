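#' Extract in-silico transposon-display tags
#'
#' Emulates the restriction-digest based transposon display used to survey
#' insertion sites: for each annotated element, the 5' flanking segment from
#' the nearest upstream restriction-site occurrence (default HindIII,
#' `AAGCTT`) through the element's 5' target-site duplication (inclusive) is
#' extracted as a tag. Tags whose upstream restriction site is missing are
#' truncated at the sequence start and flagged; tags whose nearest site
#' overlaps the target duplication are flagged degenerate.
#'
#' @param genome Genomic DNA string.
#' @param annotations List of element annotations from [annotate_element()].
#' @param enzyme_site Restriction recognition sequence (default `AAGCTT`).
#' @return Data frame with one row per element: `tag`, `tsd` (last 4 bases of
#'   the tag), `itr` (the element's first 13 bases), `element_start` (0-based),
#'   `truncated`, `degenerate`.
#' @export
extract_te_display_tags <- function(genome, annotations,
                                    enzyme_site = "AAGCTT") {
  genome <- as_dna(genome, arg = "genome")
  if (!nzchar(enzyme_site)) stop("`enzyme_site` must be non-empty", call. = FALSE)
  enzyme_site <- as_dna(enzyme_site, arg = "enzyme_site")
  if (!length(annotations))
    return(data.frame(tag = character(0), tsd = character(0),
                      itr = character(0), element_start = integer(0),
                      truncated = logical(0), degenerate = logical(0)))
  xc <- strsplit(genome, "", fixed = TRUE)[[1]]
  sites <- which(slide_mismatch(xc, enzyme_site) == 0L) - 1L  # 0-based starts
  elen <- nchar(enzyme_site)
  rows <- lapply(annotations, function(ann) {
    tsd_start <- ann$span[["start"]] - 4L
    tsd_end <- ann$span[["start"]]  # half-open
    cand <- sites[sites < tsd_end]
    degenerate <- FALSE
    truncated <- FALSE
    if (length(cand)) {
      e0 <- max(cand)
      if (e0 + elen > tsd_start) degenerate <- TRUE
    } else {
      e0 <- 0L
      truncated <- TRUE
    }
    tag <- substr(genome, e0 + 1L, tsd_end)
    data.frame(tag = tag,
               tsd = substr(tag, nchar(tag) - 3L, nchar(tag)),
               itr = substr(ann$sequence, 1L, 13L),
               element_start = ann$span[["start"]],
               truncated = truncated, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a presence/absence insertion-site matrix
#'
#' Insertion sites are identified by exact identity of the `flank_len` bases
#' immediately upstream of the target-site duplication, mirroring site
#' identification by flank sequencing. Site ids are assigned in order of
#' first observation across the supplied populations; a matrix entry is 1
#' when the population contributed at least one tag matching the site.
#'
#' @param tags_by_population Named list (one entry per population) of tag
#'   data frames from [extract_te_display_tags()] or plain character vectors
#'   of tag sequences.
#' @param flank_len Flank length defining site identity (default 30); must
#'   not exceed the shortest tag minus the 4-base duplication.
#' @return A `presence_matrix`: list with `values` (sites x populations 0/1
#'   integer matrix), and `sites` (data frame `site_id`, `flank_key`, `tsd`,
#'   `itr`).
#' @export
build_matrix <- function(tags_by_population, flank_len = 30L) {
  stopifnot(is.list(tags_by_population), length(tags_by_population) >= 1L,
            !is.null(names(tags_by_population)))
  pops <- names(tags_by_population)
  norm <- lapply(tags_by_population, function(x) {
    if (is.character(x))
      x <- data.frame(tag = x, tsd = substr(x, nchar(x) - 3L, nchar(x)),
                      itr = NA_character_)
    x
  })
  all_tags <- unlist(lapply(norm, function(d) d$tag), use.names = FALSE)
  if (length(all_tags) && min(nchar(all_tags)) < flank_len + 4L)
    stop(sprintf("flank_len %d exceeds shortest tag (%d bases incl. TSD)",
                 flank_len, min(nchar(all_tags))), call. = FALSE)

  registry <- character(0)   # flank keys in order of first observation
  meta_tsd <- character(0)
  meta_itr <- character(0)
  values <- matrix(0L, nrow = 0L, ncol = length(pops),
                   dimnames = list(NULL, pops))
  for (p in pops) {
    d <- norm[[p]]
    for (r in seq_len(nrow(d))) {
      tag <- d$tag[r]
      nt <- nchar(tag)
      key <- substr(tag, nt - 4L - flank_len + 1L, nt - 4L)
      idx <- match(key, registry)
      if (is.na(idx)) {
        registry <- c(registry, key)
        meta_tsd <- c(meta_tsd, d$tsd[r])
        meta_itr <- c(meta_itr, if ("itr" %in% names(d)) d$itr[r] else NA_character_)
        values <- rbind(values, 0L)
        idx <- length(registry)
      }
      values[idx, p] <- 1L
    }
  }
  site_ids <- paste0("site_", seq_along(registry))
  rownames(values) <- site_ids
  presence_matrix(values,
                  sites = data.frame(site_id = site_ids, flank_key = registry,
                                     tsd = meta_tsd, itr = meta_itr))
}

#' Presence/absence matrix constructor
#'
#' @param values Sites x populations matrix with 0/1 entries; row names are
#'   site ids, column names population ids.
#' @param sites Optional site metadata data frame (`site_id`, and optionally
#'   `tsd`, `itr`, `flank_key`); defaults to the row names.
#' @return Object of class `presence_matrix`.
#' @export
presence_matrix <- function(values, sites = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L)))
    stop("matrix entries must be 0 or 1", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("site_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("population (column) names are required", call. = FALSE)
  if (any(rowSums(values) == 0L))
    stop("every site must be present in at least one population", call. = FALSE)
  if (is.null(sites))
    sites <- data.frame(site_id = rownames(values))
  stopifnot(nrow(sites) == nrow(values))
  structure(list(values = values, sites = sites), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d sites x %d populations\n",
              nrow(x$values), ncol(x$values)))
  print(utils::head(x$values, 10))
  if (nrow(x$values) > 10) cat(sprintf("  ... %d more sites\n",
                                       nrow(x$values) - 10L))
  invisible(x)
}

#' Per-site prevalence
#'
#' @param matrix A `presence_matrix`.
#' @return Named integer vector: for each site, the number of populations in
#'   which it is present.
#' @export
site_prevalence <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  rowSums(matrix$values)
}

site_table <- function(sites) {
  if (inherits(sites, "presence_matrix")) sites <- sites$sites
  stopifnot(is.data.frame(sites))
  sites
}

#' Count sites with variant target-site duplications
#'
#' @param sites Site metadata data frame (with a `tsd` column) or a
#'   `presence_matrix`.
#' @param canonical Canonical 4-base target (default `TTAA`).
#' @return Integer count of sites whose observed duplication differs from the
#'   canonical target; the offending rows are attached as attribute
#'   `variants`.
#' @export
count_variant_tsds <- function(sites, canonical = "TTAA") {
  sites <- site_table(sites)
  var <- sites[!is.na(sites$tsd) & sites$tsd != canonical, , drop = FALSE]
  structure(nrow(var), variants = var)
}

#' Count sites with variant terminal inverted repeats
#'
#' @param sites Site metadata data frame (with an `itr` column) or a
#'   `presence_matrix`.
#' @param canonical Canonical 13-base ITR (default `CCCAGATTAGCCT`).
#' @return Integer count of sites with a non-canonical ITR; attribute
#'   `variants` holds the offending rows with the 1-based mismatch positions.
#' @export
count_variant_itrs <- function(sites, canonical = "CCCAGATTAGCCT") {
  sites <- site_table(sites)
  var <- sites[!is.na(sites$itr) & sites$itr != canonical, , drop = FALSE]
  if (nrow(var)) {
    cc <- strsplit(canonical, "", fixed = TRUE)[[1]]
    var$mismatch_positions <- vapply(var$itr, function(s) {
      sc <- strsplit(s, "", fixed = TRUE)[[1]]
      paste(which(sc != cc), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  structure(nrow(var), variants = var)
}

#' Read a presence/absence matrix TSV
#'
#' Dialect: a header line `site_id<TAB>pop1<TAB>pop2...`, one row per site,
#' entries 0/1. For fidelity with transcriptions of published tables, the
#' check mark / cross convention is also accepted and mapped to 1/0.
#'
#' @param path TSV path.
#' @param sites Optional site metadata data frame to attach.
#' @return A `presence_matrix`.
#' @export
read_presence_matrix <- function(path, sites = NULL) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  ids <- d[[1L]]
  m <- as.matrix(d[, -1L, drop = FALSE])
  m[m %in% c("√", "✓")] <- "1"
  m[m %in% c("×", "x", "X")] <- "0"
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  presence_matrix(m, sites = sites)
}

#' Write a presence/absence matrix TSV
#'
#' @param matrix A `presence_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "presence_matrix"))
  d <- data.frame(site_id = rownames(matrix$values), matrix$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
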
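# Data products behind the three visualization families: sequence views
# (alignment + mergence + composition), feature views (heat map + top
# peptides), and sequence logos over the natural or reduced alphabet.

#' Position frequency matrix and information content for a sequence logo
#'
#' Computes per-position letter frequencies over a set of pre-aligned,
#' equal-length sequences ('-' allowed as gap). With a scheme, sequences
#' are first rewritten over cluster representatives so the logo collapses
#' within-cluster variation. Gaps (and masked non-standard residues) are
#' excluded from each position's denominator. Information content follows
#' the standard logo convention, info[p] = log2(A) - H(freq[p]) bits for
#' an A-letter alphabet, without small-sample correction.
#'
#' @param seqs named character vector of >= 2 equal-length sequences.
#' @param scheme optional [raac_scheme()]; absent = natural 20-letter logo.
#' @return a `raac_logo`: list with `freq` (W x A matrix, rows summing to
#'   1 where any letter was counted), `info` (numeric W), `alphabet`,
#'   `counts` (letters counted per position), `empty` (logical, positions
#'   with nothing to count), `n_seqs`.
#' @export
logo_matrix <- function(seqs, scheme = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1]]
    stop("sequences must be pre-aligned to equal length; offending ids: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  W <- lens[1]
  chars <- do.call(rbind, lapply(seqs, function(s) residue_vector(s)))
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "raac_scheme"))
    map <- scheme_mapping(scheme)
    std <- chars %in% AA20
    reduced <- chars
    reduced[std] <- map[chars[std]]
    reduced[!std & chars != "-"] <- "X"  # masked, excluded like gaps
    chars <- reduced
    alphabet <- unique(scheme$representative)
  } else {
    alphabet <- AA20
  }
  A <- length(alphabet)
  freq <- matrix(0, nrow = W, ncol = A, dimnames = list(NULL, alphabet))
  counts <- integer(W)
  for (p in seq_len(W)) {
    col <- chars[, p]
    col <- col[col %in% alphabet]
    counts[p] <- length(col)
    if (length(col) > 0L) {
      freq[p, ] <- as.numeric(table(factor(col, levels = alphabet))) /
        length(col)
    }
  }
  empty <- counts == 0L
  info <- numeric(W)
  for (p in seq_len(W)) {
    if (!empty[p]) {
      f <- freq[p, ]
      f <- f[f > 0]
      info[p] <- log2(A) + sum(f * log2(f))
    }
  }
  structure(list(freq = freq, info = info, alphabet = alphabet,
                 counts = counts, empty = empty, n_seqs = length(seqs)),
            class = "raac_logo")
}

#' @export
print.raac_logo <- function(x, ...) {
  cat(sprintf("sequence logo: %d position(s), %d-letter alphabet, %d sequence(s)\n",
              nrow(x$freq), length(x$alphabet), x$n_seqs))
  invisible(x)
}

#' Write a logo matrix as TSV
#'
#' Long format with columns `position`, `letter`, `frequency`,
#' `info_bits` (the position's total information content, repeated per
#' letter); zero-frequency letters are omitted.
#'
#' @param logo a `raac_logo`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  stopifnot(inherits(logo, "raac_logo"))
  rows <- c("position\tletter\tfrequency\tinfo_bits")
  for (p in seq_len(nrow(logo$freq))) {
    nz <- which(logo$freq[p, ] > 0)
    for (j in nz) {
      rows <- c(rows, paste(p, logo$alphabet[j],
                            format(logo$freq[p, j], digits = 17,
                                   trim = TRUE, scientific = FALSE),
                            format(logo$info[p], digits = 17,
                                   trim = TRUE, scientific = FALSE),
                            sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Fixed qualitative palette indexed by cluster rank
#'
#' Twenty visually distinct colors; cluster i of a scheme takes color i,
#' so a reduced alphabet's palette is by construction a subset of the
#' natural one.
#'
#' @return character vector of 20 hex colors.
#' @export
raac_palette <- function() {
  c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
    "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
    "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
    "#c49c94", "#f7b6d2", "#c7c7c7", "#dbdb8d", "#9edae5")
}

#' Paired natural/reduced alignment view with cluster color indices
#'
#' For each sequence, emits the natural row, the reduced row, and the
#' per-position color index: the rank of the residue's cluster within the
#' scheme. The reduced row reuses exactly the same indices, so its palette
#' is a subset of the natural row's. Gaps and non-standard residues get
#' index `NA`.
#'
#' @param seqs named character vector of equal-length (pre-aligned)
#'   sequences; '-' allowed as gap.
#' @param scheme a [raac_scheme()].
#' @return a `raac_alignment_view`: list with `ids`, `natural` (character
#'   vector), `reduced`, `colors` (list of integer vectors), `palette`.
#' @export
alignment_view <- function(seqs, scheme) {
  stopifnot(inherits(scheme, "raac_scheme"), length(seqs) >= 1L)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must be pre-aligned to equal length; offending ids: ",
         paste(ids[lens != lens[1]], collapse = ", "), call. = FALSE)
  }
  map <- scheme_mapping(scheme)
  cluster_of <- integer(20)
  names(cluster_of) <- AA20
  for (i in seq_along(scheme$clusters)) {
    cluster_of[strsplit(scheme$clusters[i], "")[[1]]] <- i
  }
  natural <- toupper(unname(seqs))
  reduced <- character(length(seqs))
  colors <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    res <- residue_vector(seqs[s])
    std <- res %in% AA20
    out <- res
    out[std] <- map[res[std]]
    out[!std & res != "-"] <- "X"
    reduced[s] <- paste(out, collapse = "")
    ci <- rep(NA_integer_, length(res))
    ci[std] <- cluster_of[res[std]]
    colors[[s]] <- ci
  }
  structure(list(ids = ids, natural = natural, reduced = reduced,
                 colors = colors, palette = raac_palette()[seq_len(scheme$size)]),
            class = "raac_alignment_view")
}

#' Heat-map table and per-sequence top peptides for a feature matrix
#'
#' Passes the feature matrix through unchanged (rows in input order) and
#' lists, per sequence, the `top_n` highest-frequency tuple labels. Ties
#' are broken by column order (earlier column wins), so the output is
#' deterministic.
#'
#' @param features a `raac_features` object.
#' @param top_n number of top tuples per sequence (default 5).
#' @return list with `matrix` and `top` (data frame `id`, `rank`, `tuple`,
#'   `frequency`; frequencies non-increasing within a sequence).
#' @export
feature_heatmap_table <- function(features, top_n = 5L) {
  stopifnot(inherits(features, "raac_features"), top_n >= 1L)
  m <- features$matrix
  tops <- lapply(seq_len(nrow(m)), function(i) {
    ord <- order(-m[i, ], seq_len(ncol(m)))  # ties: earlier column wins
    take <- utils::head(ord, top_n)
    data.frame(id = rownames(m)[i], rank = seq_along(take),
               tuple = colnames(m)[take], frequency = unname(m[i, take]),
               stringsAsFactors = FALSE)
  })
  list(matrix = m, top = do.call(rbind, tops))
}
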
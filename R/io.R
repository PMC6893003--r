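# FASTA input/output and the synthetic two-class sequence generator.

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order as a named character vector of
#' upper-cased residue strings. Ids are the first whitespace-delimited
#' header token; full headers are kept in the `descriptions` attribute.
#' Stop codons (`*`) are stripped at read time. Duplicate ids are tolerated
#' with a warning (ids are not keys).
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences with attribute
#'   `descriptions`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' Standard FASTA with 60-column line wrapping.
#'
#' @param seqs named character vector of residue strings.
#' @param path output file path.
#' @param headers optional full header lines (defaults to the names of
#'   `seqs`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, headers = NULL) {
  if (length(seqs) == 0L) stop("no sequences to write", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (is.null(headers)) headers <- ids
  set <- Biostrings::AAStringSet(unname(as.character(seqs)))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write reduced sequences to a FASTA file
#'
#' Headers follow the convention `>{id} | scheme={type_id} size={R}` so a
#' reduced file records its provenance.
#'
#' @param reduced list of `raac_reduced` objects (from [reduce_sequence()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reduced_fasta <- function(reduced, path) {
  stopifnot(length(reduced) > 0L,
            all(vapply(reduced, inherits, logical(1), "raac_reduced")))
  seqs <- vapply(reduced, `[[`, character(1), "residues")
  ids <- vapply(reduced, function(r) {
    if (is.na(r$id)) "seq" else r$id
  }, character(1))
  headers <- vapply(reduced, function(r) {
    sprintf("%s | scheme=%s size=%s",
            if (is.na(r$id)) "seq" else r$id, r$scheme_key[1], r$scheme_key[2])
  }, character(1))
  names(seqs) <- ids
  write_fasta(seqs, path, headers = headers)
}

#' Background amino acid frequencies
#'
#' Average residue frequencies of well-characterized protein sequence
#' databases (Swiss-Prot composition statistics), normalized to sum to 1,
#' in canonical residue order. Used as the default background of the
#' synthetic sequence generator.
#'
#' @return named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.85,
         W = 1.10, Y = 2.92)
  f / sum(f)
}

#' Specification for the synthetic two-class generator
#'
#' Describes a planted-composition-bias study: negatives are drawn i.i.d.
#' from a background residue distribution; positives are drawn from the
#' same background with the probabilities of residues in the planted
#' clusters multiplied by `effect` and renormalized. `effect = 1` makes the
#' two classes exchangeable (the null).
#'
#' @param n_pos,n_neg class sizes (default 100 each, a typical benchmark
#'   scale for two-class protein studies).
#' @param length_range integer c(min, max) sequence length, drawn
#'   uniformly (default 80..120, globular-domain scale).
#' @param background named 20-vector of residue probabilities summing to 1
#'   (default [aa_background()]).
#' @param planted_clusters character vector of residue groups enriched in
#'   positives (default `"FWY"`, the aromatic cluster).
#' @param effect multiplicative enrichment factor >= 1 (default 2).
#' @param seed integer RNG seed (default 42).
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_pos = 100L, n_neg = 100L,
                           length_range = c(80L, 120L),
                           background = aa_background(),
                           planted_clusters = "FWY",
                           effect = 2, seed = 42L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2])
  background <- background[AA20]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-6) {
    stop("background must assign a probability to each of the 20 standard ",
         "residues and sum to 1", call. = FALSE)
  }
  if (effect < 1) stop("effect must be >= 1", call. = FALSE)
  planted <- unique(unlist(strsplit(toupper(planted_clusters), "")))
  bad <- setdiff(planted, AA20)
  if (length(bad) > 0L) {
    stop("planted cluster letters outside the 20-letter alphabet: ",
         paste(bad, collapse = ""), call. = FALSE)
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         length_range = as.integer(length_range), background = background,
         planted = planted, effect = effect, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic two-class protein sequence set
#'
#' Draws the positive and negative classes described by a
#' [synthetic_spec()]. Deterministic given the spec's seed; the caller's
#' RNG state is untouched.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `pos` and `neg`, each a named character vector of
#'   sequences (ids `pos1..`, `neg1..`).
#' @examples
#' sets <- generate_synthetic(synthetic_spec(n_pos = 5, n_neg = 5, seed = 1))
#' nchar(sets$pos)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p_neg <- spec$background
  p_pos <- spec$background
  p_pos[spec$planted] <- p_pos[spec$planted] * spec$effect
  p_pos <- p_pos / sum(p_pos)
  draw <- function(n, prefix, probs) {
    lens <- sample(spec$length_range[1]:spec$length_range[2], n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    names(seqs) <- paste0(prefix, seq_len(n))
    seqs
  }
  with_seed(spec$seed, {
    pos <- draw(spec$n_pos, "pos", p_pos)
    neg <- draw(spec$n_neg, "neg", p_neg)
    list(pos = pos, neg = neg)
  })
}
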